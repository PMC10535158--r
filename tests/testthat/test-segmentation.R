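test_that("rectangular_smooth preserves constants and handles edges by zero padding", {
  sig <- confidence_signal(rep(1, 100))
  sm <- rectangular_smooth(sig, 20)
  expect_length(sm, 100)
  expect_equal(sm$values[11:90], rep(1, 80))      # interior exact
  expect_lt(sm$values[1], 1)                      # edges diluted by padding
  expect_equal(rectangular_smooth(rep(0, 50), 7), rep(0, 50))
  expect_error(rectangular_smooth(sig, 0), "m must be")
  expect_error(rectangular_smooth(sig, -3), "m must be")
})

test_that("unit impulse smears to the frozen plateau computed by the convolution oracle", {
  x <- numeric(101)
  x[51] <- 1                                       # index 50, 0-based
  got <- rectangular_smooth(x, 10)
  expected <- box_conv_oracle(x, 10)
  expect_equal(got, expected, tolerance = 1e-12)
  # plateau of 0.1 over exactly the 10 windows containing the impulse
  expect_equal(sum(got > 0), 10L)
  expect_equal(unique(got[got > 0]), 0.1)
})

test_that("rectangular_smooth matches the direct convolution oracle on random signals", {
  set.seed(42)
  for (rep_i in 1:25) {
    n <- sample(5:60, 1)
    m <- sample(1:25, 1)
    x <- runif(n)
    expect_equal(rectangular_smooth(x, m), box_conv_oracle(x, m),
                 tolerance = 1e-9)
  }
})

test_that("rectangular_smooth is linear", {
  set.seed(7)
  x <- runif(80); y <- runif(80)
  a <- 0.3; b <- 1.7
  lhs <- rectangular_smooth(a * x + b * y, 13)
  rhs <- a * rectangular_smooth(x, 13) + b * rectangular_smooth(y, 13)
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("two box passes equal one pass with the self-convolved (triangular) kernel", {
  set.seed(8)
  for (m in c(4, 5, 10)) {
    # self-convolution of the box kernel, aligned to the implementation's
    # window anchor (offsets -floor(m/2) .. ceiling(m/2)-1 per pass).
    # The identity holds wherever neither pass's window is clipped by
    # the signal boundary; the two differ at the edges because each
    # pass zero-pads independently.
    box <- rep(1 / m, m)
    tri <- convolve(box, rev(box), type = "open")   # length 2m-1
    center <- 2L * (m %/% 2L) + 1L                  # offset 0 position
    x <- runif(70)
    double_pass <- rectangular_smooth(rectangular_smooth(x, m), m)
    oracle <- kernel_conv_oracle(x, tri, center)
    interior <- (2 * m):(70 - 2 * m)
    expect_equal(double_pass[interior], oracle[interior], tolerance = 1e-9)
  }
})

test_that("step_threshold uses a closed lower boundary and is idempotent on binary input", {
  expect_equal(step_threshold(c(0.005, 0.02, 0.5), 0.01), c(0, 1, 1))
  expect_equal(step_threshold(c(0.3, 0.49), 0.5), c(0, 0))
  b <- c(0, 1, 1, 0, 1)
  for (tau in c(0.01, 0.5, 1)) expect_equal(step_threshold(b, tau), b)
  sig <- confidence_signal(c(0.2, 0.6))
  expect_s3_class(step_threshold(sig, 0.5), "confidence_signal")
})

test_that("detect_contigs recovers well-separated noise-free events exactly one-to-one", {
  sched <- random_event_schedule(3, seed = 1)
  sig <- generate_signal(sched, signal_noise_model(
    dropout_prob = 0, spike_prob = 0, jitter_sd = 0, seed = 1))
  contigs <- detect_contigs(sig)
  expect_equal(nrow(contigs), 3L)
  ev <- evaluate_contigs(contigs, sched)
  expect_equal(ev$success_rate, 1.0)
  # oversizing: every true event is contained within its contig
  for (i in 1:3) {
    e <- sched$events[i, ]
    inside <- contigs$start_frame <= e$start_frame &
      contigs$end_frame >= e$end_frame
    expect_true(any(inside))
  }
})

test_that("an isolated low spike is diluted below threshold1 and yields no contig", {
  x <- numeric(200)
  x[100] <- 0.1
  # hand trace: first smoothing gives 0.1/20 = 0.005 < 0.01, so the
  # first step zeroes everything
  expect_equal(nrow(detect_contigs(confidence_signal(x))), 0L)
  expect_equal(nrow(detect_contigs(confidence_signal(numeric(150)))), 0L)
})

test_that("contigs are sorted, non-overlapping, and monotone in threshold1", {
  set.seed(33)
  for (s in 1:10) {
    sched <- random_event_schedule(4, seed = s)
    sig <- generate_signal(sched, stated_noise(s))
    ct <- detect_contigs(sig)
    if (nrow(ct) > 1L) {
      expect_true(all(diff(ct$start_frame) > 0))
      expect_true(all(ct$start_frame[-1L] >= ct$end_frame[-nrow(ct)]))
    }
    frames_at <- function(th1) {
      ct <- detect_contigs(sig, smoothing_chain_config(threshold1 = th1))
      sum(ct$end_frame - ct$start_frame)
    }
    expect_gte(frames_at(0.005), frames_at(0.01))
    expect_gte(frames_at(0.01), frames_at(0.05))
  }
})

test_that("evaluate_contigs implements the exactly-one-animal success rule", {
  sched <- event_schedule(data.frame(start_frame = c(10, 50),
                                     end_frame = c(30, 70)), 100)
  exact <- data.frame(contig_id = 0:1, start_frame = c(10L, 50L),
                      end_frame = c(30L, 70L))
  ev <- evaluate_contigs(exact, sched)
  expect_equal(ev$success_rate, 1.0)
  expect_equal(ev$n_missed + ev$n_merged + ev$n_spurious, 0L)

  merged <- data.frame(contig_id = 0L, start_frame = 5L, end_frame = 80L)
  ev2 <- evaluate_contigs(merged, sched)
  expect_equal(ev2$n_merged, 1L)
  expect_equal(ev2$success_rate, 0)

  # 10 events; 9 covered one-to-one, 1 uncovered
  sched10 <- event_schedule(data.frame(start_frame = seq(0, 900, by = 100),
                                       end_frame = seq(50, 950, by = 100)),
                            1000)
  nine <- data.frame(contig_id = 0:8,
                     start_frame = seq(0L, 800L, by = 100L),
                     end_frame = seq(55L, 855L, by = 100L))
  ev3 <- evaluate_contigs(nine, sched10)
  expect_equal(ev3$success_rate, 0.9)
  expect_equal(ev3$n_missed, 1L)

  # two contigs on one event: not a success for that event
  split2 <- data.frame(contig_id = 0:1, start_frame = c(10L, 20L),
                       end_frame = c(15L, 30L))
  ev4 <- evaluate_contigs(split2, event_schedule(
    data.frame(start_frame = 10, end_frame = 30), 50))
  expect_equal(ev4$success_rate, 0)
})

test_that("signal and contig CSVs round-trip", {
  sig <- confidence_signal(c(0, 0.25, 1, 0.5))
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_signal_csv(sig, p1)
  expect_equal(read_signal_csv(p1)$values, sig$values)

  ct <- data.frame(contig_id = 0:1, start_frame = c(3L, 20L),
                   end_frame = c(10L, 31L))
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_contigs_csv(ct, p2)
  expect_equal(read_contigs_csv(p2), ct)
})
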