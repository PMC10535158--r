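test_that("event schedules validate their invariants", {
  expect_error(event_schedule(data.frame(start_frame = 5, end_frame = 5), 10),
               "start < end")
  expect_error(event_schedule(data.frame(start_frame = c(0, 5),
                                         end_frame = c(6, 9)), 20),
               "not overlap")
  expect_error(event_schedule(NULL, 0), "n_frames = 0")
  s <- event_schedule(data.frame(start_frame = c(30, 5),
                                 end_frame = c(40, 10)), 50)
  expect_equal(s$events$start_frame, c(5L, 30L))   # sorted on construction
  expect_equal(sum(event_indicator(s)), 15)
})

test_that("noise-free signals equal the event indicator function exactly", {
  sched <- random_event_schedule(4, seed = 3)
  clean <- signal_noise_model(dropout_prob = 0, spike_prob = 0,
                              jitter_sd = 0, in_event_level = 1,
                              out_event_level = 0, seed = 3)
  sig <- generate_signal(sched, clean)
  expect_identical(sig$values, event_indicator(sched))
  expect_length(sig, sched$n_frames)
})

test_that("generate_signal is deterministic and separates in/out-event means", {
  sched <- random_event_schedule(3, seed = 4)
  noise <- signal_noise_model(dropout_prob = 0.3, spike_prob = 0.05,
                              spike_amplitude = 0.1, seed = 17)
  s1 <- generate_signal(sched, noise)
  s2 <- generate_signal(sched, noise)
  expect_identical(s1$values, s2$values)
  # recompute the means from the emitted arrays and the indicator
  ind <- event_indicator(sched)
  expect_gt(mean(s1$values[ind == 1]), mean(s1$values[ind == 0]))
  expect_true(all(s1$values >= 0 & s1$values <= 1))
})

test_that("signal_noise_model rejects inverted levels and bad probabilities", {
  expect_error(signal_noise_model(in_event_level = 0.2,
                                  out_event_level = 0.5),
               "must exceed")
  expect_error(signal_noise_model(dropout_prob = 1.3))
})

test_that("absent frames carry background only; present frames carry full ground truth", {
  g0 <- generate_frame(FALSE, image_size = c(64, 36), seed = 5)
  expect_false(g0$annotation$present)
  expect_null(g0$annotation$bbox)
  expect_equal(dim(g0$image), c(36, 64))
  expect_true(all(g0$image >= 0 & g0$image <= 255))

  g1 <- generate_frame(TRUE, "top",
                       pose = list(center = c(32, 18), angle = 0, scale = 8),
                       image_size = c(64, 36), seed = 5)
  a <- g1$annotation
  expect_true(a$present)
  expect_equal(rownames(a$keypoints), keypoint_names())
  expect_gt(a$quality, 0)
  expect_false(a$partial)
})

test_that("centered unrotated keypoints are symmetric about the vertical blob axis", {
  g <- generate_frame(TRUE, "top",
                      pose = list(center = c(64, 36), angle = 0, scale = 12),
                      image_size = c(128, 72), seed = 1)
  kp <- g$annotation$keypoints
  pairs <- list(c("crab_left", "crab_right"), c("left_eye", "right_eye"))
  for (p in pairs) {
    expect_equal(kp[p[1], "y"], kp[p[2], "y"], tolerance = 1)
    expect_equal(mean(kp[p, "x"]), 64, tolerance = 1)
  }
  for (nm in c("carapace_end", "tail_end", "last_segment"))
    expect_equal(kp[nm, "x"], 64, tolerance = 1)
})

test_that("frame rendering is deterministic and keypoints lie inside the bbox", {
  pose <- list(center = c(40, 30), angle = 0.7, scale = 10)
  g1 <- generate_frame(TRUE, "underside", pose, c(96, 54), "lobster", seed = 9)
  g2 <- generate_frame(TRUE, "underside", pose, c(96, 54), "lobster", seed = 9)
  expect_identical(g1$image, g2$image)

  set.seed(10)
  for (i in 1:10) {
    g <- generate_frame(TRUE, sample(c("top", "underside"), 1),
                        pose = list(center = c(runif(1, 35, 60),
                                               runif(1, 22, 32)),
                                    angle = runif(1, -pi, pi),
                                    scale = runif(1, 6, 10)),
                        image_size = c(96, 54),
                        species = sample(c("crab", "lobster"), 1),
                        seed = i)
    a <- g$annotation
    b <- a$bbox
    expect_true(all(a$keypoints[, "x"] >= b["x"] - 1e-9))
    expect_true(all(a$keypoints[, "x"] <= b["x"] + b["w"] + 1e-9))
    expect_true(all(a$keypoints[, "y"] >= b["y"] - 1e-9))
    expect_true(all(a$keypoints[, "y"] <= b["y"] + b["h"] + 1e-9))
    if (!a$partial) {
      expect_gte(b["x"], 0); expect_gte(b["y"], 0)
      expect_lte(b["x"] + b["w"], 96); expect_lte(b["y"] + b["h"], 54)
    }
  }
})

test_that("an oversized blob flags partial visibility and lowers quality", {
  small <- generate_frame(TRUE, "top",
                          pose = list(center = c(32, 18), angle = 0, scale = 6),
                          image_size = c(64, 36), seed = 2)
  huge <- generate_frame(TRUE, "top",
                         pose = list(center = c(32, 18), angle = 0, scale = 40),
                         image_size = c(64, 36), seed = 2)
  expect_true(huge$annotation$partial)
  expect_lt(huge$annotation$quality, small$annotation$quality)
})

test_that("generate_video emits runs of presence matching the schedule", {
  vid0 <- generate_video(event_schedule(NULL, 40), image_size = c(48, 27),
                         seed = 1, rgb = FALSE)
  expect_true(all(!vapply(vid0$annotations, `[[`, logical(1), "present")))

  vid <- local_test_video(3, seed = 2)
  pres <- vapply(vid$annotations, `[[`, logical(1), "present")
  runs <- rle(pres)
  expect_equal(sum(runs$values), 3L)       # exactly 3 maximal present runs
  # per-frame annotations consistent with the schedule
  expect_identical(pres * 1, event_indicator(vid$schedule))
})

test_that("the recorded best frame is the quality argmax within its event and view", {
  vid <- local_test_video(3, seed = 2)
  qual <- function(i, vw) {
    a <- vid$annotations[[i + 1L]]
    if (isTRUE(a$present) && a$view == vw) a$quality else -Inf
  }
  for (r in seq_len(nrow(vid$best_frames))) {
    row <- vid$best_frames[r, ]
    e <- vid$schedule$events[vid$schedule$events$event_id == row$event_id, ]
    frames <- e$start_frame:(e$end_frame - 1L)
    qs <- vapply(frames, qual, numeric(1), vw = row$view)
    expect_equal(row$frame, frames[which.max(qs)])
    expect_equal(row$quality, max(qs))
  }
})

test_that("overlapping events are rejected", {
  expect_error(event_schedule(data.frame(start_frame = c(0, 10),
                                         end_frame = c(20, 30)), 40),
               "not overlap")
})

test_that("video directories round-trip frames, schedule, signal and annotations", {
  sched <- random_event_schedule(1, min_len = 10, max_len = 12,
                                 min_gap = 5, max_gap = 8, seed = 6)
  vid <- generate_video(sched, stated_noise(6), image_size = c(32, 18),
                        seed = 6, rgb = FALSE)
  dir <- withr::local_tempdir()
  write_video_dir(vid, dir)
  back <- read_video_dir(dir)
  expect_identical(back$frames, vid$frames)
  expect_equal(back$signal$values, vid$signal$values)
  expect_equal(back$schedule$events, vid$schedule$events)
  for (i in seq_along(vid$annotations)) {
    a <- vid$annotations[[i]]; b <- back$annotations[[i]]
    expect_equal(b$present, a$present)
    if (a$present) {
      expect_equal(unname(b$bbox), unname(as.numeric(a$bbox)))
      expect_equal(unclass(b$keypoints), unclass(a$keypoints),
                   tolerance = 1e-9, ignore_attr = TRUE)
      expect_equal(b$quality, a$quality)
    }
  }
})

test_that("netpbm I/O round-trips both greyscale and RGB", {
  set.seed(3)
  g <- matrix(sample(0:255, 15 * 9, replace = TRUE), nrow = 9)
  p <- withr::local_tempfile(fileext = ".pgm")
  write_netpbm(g, p)
  expect_identical(read_netpbm(p), g * 1)
  rgb <- array(sample(0:255, 6 * 4 * 3, replace = TRUE), dim = c(4, 6, 3))
  p2 <- withr::local_tempfile(fileext = ".ppm")
  write_netpbm(rgb, p2)
  expect_identical(read_netpbm(p2), rgb * 1)
})
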