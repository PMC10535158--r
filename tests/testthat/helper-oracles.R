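# Independent oracles used across test files. These deliberately avoid
# the package's own code paths.

# Direct box-kernel convolution with zero padding: mean of the m samples
# at offsets -floor(m/2) .. ceiling(m/2)-1 around each index.
box_conv_oracle <- function(x, m) {
  n <- length(x)
  lo <- m %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (d in (-lo):(m - 1L - lo)) {
      j <- i + d
      if (j >= 1L && j <= n) acc <- acc + x[j]
    }
    out[i] <- acc / m
  }
  out
}

# General kernel convolution (zero padding), centred like the box above;
# used to check that two box passes equal one pass with the box
# self-convolution (triangular) kernel.
kernel_conv_oracle <- function(x, k, center) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (t in seq_along(k)) {
      j <- i + (t - center)
      if (j >= 1L && j <= n) acc <- acc + k[t] * x[j]
    }
    out[i] <- acc
  }
  out
}

# The noise parameters the desk-scale evaluation states: in-event level
# 1.0 with 30% dropout, 5% out-of-event spikes at amplitude 0.1, and no
# other noise source.
stated_noise <- function(seed) {
  signal_noise_model(in_event_level = 1.0, out_event_level = 0.0,
                     dropout_prob = 0.3, spike_prob = 0.05,
                     spike_amplitude = 0.1, jitter_sd = 0, seed = seed)
}

# Build (better, worse) frame pairs with strictly different quality.
quality_pairs <- function(frames, qualities, n_pairs, seed = 5) {
  set.seed(seed)
  bs <- list(); ws <- list()
  while (length(bs) < n_pairs) {
    ij <- sample(length(frames), 2L)
    if (abs(qualities[ij[1L]] - qualities[ij[2L]]) < 1e-6) next
    bs[[length(bs) + 1L]] <- frames[[ij[which.max(qualities[ij])]]]
    ws[[length(ws) + 1L]] <- frames[[ij[which.min(qualities[ij])]]]
  }
  list(better = bs, worse = ws)
}

# Small cached synthetic video shared by pipeline tests.
local_test_video <- local({
  cache <- new.env(parent = emptyenv())
  function(n_events = 3, seed = 2) {
    key <- paste0("v", n_events, "_", seed)
    if (is.null(cache[[key]])) {
      sched <- random_event_schedule(n_events, min_len = 40, max_len = 70,
                                     min_gap = 60, max_gap = 90, seed = seed)
      # 128x72 divides cleanly by the default classifier-path factor of 4
      cache[[key]] <- generate_video(sched, stated_noise(seed),
                                     image_size = c(128, 72), seed = seed)
    }
    cache[[key]]
  }
})
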