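#' Per-frame presence confidence signal
#'
#' A `confidence_signal` wraps the per-frame output of the lightweight
#' presence classifier: one value in `[0, 1]` per video frame, plus the
#' nominal frame rate. This volatile trace is the input to the temporal
#' segmentation chain.
#'
#' @param values numeric vector of confidences in `[0, 1]`
#' @param fps nominal frame rate (default 25, the deck camera rate)
#' @return an object of class `confidence_signal`
#' @seealso [detect_contigs()]
#' @export
confidence_signal <- function(values, fps = 25) {
  values <- as.numeric(values)
  if (anyNA(values) || any(values < 0 | values > 1))
    stop("confidence values must be in [0, 1] and non-missing")
  structure(list(values = values, fps = fps), class = "confidence_signal")
}

#' @export
print.confidence_signal <- function(x, ...) {
  cat(sprintf("<confidence_signal> %d frames @ %g fps, mean %.3f\n",
              length(x$values), x$fps, mean(x$values)))
  invisible(x)
}

#' @export
length.confidence_signal <- function(x) length(x$values)

as_signal_values <- function(signal) {
  if (inherits(signal, "confidence_signal")) signal$values else as.numeric(signal)
}

#' Smoothing-chain configuration
#'
#' Parameters of the two-pass rectangular-smoothing / step-threshold chain
#' used to extract contigs from the presence signal. The defaults are the
#' deployed values: a first smoothing window of 20 frames followed by a
#' very permissive threshold of 0.01 (so that any sustained activity
#' survives), then a second window of 10 frames and a final rounding
#' threshold of 0.5. At 25 fps the 20-frame window spans 0.8 s.
#'
#' @param window1,window2 box-window sizes (frames) of the two passes
#' @param threshold1,threshold2 step-function cutoffs in `(0, 1]`
#' @return an object of class `smoothing_chain_config`
#' @export
smoothing_chain_config <- function(window1 = 20, threshold1 = 0.01,
                                   window2 = 10, threshold2 = 0.5) {
  stopifnot(window1 >= 1, window2 >= 1,
            threshold1 > 0, threshold1 <= 1,
            threshold2 > 0, threshold2 <= 1)
  structure(list(window1 = as.integer(window1), threshold1 = threshold1,
                 window2 = as.integer(window2), threshold2 = threshold2),
            class = "smoothing_chain_config")
}

#' Rectangular (box) smoothing of a signal
#'
#' Replaces each sample by the mean of an `m`-wide window centred on it,
#' with indices outside the signal taken as zero. The window covers
#' samples `n - floor(m/2) .. n + ceiling(m/2) - 1` and the sum is divided
#' by exactly `m`, so constant signals are preserved in the interior.
#' Applied twice, box smoothing cheaply approximates triangular smoothing
#' while letting the two passes take different window sizes.
#'
#' @param signal a [confidence_signal()] or numeric vector
#' @param m window size in samples, `>= 1`
#' @return smoothed signal, same class and length as the input
#' @export
rectangular_smooth <- function(signal, m) {
  m <- as.integer(m)
  if (length(m) != 1L || is.na(m) || m < 1L) stop("window size m must be >= 1")
  x <- as_signal_values(signal)
  n <- length(x)
  if (n == 0L) return(signal)
  lo <- m %/% 2L                       # samples before n
  hi <- m - 1L - lo                    # samples after n
  padded <- c(rep(0, lo), x, rep(0, hi))
  out <- diff(cumsum(c(0, padded)), lag = m) / m
  if (inherits(signal, "confidence_signal"))
    confidence_signal(clamp(out, 0, 1), fps = signal$fps)
  else out
}

#' Step (hard threshold) function
#'
#' Maps each sample to 1 if it is `>= tau`, else 0. With `tau = 0.5` this
#' is round-half-up rounding of the smoothed signal.
#'
#' @inheritParams rectangular_smooth
#' @param tau cutoff in `(0, 1]`; a value equal to `tau` maps to 1
#' @return binary-valued signal of the same class and length
#' @export
step_threshold <- function(signal, tau) {
  stopifnot(length(tau) == 1L, tau > 0, tau <= 1)
  x <- as_signal_values(signal)
  out <- as.numeric(x >= tau)
  if (inherits(signal, "confidence_signal"))
    confidence_signal(out, fps = signal$fps)
  else out
}

#' Detect single-animal contigs in a presence signal
#'
#' Runs the four-stage chain smooth(`window1`) -> step(`threshold1`) ->
#' smooth(`window2`) -> step(`threshold2`) and returns the maximal runs of
#' 1s as contigs. Each contig is the pipeline's estimate of one
#' presentation event: the interval during which a fisher holds one
#' animal in view. Contigs are deliberately slightly oversized relative
#' to ground truth (a consequence of the window sizes), which ensures all
#' animal frames are collected.
#'
#' @inheritParams rectangular_smooth
#' @param config a [smoothing_chain_config()]
#' @return a data.frame with columns `contig_id`, `start_frame`
#'   (0-based, inclusive) and `end_frame` (exclusive), sorted and
#'   non-overlapping; zero rows if the signal contains no activity
#' @export
detect_contigs <- function(signal, config = smoothing_chain_config()) {
  x <- as_signal_values(signal)
  if (length(x) == 0L) return(contig_frame(integer(0), integer(0)))
  b <- step_threshold(
    rectangular_smooth(
      step_threshold(
        rectangular_smooth(x, config$window1),
        config$threshold1),
      config$window2),
    config$threshold2)
  runs <- rle(as_signal_values(b))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths
  keep <- runs$values == 1
  contig_frame(starts[keep], ends[keep])
}

contig_frame <- function(start, end) {
  data.frame(contig_id = seq_along(start) - 1L,
             start_frame = as.integer(start),
             end_frame = as.integer(end))
}

#' Score detected contigs against a ground-truth event schedule
#'
#' A contig and an event "overlap" when they share at least one frame.
#' A *success* is a contig that overlaps exactly one event, where that
#' event is overlapped by no other contig — i.e. the contig encompasses
#' exactly one animal. The success rate is successes divided by the
#' number of true events. Also reported: events missed entirely, contigs
#' merging two or more events (animals presented in quick succession),
#' and spurious contigs overlapping no event.
#'
#' @param contigs data.frame as returned by [detect_contigs()]
#' @param truth an [event_schedule()] of ground-truth presentation events
#' @return list with `success_rate`, `n_missed`, `n_merged`, `n_spurious`
#' @export
evaluate_contigs <- function(contigs, truth) {
  ev <- truth$events
  n_events <- nrow(ev)
  n_contigs <- nrow(contigs)
  if (n_events == 0L) {
    return(list(success_rate = NaN, n_missed = 0L, n_merged = 0L,
                n_spurious = n_contigs))
  }
  # overlap matrix: contigs x events (half-open interval intersection)
  ov <- matrix(FALSE, nrow = max(n_contigs, 0L), ncol = n_events)
  if (n_contigs > 0L) {
    for (i in seq_len(n_contigs)) {
      ov[i, ] <- contigs$start_frame[i] < ev$end_frame &
                 ev$start_frame < contigs$end_frame[i]
    }
  }
  events_per_contig <- if (n_contigs) rowSums(ov) else integer(0)
  contigs_per_event <- colSums(ov)
  successes <- 0L
  if (n_contigs) {
    for (i in seq_len(n_contigs)) {
      if (events_per_contig[i] == 1L) {
        j <- which(ov[i, ])
        if (contigs_per_event[j] == 1L) successes <- successes + 1L
      }
    }
  }
  list(success_rate = successes / n_events,
       n_missed = sum(contigs_per_event == 0L),
       n_merged = sum(events_per_contig >= 2L),
       n_spurious = sum(events_per_contig == 0L))
}

#' Signal and contig CSV interchange
#'
#' Signals are stored as a single-column CSV (`confidence`, one row per
#' frame); contigs as `contig_id,start_frame,end_frame`.
#'
#' @param signal a [confidence_signal()]
#' @param path file path
#' @param fps frame rate to attach on read
#' @return the read object, or the path (invisibly) on write
#' @export
write_signal_csv <- function(signal, path) {
  write.csv(data.frame(confidence = as_signal_values(signal)),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal_csv
#' @export
read_signal_csv <- function(path, fps = 25) {
  confidence_signal(read.csv(path)$confidence, fps = fps)
}

#' @rdname write_signal_csv
#' @param contigs contig data.frame
#' @export
write_contigs_csv <- function(contigs, path) {
  write.csv(contigs[, c("contig_id", "start_frame", "end_frame")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal_csv
#' @export
read_contigs_csv <- function(path) {
  df <- read.csv(path)
  contig_frame(df$start_frame, df$end_frame)
}
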