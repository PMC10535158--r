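#' Ground-truth presentation-event schedules
#'
#' An `event_schedule` lists the half-open frame intervals
#' `[start_frame, end_frame)` during which an animal is presented to the
#' camera, over a video of `n_frames` frames. Events are sorted and
#' non-overlapping: the pipeline assumes each animal enters and leaves
#' the frame exactly once.
#'
#' @param events data.frame (or 2-column matrix) with `start_frame`,
#'   `end_frame`; 0-based, half-open
#' @param n_frames total number of frames in the video
#' @return an object of class `event_schedule`
#' @export
event_schedule <- function(events, n_frames) {
  if (is.matrix(events)) {
    events <- data.frame(start_frame = events[, 1L], end_frame = events[, 2L])
  }
  if (is.null(events) || nrow(events) == 0L) {
    events <- data.frame(start_frame = integer(0), end_frame = integer(0))
  }
  n_frames <- as.integer(n_frames)
  if (n_frames < 0L) stop("n_frames must be >= 0")
  if (n_frames == 0L && nrow(events) == 0L)
    stop("empty schedule with n_frames = 0 describes no video at all")
  ev <- events[order(events$start_frame), , drop = FALSE]
  ev$start_frame <- as.integer(ev$start_frame)
  ev$end_frame <- as.integer(ev$end_frame)
  if (nrow(ev)) {
    if (any(ev$start_frame < 0L) || any(ev$end_frame > n_frames) ||
        any(ev$start_frame >= ev$end_frame))
      stop("events must satisfy 0 <= start < end <= n_frames")
    if (nrow(ev) > 1L && any(ev$start_frame[-1L] < ev$end_frame[-nrow(ev)]))
      stop("events must not overlap: each animal is presented just once")
  }
  ev$event_id <- seq_len(nrow(ev)) - 1L
  structure(list(events = ev[, c("event_id", "start_frame", "end_frame")],
                 n_frames = n_frames),
            class = "event_schedule")
}

#' @export
print.event_schedule <- function(x, ...) {
  cat(sprintf("<event_schedule> %d events over %d frames\n",
              nrow(x$events), x$n_frames))
  invisible(x)
}

#' @rdname event_schedule
#' @return `event_indicator()` returns the 0/1 presence vector of length
#'   `n_frames`.
#' @param schedule an `event_schedule`
#' @export
event_indicator <- function(schedule) {
  ind <- numeric(schedule$n_frames)
  for (i in seq_len(nrow(schedule$events))) {
    a <- schedule$events$start_frame[i]
    b <- schedule$events$end_frame[i]
    ind[(a + 1L):b] <- 1
  }
  ind
}

#' Draw a random, well-separated event schedule
#'
#' Emulates a sorting session on deck: each presentation lasts a few
#' seconds (default 50--150 frames at 25 fps, i.e. 2--6 s) and animals
#' are separated by at least `min_gap` frames of empty deck. Gap and
#' length are drawn uniformly per event.
#'
#' @param n_events number of presentation events
#' @param min_len,max_len event length bounds (frames)
#' @param min_gap,max_gap inter-event (and leading/trailing) gap bounds
#' @param seed integer seed; the schedule is a pure function of its
#'   arguments
#' @return an [event_schedule()]
#' @export
random_event_schedule <- function(n_events, min_len = 50, max_len = 150,
                                  min_gap = 60, max_gap = 150, seed = 0) {
  stopifnot(n_events >= 0, min_len >= 1, max_len >= min_len,
            min_gap >= 0, max_gap >= min_gap)
  with_seed(seed, {
    lens <- if (n_events) sample(min_len:max_len, n_events, replace = TRUE) else integer(0)
    gaps <- sample(min_gap:max_gap, n_events + 1L, replace = TRUE)
    starts <- cumsum(gaps[seq_len(n_events)] +
                       c(0L, lens[-length(lens)][seq_len(max(0L, n_events - 1L))]))
    if (n_events == 0L) starts <- integer(0)
    ends <- starts + lens
    n_frames <- (if (n_events) ends[n_events] else 0L) + gaps[n_events + 1L]
    event_schedule(data.frame(start_frame = starts, end_frame = ends),
                   n_frames = n_frames)
  })
}

#' Noise model for the synthetic presence classifier
#'
#' Emulates the volatile output stream of a lightweight presence
#' classifier run frame-by-frame over a video: in-event frames read near
#' `in_event_level` but occasionally drop out (momentary detection loss),
#' out-of-event frames read near `out_event_level` but occasionally spike
#' (splashes, shadows), and Gaussian jitter is superimposed everywhere.
#' The defaults correspond to the "moderate noise" condition used by the
#' desk-scale evaluation: 30\% in-event dropout and 5\% out-of-event
#' spikes of amplitude 0.1.
#'
#' @param in_event_level mean confidence while an animal is present
#' @param out_event_level baseline confidence on empty frames
#' @param dropout_prob probability an in-event frame reads low
#' @param spike_prob probability an out-of-event frame reads high
#' @param spike_amplitude confidence of a spurious spike
#' @param jitter_sd standard deviation of additive Gaussian jitter
#' @param seed integer seed
#' @return an object of class `signal_noise_model`
#' @export
signal_noise_model <- function(in_event_level = 1.0, out_event_level = 0.0,
                               dropout_prob = 0.3, spike_prob = 0.05,
                               spike_amplitude = 0.1, jitter_sd = 0.02,
                               seed = 0) {
  probs <- c(dropout_prob, spike_prob)
  stopifnot(all(probs >= 0 & probs <= 1),
            in_event_level >= 0, in_event_level <= 1,
            out_event_level >= 0, out_event_level <= 1,
            spike_amplitude >= 0, spike_amplitude <= 1,
            jitter_sd >= 0)
  if (in_event_level <= out_event_level)
    stop("in_event_level must exceed out_event_level")
  structure(list(in_event_level = in_event_level,
                 out_event_level = out_event_level,
                 dropout_prob = dropout_prob, spike_prob = spike_prob,
                 spike_amplitude = spike_amplitude, jitter_sd = jitter_sd,
                 seed = as.integer(seed)),
            class = "signal_noise_model")
}

#' Generate a noisy presence-confidence signal
#'
#' Produces the per-frame confidence trace the real presence classifier
#' would emit over a video with the given ground-truth schedule, under
#' the given noise model. In the noise-free limit (no dropout, no
#' spikes, no jitter, levels 1 and 0) the signal equals the event
#' indicator function exactly. Deterministic for a fixed
#' `noise$seed`.
#'
#' @param schedule an [event_schedule()]
#' @param noise a [signal_noise_model()]
#' @param fps frame rate recorded on the signal
#' @return a [confidence_signal()] of length `schedule$n_frames`
#' @export
generate_signal <- function(schedule, noise = signal_noise_model(), fps = 25) {
  ind <- event_indicator(schedule)
  n <- length(ind)
  vals <- with_seed(noise$seed, {
    v <- ifelse(ind == 1, noise$in_event_level, noise$out_event_level)
    if (n > 0L) {
      drop <- runif(n) < noise$dropout_prob
      v[ind == 1 & drop] <- noise$out_event_level
      spike <- runif(n) < noise$spike_prob
      v[ind == 0 & spike] <- noise$spike_amplitude
      if (noise$jitter_sd > 0) v <- v + rnorm(n, sd = noise$jitter_sd)
    }
    clamp(v, 0, 1)
  })
  confidence_signal(vals, fps = fps)
}

# -- synthetic frame rendering ------------------------------------------------

#' The seven named anatomical keypoints
#'
#' Canonical order of the landmarks regressed by the keypoint model:
#' carapace width points for crabs, eye/carapace/tail landmarks for
#' lobsters. This order defines the 14-value flat coordinate vector.
#'
#' @return character vector of the 7 names
#' @export
keypoint_names <- function() {
  c("crab_left", "crab_right", "left_eye", "right_eye",
    "carapace_end", "tail_end", "last_segment")
}

# Local (unrotated) keypoint offsets for a blob with semi-axes a (along
# the head->tail axis) and b (across). u runs head (-) to tail (+).
blob_keypoints_local <- function(a, b) {
  rbind(crab_left    = c(u = 0,       v = -b),
        crab_right   = c(u = 0,       v =  b),
        left_eye     = c(u = -0.9 * a, v = -0.25 * b),
        right_eye    = c(u = -0.9 * a, v =  0.25 * b),
        carapace_end = c(u = a,        v = 0),
        last_segment = c(u = 1.25 * a, v = 0),
        tail_end     = c(u = 1.5 * a,  v = 0))[keypoint_names(), , drop = FALSE]
}

#' Render one synthetic deck frame with ground truth
#'
#' The synthetic animal is an elongated two-tone blob: a filled ellipse
#' body with a triangular tail extension and a brighter head disc, so
#' orientation and landmarks are visually recoverable. The view is
#' encoded as texture — `top` is solid, `underside` is banded along the
#' body axis — giving view-specific frame scorers a learnable cue.
#' Species alters the aspect ratio (crabs wide, lobsters elongated).
#'
#' The returned annotation carries presence, view, species, a tight
#' bounding box, the 7 keypoints, and a quality label in `[0, 1]`
#' computed as centrality x scale-fitness x (1 - blur) x visible
#' fraction — mirroring hand-labelled "representativeness" (subject
#' central, well-sized, unblurred, fully in frame).
#'
#' @param present logical; if `FALSE` only textured background is drawn
#' @param view `"top"` or `"underside"`
#' @param pose list with `center` (x, y pixels), `angle` (radians,
#'   0 = body axis vertical), `scale` (body semi-axis a in pixels) and
#'   optional `blur` in `[0, 1)`
#' @param image_size `c(w, h)` in pixels
#' @param species `"crab"` or `"lobster"`
#' @param seed integer seed for the background texture
#' @return list with `image` (greyscale matrix) and `annotation`
#' @export
generate_frame <- function(present, view = c("top", "underside"),
                           pose = list(center = NULL, angle = 0, scale = 12,
                                       blur = 0),
                           image_size = c(128, 72),
                           species = c("crab", "lobster"), seed = 0) {
  view <- match.arg(view)
  species <- match.arg(species)
  w <- image_size[1L]; h <- image_size[2L]
  blur <- pose$blur %||% 0
  img <- with_seed(seed, {
    bg <- matrix(90 + 15 * rnorm(h * w), nrow = h, ncol = w)
    rectangular_blur_2d(bg, 3L)    # low-frequency deck texture
  })
  ann <- list(present = isTRUE(present), view = view,
              species = species, bbox = NULL, keypoints = NULL,
              quality = NULL, partial = FALSE)
  if (!present) {
    ann$present <- FALSE
    return(list(image = clamp(round(img), 0, 255),
                annotation = structure(ann, class = "scene_annotation")))
  }
  center <- pose$center %||% c(w / 2, h / 2)
  angle <- pose$angle %||% 0
  a <- pose$scale %||% 12
  b <- if (species == "crab") 0.8 * a else 0.38 * a
  # pixel grid in blob-local coordinates (u along axis, v across);
  # angle = 0 puts the axis vertical (u maps to +y)
  xs <- matrix(rep(seq_len(w) - 1, each = h), nrow = h)
  ys <- matrix(rep(seq_len(h) - 1, times = w), nrow = h)
  dx <- xs - center[1L]; dy <- ys - center[2L]
  u <- sin(angle) * dx + cos(angle) * dy
  v <- cos(angle) * dx - sin(angle) * dy
  body <- (u / a)^2 + (v / b)^2 <= 1
  tail_w <- clamp(0.6 * b * (1.5 * a - u) / (0.5 * a), 0, 0.6 * b)
  tail <- u >= 0 & u <= 1.5 * a & abs(v) <= tail_w
  mask <- body | tail
  tone <- if (view == "top") {
    matrix(195, nrow = h, ncol = w)
  } else {
    170 + 50 * ((floor(u / (0.35 * a)) %% 2 == 0) * 1)
  }
  img[mask] <- tone[mask]
  head_d <- ((u + 0.75 * a) / (0.3 * a))^2 + (v / (0.45 * b))^2 <= 1
  img[head_d] <- 240
  if (blur > 0) {
    k <- 1L + 2L * ceiling(3 * blur)
    img <- rectangular_blur_2d(img, k)
  }
  # ground-truth keypoints: rotate local offsets into image coordinates
  kp_local <- blob_keypoints_local(a, b)
  kx <- center[1L] + cos(angle) * kp_local[, "v"] + sin(angle) * kp_local[, "u"]
  ky <- center[2L] + cos(angle) * kp_local[, "u"] - sin(angle) * kp_local[, "v"]
  kp <- cbind(x = kx, y = ky)
  # tight bbox of the blob mask, expanded to cover the keypoints
  idx <- which(mask | head_d, arr.ind = TRUE)
  n_mask <- nrow(idx)
  x0 <- min(idx[, 2L] - 1, floor(kp[, "x"]))
  x1 <- max(idx[, 2L] - 1, ceiling(kp[, "x"]))
  y0 <- min(idx[, 1L] - 1, floor(kp[, "y"]))
  y1 <- max(idx[, 1L] - 1, ceiling(kp[, "y"]))
  partial <- x0 < 0 || y0 < 0 || x1 >= w || y1 >= h ||
    any(kp[, "x"] < 0 | kp[, "x"] >= w | kp[, "y"] < 0 | kp[, "y"] >= h)
  bx0 <- max(x0, 0); by0 <- max(y0, 0)
  bbox <- c(x = bx0, y = by0,
            w = min(x1, w - 1L) - bx0 + 1, h = min(y1, h - 1L) - by0 + 1)
  # quality label: centrality * scale fitness * (1 - blur) * visibility
  half_diag <- sqrt((w / 2)^2 + (h / 2)^2)
  centrality <- clamp(1 - sqrt(sum((center - c(w / 2, h / 2))^2)) / half_diag, 0, 1)
  ideal <- 0.18 * min(w, h)
  scale_fit <- clamp(1 - abs(a - ideal) / ideal, 0, 1)
  # visible fraction: rendered mask pixels relative to unclipped blob area
  full_area <- pi * a * b + 0.5 * (1.5 * a) * (1.2 * b)
  visibility <- clamp(n_mask / full_area, 0, 1)
  if (!partial) visibility <- 1
  quality <- centrality * scale_fit * (1 - blur) * visibility
  ann$bbox <- bbox
  ann$keypoints <- kp
  ann$quality <- quality
  ann$partial <- partial
  list(image = clamp(round(img), 0, 255),
       annotation = structure(ann, class = "scene_annotation"))
}

# cheap 2-D box blur (replicate edges), used for texture and motion blur
rectangular_blur_2d <- function(img, k) {
  if (k <= 1L) return(img)
  smooth1 <- function(m) {
    n <- nrow(m); lo <- k %/% 2L; hi <- k - 1L - lo
    pad <- rbind(m[rep(1L, lo), , drop = FALSE], m,
                 m[rep(n, hi), , drop = FALSE])
    apply(pad, 2L, function(col) diff(cumsum(c(0, col)), lag = k) / k)
  }
  t(smooth1(t(smooth1(img))))
}

#' Generate a full synthetic deck video with ground truth
#'
#' Renders a frame sequence in which one animal per scheduled event moves
#' into frame, dwells near the centre (where motion blur is lowest and
#' quality peaks), flips from top to underside view midway through the
#' presentation, and moves out again. Frames outside events contain only
#' background. The per-frame annotations, the schedule, and the
#' ground-truth best frame of each event and view (the quality argmax)
#' are returned alongside the frames.
#'
#' @param schedule an [event_schedule()]; events must not overlap
#' @param noise a [signal_noise_model()] used by [generate_signal()] to
#'   emit the matching synthetic classifier signal
#' @param image_size `c(w, h)` pixels
#' @param seed master seed driving poses, species and textures
#' @param rgb if `TRUE`, frames are emitted as H x W x 3 arrays (the
#'   synthetic camera is achromatic, so all channels are equal)
#' @return list with `frames` (list of images), `annotations` (list of
#'   scene annotations), `schedule`, `signal` (a [confidence_signal()]),
#'   `species` (per event) and `best_frames` (data.frame `event_id`,
#'   `view`, `frame`, `quality`)
#' @export
generate_video <- function(schedule, noise = signal_noise_model(),
                           image_size = c(128, 72), seed = 0, rgb = TRUE) {
  ev <- schedule$events
  n <- schedule$n_frames
  w <- image_size[1L]; h <- image_size[2L]
  par <- with_seed(seed, {
    list(species = if (nrow(ev)) sample(c("crab", "lobster"), nrow(ev),
                                        replace = TRUE) else character(0),
         scale = round(runif(max(1, nrow(ev)), 0.14, 0.22) * min(w, h)),
         angle0 = runif(max(1, nrow(ev)), -0.4, 0.4),
         bg_seed = sample.int(1e6, 1L))
  })
  frames <- vector("list", n)
  anns <- vector("list", n)
  for (f in seq_len(n)) {
    fi <- f - 1L
    ei <- which(ev$start_frame <= fi & fi < ev$end_frame)
    if (length(ei) == 0L) {
      g <- generate_frame(FALSE, image_size = image_size,
                          seed = par$bg_seed + f)
    } else {
      len <- ev$end_frame[ei] - ev$start_frame[ei]
      t01 <- (fi - ev$start_frame[ei] + 0.5) / len      # progress in (0,1)
      # enter from the left, dwell centred, leave right; blur when moving
      excursion <- 0.5 * w * cos(pi * t01)              # +w/2 .. -w/2
      cx <- w / 2 - excursion * 0.9
      cy <- h / 2 + 0.1 * h * sin(2 * pi * t01)
      blur <- clamp(0.6 * abs(cos(pi * t01)), 0, 0.6)
      view <- if (t01 < 0.5) "top" else "underside"
      g <- generate_frame(TRUE, view = view,
                          pose = list(center = c(cx, cy),
                                      angle = par$angle0[ei] * cos(2 * t01),
                                      scale = par$scale[ei], blur = blur),
                          image_size = image_size,
                          species = par$species[ei],
                          seed = par$bg_seed + f)
      g$annotation$event_id <- ev$event_id[ei]
    }
    if (rgb) {
      g$image <- array(rep(g$image, 3L), dim = c(h, w, 3L))
    }
    frames[[f]] <- g$image
    anns[[f]] <- g$annotation
  }
  # ground-truth best frame per (event, view) = quality argmax
  best <- list()
  for (i in seq_len(nrow(ev))) {
    for (vw in c("top", "underside")) {
      in_ev <- (ev$start_frame[i] + 1L):ev$end_frame[i]
      qs <- vapply(anns[in_ev], function(a)
        if (isTRUE(a$present) && a$view == vw) a$quality else -Inf, numeric(1))
      if (all(!is.finite(qs))) next
      k <- which.max(qs)
      best[[length(best) + 1L]] <- data.frame(
        event_id = ev$event_id[i], view = vw,
        frame = in_ev[k] - 1L, quality = qs[k])
    }
  }
  best <- if (length(best)) do.call(rbind, best) else
    data.frame(event_id = integer(0), view = character(0),
               frame = integer(0), quality = numeric(0))
  list(frames = frames, annotations = anns, schedule = schedule,
       signal = generate_signal(schedule, noise),
       species = par$species, best_frames = best)
}

# -- schedule / annotation I/O ------------------------------------------------

#' Schedule and annotation sidecar I/O
#'
#' Schedules travel as CSV (`event_id,start_frame,end_frame`);
#' annotations as a JSON sidecar (one object per frame); videos as a
#' directory of ASCII NetPBM frames (see [write_netpbm()]).
#'
#' @param schedule an [event_schedule()]
#' @param path file path
#' @export
write_schedule_csv <- function(schedule, path) {
  write.csv(schedule$events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @param n_frames total frame count (required on read; CSV stores only
#'   events)
#' @export
read_schedule_csv <- function(path, n_frames) {
  df <- read.csv(path)
  event_schedule(df[, c("start_frame", "end_frame")], n_frames = n_frames)
}

#' @rdname write_schedule_csv
#' @param annotations list of scene annotations
#' @export
write_annotations_json <- function(annotations, path) {
  ser <- lapply(seq_along(annotations), function(i) {
    a <- annotations[[i]]
    out <- list(frame = i - 1L, present = a$present)
    if (isTRUE(a$present)) {
      out$view <- a$view
      out$species <- a$species
      out$bbox <- unname(as.numeric(a$bbox))
      out$keypoints <- apply(a$keypoints, 1L, as.numeric, simplify = FALSE)
      out$quality <- a$quality
      out$partial <- a$partial
      if (!is.null(a$event_id)) out$event_id <- a$event_id
    }
    out
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_annotations_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(a) {
    out <- list(present = isTRUE(a$present))
    if (out$present) {
      out$view <- a$view
      out$species <- a$species
      out$bbox <- c(x = a$bbox[[1L]], y = a$bbox[[2L]],
                    w = a$bbox[[3L]], h = a$bbox[[4L]])
      kp <- t(vapply(a$keypoints, function(p) c(p[[1L]], p[[2L]]), numeric(2)))
      dimnames(kp) <- list(names(a$keypoints), c("x", "y"))
      out$keypoints <- kp[keypoint_names(), , drop = FALSE]
      out$quality <- a$quality
      out$partial <- isTRUE(a$partial)
      out$event_id <- a$event_id
    }
    structure(out, class = "scene_annotation")
  })
}

#' @rdname write_schedule_csv
#' @param video a list as returned by [generate_video()]
#' @param dir output directory (created if needed)
#' @export
write_video_dir <- function(video, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(video$frames)) {
    img <- video$frames[[i]]
    ext <- if (is_grey(img)) "pgm" else "ppm"
    write_netpbm(img, file.path(dir, sprintf("frame_%06d.%s", i - 1L, ext)))
  }
  write_schedule_csv(video$schedule, file.path(dir, "schedule.csv"))
  write_annotations_json(video$annotations, file.path(dir, "annotations.json"))
  write_signal_csv(video$signal, file.path(dir, "signal.csv"))
  invisible(dir)
}

#' @rdname write_schedule_csv
#' @export
read_video_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.(pgm|ppm)$",
                           full.names = TRUE))
  frames <- lapply(files, read_netpbm)
  anns <- read_annotations_json(file.path(dir, "annotations.json"))
  signal <- read_signal_csv(file.path(dir, "signal.csv"))
  schedule <- read_schedule_csv(file.path(dir, "schedule.csv"),
                                n_frames = length(frames))
  list(frames = frames, annotations = anns, schedule = schedule,
       signal = signal)
}
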