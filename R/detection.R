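#' Detections and pluggable object detectors
#'
#' The production pipeline localises the animal in each selected
#' full-resolution frame with an unmodified off-the-shelf object
#' detector; this package defines the *contract* — a detector is any
#' function `f(image, frame_index) -> detection or NULL` — plus two
#' reference backends: [mock_detector()], backed by synthetic ground
#' truth (optionally jittered), and [blob_detector()], a heuristic that
#' thresholds the bright foreground blob and classifies by elongation.
#'
#' @param bbox `c(x, y, w, h)` in pixels, 0-based top-left corner
#' @param class_label `"crab"` or `"lobster"`
#' @param confidence detector confidence in `[0, 1]`
#' @return `detection()` returns an object of class `detection`
#' @export
detection <- function(bbox, class_label, confidence = 1) {
  stopifnot(length(bbox) == 4L, bbox[3L] > 0, bbox[4L] > 0,
            class_label %in% c("crab", "lobster"),
            confidence >= 0, confidence <= 1)
  structure(list(bbox = c(x = bbox[[1L]], y = bbox[[2L]],
                          w = bbox[[3L]], h = bbox[[4L]]),
                 class_label = class_label, confidence = confidence),
            class = "detection")
}

#' @export
print.detection <- function(x, ...) {
  cat(sprintf("<detection> %s (%.2f) bbox x=%g y=%g w=%g h=%g\n",
              x$class_label, x$confidence, x$bbox["x"], x$bbox["y"],
              x$bbox["w"], x$bbox["h"]))
  invisible(x)
}

#' Run a detector on one full-resolution frame
#'
#' Thin dispatch honouring the stage contract: the frame is passed
#' unresized (the measurement path never resamples), and the detector's
#' highest-confidence detection — or `NULL` when nothing is found — is
#' returned. Callers log and skip contigs whose selected frame yields no
#' detection.
#'
#' @param image full-resolution frame
#' @param detector function `f(image, frame_index)` returning a
#'   [detection()] or `NULL`
#' @param frame_index 0-based index, forwarded to the detector (mock
#'   backends key on it)
#' @return a [detection()] or `NULL`
#' @export
detect <- function(image, detector, frame_index = NULL) {
  det <- detector(image, frame_index)
  if (is.null(det)) return(NULL)
  stopifnot(inherits(det, "detection"))
  det
}

#' @rdname detect
#' @param annotations per-frame synthetic scene annotations
#' @param jitter_sd Gaussian jitter (pixels) added to the true box
#'   corners, emulating detector localisation error
#' @param seed seed for the jitter stream
#' @export
mock_detector <- function(annotations, jitter_sd = 0, seed = 0) {
  force(annotations)
  counter <- new.env(parent = emptyenv())
  counter$calls <- 0L
  rng_seed <- seed
  f <- function(image, frame_index) {
    counter$calls <- counter$calls + 1L
    a <- annotations[[frame_index + 1L]]
    if (!isTRUE(a$present)) return(NULL)
    b <- as.numeric(a$bbox)
    if (jitter_sd > 0) {
      b <- with_seed(rng_seed + frame_index, b + rnorm(4L, sd = jitter_sd))
      b[3:4] <- pmax(b[3:4], 1)
    }
    detection(b, a$species, confidence = 0.95)
  }
  attr(f, "calls") <- function() counter$calls
  f
}

#' @rdname detect
#' @param fg_threshold intensity above which a pixel counts as
#'   foreground (synthetic deck background sits near 90, animals above
#'   160)
#' @param min_pixels minimum foreground pixel count for a detection
#' @param elongation_cutoff major/minor second-moment ratio above which
#'   the blob is classified as a lobster rather than a crab
#' @export
blob_detector <- function(fg_threshold = 150, min_pixels = 20,
                          elongation_cutoff = 2.2) {
  function(image, frame_index = NULL) {
    if (!is_grey(image)) image <- to_greyscale(image)
    idx <- which(image >= fg_threshold, arr.ind = TRUE)
    if (nrow(idx) < min_pixels) return(NULL)
    ys <- idx[, 1L] - 1; xs <- idx[, 2L] - 1
    bbox <- c(min(xs), min(ys), max(xs) - min(xs) + 1, max(ys) - min(ys) + 1)
    # classify by elongation of the foreground point cloud
    cc <- stats::cov(cbind(xs, ys))
    ev <- eigen(cc, symmetric = TRUE, only.values = TRUE)$values
    ratio <- sqrt(max(ev) / max(min(ev), 1e-9))
    cls <- if (ratio > elongation_cutoff) "lobster" else "crab"
    detection(bbox, cls, confidence = min(1, nrow(idx) / (4 * min_pixels)))
  }
}

#' Derive the dataset-wide fixed crop size
#'
#' The keypoint model needs a consistent input shape, so crops are cut
#' at one fixed size: the arithmetic mean of the detector's bounding-box
#' widths and heights over a dataset, rounded to the nearest even
#' integer (even sizes keep the pooling arithmetic clean). On the study
#' data this procedure yielded 560 x 540; it depends entirely on the
#' dataset.
#'
#' @param detections list of [detection()] objects
#' @return list with integer `crop_w`, `crop_h` (class `crop_spec`)
#' @export
derive_crop_size <- function(detections) {
  if (length(detections) == 0L) stop("no detections: cannot derive crop size")
  ws <- vapply(detections, function(d) d$bbox[["w"]], numeric(1))
  hs <- vapply(detections, function(d) d$bbox[["h"]], numeric(1))
  crop_spec(even_round(mean(ws)), even_round(mean(hs)))
}

# nearest even integer, ties rounding up (33 -> 34)
even_round <- function(x) as.integer(2 * floor(x / 2 + 0.5))

#' @rdname derive_crop_size
#' @param crop_w,crop_h crop dimensions in pixels
#' @export
crop_spec <- function(crop_w, crop_h) {
  stopifnot(crop_w > 0, crop_h > 0)
  structure(list(crop_w = as.integer(crop_w), crop_h = as.integer(crop_h)),
            class = "crop_spec")
}

#' Cut a fixed-size ROI around a detection, without resampling
#'
#' Centres a `crop_w x crop_h` window on the bounding-box centre and
#' translates it — never scales it — as needed to stay fully inside the
#' image. Every output pixel is a bit-identical copy of a source pixel:
#' no interpolation is permitted anywhere on the measurement path, since
#' keypoint-derived measurements inherit any warping.
#'
#' @param image full-resolution frame (greyscale or RGB)
#' @param det a [detection()]
#' @param spec a [crop_spec()]; must fit inside the image
#' @return list of class `roi_crop`: `image` (the crop), `x0`, `y0`
#'   (0-based offset of the crop in the source frame), `spec`
#' @export
crop_fixed <- function(image, det, spec) {
  d <- dim(image)
  h <- d[1L]; w <- d[2L]
  if (spec$crop_w > w || spec$crop_h > h)
    stop(sprintf("crop %dx%d exceeds image %dx%d; never downscale",
                 spec$crop_w, spec$crop_h, w, h))
  cx <- det$bbox[["x"]] + det$bbox[["w"]] / 2
  cy <- det$bbox[["y"]] + det$bbox[["h"]] / 2
  x0 <- clamp(round(cx - spec$crop_w / 2), 0, w - spec$crop_w)
  y0 <- clamp(round(cy - spec$crop_h / 2), 0, h - spec$crop_h)
  rows <- (y0 + 1L):(y0 + spec$crop_h)
  cols <- (x0 + 1L):(x0 + spec$crop_w)
  crop <- if (is_grey(image)) image[rows, cols, drop = FALSE]
          else image[rows, cols, , drop = FALSE]
  structure(list(image = crop, x0 = as.integer(x0), y0 = as.integer(y0),
                 spec = spec), class = "roi_crop")
}

#' Keypoint coordinate transforms between frame and crop
#'
#' The crop is a pure integer translation of the source frame, so the
#' coordinate transform is exact and invertible: subtract the crop
#' offset to go full-frame -> crop, add it to go back.
#'
#' @param points 2-column matrix of `(x, y)` coordinates
#' @param crop an `roi_crop` from [crop_fixed()]
#' @return transformed coordinate matrix
#' @export
to_crop_coords <- function(points, crop) {
  sweep(points, 2L, c(crop$x0, crop$y0), `-`)
}

#' @rdname to_crop_coords
#' @export
to_frame_coords <- function(points, crop) {
  sweep(points, 2L, c(crop$x0, crop$y0), `+`)
}

#' Intersection-over-union of two boxes
#'
#' @param a,b boxes `c(x, y, w, h)`
#' @return IoU in `[0, 1]`
#' @export
bbox_iou <- function(a, b) {
  ix <- max(0, min(a[1L] + a[3L], b[1L] + b[3L]) - max(a[1L], b[1L]))
  iy <- max(0, min(a[2L] + a[4L], b[2L] + b[4L]) - max(a[2L], b[2L]))
  inter <- ix * iy
  inter / (a[3L] * a[4L] + b[3L] * b[4L] - inter)
}

#' Detection CSV interchange
#'
#' Format: `frame,x,y,w,h,class,confidence`.
#'
#' @param detections named (by frame index) or plain list of
#'   [detection()]s
#' @param frames integer vector of 0-based frame indices
#' @param path file path
#' @export
write_detections_csv <- function(detections, frames, path) {
  df <- do.call(rbind, lapply(seq_along(detections), function(i) {
    d <- detections[[i]]
    data.frame(frame = frames[i], x = d$bbox[["x"]], y = d$bbox[["y"]],
               w = d$bbox[["w"]], h = d$bbox[["h"]],
               class = d$class_label, confidence = d$confidence)
  }))
  if (is.null(df)) df <- data.frame(frame = integer(0), x = numeric(0),
                                    y = numeric(0), w = numeric(0),
                                    h = numeric(0), class = character(0),
                                    confidence = numeric(0))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
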