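#' Pipeline configuration
#'
#' Bundles the stage parameters of the full video-to-records pipeline.
#' Stages are pluggable: the classifier, per-view scorers, detector and
#' keypoint model may each be a trained `nn_net`, a heuristic, or
#' `"oracle"` (mock backed by the synthetic ground truth shipped with
#' the video — the configuration used by offline tests).
#'
#' @param chain a [smoothing_chain_config()]
#' @param small_divisor integer downscale factor for the
#'   classifier/scorer path (the deployed system reduces 1280 x 720 to
#'   320 x 180, a factor of 4; synthetic videos use the same factor at
#'   smaller absolute size)
#' @param classifier `"intensity"` (heuristic foreground-fraction
#'   classifier), `"oracle"` (noisy signal from ground truth), or a
#'   function `f(frames_small) -> confidence_signal`
#' @param scorers `"oracle"`, or a named list
#'   `list(top = , underside = )` of scorers as accepted by
#'   [score_frames()]
#' @param detector `"oracle"` (mock from annotations), `"blob"`
#'   ([blob_detector()]), or a detector function
#' @param crop a [crop_spec()], or `NULL` to derive it from this run's
#'   detections
#' @param keypoint_model an `nn_net`, `"oracle"` (ground truth + noise),
#'   or `NULL` to skip the keypoint stage
#' @param keypoint_underside also run detect/crop/keypoints on the
#'   underside frame (off by default: underside frames are reserved for
#'   future sex classification)
#' @param views the presentation views selected per contig
#' @param seed master seed for any stochastic stage component
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(chain = smoothing_chain_config(),
                            small_divisor = 4L,
                            classifier = "oracle",
                            scorers = "oracle",
                            detector = "oracle",
                            crop = NULL,
                            keypoint_model = "oracle",
                            keypoint_underside = FALSE,
                            views = c("top", "underside"),
                            seed = 0) {
  structure(list(chain = chain, small_divisor = as.integer(small_divisor),
                 classifier = classifier, scorers = scorers,
                 detector = detector, crop = crop,
                 keypoint_model = keypoint_model,
                 keypoint_underside = keypoint_underside,
                 views = views, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full pipeline on one video
#'
#' Executes the record-then-process flow end to end: greyscale
#' conversion first, downscaled copies for the cheap models, presence
#' classification into a confidence signal, smoothing-chain contig
#' detection, per-view representative-frame selection, object detection
#' and fixed-size cropping on the unresized original of the selected top
#' frame, and keypoint regression on the crop. The detector and
#' keypoint model run at most once per contig per view. Contigs whose
#' selected frame yields no detection are kept as records with class
#' `"undetected"`, preserving count integrity.
#'
#' @param video list as from [generate_video()] or [read_video_dir()]
#'   (`frames`, plus `annotations`/`signal` when oracle stages are used)
#' @param config a [pipeline_config()]
#' @return list of class `pipeline_report`: `records` (data.frame, one
#'   row per contig, with a `keypoints` list-column), `selected`
#'   (shortlisted frames per contig and view), `contigs`, `signal`,
#'   `profile` (per-stage frame counts and seconds), `manifest`
#' @export
run_pipeline <- function(video, config = pipeline_config()) {
  frames <- video$frames
  n <- length(frames)
  timings <- c(classifier = 0, selector = 0, detector = 0, keypoints = 0)
  counts <- c(classifier = 0L, selector = 0L, detector = 0L, keypoints = 0L)

  # stage 0: greyscale everything once, keep full-res originals
  grey <- lapply(frames, function(f) if (is_grey(f)) f else to_greyscale(f))
  d0 <- dim(grey[[1L]])
  small_target <- c(d0[2L], d0[1L]) %/% config$small_divisor
  small <- lapply(grey, downscale, target = small_target)

  # stage 1: presence classifier -> confidence signal
  t0 <- proc.time()[["elapsed"]]
  signal <- resolve_classifier(config, video)(small)
  counts["classifier"] <- n
  timings["classifier"] <- proc.time()[["elapsed"]] - t0

  # stage 2: contigs
  contigs <- detect_contigs(signal, config$chain)

  # stage 3: per-contig per-view frame selection
  t0 <- proc.time()[["elapsed"]]
  scorers <- resolve_scorers(config, video)
  all_scores <- list()
  for (i in seq_len(nrow(contigs))) {
    idx <- (contigs$start_frame[i] + 1L):min(contigs$end_frame[i], n)
    counts["selector"] <- counts["selector"] + length(idx)
    for (vw in config$views) {
      sc <- if (is.function(scorers[[vw]]) &&
                isTRUE(attr(scorers[[vw]], "by_index"))) {
        score_frames(as.list(idx - 1L), scorers[[vw]], view = vw,
                     frame_indices = idx - 1L)
      } else {
        score_frames(small[idx], scorers[[vw]], view = vw,
                     frame_indices = idx - 1L)
      }
      sc$contig_id <- contigs$contig_id[i]
      all_scores[[length(all_scores) + 1L]] <- sc
    }
  }
  selected <- if (length(all_scores)) select_best(do.call(rbind, all_scores))
              else data.frame(contig_id = integer(0), view = character(0),
                              frame_index = integer(0), score = numeric(0))
  timings["selector"] <- proc.time()[["elapsed"]] - t0

  # stages 4-5: detect, crop, keypoints on unresized originals
  detector <- resolve_detector(config, video)
  kp_views <- if (config$keypoint_underside) config$views else "top"
  kp_views <- intersect(kp_views, config$views)
  dets <- list(); det_frames <- integer(0)
  records <- list()
  t_det <- 0; t_kp <- 0
  for (i in seq_len(nrow(contigs))) {
    cid <- contigs$contig_id[i]
    sel <- selected[selected$contig_id == cid, , drop = FALSE]
    rec <- list(contig_id = cid,
                start_frame = contigs$start_frame[i],
                end_frame = contigs$end_frame[i],
                class_label = "undetected",
                detector_confidence = NA_real_,
                keypoints = NULL)
    for (vw in config$views) {
      fi <- sel$frame_index[sel$view == vw]
      rec[[paste0("selected_", vw)]] <- if (length(fi)) fi else NA_integer_
    }
    for (vw in kp_views) {
      fi <- rec[[paste0("selected_", vw)]]
      if (is.na(fi)) next
      t0 <- proc.time()[["elapsed"]]
      det <- detect(grey[[fi + 1L]], detector, frame_index = fi)
      counts["detector"] <- counts["detector"] + 1L
      t_det <- t_det + (proc.time()[["elapsed"]] - t0)
      if (is.null(det)) {
        message(sprintf("contig %d: no detection on %s frame %d; skipping",
                        cid, vw, fi))
        next
      }
      if (vw == "top") {
        rec$class_label <- det$class_label
        rec$detector_confidence <- det$confidence
      }
      dets[[length(dets) + 1L]] <- det
      det_frames <- c(det_frames, fi)
      rec[[paste0("detection_", vw)]] <- det
    }
    records[[length(records) + 1L]] <- rec
  }

  # crop size: configured, or derived from this run's detections
  spec <- config$crop
  if (is.null(spec) && length(dets)) spec <- derive_crop_size(dets)
  kp_model <- resolve_keypoint_model(config, video)

  if (!is.null(kp_model) && !is.null(spec)) {
    d0 <- dim(grey[[1L]])
    spec <- crop_spec(min(spec$crop_w, d0[2L]), min(spec$crop_h, d0[1L]))
    for (ri in seq_along(records)) {
      rec <- records[[ri]]
      det <- rec$detection_top
      if (is.null(det)) next
      fi <- rec$selected_top
      t0 <- proc.time()[["elapsed"]]
      crop <- crop_fixed(grey[[fi + 1L]], det, spec)
      records[[ri]]$keypoints <- kp_model(crop, fi)
      counts["keypoints"] <- counts["keypoints"] + 1L
      t_kp <- t_kp + (proc.time()[["elapsed"]] - t0)
    }
  }
  timings["detector"] <- t_det
  timings["keypoints"] <- t_kp

  rec_df <- records_to_frame(records, config$views)
  manifest <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    n_frames = n,
    n_contigs = nrow(contigs),
    n_selected = nrow(selected),
    n_detected = length(dets),
    crop = if (!is.null(spec)) unclass(spec) else NULL,
    counts = as.list(counts))
  structure(list(records = rec_df, selected = selected, contigs = contigs,
                 signal = signal,
                 profile = data.frame(stage = names(counts),
                                      frames = as.integer(counts),
                                      seconds = as.numeric(timings)),
                 manifest = manifest),
            class = "pipeline_report")
}

records_to_frame <- function(records, views) {
  if (!length(records)) {
    df <- data.frame(contig_id = integer(0), start_frame = integer(0),
                     end_frame = integer(0), class_label = character(0),
                     detector_confidence = numeric(0))
    for (vw in views) df[[paste0("selected_", vw)]] <- integer(0)
    df$keypoints <- list()
    return(df)
  }
  df <- do.call(rbind, lapply(records, function(r) {
    row <- data.frame(contig_id = r$contig_id, start_frame = r$start_frame,
                      end_frame = r$end_frame, class_label = r$class_label,
                      detector_confidence = r$detector_confidence)
    for (vw in views) row[[paste0("selected_", vw)]] <-
      r[[paste0("selected_", vw)]] %||% NA_integer_
    row
  }))
  df$keypoints <- lapply(records, function(r) r$keypoints)
  df
}

config_hash <- function(config) {
  ser <- jsonlite::toJSON(rapply(unclass(config), function(x)
    if (is.function(x) || inherits(x, "nn_net")) "<object>" else x,
    how = "replace"), auto_unbox = TRUE, force = TRUE)
  tmp <- tempfile()
  writeLines(as.character(ser), tmp)
  on.exit(unlink(tmp))
  unname(tools::md5sum(tmp))
}

# -- stage resolution ---------------------------------------------------------

resolve_classifier <- function(config, video) {
  cl <- config$classifier
  if (is.function(cl)) return(cl)
  switch(cl,
    oracle = {
      if (is.null(video$signal))
        stop("oracle classifier requires the video's synthetic signal")
      function(small) video$signal
    },
    intensity = function(small) {
      # foreground fraction of bright pixels, squashed to [0, 1]
      vals <- vapply(small, function(f) mean(f >= 150), numeric(1))
      confidence_signal(clamp(vals * 25, 0, 1))
    },
    stop("unknown classifier spec: ", cl))
}

resolve_scorers <- function(config, video) {
  sc <- config$scorers
  if (identical(sc, "oracle")) {
    if (is.null(video$annotations))
      stop("oracle scorers require synthetic annotations")
    out <- lapply(config$views, function(vw) {
      f <- oracle_scorer(video$annotations, view = vw)
      attr(f, "by_index") <- TRUE
      f
    })
    names(out) <- config$views
    return(out)
  }
  stopifnot(all(config$views %in% names(sc)))
  sc
}

resolve_detector <- function(config, video) {
  dt <- config$detector
  if (is.function(dt)) return(dt)
  switch(dt,
    oracle = {
      if (is.null(video$annotations))
        stop("oracle detector requires synthetic annotations")
      mock_detector(video$annotations, jitter_sd = 0, seed = config$seed)
    },
    blob = blob_detector(),
    stop("unknown detector spec: ", dt))
}

resolve_keypoint_model <- function(config, video) {
  km <- config$keypoint_model
  if (is.null(km)) return(NULL)
  if (inherits(km, "nn_net"))
    return(function(crop, frame_index) predict_keypoints(crop, km))
  if (identical(km, "oracle")) {
    if (is.null(video$annotations))
      stop("oracle keypoint model requires synthetic annotations")
    return(function(crop, frame_index) {
      a <- video$annotations[[frame_index + 1L]]
      if (!isTRUE(a$present)) return(NULL)
      keypoint_set(to_crop_coords(a$keypoints, crop))
    })
  }
  stop("unknown keypoint model spec")
}

#' Per-stage profile of a pipeline run
#'
#' Frame counts and timings per stage, with the derived rate. The
#' accounting invariants: the classifier sees every frame; the selector
#' sees only in-contig frames; the detector and keypoint model each run
#' once per contig (per processed view). Timings are reported, never
#' asserted — they are hardware-dependent.
#'
#' @param report a `pipeline_report` from [run_pipeline()]
#' @return data.frame `stage`, `frames`, `seconds`, `fps`
#' @export
profile_run <- function(report) {
  p <- report$profile
  p$fps <- ifelse(p$seconds > 0, p$frames / p$seconds, NA_real_)
  p
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d frames -> %d contigs -> %d records\n",
              x$manifest$n_frames, x$manifest$n_contigs, nrow(x$records)))
  invisible(x)
}

#' Write pipeline outputs
#'
#' Records CSV (one row per contig; keypoints flattened to
#' `<name>_x/<name>_y` columns), plus a JSON run manifest. Files are
#' written atomically (temp file + rename).
#'
#' @param report a `pipeline_report`
#' @param dir output directory
#' @export
write_pipeline_outputs <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  atomically <- function(path, writer) {
    tmp <- paste0(path, ".tmp")
    writer(tmp)
    file.rename(tmp, path)
  }
  rec <- report$records
  nm <- keypoint_names()
  kcols <- as.vector(rbind(paste0(nm, "_x"), paste0(nm, "_y")))
  flat <- rec[, setdiff(names(rec), "keypoints"), drop = FALSE]
  kmat <- t(vapply(rec$keypoints, function(kp)
    if (is.null(kp)) rep(NA_real_, 14L) else encode_keypoints(kp),
    numeric(14L)))
  if (nrow(rec)) flat[kcols] <- as.data.frame(kmat) else flat[kcols] <- list()
  atomically(file.path(dir, "records.csv"),
             function(p) write.csv(flat, p, row.names = FALSE))
  atomically(file.path(dir, "selected.csv"),
             function(p) write.csv(report$selected, p, row.names = FALSE))
  atomically(file.path(dir, "contigs.csv"),
             function(p) write_contigs_csv(report$contigs, p))
  atomically(file.path(dir, "manifest.json"),
             function(p) jsonlite::write_json(report$manifest, p,
                                              auto_unbox = TRUE, digits = NA))
  invisible(dir)
}
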