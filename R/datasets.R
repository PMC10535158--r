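#' Seeded synthetic training datasets
#'
#' Builders for desk-scale labelled datasets backing the two reference
#' models. Frames are rendered directly at the network input size
#' (the full-scale system renders at camera resolution and downscales;
#' at desk scale that indirection buys nothing). All randomness flows
#' from `seed`, so a dataset is a pure function of its arguments.
#'
#' `synthetic_scorer_dataset()` draws frames of one view with the pose
#' varied over the quality-relevant axes — centrality, scale and motion
#' blur — and labels each frame with the generator's ground-truth
#' quality.
#'
#' @param n number of frames
#' @param view the presentation view rendered
#' @param image_size `c(w, h)` of the frames (the scorer input size)
#' @param seed integer seed
#' @return list with `frames` (greyscale matrices), `qualities`,
#'   `annotations` and `input_size`
#' @export
synthetic_scorer_dataset <- function(n, view = "top",
                                     image_size = c(32, 18), seed = 0) {
  w <- image_size[1L]; h <- image_size[2L]
  poses <- with_seed(seed, data.frame(
    cx = runif(n, 0.15 * w, 0.85 * w),
    cy = runif(n, 0.2 * h, 0.8 * h),
    angle = runif(n, -0.6, 0.6),
    scale = runif(n, 0.08, 0.35) * min(w, h),
    blur = runif(n, 0, 0.5),
    species = sample(c("crab", "lobster"), n, replace = TRUE),
    bg = sample.int(1e6, n)))
  frames <- vector("list", n)
  anns <- vector("list", n)
  for (i in seq_len(n)) {
    g <- generate_frame(TRUE, view = view,
                        pose = list(center = c(poses$cx[i], poses$cy[i]),
                                    angle = poses$angle[i],
                                    scale = poses$scale[i],
                                    blur = poses$blur[i]),
                        image_size = image_size,
                        species = poses$species[i], seed = poses$bg[i])
    frames[[i]] <- g$image
    anns[[i]] <- g$annotation
  }
  list(frames = frames,
       qualities = vapply(anns, function(a) a$quality, numeric(1)),
       annotations = anns, input_size = image_size)
}

#' @rdname synthetic_scorer_dataset
#' @details `synthetic_keypoint_dataset()` renders near-centred animals,
#'   cuts a fixed-size crop around the ground-truth box (the mock of the
#'   detect-and-crop stage), and returns crop-coordinate keypoint
#'   targets.
#' @param frame_size `c(w, h)` of the rendered full frames
#' @param spec a [crop_spec()] for the fixed crop
#' @return list with `crops`, `targets` (list of [keypoint_set()]s),
#'   `bboxes` (ground-truth boxes in full-frame pixels) and `spec`
#' @export
synthetic_keypoint_dataset <- function(n, frame_size = c(72, 72),
                                       spec = crop_spec(48, 48), seed = 0) {
  w <- frame_size[1L]; h <- frame_size[2L]
  poses <- with_seed(seed, data.frame(
    cx = w / 2 + runif(n, -0.08, 0.08) * w,
    cy = h / 2 + runif(n, -0.08, 0.08) * h,
    angle = runif(n, -pi, pi),
    scale = runif(n, 0.16, 0.2) * min(w, h),
    species = sample(c("crab", "lobster"), n, replace = TRUE),
    bg = sample.int(1e6, n)))
  crops <- vector("list", n)
  targets <- vector("list", n)
  bboxes <- vector("list", n)
  for (i in seq_len(n)) {
    g <- generate_frame(TRUE, view = "top",
                        pose = list(center = c(poses$cx[i], poses$cy[i]),
                                    angle = poses$angle[i],
                                    scale = poses$scale[i], blur = 0),
                        image_size = frame_size,
                        species = poses$species[i], seed = poses$bg[i])
    det <- detection(g$annotation$bbox, poses$species[i])
    crop <- crop_fixed(g$image, det, spec)
    crops[[i]] <- crop$image
    targets[[i]] <- keypoint_set(to_crop_coords(g$annotation$keypoints, crop))
    bboxes[[i]] <- g$annotation$bbox
  }
  list(crops = crops, targets = targets, bboxes = bboxes, spec = spec)
}
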