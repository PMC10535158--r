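#' Reference frame-scorer architecture
#'
#' Builds the per-view "representativeness" scorer: a small stack of
#' 3 x 3 convolution + 2 x 2 max-pool blocks (widths 8/16/32), a dense
#' layer, and a single sigmoid output unit. The same architecture is
#' used for every view; only the training targets differ. The deployed
#' system trains each view's scorer for 200 epochs on 950 labelled
#' frames at learning rate 1e-5 on 320 x 180 greyscale input; at desk
#' scale the input is smaller and epochs fewer, set by the caller.
#'
#' @param input_size `c(w, h)` of the greyscale scorer input
#' @param widths convolution widths per block
#' @param dense_units width of the dense layer before the output unit
#' @param seed weight-initialisation seed
#' @return an `nn_net` emitting one score in `[0, 1]`
#' @export
scorer_network <- function(input_size = c(320, 180), widths = c(8, 16, 32),
                           dense_units = 32, seed = 0) {
  layers <- list()
  for (w in widths) {
    layers <- c(layers, list(nn_conv(w), nn_maxpool()))
  }
  layers <- c(layers, list(nn_dense(dense_units, activation = "relu"),
                           nn_dense(1L, activation = "sigmoid")))
  nn_network(c(input_size[2L], input_size[1L], 1L), layers, seed = seed)
}

#' Score the frames of one contig for representativeness
#'
#' Applies a scorer to every frame inside a single contig and returns
#' one score per frame. Frames outside contig boundaries are discarded
#' before this stage and are never scored. A scorer is either an
#' `nn_net` (frames must already be greyscale at its input size) or any
#' function `f(image) -> score in [0, 1]` — e.g. [oracle_scorer()]
#' backed by synthetic ground truth, or [constant_scorer()].
#'
#' @param frames list of greyscale frames belonging to one contig,
#'   already downscaled to the scorer's input size
#' @param scorer `nn_net` or scoring function
#' @param view `"top"` or `"underside"`, recorded on the result
#' @param frame_indices 0-based video frame indices of `frames`
#' @return data.frame with `frame_index`, `view`, `score`
#' @export
score_frames <- function(frames, scorer, view = "top",
                         frame_indices = seq_along(frames) - 1L) {
  if (length(frames) == 0L) stop("empty contig: nothing to score")
  stopifnot(length(frame_indices) == length(frames))
  f <- as_scorer_fn(scorer)
  scores <- vapply(frames, f, numeric(1))
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
  data.frame(frame_index = as.integer(frame_indices),
             view = view, score = scores)
}

as_scorer_fn <- function(scorer) {
  if (inherits(scorer, "nn_net")) {
    # networks consume intensities rescaled to [0, 1]
    function(img) nn_predict(scorer, img / 255)[1L]
  } else if (is.function(scorer)) {
    scorer
  } else stop("scorer must be an nn_net or a function(image) -> score")
}

#' @rdname score_frames
#' @param annotations per-frame scene annotations (ground truth); the
#'   oracle scores a frame by its true quality when its view matches,
#'   and 0 otherwise
#' @export
oracle_scorer <- function(annotations, view = "top") {
  force(annotations); force(view)
  # keyed by frame index, so pass frame indices not images
  function(frame_index) {
    a <- annotations[[frame_index + 1L]]
    if (isTRUE(a$present) && a$view == view) a$quality else 0
  }
}

#' @rdname score_frames
#' @param value the constant score returned for every frame
#' @export
constant_scorer <- function(value = 0.5) {
  force(value)
  function(img) value
}

#' Select the most representative frame per contig and view
#'
#' Takes per-frame scores grouped by contig and view and returns the
#' argmax frame for each group: the highest scoring frame in the contig
#' becomes the "most representative" frame for that view. Ties break to
#' the earliest frame. With `k` contigs and `v` views, exactly `k * v`
#' frames are shortlisted (e.g. 5 contigs, 2 angles = 10 frames).
#'
#' @param scores data.frame with columns `contig_id`, `view`,
#'   `frame_index`, `score` (rbind of [score_frames()] results)
#' @return data.frame with one row per (contig, view): `contig_id`,
#'   `view`, `frame_index`, `score`
#' @export
select_best <- function(scores) {
  stopifnot(all(c("contig_id", "view", "frame_index", "score") %in%
                  names(scores)))
  if (nrow(scores) == 0L)
    return(scores[, c("contig_id", "view", "frame_index", "score")])
  picks <- lapply(split(scores, list(scores$contig_id, scores$view),
                        drop = TRUE), function(g) {
    g <- g[order(g$frame_index), , drop = FALSE]   # tie-break: earliest
    g[which.max(g$score), c("contig_id", "view", "frame_index", "score")]
  })
  out <- do.call(rbind, picks)
  out <- out[order(out$contig_id, out$view), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pairwise preference accuracy of a frame scorer
#'
#' Evaluation analogue of the selection task: present two frames of
#' strictly different ground-truth quality and record whether the scorer
#' assigns the higher score to the better frame. Ties count as
#' failures, since a tie gives the selector no usable preference. An
#' oracle scorer scores 1.0; a constant scorer scores 0.0; an
#' independent random scorer converges to 0.5.
#'
#' @param scorer `nn_net` or function, as in [score_frames()]
#' @param better,worse parallel lists of frames (or scorer inputs),
#'   where each `better[[i]]` has strictly higher true quality than
#'   `worse[[i]]`
#' @return fraction of pairs ranked correctly, in `[0, 1]`
#' @export
pairwise_accuracy <- function(scorer, better, worse) {
  if (length(better) == 0L) stop("no evaluation pairs supplied")
  stopifnot(length(better) == length(worse))
  f <- as_scorer_fn(scorer)
  wins <- mapply(function(b, w) f(b) > f(w), better, worse)
  mean(wins)
}

#' Train a frame scorer on quality-labelled frames
#'
#' Scalar regression of the representativeness label in `[0, 1]` with
#' squared-error loss (relative/pairwise training is deliberately not
#' used: it underperforms in architectures this light). Frames must be
#' greyscale at the network input size.
#'
#' @param net a [scorer_network()]
#' @param frames list of greyscale training frames
#' @param qualities numeric vector of labels in `[0, 1]`
#' @param epochs,lr,seed training-loop controls (deployed values: 200
#'   epochs, lr 1e-5 at full scale; desk scale uses fewer/larger)
#' @return the trained `nn_net`
#' @export
train_frame_scorer <- function(net, frames, qualities, epochs = 20,
                               lr = 1e-3, seed = 0) {
  stopifnot(length(frames) == length(qualities),
            all(qualities >= 0 & qualities <= 1))
  nn_train(net, lapply(frames, function(f) f / 255),
           matrix(qualities, ncol = 1L), epochs = epochs,
           lr = lr, loss = "mse", seed = seed)
}
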