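#' Greyscale conversion
#'
#' Converts an RGB frame to a single luminance channel using the ITU-R
#' BT.601 weights (0.299, 0.587, 0.114). All frames are converted to
#' greyscale at the start of the pipeline: this cuts the input size by
#' exactly a factor of 3 with no loss of downstream performance for
#' these models. Pure grey inputs (R = G = B = v) map to v exactly,
#' since the weights sum to 1.
#'
#' @param image H x W x 3 array of integer intensities in 0..255
#' @return H x W greyscale matrix; single-channel input passes through
#'   unchanged with a warning
#' @export
to_greyscale <- function(image) {
  if (is_grey(image)) {
    warning("image is already single-channel; passing through")
    return(image)
  }
  d <- dim(image)
  stopifnot(length(d) == 3L, d[3L] == 3L)
  g <- 0.299 * image[, , 1L] + 0.587 * image[, , 2L] + 0.114 * image[, , 3L]
  round(g)
}

#' Aspect-preserving downscale by area interpolation
#'
#' Reduces an image to `target = c(w, h)` by exact area averaging (each
#' output pixel is the mean of the source region it covers). The target
#' aspect ratio must equal the source's: measurement-path images are
#' never resized at all, and the classifier/scorer path must not distort
#' proportions either. The deployed reduction is 1280 x 720 to
#' 320 x 180.
#'
#' @param image greyscale matrix or RGB array
#' @param target `c(w, h)` of the output
#' @return image of exactly the target dimensions
#' @export
downscale <- function(image, target) {
  d <- dim(image)
  sh <- d[1L]; sw <- d[2L]
  tw <- as.integer(target[1L]); th <- as.integer(target[2L])
  stopifnot(tw >= 1, th >= 1)
  if (tw > sw || th > sh) stop("downscale cannot enlarge")
  # exact aspect check via integer cross-product
  if (sw * th != sh * tw)
    stop(sprintf("aspect ratio mismatch: source %d:%d vs target %d:%d",
                 sw, sh, tw, th))
  if (tw == sw && th == sh) return(image)
  A <- area_weights(sh, th)            # th x sh
  B <- area_weights(sw, tw)            # tw x sw
  if (is_grey(image)) {
    A %*% image %*% t(B)
  } else {
    out <- array(0, dim = c(th, tw, d[3L]))
    for (ch in seq_len(d[3L])) out[, , ch] <- A %*% image[, , ch] %*% t(B)
    out
  }
}

# n_dst x n_src row-stochastic matrix of source-interval overlap
# fractions; reduces to exact block means for integer factors.
area_weights <- function(n_src, n_dst) {
  scale <- n_src / n_dst
  W <- matrix(0, nrow = n_dst, ncol = n_src)
  for (i in seq_len(n_dst)) {
    lo <- (i - 1) * scale
    hi <- i * scale
    js <- (floor(lo) + 1L):ceiling(hi)
    W[i, js] <- (pmin(hi, js) - pmax(lo, js - 1)) / scale
  }
  W
}

#' Training-time augmentation
#'
#' `augmentation_config()` holds the stochastic augmentation chain
#' applied to every training image (never to test or measurement
#' images): horizontal flip with probability 0.5, vertical flip with
#' probability 0.5, blur with probability 0.3, and a +/-20\% intensity
#' shift with probability 0.3 (simulating varied lighting). The four
#' draws are independent and the operations are applied sequentially in
#' that fixed order, so the chance of all four firing is
#' 0.5 x 0.5 x 0.3 x 0.3 = 2.25\%.
#'
#' The intensity shift is multiplicative: all pixels are scaled by a
#' factor uniform in `[0.8, 1.2]`, then clipped to `[0, 255]`.
#'
#' @param p_hflip,p_vflip,p_blur,p_intensity per-op probabilities
#' @param intensity_range half-width of the multiplicative shift (0.2
#'   means factors in `[0.8, 1.2]`)
#' @param blur_kernel odd box/Gaussian kernel width used by the blur op
#' @param seed integer seed
#' @return an object of class `augmentation_config`
#' @export
augmentation_config <- function(p_hflip = 0.5, p_vflip = 0.5, p_blur = 0.3,
                                p_intensity = 0.3, intensity_range = 0.2,
                                blur_kernel = 5L, seed = 0) {
  probs <- c(p_hflip, p_vflip, p_blur, p_intensity)
  stopifnot(all(probs >= 0 & probs <= 1), intensity_range >= 0,
            blur_kernel >= 1, blur_kernel %% 2 == 1)
  structure(list(p_hflip = p_hflip, p_vflip = p_vflip, p_blur = p_blur,
                 p_intensity = p_intensity, intensity_range = intensity_range,
                 blur_kernel = as.integer(blur_kernel),
                 seed = as.integer(seed)),
            class = "augmentation_config")
}

#' @rdname augmentation_config
#' @param n number of independent draws
#' @details `draw_augmentation_ops()` is the single code path through
#'   which augmentation randomness is drawn; [augment()] uses one row of
#'   it, and Monte Carlo estimates of chain probabilities use many.
#' @return `draw_augmentation_ops()`: a data.frame with logical columns
#'   `hflip`, `vflip`, `blur`, `intensity` and numeric `factor`
#' @export
draw_augmentation_ops <- function(config, n = 1L) {
  data.frame(
    hflip = runif(n) < config$p_hflip,
    vflip = runif(n) < config$p_vflip,
    blur = runif(n) < config$p_blur,
    intensity = runif(n) < config$p_intensity,
    factor = runif(n, 1 - config$intensity_range, 1 + config$intensity_range))
}

#' @rdname augmentation_config
#' @param image greyscale matrix or RGB array
#' @param config an `augmentation_config`
#' @param seed optional seed for this single draw; `NULL` uses the
#'   current RNG stream (for use inside a seeded training loop)
#' @return `augment()`: list with `image` and `applied_ops` (character
#'   vector of the ops that fired, possibly empty)
#' @export
augment <- function(image, config = augmentation_config(), seed = NULL) {
  ops <- with_seed(seed, draw_augmentation_ops(config, 1L))
  applied <- character(0)
  if (ops$hflip) { image <- hflip(image); applied <- c(applied, "hflip") }
  if (ops$vflip) { image <- vflip(image); applied <- c(applied, "vflip") }
  if (ops$blur) {
    image <- gaussian_blur(image, config$blur_kernel)
    applied <- c(applied, "blur")
  }
  if (ops$intensity) {
    image <- clamp(image * ops$factor, 0, 255)
    applied <- c(applied, "intensity")
  }
  list(image = image, applied_ops = applied)
}

#' @rdname augmentation_config
#' @export
hflip <- function(image) {
  if (is_grey(image)) image[, rev(seq_len(ncol(image))), drop = FALSE]
  else image[, rev(seq_len(dim(image)[2L])), , drop = FALSE]
}

#' @rdname augmentation_config
#' @export
vflip <- function(image) {
  if (is_grey(image)) image[rev(seq_len(nrow(image))), , drop = FALSE]
  else image[rev(seq_len(dim(image)[1L])), , , drop = FALSE]
}

#' @rdname augmentation_config
#' @param width odd kernel width
#' @param sigma Gaussian standard deviation in pixels
#' @export
gaussian_blur <- function(image, width = 5L, sigma = width / 4) {
  stopifnot(width >= 1, width %% 2 == 1)
  if (width == 1L) return(image)
  half <- (width - 1L) %/% 2L
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(m) {
    # replicate-pad rows, separable 1-D convolution down columns
    n <- nrow(m)
    pad <- rbind(m[rep(1L, half), , drop = FALSE], m,
                 m[rep(n, half), , drop = FALSE])
    out <- matrix(0, nrow = n, ncol = ncol(m))
    for (j in seq_len(width)) {
      out <- out + k[j] * pad[j:(j + n - 1L), , drop = FALSE]
    }
    out
  }
  blur_grey <- function(m) t(conv1(t(conv1(m))))
  if (is_grey(image)) blur_grey(image)
  else {
    out <- image
    for (ch in seq_len(dim(image)[3L])) out[, , ch] <- blur_grey(image[, , ch])
    out
  }
}
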