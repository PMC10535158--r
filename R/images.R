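#' Image containers and plain-text NetPBM I/O
#'
#' Images are plain numeric objects: a greyscale frame is an `H x W`
#' matrix (rows are image rows, i.e. y), an RGB frame an `H x W x 3`
#' array. Intensities are integers in `[0, 255]` (stored as numeric).
#' Frames are read and written as ASCII NetPBM: `P2` (PGM) for greyscale
#' and `P3` (PPM) for RGB — dependency-free plain-text formats.
#'
#' @param h,w image height and width in pixels
#' @param value fill intensity
#' @return `blank_image()` returns an `H x W` matrix of `value`.
#' @export
blank_image <- function(h, w, value = 0) {
  matrix(value, nrow = h, ncol = w)
}

#' @rdname blank_image
#' @param image greyscale matrix or RGB array
#' @export
is_grey <- function(image) is.matrix(image)

#' @rdname blank_image
#' @export
image_size <- function(image) {
  d <- dim(image)
  c(w = d[2L], h = d[1L])
}

#' @rdname blank_image
#' @param path file path (`.pgm` for greyscale, `.ppm` for RGB)
#' @export
write_netpbm <- function(image, path) {
  d <- dim(image)
  vals <- as.integer(round(pmin(pmax(image, 0), 255)))
  if (is_grey(image)) {
    header <- c("P2", paste(d[2L], d[1L]), "255")
    # PGM is row-major; R matrices are column-major
    body <- matrix(vals, nrow = d[1L])
    lines <- apply(body, 1L, paste, collapse = " ")
  } else {
    stopifnot(length(d) == 3L, d[3L] == 3L)
    header <- c("P3", paste(d[2L], d[1L]), "255")
    arr <- array(vals, dim = d)
    # interleave R,G,B per pixel, row-major
    px <- aperm(arr, c(3L, 2L, 1L))      # channel, col, row
    body <- matrix(as.vector(px), ncol = 3L * d[2L], byrow = TRUE)
    lines <- apply(body, 1L, paste, collapse = " ")
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' @rdname blank_image
#' @export
read_netpbm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  magic <- toks[1L]
  w <- as.integer(toks[2L]); h <- as.integer(toks[3L])
  vals <- as.numeric(toks[-(1:4)])
  if (magic == "P2") {
    matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  } else if (magic == "P3") {
    px <- array(vals, dim = c(3L, w, h))
    aperm(px, c(3L, 2L, 1L))
  } else {
    stop("unsupported NetPBM magic: ", magic)
  }
}

# clamp helper used throughout
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
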