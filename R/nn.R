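#' Minimal convolutional-network engine
#'
#' A small, dependency-free CNN implementation sufficient for the two
#' reference models in this package: the per-view frame scorer (conv/pool
#' blocks ending in one sigmoid unit) and the keypoint regressor
#' (alternating conv and max-pool layers, a dense layer, and 14 linear
#' outputs). Convolutions are 3 x 3, valid, stride 1, computed by im2col
#' matrix multiplication; pooling is 2 x 2 max with stride 2. Training is
#' per-sample Adam on MSE or RMSE loss. This is not a general deep
#' learning framework: it exists because the target models must be tiny
#' enough for 512 MB-class hardware, and it keeps the package fully
#' self-contained and testable offline.
#'
#' @param input_shape `c(h, w, channels)` of the network input
#' @param layers list of layer specs from [nn_conv()], [nn_maxpool()],
#'   [nn_dense()]
#' @param seed seed for weight initialisation (He-scaled Gaussians)
#' @return an object of class `nn_net`
#' @export
nn_network <- function(input_shape, layers, seed = 0) {
  if (length(input_shape) == 2L) input_shape <- c(input_shape, 1L)
  shape <- input_shape
  built <- list()
  with_seed(seed, {
    for (spec in layers) {
      l <- switch(spec$type,
        conv = {
          kh <- spec$size; kw <- spec$size
          oh <- shape[1L] - kh + 1L; ow <- shape[2L] - kw + 1L
          if (oh < 1L || ow < 1L) stop("feature map too small for conv")
          fan_in <- kh * kw * shape[3L]
          W <- matrix(rnorm(fan_in * spec$filters, sd = sqrt(2 / fan_in)),
                      nrow = fan_in)
          l <- list(type = "conv", W = W, b = numeric(spec$filters),
                    size = spec$size, activation = spec$activation,
                    in_shape = shape, out_shape = c(oh, ow, spec$filters),
                    idx = im2col_index(shape, spec$size))
          shape <- l$out_shape
          l
        },
        maxpool = {
          oh <- shape[1L] %/% 2L; ow <- shape[2L] %/% 2L
          if (oh < 1L || ow < 1L) stop("feature map too small for pooling")
          l <- list(type = "maxpool", in_shape = shape,
                    out_shape = c(oh, ow, shape[3L]))
          shape <- l$out_shape
          l
        },
        dense = {
          fan_in <- prod(shape)
          W <- matrix(rnorm(fan_in * spec$units, sd = sqrt(2 / fan_in)),
                      nrow = fan_in)
          l <- list(type = "dense", W = W, b = numeric(spec$units),
                    activation = spec$activation, in_shape = shape,
                    out_shape = c(spec$units))
          shape <- spec$units
          l
        },
        stop("unknown layer type: ", spec$type))
      built[[length(built) + 1L]] <- l
    }
  })
  structure(list(input_shape = input_shape, layers = built,
                 opt = NULL), class = "nn_net")
}

#' @rdname nn_network
#' @param filters number of convolution filters
#' @param size kernel width (square)
#' @param activation `"relu"`, `"sigmoid"` or `"linear"`
#' @export
nn_conv <- function(filters, size = 3L, activation = "relu") {
  list(type = "conv", filters = as.integer(filters), size = as.integer(size),
       activation = activation)
}

#' @rdname nn_network
#' @export
nn_maxpool <- function() list(type = "maxpool")

#' @rdname nn_network
#' @param units number of dense output units
#' @export
nn_dense <- function(units, activation = "linear") {
  list(type = "dense", units = as.integer(units), activation = activation)
}

# Precomputed im2col gather index for a given input shape and kernel:
# rows = output positions (oh*ow), cols = patch entries (k*k*C).
im2col_index <- function(shape, k) {
  h <- shape[1L]; w <- shape[2L]; C <- shape[3L]
  oh <- h - k + 1L; ow <- w - k + 1L
  base_r <- rep(seq_len(oh), times = ow)
  base_c <- rep(seq_len(ow), each = oh)
  cols <- integer(0)
  idx <- matrix(0L, nrow = oh * ow, ncol = k * k * C)
  p <- 1L
  for (ch in seq_len(C)) {
    off_ch <- (ch - 1L) * h * w
    for (dc in 0:(k - 1L)) {
      for (dr in 0:(k - 1L)) {
        idx[, p] <- off_ch + (base_c + dc - 1L) * h + (base_r + dr)
        p <- p + 1L
      }
    }
  }
  idx
}

apply_activation <- function(z, act) {
  switch(act,
         relu = pmax(z, 0),
         sigmoid = 1 / (1 + exp(-z)),
         linear = z)
}

activation_grad <- function(a, act) {
  switch(act,
         relu = (a > 0) * 1,
         sigmoid = a * (1 - a),
         linear = 1)
}

# forward pass; returns output and per-layer caches for backprop
nn_forward <- function(net, x, keep_cache = FALSE) {
  a <- as.numeric(x)
  caches <- if (keep_cache) vector("list", length(net$layers)) else NULL
  for (li in seq_along(net$layers)) {
    l <- net$layers[[li]]
    if (l$type == "conv") {
      patches <- matrix(a[l$idx], nrow = nrow(l$idx))
      z <- patches %*% l$W
      z <- sweep(z, 2L, l$b, `+`)
      out <- apply_activation(z, l$activation)
      if (keep_cache) caches[[li]] <- list(patches = patches, out = out)
      a <- as.numeric(out)
    } else if (l$type == "maxpool") {
      s <- l$in_shape
      arr <- array(a, dim = s)
      oh <- l$out_shape[1L]; ow <- l$out_shape[2L]
      r1 <- seq(1L, by = 2L, length.out = oh)
      c1 <- seq(1L, by = 2L, length.out = ow)
      cand <- array(0, dim = c(oh, ow, s[3L], 4L))
      cand[, , , 1L] <- arr[r1, c1, , drop = FALSE]
      cand[, , , 2L] <- arr[r1 + 1L, c1, , drop = FALSE]
      cand[, , , 3L] <- arr[r1, c1 + 1L, , drop = FALSE]
      cand[, , , 4L] <- arr[r1 + 1L, c1 + 1L, , drop = FALSE]
      out <- array(pmax(cand[, , , 1L], cand[, , , 2L],
                        cand[, , , 3L], cand[, , , 4L]),
                   dim = l$out_shape)
      if (keep_cache) caches[[li]] <- list(cand = cand, out = out)
      a <- as.numeric(out)
    } else {                              # dense
      z <- as.numeric(crossprod(l$W, a)) + l$b
      out <- apply_activation(z, l$activation)
      if (keep_cache) caches[[li]] <- list(input = a, out = out)
      a <- out
    }
  }
  list(out = a, caches = caches)
}

# backward pass: returns list of per-layer grads (W, b) given dL/d_output
nn_backward <- function(net, caches, dout) {
  grads <- vector("list", length(net$layers))
  da <- dout
  for (li in rev(seq_along(net$layers))) {
    l <- net$layers[[li]]
    cache <- caches[[li]]
    if (l$type == "dense") {
      dz <- da * activation_grad(cache$out, l$activation)
      grads[[li]] <- list(W = tcrossprod(cache$input, dz),
                          b = dz)
      da <- as.numeric(l$W %*% dz)
    } else if (l$type == "maxpool") {
      s <- l$in_shape
      oh <- l$out_shape[1L]; ow <- l$out_shape[2L]
      dupstream <- array(da, dim = l$out_shape)
      cand <- cache$cand
      out <- cache$out
      dx <- array(0, dim = s)
      r1 <- seq(1L, by = 2L, length.out = oh)
      c1 <- seq(1L, by = 2L, length.out = ow)
      taken <- array(FALSE, dim = dim(out))   # route to first max only
      for (q in 1:4) {
        cq <- array(cand[, , , q], dim = dim(out))
        is_max <- (cq == out) & !taken
        taken <- taken | is_max
        g <- dupstream * is_max
        rr <- r1 + c(0L, 1L, 0L, 1L)[q]
        cc <- c1 + c(0L, 0L, 1L, 1L)[q]
        dx[rr, cc, ] <- dx[rr, cc, , drop = FALSE] + g
      }
      da <- as.numeric(dx)
    } else {                              # conv
      dz <- matrix(da, nrow = nrow(l$idx)) *
        activation_grad(cache$out, l$activation)
      grads[[li]] <- list(W = crossprod(cache$patches, dz),
                          b = colSums(dz))
      dpatch <- tcrossprod(dz, l$W)       # positions x (k*k*C)
      dx <- numeric(prod(l$in_shape))
      for (p in seq_len(ncol(l$idx))) {
        col <- l$idx[, p]
        dx[col] <- dx[col] + dpatch[, p]
      }
      da <- dx
    }
  }
  grads
}

loss_and_grad <- function(pred, target, loss) {
  d <- pred - target
  n <- length(d)
  mse <- mean(d^2)
  if (loss == "mse") {
    list(loss = mse, grad = 2 * d / n)
  } else {                                # rmse
    r <- sqrt(mse)
    list(loss = r, grad = if (r > 1e-12) d / (n * r) else d * 0)
  }
}

#' @rdname nn_network
#' @param net an `nn_net`
#' @param x single input (array matching `input_shape`, or matrix for
#'   single-channel input)
#' @return `nn_predict()`: numeric vector of network outputs
#' @export
nn_predict <- function(net, x) {
  nn_forward(net, x)$out
}

#' @rdname nn_network
#' @param xs list of inputs
#' @param ys numeric matrix of targets, one row per input
#' @param epochs passes over the data
#' @param lr Adam learning rate
#' @param loss `"mse"` or `"rmse"`
#' @param shuffle reshuffle sample order each epoch (seeded)
#' @param verbose print a loss line every `verbose` epochs (0 = silent)
#' @return `nn_train()`: the trained network, with a `history` attribute
#'   (mean per-epoch loss)
#' @export
nn_train <- function(net, xs, ys, epochs = 10, lr = 1e-3, loss = "mse",
                     seed = 0, shuffle = TRUE, verbose = 0) {
  ys <- as.matrix(ys)
  stopifnot(length(xs) == nrow(ys))
  # Adam state per parameterised layer
  opt <- lapply(net$layers, function(l) {
    if (!is.null(l$W)) list(mW = l$W * 0, vW = l$W * 0,
                            mb = l$b * 0, vb = l$b * 0) else NULL
  })
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t <- 0L
  history <- numeric(epochs)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- if (shuffle) sample.int(length(xs)) else seq_along(xs)
      ep_loss <- 0
      for (i in ord) {
        fw <- nn_forward(net, xs[[i]], keep_cache = TRUE)
        lg <- loss_and_grad(fw$out, ys[i, ], loss)
        ep_loss <- ep_loss + lg$loss
        grads <- nn_backward(net, fw$caches, lg$grad)
        t <- t + 1L
        for (li in seq_along(net$layers)) {
          if (is.null(grads[[li]])) next
          g <- grads[[li]]; o <- opt[[li]]; l <- net$layers[[li]]
          o$mW <- beta1 * o$mW + (1 - beta1) * g$W
          o$vW <- beta2 * o$vW + (1 - beta2) * g$W^2
          o$mb <- beta1 * o$mb + (1 - beta1) * g$b
          o$vb <- beta2 * o$vb + (1 - beta2) * g$b^2
          mhW <- o$mW / (1 - beta1^t); vhW <- o$vW / (1 - beta2^t)
          mhb <- o$mb / (1 - beta1^t); vhb <- o$vb / (1 - beta2^t)
          l$W <- l$W - lr * mhW / (sqrt(vhW) + eps)
          l$b <- l$b - lr * mhb / (sqrt(vhb) + eps)
          net$layers[[li]] <- l
          opt[[li]] <- o
        }
      }
      history[ep] <- ep_loss / length(xs)
      if (verbose > 0 && ep %% verbose == 0)
        message(sprintf("epoch %d/%d  %s %.5f", ep, epochs, loss, history[ep]))
    }
  })
  attr(net, "history") <- history
  net
}

#' @rdname nn_network
#' @param path file path for the plain-text checkpoint (RDS-free JSON)
#' @export
nn_save <- function(net, path) {
  ser <- list(input_shape = net$input_shape,
              layers = lapply(net$layers, function(l) {
                out <- l[setdiff(names(l), "idx")]
                if (!is.null(out$W)) {
                  out$W_dim <- dim(out$W)
                  out$W <- as.numeric(out$W)
                }
                out
              }))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname nn_network
#' @export
nn_load <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  layers <- lapply(raw$layers, function(l) {
    out <- list(type = l$type)
    for (nm in c("size", "activation")) if (!is.null(l[[nm]])) out[[nm]] <- l[[nm]]
    for (nm in c("in_shape", "out_shape"))
      if (!is.null(l[[nm]])) out[[nm]] <- as.integer(unlist(l[[nm]]))
    if (!is.null(l$W)) {
      out$W <- matrix(as.numeric(unlist(l$W)),
                      nrow = as.integer(l$W_dim[[1L]]))
      out$b <- as.numeric(unlist(l$b))
    }
    if (out$type == "conv") out$idx <- im2col_index(out$in_shape, out$size)
    out
  })
  structure(list(input_shape = as.integer(unlist(raw$input_shape)),
                 layers = layers, opt = NULL), class = "nn_net")
}

#' @export
print.nn_net <- function(x, ...) {
  cat(sprintf("<nn_net> input %s\n",
              paste(x$input_shape, collapse = "x")))
  for (l in x$layers) {
    cat(sprintf("  %-8s -> %s%s\n", l$type,
                paste(l$out_shape, collapse = "x"),
                if (!is.null(l$activation)) paste0(" (", l$activation, ")")
                else ""))
  }
  invisible(x)
}
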