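#' Centred 2-D kernel application with replicate-edge padding
#'
#' Applies an odd-sized kernel centred on every pixel (correlation form:
#' `out[r, c] = sum_{u,v} x[r + u, c + v] * k[u, v]` with `u`, `v` running
#' over the centred kernel support). Out-of-field samples take the value of
#' the nearest edge pixel (replicate padding), which avoids injecting
#' spurious contrast at the field borders. All kernels used by the model are
#' symmetric, so this equals true convolution.
#'
#' @param x numeric matrix.
#' @param kernel numeric matrix with odd dimensions.
#' @return numeric matrix of the same dimensions as `x`.
#' @examples
#' conv2_replicate(matrix(1, 4, 4), matrix(1 / 9, 3, 3))
#' @export
conv2_replicate <- function(x, kernel) {
  stopifnot(is.matrix(x), is.matrix(kernel))
  if (any(dim(kernel) %% 2 == 0)) {
    stop("kernel dimensions must be odd")
  }
  cpp_conv2_replicate(x, kernel)
}

#' Truncated 2-D Gaussian kernel
#'
#' Builds the `(2 * halfwidth + 1)^2` Gaussian kernel used by the divisive
#' contrast normalization surround. With `normalize = TRUE` (the default) the
#' truncated kernel is rescaled to unit sum so that a uniform field is its
#' own surround estimate; with `normalize = FALSE` the raw analytic
#' truncation `exp(-(u^2 + v^2) / (2 sigma^2)) / (2 pi sigma^2)` is returned
#' (its mass is about 0.53 at `sigma = 5`, `halfwidth = 5`).
#'
#' @param sigma Gaussian standard deviation in pixels.
#' @param halfwidth kernel half-width in pixels.
#' @param normalize rescale the truncated kernel to unit sum?
#' @return numeric matrix of dimension `2 * halfwidth + 1` squared.
#' @export
gaussian_kernel <- function(sigma = 5, halfwidth = 5, normalize = TRUE) {
  stopifnot(sigma > 0, halfwidth >= 0)
  u <- -halfwidth:halfwidth
  g1 <- exp(-u^2 / (2 * sigma^2))
  k <- outer(g1, g1)
  if (normalize) k / sum(k) else k / (2 * pi * sigma^2)
}

# Shift a matrix by (dy, dx) with zero fill: out[r, c] = x[r + dy, c + dx]
# when in range, else 0. Used by the directional correlators, whose support
# therefore shrinks at the field borders.
shift2 <- function(x, dy, dx) {
  h <- nrow(x)
  w <- ncol(x)
  out <- matrix(0, h, w)
  r0 <- max(1, 1 - dy)
  r1 <- min(h, h - dy)
  c0 <- max(1, 1 - dx)
  c1 <- min(w, w - dx)
  if (r1 >= r0 && c1 >= c0) {
    out[r0:r1, c0:c1] <- x[(r0 + dy):(r1 + dy), (c0 + dx):(c1 + dx)]
  }
  out
}

# 3x3 surround ring of 1/8 weights with zero centre (lateral inhibition and
# centre-surround competition kernel).
ring_kernel <- function() {
  k <- matrix(1 / 8, 3, 3)
  k[2, 2] <- 0
  k
}
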