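#' Divisive tanh contrast normalization
#'
#' Each nonnegative input map is divided by its Gaussian-blurred surround
#' plus the baseline contrast sensitivity `psi` and squashed through tanh:
#' `N = tanh(S / (Shat + psi))`, where `Shat` is the truncated-Gaussian
#' surround estimate (see [gaussian_kernel()]). For nonnegative input the
#' output lies in `[0, 1)`. This instantaneous feedback normalization is
#' part of the motion path and stays active in every model variant.
#'
#' @param S a nonnegative `polar_pair` at stage `"S"` (or `"DN"`).
#' @param params a [medulla_params()] list.
#' @return a `polar_pair` at stage `"N"`.
#' @export
contrast_normalize <- function(S, params = medulla_params()) {
  stopifnot(inherits(S, "polar_pair"))
  k <- gaussian_kernel(params$sigma, params$kernel_halfwidth,
                       params$normalize_kernel)
  norm_one <- function(x) tanh(x / (conv2_replicate(x, k) + params$psi))
  polar_pair(norm_one(S$on), norm_one(S$off), "N")
}

#' Centre-surround local contrast pathways
#'
#' The local contrast signal is the competition between each neuron and its
#' surround: `C = N - ring * N`, where `ring` is the 3x3 surround of 1/8
#' weights with zero centre. The output is signed. With
#' `contrast_enabled = FALSE` all-zero maps are returned, the ablation
#' variant without the ON/OFF contrast neural computation.
#'
#' @param N a `polar_pair` at stage `"N"`.
#' @param params a [medulla_params()] list.
#' @return a `polar_pair` at stage `"C"`.
#' @export
local_contrast <- function(N, params = medulla_params()) {
  stopifnot(inherits(N, "polar_pair"))
  if (!params$contrast_enabled) {
    z <- matrix(0, nrow(N$on), ncol(N$on))
    return(polar_pair(z, z, "C"))
  }
  k <- ring_kernel()
  polar_pair(N$on - conv2_replicate(N$on, k),
             N$off - conv2_replicate(N$off, k), "C")
}

# Four co-registered directional maps keyed U/D/R/L.
directional_quad <- function(U, D, R, L, stage) {
  structure(list(U = U, D = D, R = R, L = L, stage = stage),
            class = "directional_quad")
}

#' @export
print.directional_quad <- function(x, ...) {
  cat(sprintf("directional_quad [stage %s]: %d x %d\n", x$stage,
              nrow(x$U), ncol(x$U)))
  invisible(x)
}

# Shared four-direction pairwise correlator: for each direction the
# spatially shifted current map is multiplied with the delayed map and the
# mirrored product subtracted. Out-of-field shifted samples are zeros, so
# correlator support shrinks at the borders. "Up" is decreasing row index.
correlate_quad <- function(now, delayed, sd, stage) {
  if (!identical(dim(now), dim(delayed))) {
    stop("current and delayed maps must have identical dimensions")
  }
  one <- function(dy, dx) {
    shift2(now, dy, dx) * delayed - now * shift2(delayed, dy, dx)
  }
  directional_quad(one(-sd, 0), one(sd, 0), one(0, sd), one(0, -sd), stage)
}

#' Four-directional T4 correlators (ON pathway)
#'
#' Correlation-type motion detection on the normalized ON signal: for the
#' rightward subtype, `T4R(x, y) = N(x + sd, y) * ND(x, y) -
#' N(x, y) * ND(x + sd, y)` with `ND` the delayed normalized ON map, and
#' analogously for up/down/left. Swapping the current and delayed inputs
#' negates every map.
#'
#' @param n_on_now current normalized ON map (matrix).
#' @param n_on_delayed normalized ON map `delay_frames` earlier (all-zero
#'   before history exists).
#' @param sd sampling distance of every pairwise detector, in pixels.
#' @return a `directional_quad` at stage `"T4"`.
#' @export
t4_correlate <- function(n_on_now, n_on_delayed, sd = 4) {
  correlate_quad(n_on_now, n_on_delayed, sd, "T4")
}
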