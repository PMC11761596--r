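#' Convert a frame to grayscale
#'
#' Three-channel frames are combined with ITU-R BT.601 luma weights
#' (0.299, 0.587, 0.114); single-channel input passes through unchanged.
#'
#' @param frame a matrix, or an array with a trailing channel dimension of
#'   size 1 or 3.
#' @return a numeric matrix.
#' @export
to_grayscale <- function(frame) {
  if (is.matrix(frame)) {
    return(frame)
  }
  d <- dim(frame)
  if (length(d) == 3 && d[3] == 1) {
    return(matrix(frame[, , 1], d[1], d[2]))
  }
  if (length(d) == 3 && d[3] == 3) {
    g <- 0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
    return(matrix(g, d[1], d[2]))
  }
  stop("unsupported channel count: expected 1 or 3 channels")
}

#' Luminance change between two successive frames
#'
#' The photoreceptor stage: the signed difference `curr - prev`.
#'
#' @param prev,curr equally sized numeric matrices.
#' @return a signed numeric matrix.
#' @export
luminance_change <- function(prev, curr) {
  if (!identical(dim(prev), dim(curr))) {
    stop("frame dimension mismatch")
  }
  curr - prev
}

# Co-registered ON and OFF 2-D signal maps at one time step.
polar_pair <- function(on, off, stage) {
  structure(list(on = on, off = off, stage = stage), class = "polar_pair")
}

#' @export
print.polar_pair <- function(x, ...) {
  cat(sprintf("polar_pair [stage %s]: %d x %d\n", x$stage,
              nrow(x$on), ncol(x$on)))
  invisible(x)
}

#' Half-wave rectification into ON and OFF pathways
#'
#' Splits a signed luminance change into the brightness-increment (ON) and
#' brightness-decrement (OFF) channels; the OFF signal is sign-inverted so
#' both maps are nonnegative.
#'
#' @param P signed luminance-change matrix.
#' @return a `polar_pair` at stage `"L"`.
#' @export
hwr_split <- function(P) {
  polar_pair(pmax(P, 0), pmax(-P, 0), "L")
}

#' Normalized passing coefficient of the spatial denoising mechanism
#'
#' For each polarity, the average luminance change (ALC) is the uniform 3x3
#' neighbourhood mean, so clustered excitation obtains a large coefficient
#' and isolated excitation a small one. The normalized passing coefficient
#' (NPC) divides the ALC by `delta_c` plus the frame-wide ALC maximum of
#' that polarity; an all-zero polarity yields an all-zero NPC.
#'
#' @param L a `polar_pair` at stage `"L"`.
#' @param delta_c small positive constant preventing a vanishing
#'   denominator.
#' @return list with nonnegative matrices `on` and `off`, each in `[0, 1)`.
#' @export
passing_coefficient <- function(L, delta_c = 0.01) {
  stopifnot(inherits(L, "polar_pair"))
  box <- matrix(1 / 9, 3, 3)
  npc_one <- function(x) {
    alc <- conv2_replicate(x, box)
    m <- max(alc)
    if (m <= 0) alc * 0 else alc / (delta_c + m)
  }
  list(on = npc_one(L$on), off = npc_one(L$off))
}

#' Spatial denoising by the passing coefficient and threshold comparison
#'
#' Multiplies each polarity by its normalized passing coefficient and then
#' zeroes values that decayed below `iso_threshold` (the threshold
#' comparison filtering isolated excitation). With
#' `denoise_enabled = FALSE` the input passes through unchanged, which is
#' the ablation variant without the spatial denoising mechanism.
#'
#' @param L a `polar_pair` at stage `"L"`.
#' @param params a [lamina_params()] list.
#' @return a `polar_pair` at stage `"DN"`.
#' @export
spatial_denoise <- function(L, params = lamina_params()) {
  stopifnot(inherits(L, "polar_pair"))
  if (!params$denoise_enabled) {
    return(polar_pair(L$on, L$off, "DN"))
  }
  npc <- passing_coefficient(L, params$delta_c)
  dn_one <- function(x, npc) {
    dn <- x * npc
    dn[dn < params$iso_threshold] <- 0
    dn
  }
  polar_pair(dn_one(L$on, npc$on), dn_one(L$off, npc$off), "DN")
}

#' Spatio-temporal lateral inhibition
#'
#' Each inter-neuron is inhibited by the one-frame-delayed activity of its
#' 3x3 surround (delayed propagation): the surround mean of the previous
#' step's denoised map, scaled by `li_weight`, is subtracted and the result
#' rectified at zero. With no history (`DN_prev` all zero) the input passes
#' through; `li_enabled = FALSE` disables the mechanism.
#'
#' @param DN a `polar_pair` at stage `"DN"` for the current step.
#' @param DN_prev the previous step's `"DN"` pair (all-zero at the first
#'   step).
#' @param params a [lamina_params()] list.
#' @return a nonnegative `polar_pair` at stage `"S"`.
#' @export
lateral_inhibition <- function(DN, DN_prev, params = lamina_params()) {
  stopifnot(inherits(DN, "polar_pair"), inherits(DN_prev, "polar_pair"))
  if (!params$li_enabled) {
    return(polar_pair(DN$on, DN$off, "S"))
  }
  k <- ring_kernel()
  li_one <- function(x, prev) {
    pmax(x - params$li_weight * conv2_replicate(prev, k), 0)
  }
  polar_pair(li_one(DN$on, DN_prev$on), li_one(DN$off, DN_prev$off), "S")
}

#' Alternative early visual pre-processing variants
#'
#' Replaces the cluster-based spatial denoising (passing coefficient +
#' threshold comparison) with a comparison filter: `"dog"` is a difference
#' of two Gaussian blurs rectified at zero; `"gaussian"`, `"mean"` and
#' `"median"` are the standard 3x3 filters; `"fdsr"` is a per-pixel
#' fast-depolarizing slow-repolarizing temporal filter (the baseline rises
#' instantly with the signal and decays with time constant `fdsr_tau`
#' frames; the delayed baseline is subtracted and the result rectified).
#' `"cluster"` dispatches to [spatial_denoise()].
#'
#' @param L a `polar_pair` at stage `"L"`.
#' @param params a [lamina_params()] list (fields `preprocessor`,
#'   `dog_sigma`, `fdsr_tau`).
#' @param state per-sequence filter state (used by `"fdsr"`); pass the
#'   `state` element of the previous call, or `NULL` at the first step.
#' @return list with elements `pair` (a `polar_pair` at stage `"DN"`) and
#'   `state`.
#' @export
apply_preprocessor <- function(L, params = lamina_params(), state = NULL) {
  stopifnot(inherits(L, "polar_pair"))
  v <- params$preprocessor
  if (v == "cluster") {
    return(list(pair = spatial_denoise(L, params), state = NULL))
  }
  filt <- switch(v,
    dog = function(x) {
      s1 <- params$dog_sigma[1]
      s2 <- params$dog_sigma[2]
      b1 <- conv2_replicate(x, gaussian_kernel(s1, ceiling(3 * s1)))
      b2 <- conv2_replicate(x, gaussian_kernel(s2, ceiling(3 * s2)))
      pmax(b1 - b2, 0)
    },
    gaussian = function(x) {
      conv2_replicate(x, matrix(c(1, 2, 1, 2, 4, 2, 1, 2, 1) / 16, 3, 3))
    },
    mean = function(x) conv2_replicate(x, matrix(1 / 9, 3, 3)),
    median = median_filter3,
    fdsr = NULL,
    stop("unknown preprocessor variant: ", v)
  )
  if (v == "fdsr") {
    if (is.null(state)) {
      z <- matrix(0, nrow(L$on), ncol(L$on))
      state <- list(on = z, off = z)
    }
    decay <- exp(-1 / params$fdsr_tau)
    out_on <- pmax(L$on - state$on, 0)
    out_off <- pmax(L$off - state$off, 0)
    state <- list(on = pmax(L$on, state$on * decay),
                  off = pmax(L$off, state$off * decay))
    return(list(pair = polar_pair(out_on, out_off, "DN"), state = state))
  }
  list(pair = polar_pair(filt(L$on), filt(L$off), "DN"), state = NULL)
}

# 3x3 median filter with replicate padding.
median_filter3 <- function(x) {
  h <- nrow(x)
  w <- ncol(x)
  xp <- x[c(1, 1:h, h), c(1, 1:w, w)]
  stack <- vapply(1:3, function(i) {
    vapply(1:3, function(j) xp[i:(i + h - 1), j:(j + w - 1)],
           matrix(0, h, w))
  }, array(0, c(h, w, 3)))
  apply(array(stack, c(h, w, 9)), c(1, 2), stats::median)
}
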