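#' Four-directional T5 correlators (OFF pathway)
#'
#' Structurally identical to [t4_correlate()] but operating on the
#' normalized OFF signal and its delayed copy.
#'
#' @param n_off_now current normalized OFF map (matrix).
#' @param n_off_delayed normalized OFF map `delay_frames` earlier.
#' @param sd sampling distance in pixels.
#' @return a `directional_quad` at stage `"T5"`.
#' @export
t5_correlate <- function(n_off_now, n_off_delayed, sd = 4) {
  correlate_quad(n_off_now, n_off_delayed, sd, "T5")
}

#' Convergence of motion and contrast pathways on the LPTC
#'
#' Per direction `X`, the ON-pathway motion signal minus the ON contrast
#' signal and the OFF-pathway motion signal minus the OFF contrast signal
#' are rectified at zero, raised to the exponents `gamma1` and `gamma2`, and
#' summed: `LPTC_X = max(T4_X - C_on, 0)^gamma1 +
#' max(T5_X - C_off, 0)^gamma2`. Rectifying before the (fractional) power
#' keeps the response real and nonnegative, consistent with firing-rate
#' semantics. The contrast pathways thus negatively gate the motion
#' pathways, suppressing high-contrast optical flow.
#'
#' @param T4 a `directional_quad` at stage `"T4"`.
#' @param T5 a `directional_quad` at stage `"T5"`.
#' @param C a `polar_pair` at stage `"C"` (all-zero when the contrast
#'   computation is ablated).
#' @param params a [lobula_params()] list.
#' @return a nonnegative `directional_quad` at stage `"LPTC"`.
#' @export
lptc_converge <- function(T4, T5, C, params = lobula_params()) {
  stopifnot(inherits(T4, "directional_quad"),
            inherits(T5, "directional_quad"), inherits(C, "polar_pair"))
  pow_rect <- function(v, g) pmax(v, 0)^g
  one <- function(d) {
    pow_rect(T4[[d]] - C$on, params$gamma1) +
      pow_rect(T5[[d]] - C$off, params$gamma2)
  }
  directional_quad(one("U"), one("D"), one("R"), one("L"), "LPTC")
}

#' LPi direction opponency: vertical and horizontal system responses
#'
#' Opposite LPTC directions inhibit each other through sign-inverting LPi
#' pairing (the upward LPi signal is the downward LPTC map and vice versa;
#' likewise left/right). The vertical system response is
#' `VS = sum[LPTC_U - LPTC_D]+ - sum[LPTC_D - LPTC_U]+` over all pixels
#' (`[.]+` denoting rectification), and the horizontal response HS is the
#' analogous right/left sum. `VS > 0` encodes upward and `VS < 0` downward
#' motion; `HS > 0` rightward and `HS < 0` leftward.
#'
#' @param LPTC a `directional_quad` at stage `"LPTC"`.
#' @return named numeric vector `c(vs = ..., hs = ...)` for this frame.
#' @export
lpi_opponency <- function(LPTC) {
  stopifnot(inherits(LPTC, "directional_quad"))
  vs <- sum(pmax(LPTC$U - LPTC$D, 0)) - sum(pmax(LPTC$D - LPTC$U, 0))
  hs <- sum(pmax(LPTC$R - LPTC$L, 0)) - sum(pmax(LPTC$L - LPTC$R, 0))
  c(vs = vs, hs = hs)
}

#' Decode the per-frame motion direction label
#'
#' The channel with the larger magnitude wins (exact ties go to the
#' vertical channel); the winning channel's sign selects the label. Frames
#' whose strongest response is below `epsilon` decode as `"none"` and count
#' as detection failures.
#'
#' @param vs,hs vertical and horizontal system responses.
#' @param epsilon minimal response magnitude for a valid detection.
#' @return one of `"up"`, `"down"`, `"left"`, `"right"`, `"none"`.
#' @export
decide_direction <- function(vs, hs, epsilon = 1e-9) {
  if (max(abs(vs), abs(hs)) < epsilon) {
    return("none")
  }
  if (abs(vs) >= abs(hs)) {
    if (vs > 0) "up" else "down"
  } else {
    if (hs > 0) "right" else "left"
  }
}
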