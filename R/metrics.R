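#' Detection success rate
#'
#' Percentage of evaluated frames whose decoded direction matches the
#' ground-truth motion direction; `"none"` decisions count as failures.
#'
#' @param decisions character vector of decoded labels.
#' @param truth ground-truth label(s); a scalar is recycled.
#' @return percentage in `[0, 100]`.
#' @export
detection_rate <- function(decisions, truth) {
  if (!length(decisions)) stop("no decisions to evaluate")
  if (length(truth) == 1) truth <- rep(truth, length(decisions))
  if (length(truth) != length(decisions)) {
    stop("decisions and truth must have equal length")
  }
  100 * mean(decisions == truth)
}

#' Per-frame coefficient of variation across an ensemble
#'
#' For an ensemble of response series recorded under varying conditions
#' (e.g. the ten object grey values of one direction), the coefficient of
#' variation at frame `t` is the population standard deviation divided by
#' the mean of the ensemble values at `t`. Frames with zero mean yield 0.
#'
#' @param ensemble numeric matrix, frames in rows and ensemble members in
#'   columns (at least 2 members).
#' @return numeric vector of per-frame coefficients of variation.
#' @export
coefficient_of_variation <- function(ensemble) {
  ensemble <- as.matrix(ensemble)
  if (ncol(ensemble) < 2) stop("need at least 2 ensemble members")
  m <- rowMeans(ensemble)
  s <- sqrt(rowMeans((ensemble - m)^2))  # population standard deviation
  ifelse(m == 0, 0, s / m)
}

#' Inter-quartile range and sum of a coefficient-of-variation series
#'
#' `IQR = Q3 - Q1` with linear-interpolation (type 7) quantiles on the
#' pooled values; `S` is the plain sum.
#'
#' @param cv numeric vector of pooled coefficient-of-variation values.
#' @return list with elements `iqr` and `s`.
#' @export
iqr_and_sum <- function(cv) {
  if (!length(cv)) stop("empty coefficient-of-variation series")
  q <- quantile(cv, c(0.25, 0.75), type = 7, names = FALSE)
  list(iqr = q[2] - q[1], s = sum(cv))
}
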