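#' Lamina-layer parameters
#'
#' Parameters of the ON/OFF pre-processing performed in the lamina: the
#' cluster-based spatial denoising (neighbourhood-average passing
#' coefficient, max-normalized with floor constant `delta_c`, followed by a
#' threshold comparison that removes decayed isolated excitation) and the
#' spatio-temporal lateral inhibition by the one-frame-delayed 3x3 surround.
#'
#' @param delta_c small positive constant in the passing-coefficient
#'   normalization denominator (default 0.01).
#' @param iso_threshold threshold of the comparison that zeroes decayed
#'   (isolated) excitation after denoising; chosen so that a single isolated
#'   pixel at typical figure-ground contrast decays below it while 3x3
#'   clusters survive.
#' @param li_weight weight in `[0, 1]` of the delayed-surround subtraction.
#' @param li_enabled apply lateral inhibition?
#' @param denoise_enabled apply spatial denoising (FALSE gives the ablation
#'   variant without the denoising mechanism)?
#' @param preprocessor early visual pre-processing variant: `"cluster"` is
#'   the model's own passing-coefficient denoiser; `"dog"`, `"fdsr"`,
#'   `"gaussian"`, `"mean"` and `"median"` replace it with a difference of
#'   Gaussians, a fast-depolarizing slow-repolarizing temporal filter, or a
#'   standard 3x3 Gaussian/mean/median filter, for comparison studies.
#' @param dog_sigma the two blur standard deviations of the `"dog"` variant.
#' @param fdsr_tau decay time constant, in frames, of the `"fdsr"` variant.
#' @return a validated list of class `lamina_params`.
#' @export
lamina_params <- function(delta_c = 0.01, iso_threshold = 10, li_weight = 0.25,
                          li_enabled = TRUE, denoise_enabled = TRUE,
                          preprocessor = c("cluster", "dog", "fdsr",
                                           "gaussian", "mean", "median"),
                          dog_sigma = c(1, 2), fdsr_tau = 3) {
  preprocessor <- match.arg(preprocessor)
  p <- structure(list(delta_c = delta_c, iso_threshold = iso_threshold,
                      li_weight = li_weight, li_enabled = li_enabled,
                      denoise_enabled = denoise_enabled,
                      preprocessor = preprocessor, dog_sigma = dog_sigma,
                      fdsr_tau = fdsr_tau),
                 class = "lamina_params")
  validate_lamina_params(p)
}

validate_lamina_params <- function(p) {
  if (!is.numeric(p$delta_c) || p$delta_c <= 0) {
    stop("delta_c must be a positive number")
  }
  if (!is.numeric(p$iso_threshold) || p$iso_threshold < 0) {
    stop("iso_threshold must be >= 0")
  }
  if (!is.numeric(p$li_weight) || p$li_weight < 0 || p$li_weight > 1) {
    stop("li_weight must lie in [0, 1]")
  }
  if (length(p$dog_sigma) != 2 || any(p$dog_sigma <= 0)) {
    stop("dog_sigma must be two positive standard deviations")
  }
  if (p$fdsr_tau <= 0) stop("fdsr_tau must be positive")
  p
}

#' Medulla-layer parameters
#'
#' Parameters of the divisive tanh contrast normalization (baseline contrast
#' sensitivity `psi`, Gaussian surround of standard deviation `sigma`
#' truncated at `kernel_halfwidth`), of the temporal delay unit feeding the
#' correlators, and of the pairwise correlator sampling distance `sd`.
#'
#' @param psi baseline contrast sensitivity added to the surround estimate
#'   in the divisive normalization denominator.
#' @param sigma standard deviation, in pixels, of the Gaussian surround.
#' @param kernel_halfwidth half-width of the truncated Gaussian kernel.
#' @param sd sampling distance, in pixels, of every pairwise detector.
#' @param delay_frames delay, in frames, of the temporal delay unit.
#' @param contrast_enabled activate the ON/OFF contrast pathways (FALSE gives
#'   the ablation variant without the contrast neural computation; the
#'   normalization itself remains active)?
#' @param normalize_kernel renormalize the truncated Gaussian surround kernel
#'   to unit sum (see [gaussian_kernel()])?
#' @return a validated list of class `medulla_params`.
#' @export
medulla_params <- function(psi = 20, sigma = 5, kernel_halfwidth = 5, sd = 4,
                           delay_frames = 1, contrast_enabled = TRUE,
                           normalize_kernel = TRUE) {
  p <- structure(list(psi = psi, sigma = sigma,
                      kernel_halfwidth = kernel_halfwidth, sd = sd,
                      delay_frames = delay_frames,
                      contrast_enabled = contrast_enabled,
                      normalize_kernel = normalize_kernel),
                 class = "medulla_params")
  validate_medulla_params(p)
}

validate_medulla_params <- function(p) {
  if (!is.numeric(p$psi) || p$psi <= 0) stop("psi must be positive")
  if (!is.numeric(p$sigma) || p$sigma <= 0) stop("sigma must be positive")
  if (p$kernel_halfwidth < 0) stop("kernel_halfwidth must be >= 0")
  if (!is.numeric(p$sd) || p$sd < 1) stop("sd must be >= 1")
  if (p$delay_frames < 1) stop("delay_frames must be >= 1")
  p
}

#' Lobula-complex parameters
#'
#' @param gamma1,gamma2 exponents applied to the rectified ON and OFF terms
#'   when motion and contrast pathways converge on the LPTC.
#' @param decision_epsilon minimal `max(|VS|, |HS|)` for a frame to count as
#'   a valid detection; numerically silent frames decode as `"none"`.
#' @return a validated list of class `lobula_params`.
#' @export
lobula_params <- function(gamma1 = 0.5, gamma2 = 0.5,
                          decision_epsilon = 1e-9) {
  p <- structure(list(gamma1 = gamma1, gamma2 = gamma2,
                      decision_epsilon = decision_epsilon),
                 class = "lobula_params")
  validate_lobula_params(p)
}

validate_lobula_params <- function(p) {
  if (!is.numeric(p$gamma1) || p$gamma1 <= 0 ||
      !is.numeric(p$gamma2) || p$gamma2 <= 0) {
    stop("gamma1 and gamma2 must be positive")
  }
  if (p$decision_epsilon < 0) stop("decision_epsilon must be >= 0")
  p
}

#' Full model parameter set
#'
#' Bundles the per-layer parameter lists. The defaults reproduce the model's
#' reference configuration: `delta_c = 0.01`, `psi = 20.0`, `sigma = 5`,
#' `sd = 4`, `gamma1 = gamma2 = 0.5`.
#'
#' @param lamina a [lamina_params()] list.
#' @param medulla a [medulla_params()] list.
#' @param lobula a [lobula_params()] list.
#' @param frame_rate default stimulus frame rate in frames/second.
#' @return a list of class `model_params`.
#' @export
model_params <- function(lamina = lamina_params(),
                         medulla = medulla_params(),
                         lobula = lobula_params(),
                         frame_rate = 30) {
  stopifnot(inherits(lamina, "lamina_params"),
            inherits(medulla, "medulla_params"),
            inherits(lobula, "lobula_params"))
  if (!is.numeric(frame_rate) || frame_rate <= 0) {
    stop("frame_rate must be positive")
  }
  structure(list(lamina = lamina, medulla = medulla, lobula = lobula,
                 frame_rate = frame_rate),
            class = "model_params")
}

# Flat parameter list consumed by the compiled sequence engine.
engine_par <- function(params) {
  la <- params$lamina
  me <- params$medulla
  lo <- params$lobula
  list(delta_c = la$delta_c, iso_threshold = la$iso_threshold,
       li_weight = la$li_weight, li_enabled = la$li_enabled,
       denoise_enabled = la$denoise_enabled,
       psi = me$psi, sigma = me$sigma,
       kernel_halfwidth = as.integer(me$kernel_halfwidth),
       sd = as.integer(me$sd), delay_frames = as.integer(me$delay_frames),
       gamma1 = lo$gamma1, gamma2 = lo$gamma2,
       contrast_enabled = me$contrast_enabled,
       normalize_kernel = me$normalize_kernel)
}

#' Load a model configuration file
#'
#' Reads a YAML configuration with optional `lamina:`, `medulla:`, `lobula:`
#' and `frame_rate:` sections; keys that are absent keep their defaults (see
#' [model_params()]). Unknown keys and out-of-range values raise a named
#' validation error.
#'
#' @param path path to a YAML file, or `NULL` for the pure defaults.
#' @return a `model_params` list.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) {
    return(model_params())
  }
  cfg <- yaml::read_yaml(path)
  known <- c("lamina", "medulla", "lobula", "frame_rate")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    stop("unknown configuration section(s): ", paste(bad, collapse = ", "))
  }
  merge_section <- function(ctor, section, class_name) {
    defaults <- ctor()
    given <- cfg[[section]]
    if (is.null(given)) {
      return(defaults)
    }
    bad <- setdiff(names(given), names(unclass(defaults)))
    if (length(bad)) {
      stop("unknown key(s) in '", section, "': ", paste(bad, collapse = ", "))
    }
    do.call(ctor, given)
  }
  model_params(
    lamina = merge_section(lamina_params, "lamina"),
    medulla = merge_section(medulla_params, "medulla"),
    lobula = merge_section(lobula_params, "lobula"),
    frame_rate = if (is.null(cfg$frame_rate)) 30 else cfg$frame_rate
  )
}
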