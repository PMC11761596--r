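#' Canonical translating-object stimulus of the benchmark datasets
#'
#' The benchmark geometry: a 500 x 250 field with solid background grey 1,
#' a solid rectangular object of the given grey value translating at
#' 2000 pixels/second, 100 frames at 30 fps. The object measures 100 pixels
#' along the motion axis and 50 pixels across it (100 x 50 for vertical,
#' 50 x 100 for horizontal motion), so that at 66.67 pixels/frame the
#' ON/OFF difference strips of consecutive frames abut and the pairwise
#' correlators see the motion.
#'
#' @param gray object grey value in `[0, 255]`.
#' @param direction `"up"`, `"down"`, `"left"` or `"right"`.
#' @param noise a [noise_spec()].
#' @param frame_count number of frames.
#' @return a [stimulus_spec()].
#' @export
study_stimulus_spec <- function(gray, direction, noise = noise_spec("none"),
                                frame_count = 100) {
  vertical <- direction %in% c("up", "down")
  stimulus_spec(
    field_width = 500, field_height = 250, background_gray = 1,
    object_gray = gray,
    object_width = if (vertical) 50 else 100,
    object_height = if (vertical) 100 else 50,
    direction = direction, object_velocity = 2000,
    frame_count = frame_count, frame_rate = 30, noise = noise
  )
}

#' Benchmark noise conditions
#'
#' The ten noise conditions of the fixed-contrast noisy dataset: clean,
#' salt-and-pepper ratios 0.01-0.04 and Gaussian standard deviations
#' 10, 20, 30, 50, 80.
#'
#' @param seed base noise seed recorded in every condition.
#' @return named list of [noise_spec()] objects.
#' @export
default_noise_grid <- function(seed = 1L) {
  specs <- c(
    list(none = noise_spec("none", seed = seed)),
    lapply(c(0.01, 0.02, 0.03, 0.04), function(r) {
      noise_spec("salt_pepper", spn_ratio = r, seed = seed)
    }),
    lapply(c(10, 20, 30, 50, 80), function(s) {
      noise_spec("gaussian", gn_std = s, seed = seed)
    })
  )
  names(specs) <- c("none", paste0("spn_", c(0.01, 0.02, 0.03, 0.04)),
                    paste0("gn_", c(10, 20, 30, 50, 80)))
  specs
}

#' Parameter sets of the named model variants
#'
#' `"full"` is the complete model; `"model1_no_contrast"` disables the
#' ON/OFF contrast pathways (the normalization itself stays active);
#' `"model2_no_denoise"` disables the spatial denoising mechanism;
#' `"model3_dog"` through `"model7_median"` replace the denoiser with the
#' corresponding pre-processing filter (see [apply_preprocessor()]).
#'
#' @param variant variant name.
#' @param base a [model_params()] list to derive from.
#' @return a `model_params` list with the variant's flags set.
#' @export
model_variant_params <- function(variant = c("full", "model1_no_contrast",
                                             "model2_no_denoise",
                                             "model3_dog", "model4_fdsr",
                                             "model5_gaussian", "model6_mean",
                                             "model7_median"),
                                 base = model_params()) {
  variant <- match.arg(variant)
  la <- unclass(base$lamina)
  me <- unclass(base$medulla)
  if (variant == "model1_no_contrast") {
    me$contrast_enabled <- FALSE
  } else if (variant == "model2_no_denoise") {
    la$denoise_enabled <- FALSE
  } else if (variant != "full") {
    la$preprocessor <- switch(variant,
                              model3_dog = "dog", model4_fdsr = "fdsr",
                              model5_gaussian = "gaussian",
                              model6_mean = "mean", model7_median = "median")
  }
  model_params(lamina = do.call(lamina_params, la),
               medulla = do.call(medulla_params, me),
               lobula = base$lobula, frame_rate = base$frame_rate)
}

# Dominant-channel response magnitude for a truth direction.
dominant_response <- function(out, truth) {
  if (truth %in% c("up", "down")) abs(out$vs) else abs(out$hs)
}

# Pool per-frame coefficients of variation across directions: `by_direction`
# is a named list of frames x members matrices of dominant-channel response
# magnitudes; returns the concatenated CV series (direction order fixed).
pooled_cv <- function(by_direction) {
  unlist(lapply(by_direction, coefficient_of_variation), use.names = FALSE)
}

#' Run the variable-contrast benchmark under one noise condition
#'
#' Generates the 10 grey values x 4 directions sub-dataset (see
#' [study_stimulus_spec()]), optionally corrupts every sequence with the
#' given noise, runs the selected model on each, and aggregates the pooled
#' detection success rate together with the response-stability metrics: the
#' per-frame coefficient of variation is taken across the grey-value
#' ensemble of each direction on the dominant-channel response magnitude
#' (|VS| for vertical, |HS| for horizontal truth) and pooled over the four
#' directions for the inter-quartile range and sum.
#'
#' Every (direction, grey) condition uses its own noise stream derived from
#' `seed`, so repeated calls with the same seed are identical.
#'
#' @param noise a [noise_spec()]; its `seed` field is overridden per
#'   condition from `seed`.
#' @param params a [model_params()] list (use [model_variant_params()] for
#'   the ablation variants).
#' @param grays object grey values of the ensemble.
#' @param directions motion directions.
#' @param seed base seed for the per-condition noise streams.
#' @param frame_count frames per sequence.
#' @return list with elements `dr` (pooled detection rate, %), `cv`
#'   (pooled coefficient-of-variation series), `iqr`, `s`, `n_frames`
#'   (evaluated decisions pooled into `dr`) and `responses` (per-direction
#'   frames x greys matrices of dominant responses).
#' @export
run_pure_benchmark <- function(noise = noise_spec("none"),
                               params = model_params(),
                               grays = seq(250, 25, by = -25),
                               directions = c("up", "down", "left", "right"),
                               seed = 1L, frame_count = 100) {
  correct <- 0L
  total <- 0L
  responses <- list()
  cond <- 0L
  for (dir in directions) {
    ens <- NULL
    for (g in grays) {
      cond <- cond + 1L
      spec <- study_stimulus_spec(g, dir, frame_count = frame_count)
      seq <- render_sequence(spec)
      if (noise$kind != "none") {
        nspec <- noise
        nspec$seed <- as.integer(seed + 1000L * cond)
        seq <- add_noise(seq, nspec)
      }
      out <- run_model(seq, params)
      correct <- correct + sum(out$decision == dir)
      total <- total + nrow(out)
      ens <- cbind(ens, dominant_response(out, dir))
    }
    responses[[dir]] <- ens
  }
  cv <- pooled_cv(responses)
  stats <- iqr_and_sum(cv)
  list(dr = 100 * correct / total, cv = cv, iqr = stats$iqr, s = stats$s,
       n_frames = total, responses = responses)
}

#' Contrast-computation ablation study (variable contrast, no noise)
#'
#' Runs the full model and the variant without the ON/OFF contrast neural
#' computation on the noise-free variable-contrast dataset and compares the
#' stability metrics. The reported percentage reductions are
#' `100 * (metric_ablated - metric_full) / metric_ablated`.
#'
#' @param params base [model_params()].
#' @param grays,directions,frame_count forwarded to
#'   [run_pure_benchmark()].
#' @return list with the two models' `iqr`/`s`, the pooled detection rates,
#'   and `iqr_reduction_pct` / `s_reduction_pct`.
#' @export
ablation_contrast_study <- function(params = model_params(),
                                    grays = seq(250, 25, by = -25),
                                    directions = c("up", "down", "left",
                                                   "right"),
                                    frame_count = 100) {
  full <- run_pure_benchmark(params = params, grays = grays,
                             directions = directions,
                             frame_count = frame_count)
  m1 <- run_pure_benchmark(
    params = model_variant_params("model1_no_contrast", params),
    grays = grays, directions = directions, frame_count = frame_count)
  list(full = full, model1 = m1,
       iqr_reduction_pct = 100 * (m1$iqr - full$iqr) / m1$iqr,
       s_reduction_pct = 100 * (m1$s - full$s) / m1$s)
}

#' Spatial-denoising ablation study (fixed contrast, variable noise)
#'
#' Builds the fixed-contrast noisy dataset (object grey 250, the ten noise
#' conditions of [default_noise_grid()], four directions), runs the full
#' model and the variant without the spatial denoising mechanism on the
#' *same* noisy sequences (matched noise streams), and compares the pooled
#' stability metrics. The coefficient-of-variation ensemble of each
#' direction is taken across the ten noise conditions.
#'
#' @param seed base seed of the per-condition noise streams.
#' @param params base [model_params()].
#' @param gray fixed object grey value.
#' @param directions motion directions.
#' @param noise_grid list of [noise_spec()] conditions.
#' @param frame_count frames per sequence.
#' @return list with `full` and `model2` metric lists and the
#'   `iqr_reduction_pct` / `s_reduction_pct` of the full model relative to
#'   the ablated one.
#' @export
denoise_ablation_study <- function(seed = 1L, params = model_params(),
                                   gray = 250,
                                   directions = c("up", "down", "left",
                                                  "right"),
                                   noise_grid = default_noise_grid(),
                                   frame_count = 100) {
  p_full <- params
  p_m2 <- model_variant_params("model2_no_denoise", params)
  resp_full <- list()
  resp_m2 <- list()
  cond <- 0L
  for (dir in directions) {
    ens_full <- NULL
    ens_m2 <- NULL
    for (k in seq_along(noise_grid)) {
      cond <- cond + 1L
      spec <- study_stimulus_spec(gray, dir, frame_count = frame_count)
      seq <- render_sequence(spec)
      nspec <- noise_grid[[k]]
      if (nspec$kind != "none") {
        nspec$seed <- as.integer(seed + 1000L * cond)
        seq <- add_noise(seq, nspec)
      }
      out_full <- run_model(seq, p_full)
      out_m2 <- run_model(seq, p_m2)
      ens_full <- cbind(ens_full, dominant_response(out_full, dir))
      ens_m2 <- cbind(ens_m2, dominant_response(out_m2, dir))
    }
    resp_full[[dir]] <- ens_full
    resp_m2[[dir]] <- ens_m2
  }
  st_full <- iqr_and_sum(pooled_cv(resp_full))
  st_m2 <- iqr_and_sum(pooled_cv(resp_m2))
  list(full = st_full, model2 = st_m2,
       iqr_reduction_pct = 100 * (st_m2$iqr - st_full$iqr) / st_m2$iqr,
       s_reduction_pct = 100 * (st_m2$s - st_full$s) / st_m2$s)
}

#' Run a benchmark experiment and write its result tables
#'
#' High-level harness over the benchmark runners: evaluates the selected
#' model variant on the selected dataset preset, optionally across several
#' seeds, and (when `out_dir` is given) writes a per-condition CSV of the
#' metrics plus a JSON provenance record (seeds, parameters, grid) that
#' suffices to re-run the experiment bit-identically.
#'
#' @param dataset_preset `"dataset1"` (variable contrast, no noise),
#'   `"dataset2"` (fixed contrast, the ten noise conditions) or
#'   `"dataset3"` (variable contrast under each requested noise condition).
#' @param model_variant a [model_variant_params()] name.
#' @param noise_grid noise conditions for presets 2 and 3.
#' @param seeds integer vector of noise seeds (results are averaged).
#' @param params base [model_params()].
#' @param out_dir optional output directory.
#' @param frame_count frames per sequence.
#' @return data frame of per-condition, per-seed metrics (`dr`, `iqr`, `s`).
#' @export
run_experiment <- function(dataset_preset = c("dataset1", "dataset2",
                                              "dataset3"),
                           model_variant = "full",
                           noise_grid = default_noise_grid(),
                           seeds = 1L, params = model_params(),
                           out_dir = NULL, frame_count = 100) {
  dataset_preset <- match.arg(dataset_preset)
  vp <- model_variant_params(model_variant, params)
  rows <- list()
  if (dataset_preset == "dataset1") {
    b <- run_pure_benchmark(params = vp, frame_count = frame_count)
    rows[[1]] <- data.frame(condition = "none", seed = NA_integer_,
                            dr = b$dr, iqr = b$iqr, s = b$s)
  } else if (dataset_preset == "dataset2") {
    for (s in seeds) {
      st <- denoise_ablation_study(seed = s, params = params,
                                   noise_grid = noise_grid,
                                   frame_count = frame_count)
      pick <- if (model_variant == "model2_no_denoise") st$model2 else st$full
      rows[[length(rows) + 1]] <- data.frame(condition = "pooled", seed = s,
                                             dr = NA_real_, iqr = pick$iqr,
                                             s = pick$s)
    }
  } else {
    for (k in seq_along(noise_grid)) {
      for (s in seeds) {
        b <- run_pure_benchmark(noise = noise_grid[[k]], params = vp,
                                seed = s, frame_count = frame_count)
        rows[[length(rows) + 1]] <- data.frame(
          condition = names(noise_grid)[k], seed = s,
          dr = b$dr, iqr = b$iqr, s = b$s)
      }
    }
  }
  res <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(res, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    prov <- list(dataset_preset = dataset_preset,
                 model_variant = model_variant, seeds = seeds,
                 frame_count = frame_count,
                 noise_grid = lapply(noise_grid, unclass),
                 params = lapply(unclass(params), function(x) {
                   if (is.list(x)) unclass(x) else x
                 }),
                 package_version = as.character(
                   utils::packageVersion("lptcmotion")))
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}
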