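# Benchmark reproduction presets: each target re-runs one of the package's
# reference experiments end-to-end and reports the computed metrics next to
# the published reference values for that benchmark configuration, with a
# documented tolerance per row.

reference_values <- function(target) {
  conds <- c("none", "spn_0.01", "spn_0.02", "spn_0.03", "spn_0.04",
             "gn_10", "gn_20", "gn_30", "gn_50", "gn_80")
  switch(target,
    table5 = data.frame(indicator = c("iqr_reduction_pct", "s_reduction_pct"),
                        reference = c(30.03, 42.48), tolerance = c(10, 10)),
    table6 = data.frame(indicator = c("iqr_reduction_pct", "s_reduction_pct"),
                        reference = c(57.38, 17.36), tolerance = c(15, 15)),
    table7 = data.frame(condition = conds,
                        reference = c(99.88, 99.70, 97.75, 94.95, 93.33,
                                      99.85, 99.80, 99.83, 99.63, 99.83),
                        tolerance = c(1, rep(3, 4), rep(1, 5))),
    table8 = data.frame(condition = conds,
                        reference = c(6.228e-10, 0.051, 0.156, 0.276, 0.436,
                                      0.002, 0.007, 0.008, 0.010, 0.034),
                        tolerance = c(1e-3, rep(0.1, 4), rep(0.05, 5))),
    table9 = data.frame(condition = conds,
                        reference = c(121.5, 200.5, 218.8, 243.0, 266.0,
                                      125.2, 126.3, 127.1, 126.9, 124.5),
                        tolerance = rep(40, 10)),
    stop("unknown reproduction target: ", target)
  )
}

#' Reproduce a reference benchmark table
#'
#' Runs the experiment behind one of the reference result tables for the
#' full model (and its ablation twin where the table requires one) and
#' returns the computed metrics side by side with the published reference
#' values and a pass flag at the documented tolerance. `table5` is the
#' contrast-computation ablation on the variable-contrast dataset;
#' `table6` the spatial-denoising ablation on the fixed-contrast noisy
#' dataset; `table7`/`table8`/`table9` the detection success rate,
#' coefficient-of-variation inter-quartile range and sum per noise
#' condition on the variable-contrast noisy dataset.
#'
#' @param target one of `"table5"` ... `"table9"`.
#' @param out_dir optional directory for the CSV report.
#' @param seeds noise seeds (stochastic targets are averaged across them).
#' @param conditions subset of condition names for tables 7-9 (default all
#'   ten; running all is expensive).
#' @param params base [model_params()].
#' @param frame_count frames per sequence.
#' @return data frame with computed values, reference values, tolerance and
#'   pass flag.
#' @export
reproduce <- function(target = c("table5", "table6", "table7", "table8",
                                 "table9"),
                      out_dir = NULL, seeds = 1:3,
                      conditions = NULL, params = model_params(),
                      frame_count = 100) {
  target <- match.arg(target)
  ref <- reference_values(target)
  if (target == "table5") {
    st <- ablation_contrast_study(params = params, frame_count = frame_count)
    ref$value <- c(st$iqr_reduction_pct, st$s_reduction_pct)
  } else if (target == "table6") {
    runs <- lapply(seeds, denoise_ablation_study, params = params,
                   frame_count = frame_count)
    ref$value <- c(mean(vapply(runs, `[[`, 0, "iqr_reduction_pct")),
                   mean(vapply(runs, `[[`, 0, "s_reduction_pct")))
  } else {
    if (!is.null(conditions)) {
      keep <- ref$condition %in% conditions
      ref <- ref[keep, , drop = FALSE]
    }
    grid <- default_noise_grid()[ref$condition]
    metric <- switch(target, table7 = "dr", table8 = "iqr", table9 = "s")
    ref$value <- vapply(seq_along(grid), function(k) {
      use_seeds <- if (grid[[k]]$kind == "none") seeds[1] else seeds
      mean(vapply(use_seeds, function(s) {
        run_pure_benchmark(noise = grid[[k]], params = params, seed = s,
                           frame_count = frame_count)[[metric]]
      }, 0))
    }, 0)
  }
  ref$pass <- abs(ref$value - ref$reference) <= ref$tolerance
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(ref, file.path(out_dir, paste0(target, "_report.csv")),
              row.names = FALSE)
  }
  ref
}
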