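#!/usr/bin/env Rscript
# Step 3 — age-period-cohort decomposition with the Intrinsic Estimator.
#
# Fits the Poisson APC model per stratum on its full study window (Japan 12
# periods, Singapore 10, Korea 5; ovarian 4 everywhere, with Korea's 1994
# gap imputed), writes the full coefficient tables, the common-window
# display tables, per-fit statistics and effect-curve plots, and — when the
# inputs are the synthetic extract of step 1 — reports how far each fitted
# effect lies from the generating truth.

library(apcie)

manifest <- yaml::read_yaml("results/fixture_manifest.yaml")
cfg <- default_config(output_dir = "results/apc")
cfg$paths <- manifest$paths
cfg$plots <- TRUE

fits <- run_apc(cfg)

cat(sprintf("fitted %d strata; outputs in results/apc/\n", length(fits)))
for (key in names(fits)) {
  st <- fits[[key]]$stats
  cat(sprintf("  %-32s deviance %8.3f  AIC %7.3f  BIC %9.3f (n=%d, rank=%d)\n",
              key, st$deviance, st$aic, st$bic, st$n_obs, st$model_rank))
}

if (file.exists("results/fixture_truth.csv")) {
  truth <- read.csv("results/fixture_truth.csv")
  cat("\nrecovery against the synthetic generating effects:\n")
  for (key in names(fits)) {
    f <- fits[[key]]
    tr <- truth[truth$stratum == key, ]
    est <- c(unname(f$alpha), unname(f$beta), unname(f$gamma))
    cat(sprintf("  %-32s max |error| %.3f  rmse %.3f\n", key,
                max(abs(est - tr$truth)), sqrt(mean((est - tr$truth)^2))))
  }
  cat("(errors at this realistic mortality scale are sampling-dominated,\n",
      "largest in the single-cell corner cohorts)\n")
}
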