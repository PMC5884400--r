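#!/usr/bin/env Rscript
# Step 4 — validation: Intrinsic Estimator recovery across exposure levels.
#
# Simulates replicate 12x5 tables from known smooth effects (orthogonalized
# to the design null vector) at person-years per cell from 1e4 to 1e7 and
# summarises per-block bias, RMSE and maximum absolute error. Run at the
# benchmark event rate so the top of the exposure ladder isolates
# identification bias from Monte Carlo noise.

library(apcie)

study <- run_simulation_study(R = 20, exposures = c(1e4, 1e5, 1e6, 1e7),
                              A = 12, P = 5, seed = 20180321)
dir.create("results", showWarnings = FALSE)
write.csv(study, "results/simulation_recovery.csv", row.names = FALSE)

cat("IE effect recovery (20 replicates per exposure, 12x5 grid):\n")
print(study, digits = 3, row.names = FALSE)

overall <- vapply(split(study, study$exposure),
                  function(d) sqrt(mean(d$rmse^2)), numeric(1))
overall <- overall[order(as.numeric(names(overall)))]
cat("\noverall RMSE by exposure (should fall ~3.2x per decade):\n")
print(round(overall, 5))
stopifnot(all(diff(overall) < 0))
cat("bias shrinks monotonically with exposure.\n")
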