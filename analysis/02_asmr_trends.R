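#!/usr/bin/env Rscript
# Step 2 — yearly age-standardized mortality-rate trends.
#
# For each country x cancer stratum, computes yearly age-specific rates over
# the study window, standardizes them directly against the Segi (1960) world
# standard (ages 20-79), and writes one tidy CSV per stratum plus a line
# plot. Run analysis/01_make_fixtures.R first.

library(apcie)

manifest <- yaml::read_yaml("results/fixture_manifest.yaml")
cfg <- default_config(output_dir = "results/asmr")
cfg$paths <- manifest$paths
cfg$plots <- TRUE

series <- run_asmr(cfg)

cat(sprintf("wrote %d ASMR series to results/asmr/\n", length(series)))
for (key in names(series)) {
  s <- series[[key]]
  ok <- !is.na(s$asmr)
  cat(sprintf("  %-32s %d-%d: ASMR %6.2f -> %6.2f per 100,000\n",
              key, min(s$year), max(s$year),
              s$asmr[ok][1], s$asmr[ok][sum(ok)]))
}
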