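---
title: "Age-period-cohort decomposition of cancer mortality with the Intrinsic Estimator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-period-cohort decomposition of cancer mortality with the Intrinsic Estimator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(apcie)
```

## The problem

Cancer mortality observed over decades mixes three time scales. Rates change
with **age** (biology and care-seeking differ at 25 and 75), with calendar
**period** (screening programmes, treatment advances and coding changes hit
every age group in the same year), and with birth **cohort** (generations
carry different lifetime exposure profiles — reproductive history, diet,
infections). `apcie` separates these three contributions for age × period
tables of death counts and person-years, the way national mortality data
arrive: here, female breast, cervical and ovarian cancer deaths at ages
20–79 in twelve 5-year age groups crossed with 5-year calendar periods.
Deaths below age 20 are too rare to support rates and deaths above 80 are
heavily entangled with competing causes, so both tails are excluded from
every table.

## The model

For age group $i = 1..A$ and period $j = 1..P$, with person-years $N_{ij}$,
the death count is modelled as

$$D_{ij} \sim \text{Poisson}\!\left(N_{ij}\,
  e^{\mu + \alpha_i + \beta_j + \gamma_{k(i,j)}}\right),
  \qquad k(i,j) = A - i + j,$$

a Poisson log-linear rate model with log person-years offset. The cohort
index $k$ runs along the diagonals of the Lexis diagram: $k = 1$ is the
oldest cohort (oldest age group in the earliest period) and $k = C = A+P-1$
the youngest. Because a 5-year age group crossed with a 5-year period spans
about ten birth years, these are *synthetic* cohorts, labelled by their
central five years; with the integer midpoint convention used throughout
(bin start + 2) the label midpoint is period midpoint minus age midpoint,
which places a 12 × 5 grid starting at 1989 on the cohorts 1912–1916 through
1987–1991.

Effects are sum-to-zero ("effect") coded: each block satisfies
$\sum_i \alpha_i = \sum_j \beta_j = \sum_k \gamma_k = 0$, and the omitted
last category of each block is reconstructed as the negative sum of the
others, with its standard error from the covariance of that sum.

## The identification problem and the Intrinsic Estimator

The three indices are linearly dependent — cohort = period − age — so the
design matrix has a one-dimensional null space: rank $m-1$ with $m = 1 +
(A-1) + (P-1) + (C-1)$ columns. Adding any multiple of the null vector
$B_0$ to the coefficient vector leaves every fitted rate unchanged, which
means the linear trends of the three blocks cannot be separated by the data
alone. Within each block, $B_0$'s entries are linear in category index —
the signature of the confounded trend (`apc_design()` verifies the kernel
is exactly one-dimensional and exposes $B_0$).

The **Intrinsic Estimator** (IE) resolves this by picking the unique
solution orthogonal to $B_0$: the minimum-norm solution of the Poisson
normal equations. `fit_ie()` realises it by the principal-components route:

1. compute $B_0$ from the spectral decomposition of $X^\top X$ (sign fixed
   so the first age-block entry is positive);
2. project the design onto the orthogonal complement of $B_0$ (the $m-1$
   non-null right singular vectors) and fit the reduced Poisson regression
   by iteratively reweighted least squares with the log person-years
   offset;
3. map coefficients and covariance back through the same basis.

This is mathematically equivalent to the Moore–Penrose pseudo-inverse of a
one-shot weighted least squares but numerically stabler, and it makes the
defining property directly assertable: the returned coefficient vector is
orthogonal to $B_0$ to machine precision.

Two properties deserve emphasis.

* **Estimable functions are safe.** Second differences
  $\Delta^2\alpha_i = \alpha_{i+1} - 2\alpha_i + \alpha_{i-1}$ (and likewise
  for $\beta$, $\gamma$) are invariant to *any* resolution of the
  identification problem. The test suite verifies them against an
  independently coded just-identified Poisson GLM (two cohort categories
  equated) on a hundred random grids.
* **The IE itself is coding-dependent.** The minimum-norm criterion lives
  in the effect-coded parameter space, and relabelling categories (say,
  reversing their order) changes that space non-orthogonally, so the raw IE
  effects are only approximately stable under relabelling (differences of
  order 0.01 on typical tables), while fitted rates and estimable functions
  are exactly stable. This is a known limitation of the estimator, not of
  the implementation; read the effect *curves* (their curvature and local
  contrasts), not the absolute level of any single coefficient.

### Fit statistics

Per fit, the package reports the Poisson residual deviance
$2\sum_{ij}[D_{ij}\log(D_{ij}/\hat\mu_{ij}) - (D_{ij}-\hat\mu_{ij})]$ (with
$0\log 0 = 0$), and two information criteria under the conventions of the
APC-IE software lineage this package follows: a per-observation AIC,
$(-2\log L + 2r)/n$ with the full Poisson log-likelihood, and a
deviance-based BIC, $\text{deviance} - (n-r)\log n$, where $n = AP$ and the
effective parameter count is $r = m - 1 = 2A + 2P - 4$. The log-likelihood
is written with `lgamma` so that imputed, non-integer counts keep a
well-defined value. The BIC convention was validated against nine published
(deviance, BIC) pairs spanning $n = 48$ to $144$; the AIC convention cannot
be pinned down the same way without the underlying data and is documented
as the lineage's convention.

## Rates, standardization, imputation

Age-specific rates are $10^5 D_{ij}/N_{ij}$ per 100,000 person-years.
Yearly trend series are summarised by **direct standardization**: a
weighted mean of age-specific rates with the Segi (1960) world standard
population, restricted to ages 20–79 (weights 8000, 8000, 6000, 6000, 6000,
6000, 5000, 4000, 4000, 3000, 2000, 1000 for 20–24 … 75–79, out of the
conventional 100,000 total). Weights are renormalised over the groups
present, so any positive rescaling of the standard gives the same ASMR, and
the ASMR always lies between the smallest and largest age-specific rate.
Standardizing over 20–79 rather than the whole life span matches the case
restriction of the tables; whole-life standardization is out of scope.

A single missing calendar year inside an otherwise complete series (the
motivating case is a 1994 gap in an ovarian-cancer series) is filled by
`impute_missing_year()`: the arithmetic mean of the $k = 4$ available years
nearest in time, ties broken toward earlier years, applied independently
per age group and separately to deaths and person-years, before period
binning. "Nearest four calendar years" admits several readings (which
four; counts versus rates); nearest-by-calendar-distance on counts is the
implemented one. Imputation is off by default and enabled per stratum in
the analysis config.

## Reading WHO Mortality Database files

`read_who_deaths()` / `read_who_population()` accept the flat-file dialect
with columns `Country, Year, Cause, Sex, Frmat` and 26 age columns
(`Deaths1..Deaths26` / `Pop1..Pop26`); ages 20–79 occupy columns 10–21.
Deliberate restrictions, chosen rather than guessed:

* only age formats 00/01 (full 5-year detail) are accepted — coarser
  formats would need a disaggregation rule the analysis never defines;
  rows in other formats are rejected with a counted warning;
* rows with non-empty subnational `Admin1`/`SubDiv` codes are dropped by
  default (national totals only, avoiding double counting), toggleable;
* sex codes map 1 → male, 2 → female; only female rows are retained by
  default;
* the built-in cause map is ICD-10 only: breast → C50, cervical → C53,
  ovarian → C56, matched by prefix so C509 counts as C50. Earlier ICD
  revisions need a user-supplied code set — the package does not invent
  historical code bridges;
* duplicate (year, cause) rows within a stratum are summed; an empty
  result raises a classed warning rather than failing silently, and the
  unknown-age column is discarded with the other out-of-range columns.

## The synthetic-data generator

`make_effects()` draws one smooth curve per block — a random cubic trend in
scaled category index plus a little Gaussian noise — then centers each
block and projects the stacked coefficient vector off $B_0$. The
projection makes the truth exactly identifiable, so the IE is consistent
for it; skipping the projection (`project = FALSE`) is the identification
problem made testable, and the suite asserts that the IE then recovers the
*projected* truth, not the raw truth. `simulate_counts()` draws Poisson
counts around the implied surface; `simulate_yearly()` spreads exposure
evenly over each bin's five calendar years so that per-year counts re-bin
to the period table; `write_who_fixture()` emits those per-year records in
the WHO dialect (optionally with a male decoy row and with configured years
blanked) so the whole reading/binning/fitting path can be exercised offline
with known ground truth.

The generator emulates the *structure* of real mortality surfaces — smooth
monotone-ish age effects, gentle period and cohort curves, Poisson cell
counts, the 12 × 5 Korea-like default grid, a one-year gap for the
imputation rule. It does not emulate real rate levels beyond order of
magnitude, ICD-revision changes mid-series, population migration between
bins, or reporting-completeness drift; passing tests therefore demonstrate
correctness of the estimator and plumbing, not faithfulness of any
particular country's series.

### Calibration of the recovery benchmark

Recovery of the generating effects is judged by max absolute error across
all $A+P+C$ effects. Its floor is Monte Carlo noise: the corner cohorts are
informed by a single cell, so their error scales as
$1/\sqrt{\text{count}}$. At mortality-realistic baseline rates (around
$10^{-4}$–$10^{-3}$ per person-year) that floor is 0.015–0.03 even at
$10^7$ person-years per cell — which is exactly why published corner-cohort
standard errors are huge. The recovery benchmark therefore runs at a high
event rate, $\mu = \log 0.05$ with curve amplitude 0.3, putting the floor
near 0.002 at the top of the exposure ladder so that the 0.01 recovery
bound tests systematic identification bias rather than noise. Pipeline
fixtures keep the realistic default $\mu = \log(2\times10^{-4})$; their
recovery errors (of order 0.1 at the corner cohorts) are the honest
sampling-dominated picture at real-data scale.

## The analysis pipeline

The built-in study design (the `default_config()`): female breast,
cervical and ovarian cancer in Japan (1954–2013, twelve 5-year periods),
the Republic of Korea (1989–2013, five) and Singapore (1964–2013, ten),
ovarian restricted to 1994–2013 (four periods) everywhere with Korea's 1994
gap imputed. Long-series fits are computed on their full spans and
*displayed* on the common 1989–2013 window by `display_subset()`, which
selects rows without refitting — so displayed long-series period/cohort
columns need not sum to zero even though the full blocks do. Every
study-design constant lives in the config (YAML-overridable via
`read_config()`), so the default run reproduces the built-in design and any
variant is an edit.

Real WHO extracts are user-supplied (drop `deaths.csv`/`pop.csv` under
`data/who/`); reproduction of any published table from them is opt-in and
extract-vintage dependent — mortality databases are revised, so
coefficients can shift in the third decimal between extracts. Without an
extract, `analysis/01_make_fixtures.R` generates the synthetic equivalent
with known truth and the numbered analysis scripts run the identical code
path.

## Numerical choices and degenerate inputs

* IRLS starts at the intercept-only fit, stops when the deviance change
  falls below $10^{-10}$ (at most 100 iterations), and reports
  non-convergence with the full deviance trace. Tolerances much below
  $10^{-12}$ sit under the floating-point plateau of the deviance and are
  not meaningful.
* Kernel detection works on the eigenvalue scale of $X^\top X$ (noise in a
  zero eigenvalue is relative to the largest eigenvalue, not its square
  root); a kernel dimension other than one is a hard error.
* Zero-death cells are retained — they are valid Poisson observations, and
  trimming the sparse youngest cohorts would bias the very effects of
  interest; zero person-years cells are invalid by construction.
* Ties in the imputation rule break toward earlier years; the null-vector
  sign is fixed by the first age entry; grids as small as 2 × 2 keep a
  one-dimensional kernel and remain fittable.

## Problem sizes used in the tests

Unit and property tests run on grids from 3 × 3 to 12 × 12 with exposures
$10^4$–$10^7$ per cell; the oracle-agreement property uses 100 random grids
with $A, P \in \{3..6\}$; the ASMR bound property uses 1,000 random rate
vectors; the recovery benchmark uses the 12 × 5 grid at the calibrated
scale; the end-to-end pipeline tests run a reduced one-country study. The
full three-country analysis scripts complete in well under a minute.

## A compact example

```{r example}
spec <- synthetic_spec(A = 12, P = 5, mu = log(0.05), amplitude = 0.3,
                       exposure = 1e7, seed = 1)
tab <- simulate_counts(spec)
fit <- fit_ie(tab)
fit
max(abs(unname(fit$alpha) - spec$alpha))
head(coef_table(fit))
estimable_second_differences(fit)$period
```

## Known limitations

* The IE's absolute coefficient levels are coding-dependent (see above);
  comparisons across studies should rest on estimable functions or on
  identically coded fits.
* No overdispersion handling: variance beyond Poisson inflates the
  reported precision. No alternative identification schemes (drift models,
  hierarchical APC) are provided.
* ASMR series are reported as computed — no smoothing, joinpoint or
  annual-percent-change summarisation.
* The imputation rule is designed for isolated single-year gaps; long runs
  of missing years should be treated as missing design cells, not imputed.
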