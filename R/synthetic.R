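# Synthetic APC-structured mortality data with known ground truth.
#
# The generator draws smooth effect curves (random cubic trends plus a
# little noise, mimicking the monotone age effects and gentle period/cohort
# curves of real cancer mortality surfaces), centers each block to sum zero,
# and projects the stacked coefficient vector off the design's null vector
# so that the Intrinsic Estimator recovers the generating effects in
# expectation. Death counts are Poisson draws around the log-linear rate
# surface times person-years.

#' Construct a synthetic APC specification
#'
#' @param A,P grid dimensions (age groups x periods).
#' @param mu baseline log rate (log deaths per person-year). The default,
#'   `log(2e-4)`, is of the order of female site-specific cancer mortality
#'   at ages 20-79 (about 20 deaths per 100,000 person-years).
#' @param alpha,beta,gamma effect vectors (lengths A, P, A+P-1), each
#'   summing to zero; defaults drawn by [make_effects()].
#' @param exposure person-years per cell: scalar or A x P matrix, positive.
#'   The default 1e6 corresponds to roughly 200,000 women per age group
#'   observed for a 5-year period.
#' @param seed RNG seed governing both effect draws (when defaulted) and
#'   count simulation.
#' @param first_age youngest age-group start (calendar anchoring).
#' @param first_period_year first period-bin start year.
#' @param missing_years calendar years to blank when emitting per-year
#'   fixtures, to exercise the missing-year imputation rule.
#' @param smoothness,amplitude passed to [make_effects()] when effects are
#'   defaulted.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(A = 12L, P = 5L, mu = log(2e-4),
                           alpha = NULL, beta = NULL, gamma = NULL,
                           exposure = 1e6, seed = 1L,
                           first_age = 20L, first_period_year = 1989L,
                           missing_years = integer(0), smoothness = 1,
                           amplitude = 0.5) {
  A <- as.integer(A); P <- as.integer(P)
  stopifnot(A >= 3, P >= 3)
  C <- A + P - 1L
  if (is.null(alpha) || is.null(beta) || is.null(gamma)) {
    eff <- make_effects(A, P, smoothness = smoothness, amplitude = amplitude,
                        seed = seed)
    if (is.null(alpha)) alpha <- eff$alpha
    if (is.null(beta)) beta <- eff$beta
    if (is.null(gamma)) gamma <- eff$gamma
  }
  stopifnot(length(alpha) == A, length(beta) == P, length(gamma) == C)
  for (v in list(alpha, beta, gamma)) {
    if (abs(sum(v)) > 1e-8) stop("effect vectors must each sum to zero")
  }
  if (length(exposure) == 1) exposure <- matrix(exposure, A, P)
  exposure <- as.matrix(exposure)
  stopifnot(all(dim(exposure) == c(A, P)))
  if (any(exposure <= 0)) stop("exposure must be positive in every cell")
  structure(
    list(A = A, P = P, C = C, mu = mu,
         alpha = alpha, beta = beta, gamma = gamma,
         exposure = exposure, seed = as.integer(seed),
         first_age = as.integer(first_age),
         first_period_year = as.integer(first_period_year),
         missing_years = as.integer(missing_years)),
    class = "synthetic_spec")
}

#' Draw smooth sum-to-zero APC effect curves identifiable by the IE
#'
#' Each block's curve is a random cubic trend in scaled category index plus
#' Gaussian noise whose scale shrinks with `smoothness`. Blocks are centered
#' to sum zero, the stacked effect-coded coefficient vector is projected off
#' the design's null vector, and blocks are re-expanded (which re-imposes
#' the zero sums exactly). The projection makes the truth orthogonal to the
#' null vector, so the Intrinsic Estimator — the minimum-norm solution — is
#' consistent for it; skipping the projection demonstrates the
#' identification problem instead (the IE then recovers the projected
#' truth).
#'
#' @param A,P grid dimensions.
#' @param smoothness positive scale; larger = smoother curves (noise sd =
#'   `0.1 * amplitude / smoothness` around the cubic trends).
#' @param amplitude standard deviation of the random cubic-trend
#'   coefficients; sets the typical size of the effects on the log-rate
#'   scale. Applied before the null-vector projection, so the returned
#'   effects are exactly identifiable whatever the amplitude.
#' @param seed RNG seed.
#' @param project if `FALSE`, skip the null-vector projection.
#' @return list with `alpha`, `beta`, `gamma` and the design `null_vector`.
#' @export
make_effects <- function(A, P, smoothness = 1, amplitude = 0.5, seed = 1L,
                         project = TRUE) {
  stopifnot(A >= 3, P >= 3, smoothness > 0, amplitude > 0)
  C <- A + P - 1L
  set.seed(as.integer(seed))
  draw <- function(L) {
    x <- seq(-1, 1, length.out = L)
    co <- stats::rnorm(3, 0, amplitude)
    v <- co[1] * x + co[2] * x^2 + co[3] * x^3 +
      stats::rnorm(L, 0, 0.1 * amplitude / smoothness)
    v - mean(v)
  }
  alpha <- draw(A); beta <- draw(P); gamma <- draw(C)

  design <- apc_design(A, P)
  b0 <- design$null_vector
  stack <- c(0, alpha[-A], beta[-P], gamma[-C])
  if (project) stack <- stack - sum(stack * b0) * b0
  bl <- design$blocks
  expand <- function(v) c(v, -sum(v))
  list(alpha = expand(stack[bl$age]),
       beta = expand(stack[bl$period]),
       gamma = expand(stack[bl$cohort]),
       null_vector = b0)
}

# expected deaths surface implied by a spec
spec_lambda <- function(spec) {
  A <- spec$A; P <- spec$P
  i <- rep(seq_len(A), each = P)
  j <- rep(seq_len(P), times = A)
  k <- cohort_index(i, j, A)
  lam <- matrix(NA_real_, A, P)
  lam[cbind(i, j)] <- spec$exposure[cbind(i, j)] *
    exp(spec$mu + spec$alpha[i] + spec$beta[j] + spec$gamma[k])
  lam
}

spec_age_starts <- function(spec) {
  seq.int(spec$first_age, by = 5L, length.out = spec$A)
}

spec_period_starts <- function(spec) {
  period_bin_starts(spec$first_period_year, spec$P)
}

#' Simulate an age x period table of Poisson death counts
#'
#' Draws `deaths_ij ~ Poisson(exposure_ij * exp(mu + alpha_i + beta_j +
#' gamma_k))` with the Lexis cohort index k = A - i + j. Deterministic under
#' the spec's seed.
#'
#' @param spec a [synthetic_spec()].
#' @return a [rate_table()] carrying attribute `"spec"`.
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  lam <- spec_lambda(spec)
  set.seed(spec$seed)
  deaths <- matrix(stats::rpois(length(lam), lam), spec$A, spec$P)
  out <- rate_table(deaths, spec$exposure,
                    spec_age_starts(spec), spec_period_starts(spec),
                    country = "synthetic", cancer = "synthetic")
  attr(out, "spec") <- spec
  out
}

#' Simulate per-year death counts and person-years
#'
#' Spreads each cell's exposure evenly over its 5 calendar years and draws
#' yearly Poisson counts (so yearly counts binned back into periods are
#' Poisson with the cell's full rate). Deterministic under the spec's seed.
#' Years listed in `spec$missing_years` are set to `NA` in both matrices.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `deaths` and `person_years`, each A x (5P) with
#'   calendar-year column names, plus the binned `table` implied by the
#'   complete (pre-blanking) values.
#' @export
simulate_yearly <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  lam <- spec_lambda(spec)
  years <- seq.int(spec$first_period_year,
                   length.out = 5L * spec$P)
  ny <- length(years)
  set.seed(spec$seed)
  deaths <- matrix(NA_real_, spec$A, ny,
                   dimnames = list(age = age_group_labels(spec_age_starts(spec)),
                                   year = years))
  pys <- deaths
  for (j in seq_len(spec$P)) {
    for (y in 1:5) {
      col <- (j - 1L) * 5L + y
      deaths[, col] <- stats::rpois(spec$A, lam[, j] / 5)
      pys[, col] <- spec$exposure[, j] / 5
    }
  }
  Dbin <- t(apply(deaths, 1, function(r) tapply(r, rep(seq_len(spec$P), each = 5), sum)))
  Nbin <- t(apply(pys, 1, function(r) tapply(r, rep(seq_len(spec$P), each = 5), sum)))
  table <- rate_table(Dbin, Nbin, spec_age_starts(spec), spec_period_starts(spec),
                      country = "synthetic", cancer = "synthetic")
  blank <- as.character(intersect(spec$missing_years, years))
  deaths[, blank] <- NA_real_
  pys[, blank] <- NA_real_
  list(deaths = deaths, person_years = pys, table = table)
}

#' Write a synthetic stratum as WHO Mortality Database flat files
#'
#' Emits per-year deaths and population rows in the accepted WHO dialect
#' (26 age columns, age format 01, national rows) so that the reader,
#' year-matrix assembly and period binning can be exercised end to end: the
#' files round-trip to exactly the table returned in `$table`. Years in
#' `spec$missing_years` are omitted from both files. Optionally adds a male
#' deaths row, which a correct read must drop.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @param country WHO numeric country code to stamp on the rows.
#' @param cause cause code to stamp on deaths rows (e.g. "C50").
#' @param append append to existing files rather than overwrite.
#' @param write_population set `FALSE` when appending a second cause for a
#'   country whose population rows are already present.
#' @param male_decoy add one male deaths row with nonzero counts.
#' @return list with `deaths_path`, `pop_path`, `yearly` (the per-year
#'   matrices), and `table` (the binned ground-truth [rate_table()] before
#'   any blanking).
#' @export
write_who_fixture <- function(spec, dir, country = 9999L, cause = "C50",
                              append = FALSE, write_population = TRUE,
                              male_decoy = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$first_age != 20L || spec$A != 12L) {
    stop("WHO fixtures use the 26-column layout with ages 20-79 in columns ",
         "10..21; the spec must have A = 12 groups starting at age 20")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  yr <- simulate_yearly(spec)
  years <- as.integer(colnames(yr$deaths))
  keep <- !(years %in% spec$missing_years)

  age_block <- function(counts12) {
    v <- matrix(0, nrow = ncol(counts12), ncol = 26)
    v[, WHO_AGE2079_COLS] <- t(counts12)
    v[, 1] <- rowSums(v[, 2:26, drop = FALSE])
    v
  }

  d_keep <- yr$deaths[, keep, drop = FALSE]
  dmat <- age_block(d_keep)
  deaths_df <- data.frame(Country = country, Admin1 = "", SubDiv = "",
                          Year = years[keep], List = "104", Cause = cause,
                          Sex = 2L, Frmat = "01", IM_Frmat = "01",
                          stringsAsFactors = FALSE)
  deaths_df[paste0("Deaths", 1:26)] <- as.data.frame(dmat)
  if (male_decoy) {
    male <- deaths_df[1, ]
    male$Sex <- 1L
    male[paste0("Deaths", 1:26)] <- male[paste0("Deaths", 1:26)] * 0 + 1
    male$Deaths1 <- 25
    deaths_df <- rbind(deaths_df, male)
  }

  deaths_path <- file.path(dir, "deaths.csv")
  pop_path <- file.path(dir, "pop.csv")
  utils::write.table(deaths_df, deaths_path, sep = ",", row.names = FALSE,
                     col.names = !append || !file.exists(deaths_path),
                     append = append && file.exists(deaths_path), qmethod = "double")

  if (write_population) {
    p_keep <- yr$person_years[, keep, drop = FALSE]
    pmat <- age_block(p_keep)
    pop_df <- data.frame(Country = country, Admin1 = "", SubDiv = "",
                         Year = years[keep], Sex = 2L, Frmat = "01",
                         stringsAsFactors = FALSE)
    pop_df[paste0("Pop", 1:26)] <- as.data.frame(pmat)
    utils::write.table(pop_df, pop_path, sep = ",", row.names = FALSE,
                       col.names = !append || !file.exists(pop_path),
                       append = append && file.exists(pop_path), qmethod = "double")
  }

  list(deaths_path = deaths_path, pop_path = pop_path,
       yearly = yr[c("deaths", "person_years")], table = yr$table)
}
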