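# Independent oracles and small fixture builders shared across tests.

# closed-form Poisson residual deviance, written independently of the
# package's internal formula
oracle_deviance <- function(d, mu) {
  ll_sat <- sum(ifelse(d > 0, d * log(d) - d, 0))
  ll_fit <- sum(d * log(mu) - mu)
  2 * (ll_sat - ll_fit)
}

# just-identified constrained Poisson APC fit via stats::glm: treatment
# coding with the rank deficiency resolved by equating the first two cohort
# categories (gamma_1 = gamma_2 = 0), which pins the unidentified linear
# trend and leaves a full-rank design. Returns expanded (reference = 0)
# effect vectors; any estimable function of these matches any other
# resolution of the identification problem.
oracle_constrained_fit <- function(deaths, person_years) {
  A <- nrow(deaths); P <- ncol(deaths)
  i <- rep(seq_len(A), each = P)
  j <- rep(seq_len(P), times = A)
  k <- A - i + j
  k_merged <- ifelse(k == 2L, 1L, k)
  df <- data.frame(
    d = deaths[cbind(i, j)],
    off = log(person_years[cbind(i, j)]),
    age = factor(i), period = factor(j), cohort = factor(k_merged))
  fit <- stats::glm(
    d ~ age + period + cohort, offset = off,
    family = stats::poisson(), data = df,
    control = stats::glm.control(epsilon = 1e-11, maxit = 200))
  co <- stats::coef(fit)
  pick <- function(pfx, L, skip = integer(0)) {
    v <- numeric(L)
    for (l in setdiff(2:L, skip)) {
      nm <- paste0(pfx, l)
      v[l] <- co[[nm]]
    }
    v
  }
  list(age = pick("age", A), period = pick("period", P),
       cohort = pick("cohort", A + P - 1L, skip = 2L),
       fitted = stats::fitted(fit), deviance = fit$deviance)
}

second_diff <- function(x) diff(x, differences = 2)

# quick synthetic table at the recovery-benchmark scale
bench_table <- function(A = 12, P = 5, exposure = 1e7, seed = 1,
                        mu = log(0.05), amplitude = 0.3) {
  spec <- synthetic_spec(A, P, mu = mu, exposure = exposure, seed = seed,
                         amplitude = amplitude)
  simulate_counts(spec)
}
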