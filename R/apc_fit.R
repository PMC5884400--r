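# The Intrinsic Estimator for Poisson age-period-cohort models.
#
# Identification route: project the effect-coded design onto the orthogonal
# complement of its null vector (orthonormal basis from the SVD), fit the
# Poisson rate regression there by IRLS with a log person-years offset, and
# map coefficients and covariance back. The result is the minimum-norm
# solution to the APC normal equations — the unique solution orthogonal to
# the null vector — and the orthogonality is directly assertable on the
# returned coefficient vector.

poisson_deviance <- function(d, mu) {
  # 2 * sum[d log(d/mu) - (d - mu)], with 0 log 0 = 0
  term <- ifelse(d > 0, d * log(d / mu), 0)
  2 * sum(term - (d - mu))
}

irls_poisson <- function(y, Z, offset, tol = 1e-10, max_iter = 100L) {
  n <- length(y)
  stopifnot(nrow(Z) == n)
  # initialize at the intercept-only fit: common rate = total events/exposure
  rate0 <- sum(y) / sum(exp(offset))
  if (rate0 <= 0) rate0 <- 1 / sum(exp(offset))
  eta <- log(rate0) + offset
  mu <- exp(eta)
  dev <- poisson_deviance(y, mu)
  trace <- dev

  for (iter in seq_len(max_iter)) {
    w <- mu
    z <- (eta - offset) + (y - mu) / mu
    qz <- qr(Z * sqrt(w))
    b <- qr.coef(qz, sqrt(w) * z)
    eta <- drop(Z %*% b) + offset
    mu <- exp(eta)
    dev_new <- poisson_deviance(y, mu)
    trace <- c(trace, dev_new)
    if (abs(dev - dev_new) < tol) {
      R <- qr.R(qz)
      cov_b <- chol2inv(R)
      return(list(coefficients = b, covariance = cov_b, fitted = mu,
                  deviance = dev_new, iterations = iter, trace = trace))
    }
    dev <- dev_new
  }
  stop(errorCondition(
    paste0("IRLS did not converge in ", max_iter,
           " iterations (last deviance change ",
           format(abs(dev - trace[length(trace) - 1])), ")"),
    class = "apc_irls_nonconvergence", trace = trace))
}

expand_block <- function(coefs, cov_block) {
  # reconstruct the omitted (last) category of a sum-to-zero block as the
  # negative sum, with its SE from the covariance of the sum
  L1 <- length(coefs)
  M <- rbind(diag(L1), rep(-1, L1))
  full <- drop(M %*% coefs)
  V <- M %*% cov_block %*% t(M)
  list(coef = full, se = sqrt(pmax(diag(V), 0)))
}

#' Fit the Intrinsic Estimator to an age x period rate table
#'
#' Fits the Poisson log-linear rate model
#' `deaths_ij ~ Poisson(N_ij * exp(mu + alpha_i + beta_j + gamma_k))`,
#' k = cohort of cell (i, j), under effect (sum-to-zero) coding, resolving
#' the age-period-cohort identification problem with the Intrinsic
#' Estimator: the design columns are projected onto the orthogonal
#' complement of the design's null vector, the reduced model is fitted by
#' iteratively reweighted least squares with a log person-years offset
#' (deviance-change tolerance 1e-10, at most 100 iterations), and the
#' coefficients and covariance are mapped back through the same basis. The
#' returned effects are the minimum-norm solution; each block sums to zero
#' and the stacked coefficient vector is orthogonal to the null vector.
#' Zero-death cells are retained as valid Poisson observations.
#'
#' @param table a [rate_table()].
#' @param tol IRLS deviance-change convergence tolerance.
#' @param max_iter IRLS iteration cap.
#' @return object of class `apc_ie_fit` with components `mu`, `mu_se`,
#'   `alpha`, `beta`, `gamma` (named effect vectors), `alpha_se`,
#'   `beta_se`, `gamma_se`, `coefficients`/`covariance` on the full
#'   effect-coded scale, `reduced` (coefficients and covariance on the
#'   m-1-dimensional identified scale), `fitted_deaths`, `stats` (see
#'   [fit_stats()]), `design`, `table`, `iterations`.
#' @export
fit_ie <- function(table, tol = 1e-10, max_iter = 100L) {
  stopifnot(inherits(table, "rate_table"))
  A <- length(table$age_starts)
  P <- length(table$period_starts)
  design <- apc_design(A, P)

  # vectorize in the design's age-major row order
  idx <- cbind(design$age, design$period)
  y <- table$deaths[idx]
  offs <- log(table$person_years[idx])

  V1 <- nonnull_basis(design)
  Z <- design$matrix %*% V1
  fit <- irls_poisson(y, Z, offs, tol = tol, max_iter = max_iter)

  beta_full <- drop(V1 %*% fit$coefficients)
  cov_full <- V1 %*% fit$covariance %*% t(V1)

  bl <- design$blocks
  age_x <- expand_block(beta_full[bl$age], cov_full[bl$age, bl$age, drop = FALSE])
  per_x <- expand_block(beta_full[bl$period], cov_full[bl$period, bl$period, drop = FALSE])
  coh_x <- expand_block(beta_full[bl$cohort], cov_full[bl$cohort, bl$cohort, drop = FALSE])

  age_labs <- age_group_labels(table$age_starts)
  per_labs <- period_bin_labels(table$period_starts)
  coh_start0 <- cohort_label_start(table$age_starts[A], table$period_starts[1])
  coh_labs <- period_bin_labels(seq.int(coh_start0, by = 5L, length.out = design$C))

  fitted_deaths <- matrix(NA_real_, A, P,
                          dimnames = dimnames(table$deaths))
  fitted_deaths[idx] <- fit$fitted

  out <- structure(
    list(mu = beta_full[1], mu_se = sqrt(cov_full[1, 1]),
         alpha = stats::setNames(age_x$coef, age_labs),
         alpha_se = stats::setNames(age_x$se, age_labs),
         beta = stats::setNames(per_x$coef, per_labs),
         beta_se = stats::setNames(per_x$se, per_labs),
         gamma = stats::setNames(coh_x$coef, coh_labs),
         gamma_se = stats::setNames(coh_x$se, coh_labs),
         coefficients = beta_full, covariance = cov_full,
         reduced = list(coefficients = fit$coefficients,
                        covariance = fit$covariance),
         fitted_deaths = fitted_deaths,
         design = design, table = table,
         iterations = fit$iterations),
    class = "apc_ie_fit")
  out$stats <- fit_stats(out)
  out
}

#' @export
print.apc_ie_fit <- function(x, ...) {
  cat(sprintf("Intrinsic Estimator fit: A=%d, P=%d, C=%d (%d cells)\n",
              x$design$A, x$design$P, x$design$C, x$stats$n_obs))
  cat(sprintf("  deviance %.4f, AIC %.4f, BIC %.4f (rank %d), %d IRLS iterations\n",
              x$stats$deviance, x$stats$aic, x$stats$bic,
              x$stats$model_rank, x$iterations))
  invisible(x)
}

#' Per-observation AIC and deviance-based BIC
#'
#' Fit-statistic conventions used for the goodness-of-fit rows of the
#' coefficient tables: `aic = (-2 logLik + 2 rank)/n` (per observation,
#' full Poisson log-likelihood including the factorial term) and
#' `bic = deviance - (n - rank) * log(n)`, with `rank = 2A + 2P - 4`, the
#' effective parameter count of the Intrinsic Estimator.
#'
#' @param loglik total Poisson log-likelihood of the fitted model.
#' @param deviance Poisson residual deviance.
#' @param n_obs number of cells.
#' @param rank effective number of parameters.
#' @return numeric scalar.
#' @export
apc_aic <- function(loglik, n_obs, rank) (-2 * loglik + 2 * rank) / n_obs

#' @rdname apc_aic
#' @export
apc_bic <- function(deviance, n_obs, rank) deviance - (n_obs - rank) * log(n_obs)

#' Goodness-of-fit statistics for an Intrinsic Estimator fit
#'
#' @param fit an [fit_ie()] result.
#' @return list with `deviance`, `loglik`, `aic`, `bic`, `n_obs`,
#'   `model_rank` (= 2A + 2P - 4, the count of identified parameters).
#' @export
fit_stats <- function(fit) {
  stopifnot(inherits(fit, "apc_ie_fit"))
  idx <- cbind(fit$design$age, fit$design$period)
  d <- fit$table$deaths[idx]
  mu <- fit$fitted_deaths[idx]
  n <- length(d)
  rank <- 2L * fit$design$A + 2L * fit$design$P - 4L
  dev <- poisson_deviance(d, mu)
  # written out so imputed (non-integer) counts keep a well-defined likelihood
  ll <- sum(d * log(mu) - mu - lgamma(d + 1))
  list(deviance = dev, loglik = ll,
       aic = apc_aic(ll, n, rank),
       bic = apc_bic(dev, n, rank),
       n_obs = n, model_rank = rank)
}

#' Second differences of the fitted effects
#'
#' Second differences `x[i+1] - 2 x[i] + x[i-1]` of each effect block.
#' Unlike the effects themselves, these are estimable functions: they are
#' identical under every resolution of the age-period-cohort identification
#' problem, so they provide a verification surface independent of the
#' Intrinsic Estimator's choice of solution. Blocks with fewer than 3
#' categories yield an empty sequence.
#'
#' @param fit an [fit_ie()] result.
#' @return list with numeric vectors `age`, `period`, `cohort`.
#' @export
estimable_second_differences <- function(fit) {
  stopifnot(inherits(fit, "apc_ie_fit"))
  d2 <- function(x) if (length(x) >= 3) diff(x, differences = 2) else numeric(0)
  list(age = d2(unname(fit$alpha)),
       period = d2(unname(fit$beta)),
       cohort = d2(unname(fit$gamma)))
}

#' Coefficient table of an Intrinsic Estimator fit
#'
#' Long-format table of every reported coefficient: one intercept row, A age
#' rows, P period rows and C cohort rows, each with its standard error.
#'
#' @param fit an [fit_ie()] result.
#' @return data.frame with columns `block`, `label`, `coef`, `se`.
#' @export
coef_table <- function(fit) {
  stopifnot(inherits(fit, "apc_ie_fit"))
  data.frame(
    block = c("intercept",
              rep("age", length(fit$alpha)),
              rep("period", length(fit$beta)),
              rep("cohort", length(fit$gamma))),
    label = c("(Intercept)", names(fit$alpha), names(fit$beta), names(fit$gamma)),
    coef = c(fit$mu, unname(fit$alpha), unname(fit$beta), unname(fit$gamma)),
    se = c(fit$mu_se, unname(fit$alpha_se), unname(fit$beta_se),
           unname(fit$gamma_se)),
    stringsAsFactors = FALSE)
}

#' Display a subset of fitted coefficients without refitting
#'
#' Long-series fits are conventionally displayed on a common calendar
#' window: the full-span fit is computed once and only the requested period
#' and cohort rows are shown. Values are taken unchanged from the full fit —
#' subsetting never refits, so displayed long-series period/cohort columns
#' need not sum to zero even though the full blocks do.
#'
#' @param fit an [fit_ie()] result.
#' @param periods period labels to keep (`NULL` = all).
#' @param cohorts cohort labels to keep (`NULL` = all).
#' @return data.frame in [coef_table()] layout (intercept and all age rows
#'   always included).
#' @export
display_subset <- function(fit, periods = NULL, cohorts = NULL) {
  tab <- coef_table(fit)
  keep_block <- function(block, labels) {
    rows <- tab$block == block
    if (is.null(labels)) return(rows)
    unknown <- setdiff(labels, tab$label[rows])
    if (length(unknown) > 0) {
      stop("unknown ", block, " label(s): ", paste(unknown, collapse = ", "))
    }
    rows & tab$label %in% labels
  }
  out <- tab[tab$block %in% c("intercept", "age") |
               keep_block("period", periods) |
               keep_block("cohort", cohorts), , drop = FALSE]
  rownames(out) <- NULL
  out
}
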