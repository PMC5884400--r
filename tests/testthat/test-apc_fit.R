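test_that("a flat rate surface yields null effects and the log rate as intercept", {
  r <- 3e-4
  N <- matrix(1e7, 12, 5)
  D <- round(N * r)
  tab <- rate_table(D, N, age_group_starts(), period_bin_starts(1989, 5))
  fit <- fit_ie(tab)
  expect_lt(max(abs(c(fit$alpha, fit$beta, fit$gamma))), 1e-8)
  expect_equal(fit$mu, log(r), tolerance = 1e-8)
  expect_equal(unname(fit$fitted_deaths), unname(D), tolerance = 1e-6)
})

test_that("IE recovers orthogonalized generating effects at large exposure", {
  spec <- synthetic_spec(12, 5, mu = log(0.05), exposure = 1e7, seed = 1,
                         amplitude = 0.3)
  fit <- fit_ie(simulate_counts(spec))
  expect_lt(max(abs(unname(fit$alpha) - spec$alpha)), 0.01)
  expect_lt(max(abs(unname(fit$beta) - spec$beta)), 0.01)
  expect_lt(max(abs(unname(fit$gamma) - spec$gamma)), 0.01)
})

test_that("fitted effects sum to zero per block and are orthogonal to the null vector", {
  for (seed in 1:5) {
    tab <- bench_table(A = 6, P = 4, exposure = 1e5, seed = seed)
    fit <- fit_ie(tab)
    expect_lt(abs(sum(fit$alpha)), 1e-8)
    expect_lt(abs(sum(fit$beta)), 1e-8)
    expect_lt(abs(sum(fit$gamma)), 1e-8)
    b0 <- apc_null_vector(fit$design)
    expect_lt(abs(sum(fit$coefficients * b0)),
              1e-8 * sqrt(sum(fit$coefficients^2)))
  }
})

test_that("deviance matches the closed-form Poisson oracle", {
  tab <- bench_table(A = 5, P = 5, exposure = 1e5, seed = 3)
  fit <- fit_ie(tab)
  d <- as.vector(tab$deaths)
  mu <- as.vector(fit$fitted_deaths)
  expect_equal(fit$stats$deviance, oracle_deviance(d, mu), tolerance = 1e-8)
  # saturated limit: fitted == observed -> deviance 0
  expect_equal(oracle_deviance(d, d), 0)
})

test_that("second differences agree with a constrained Poisson GLM oracle", {
  for (seed in 1:8) {
    A <- sample(3:6, 1)
    P <- sample(3:6, 1)
    tab <- bench_table(A = A, P = P, exposure = 1e5, seed = 100 + seed)
    fit <- fit_ie(tab)
    ora <- oracle_constrained_fit(tab$deaths, tab$person_years)
    d2 <- estimable_second_differences(fit)
    expect_equal(d2$age, second_diff(ora$age), tolerance = 1e-6)
    expect_equal(d2$period, second_diff(ora$period), tolerance = 1e-6)
    expect_equal(d2$cohort, second_diff(ora$cohort), tolerance = 1e-6)
    # both resolutions fit the same surface
    idx <- cbind(fit$design$age, fit$design$period)
    expect_equal(unname(fit$fitted_deaths[idx]), unname(ora$fitted),
                 tolerance = 1e-6)
  }
})

test_that("second differences annihilate linear-in-index effects", {
  expect_equal(second_diff(c(1, 0, 1)), 2)
  spec_lin <- synthetic_spec(
    5, 4, mu = log(1e-3),
    alpha = scale(1:5, scale = FALSE)[, 1] * 0.1,
    beta = scale(1:4, scale = FALSE)[, 1] * -0.1,
    gamma = scale(1:8, scale = FALSE)[, 1] * 0.05,
    exposure = 1e10, seed = 4)
  fit <- fit_ie(simulate_counts(spec_lin))
  d2 <- estimable_second_differences(fit)
  # purely linear generating effects leave no curvature to recover (bound =
  # a few times the Poisson sampling floor at ~1e7 events per cell)
  expect_lt(max(abs(unlist(d2))), 5e-3)
})

test_that("reversing category order preserves the fitted surface and estimable functions", {
  tab <- bench_table(A = 5, P = 4, exposure = 1e6, seed = 11)
  fit <- fit_ie(tab)
  D <- tab$deaths[5:1, 4:1]
  N <- tab$person_years[5:1, 4:1]
  tab_r <- rate_table(D, N, tab$age_starts, tab$period_starts)
  fit_r <- fit_ie(tab_r)
  expect_equal(unname(fit_r$fitted_deaths), unname(fit$fitted_deaths[5:1, 4:1]),
               tolerance = 1e-8)
  d2 <- estimable_second_differences(fit)
  d2r <- estimable_second_differences(fit_r)
  expect_equal(d2r$age, rev(d2$age), tolerance = 1e-8)
  expect_equal(d2r$period, rev(d2$period), tolerance = 1e-8)
  expect_equal(d2r$cohort, rev(d2$cohort), tolerance = 1e-8)
  # the raw IE effects are only approximately reversal-stable (the IE's
  # implicit constraint depends on the coding); they stay close
  expect_equal(unname(fit_r$alpha), rev(unname(fit$alpha)), tolerance = 0.05)
})

test_that("fit statistics follow the deviance-BIC and per-observation-AIC conventions", {
  tab <- bench_table(A = 12, P = 5, exposure = 1e6, seed = 2)
  fit <- fit_ie(tab)
  st <- fit$stats
  expect_equal(st$n_obs, 60L)
  expect_equal(st$model_rank, 2 * 12 + 2 * 5 - 4)
  expect_equal(st$bic, st$deviance - (60 - 30) * log(60))
  ll <- sum(dpois(as.vector(tab$deaths), as.vector(fit$fitted_deaths), log = TRUE))
  expect_equal(st$aic, (-2 * ll + 2 * 30) / 60)
})

test_that("standard errors are reported for every category including the omitted one", {
  tab <- bench_table(A = 12, P = 5, exposure = 1e6, seed = 8)
  fit <- fit_ie(tab)
  expect_length(fit$alpha_se, 12)
  expect_length(fit$beta_se, 5)
  expect_length(fit$gamma_se, 16)
  expect_true(all(c(fit$alpha_se, fit$beta_se, fit$gamma_se) > 0))
  # the sparse corner cohorts (single supporting cell) carry the largest SEs
  expect_equal(which.max(fit$gamma_se), c(`1987-1991` = 16L))
  # delta-method check of the omitted category: SE of the negative sum
  bl <- fit$design$blocks
  V <- fit$covariance[bl$age, bl$age]
  expect_equal(unname(fit$alpha_se[12]), sqrt(sum(V)), tolerance = 1e-10)
})

test_that("coefficient tables have the full layout and display subsets never refit", {
  tab <- bench_table(A = 12, P = 5, exposure = 1e6, seed = 13)
  fit <- fit_ie(tab)
  ct <- coef_table(fit)
  expect_equal(nrow(ct), 1 + 12 + 5 + 16)
  expect_equal(as.vector(table(ct$block)[c("age", "period", "cohort")]),
               c(12L, 5L, 16L))
  # full subset is the identity
  expect_equal(display_subset(fit), ct)
  # partial display: values unchanged from the full fit
  keep_p <- names(fit$beta)[2:4]
  sub <- display_subset(fit, periods = keep_p)
  expect_equal(sub$coef[sub$block == "period"], unname(fit$beta[2:4]))
  expect_equal(nrow(sub), 1 + 12 + 3 + 16)
  expect_error(display_subset(fit, periods = "1900-1904"), "unknown period")
})

test_that("long-series fits displayed on a common window keep full-fit values", {
  spec <- synthetic_spec(12, 12, mu = log(1e-3), exposure = 1e6, seed = 17,
                         first_period_year = 1954)
  fit <- fit_ie(simulate_counts(spec))
  expect_equal(fit$stats$n_obs, 144L)
  expect_equal(fit$stats$model_rank, 44L)
  disp <- display_subset(fit, periods = period_bin_labels(period_bin_starts(1989, 5)))
  shown <- disp$coef[disp$block == "period"]
  expect_equal(shown, unname(fit$beta[8:12]))
  # the displayed period column of a long fit need not sum to zero even
  # though the full block does
  expect_lt(abs(sum(fit$beta)), 1e-8)
})

test_that("non-convergence carries an iteration trace", {
  # a one-iteration cap cannot converge on a structured surface
  tab <- bench_table(A = 4, P = 4, exposure = 1e5, seed = 19)
  err <- tryCatch(fit_ie(tab, max_iter = 1L), error = function(e) e)
  expect_s3_class(err, "apc_irls_nonconvergence")
  expect_true(length(err$trace) >= 2)
})
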