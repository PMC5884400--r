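test_that("age and period bins follow the 5-year integer-midpoint convention", {
  expect_equal(age_group_starts(), seq(20L, 75L, 5L))
  expect_equal(age_group_labels(c(20L, 75L)), c("20-24", "75-79"))
  expect_equal(period_bin_starts(1989, 5), c(1989L, 1994L, 1999L, 2004L, 2009L))
  expect_equal(period_bin_starts(1994, 4), c(1994L, 1999L, 2004L, 2009L))
})

test_that("cohort indexing walks the Lexis diagonals from the oldest cohort", {
  expect_equal(cohort_index(12, 1, A = 12), 1L)
  expect_equal(cohort_index(1, 5, A = 12), 16L)
  expect_equal(cohort_index(1, 4, A = 12), 15L)
  expect_error(cohort_index(13, 1, A = 12), "out of range")
  expect_error(cohort_index(0, 1, A = 12), "out of range")
})

test_that("cohort labels land on conventional 5-year birth cohorts", {
  expect_equal(cohort_label_start(75, 1989), 1912L)
  expect_equal(cohort_label_start(20, 2009), 1987L)
  expect_equal(cohort_label_start(20, 1994), 1972L)
})

test_that("a full 12x5 grid yields 16 consecutive distinct cohort labels", {
  ages <- age_group_starts()
  periods <- period_bin_starts(1989, 5)
  labs <- sort(unique(as.vector(outer(ages, periods, cohort_label_start))))
  expect_length(labs, 16L)
  expect_equal(diff(labs), rep(5L, 15L))
  expect_equal(range(labs), c(1912L, 1987L))
})

test_that("missing-year imputation averages the k nearest years, ties to earlier", {
  expect_equal(impute_missing_year(c(`1995` = 2, `1996` = 4, `1997` = 6, `1998` = 8), 1994), 5)
  expect_equal(impute_missing_year(c(`1992` = 1, `1993` = 3, `1995` = 5, `1996` = 7), 1994), 4)
  expect_error(impute_missing_year(c(`1995` = 2, `1996` = 4, `1997` = 6), 1994),
               "at least 4")
  # tie at distance 2 (1992 vs 1996) for the last slot: earlier year wins
  s <- c(`1992` = 20, `1993` = 30, `1995` = 40, `1996` = 1000)
  expect_equal(impute_missing_year(s, 1994, k = 3), mean(c(30, 40, 20)))
  # k is configurable
  expect_equal(impute_missing_year(c(`1993` = 2, `1995` = 4), 1994, k = 2), 3)
})

test_that("bin_years sums complete years and conserves totals", {
  set.seed(5)
  A <- 12
  years <- 1989:1998
  D <- matrix(rpois(A * 10, 20), A, 10, dimnames = list(NULL, years))
  N <- matrix(1e4, A, 10, dimnames = list(NULL, years))
  tab <- bin_years(D, N, period_bin_starts(1989, 2))
  expect_s3_class(tab, "rate_table")
  expect_equal(unname(tab$deaths[, 1]), unname(rowSums(D[, 1:5])))
  expect_equal(sum(tab$deaths), sum(D))
  expect_equal(sum(tab$person_years), sum(N))
  expect_length(attr(tab, "imputed_years"), 0)
  # constant series: 5 years of 2 deaths -> cell count 10
  D2 <- matrix(2, A, 10, dimnames = list(NULL, years))
  tab2 <- bin_years(D2, N, period_bin_starts(1989, 2))
  expect_true(all(tab2$deaths == 10))
})

test_that("bin_years imputes a configured gap and errors without imputation", {
  A <- 12
  years <- 1994:2013
  set.seed(6)
  D <- matrix(rpois(A * 20, 50), A, 20, dimnames = list(NULL, years))
  N <- matrix(2e4, A, 20, dimnames = list(NULL, years))
  D[, "1994"] <- NA
  N[, "1994"] <- NA
  bins <- period_bin_starts(1994, 4)
  expect_error(bin_years(D, N, bins), "1994")
  tab <- bin_years(D, N, bins, impute = TRUE)
  expect_equal(attr(tab, "imputed_years"), 1994L)
  # imputed 1994 value per age = mean of 1995..1998, applied to deaths and
  # person-years alike
  expected_first_bin <- rowMeans(D[, as.character(1995:1998)]) +
    rowSums(D[, as.character(1995:1998)])
  expect_equal(unname(tab$deaths[, 1]), unname(expected_first_bin))
  expect_equal(unname(tab$person_years[, 1]), rep(2e4 + 4 * 2e4, A))
  # later bins untouched
  expect_equal(unname(tab$deaths[, 2]),
               unname(rowSums(D[, as.character(1999:2003)])))
})

test_that("bin_years rejects a bin with no available years", {
  A <- 12
  years <- 1994:2008
  D <- matrix(5, A, length(years), dimnames = list(NULL, years))
  N <- matrix(1e4, A, length(years), dimnames = list(NULL, years))
  expect_error(bin_years(D, N, period_bin_starts(1994, 4), impute = TRUE),
               "2009-2013")
})

test_that("rate_table validates shapes, positivity and contiguity", {
  D <- matrix(1, 12, 5); N <- matrix(1e4, 12, 5)
  expect_s3_class(rate_table(D, N, age_group_starts(), period_bin_starts(1989, 5)),
                  "rate_table")
  expect_error(rate_table(D, N[, 1:4], age_group_starts(), period_bin_starts(1989, 5)))
  N0 <- N; N0[3, 2] <- 0
  expect_error(rate_table(D, N0, age_group_starts(), period_bin_starts(1989, 5)),
               "positive")
  expect_error(rate_table(D, N, age_group_starts(), c(1989L, 1995L, 2000L, 2005L, 2010L)),
               "contiguous")
})

test_that("age-specific rates equal element-wise hand division per 100,000", {
  set.seed(9)
  D <- matrix(rpois(60, 30), 12, 5)
  N <- matrix(runif(60, 1e4, 1e6), 12, 5)
  tab <- rate_table(D, N, age_group_starts(), period_bin_starts(1989, 5))
  r <- age_specific_rates(tab)
  for (i in 1:12) for (j in 1:5) {
    expect_identical(r[i, j], 1e5 * D[i, j] / N[i, j])
  }
  expect_equal(r[1, 1], 1e5 * D[1, 1] / N[1, 1])
})

test_that("direct standardization matches the hand-computed weighted mean", {
  w <- segi_world_standard()
  expect_equal(sum(w), 59000)
  # constant rates pass through any standard
  r <- setNames(rep(7.7, 12), names(w))
  expect_equal(asmr(r), 7.7)
  # mass in one group only: hand-computed Segi weighting
  r1 <- setNames(c(10, rep(0, 11)), names(w))
  expect_equal(asmr(r1), 10 * 8000 / 59000)
  # weight rescaling invariance
  set.seed(10)
  rr <- setNames(runif(12, 0, 50), names(w))
  expect_equal(asmr(rr, w), asmr(rr, 17.3 * w))
  # missing weight is an error
  bad <- setNames(1:3, c("20-24", "25-29", "95-99"))
  expect_error(asmr(bad), "95-99")
})

test_that("asmr is bounded by the extreme age-specific rates", {
  w <- segi_world_standard()
  set.seed(11)
  for (rep in 1:50) {
    r <- setNames(runif(12, 0, 100), names(w))
    a <- asmr(r, w)
    expect_gte(a, min(r))
    expect_lte(a, max(r))
  }
})

test_that("asmr_series standardizes year by year", {
  set.seed(12)
  years <- 2000:2004
  D <- matrix(rpois(60, 40), 12, 5, dimnames = list(NULL, years))
  N <- matrix(runif(60, 1e4, 1e5), 12, 5, dimnames = list(NULL, years))
  ser <- asmr_series(D, N)
  expect_equal(ser$year, years)
  w <- segi_world_standard()
  hand <- sum(w * (1e5 * D[, 3] / N[, 3])) / sum(w)
  expect_equal(ser$asmr[3], hand)
})
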