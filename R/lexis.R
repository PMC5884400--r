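#' Five-year age groups
#'
#' Age groups are represented by their integer start year; every group is 5
#' years wide. The default analysis range is 20-79 (twelve groups), the ages
#' at which female breast, cervical and ovarian cancer deaths are both
#' non-negligible and attributable: deaths under 20 are very rare and deaths
#' over 80 are heavily confounded by competing causes, so both tails are
#' excluded from all rate tables.
#'
#' @param from,to first and last group start (multiples of 5).
#' @return integer vector of group starts.
#' @export
age_group_starts <- function(from = 20L, to = 75L) {
  stopifnot(from %% 5 == 0, to %% 5 == 0, to >= from)
  seq.int(as.integer(from), as.integer(to), by = 5L)
}

#' @rdname age_group_starts
#' @param starts integer group starts.
#' @export
age_group_labels <- function(starts) {
  sprintf("%d-%d", starts, starts + 4L)
}

#' Five-year period bins
#'
#' Periods are contiguous 5-year calendar bins labelled by their start year.
#' The integer midpoint convention (start + 2) is used throughout so that
#' cohort labels derived from period and age midpoints land exactly on
#' conventional 5-year birth-cohort bins.
#'
#' @param first_year start of the earliest bin.
#' @param n_periods number of bins.
#' @return integer vector of bin start years.
#' @export
period_bin_starts <- function(first_year, n_periods) {
  stopifnot(n_periods >= 1)
  seq.int(as.integer(first_year), by = 5L, length.out = n_periods)
}

#' @rdname period_bin_starts
#' @param starts bin start years.
#' @export
period_bin_labels <- function(starts) {
  sprintf("%d-%d", starts, starts + 4L)
}

bin_midpoint <- function(start) start + 2L

#' Cohort index of a Lexis cell
#'
#' On an A x P grid of 5-year age groups (position 1 = youngest) crossed with
#' 5-year periods (position 1 = earliest), each cell belongs to one of the
#' A + P - 1 synthetic birth cohorts. Cohort 1 is the oldest (oldest age in
#' the earliest period); the index increases along diagonals of the Lexis
#' diagram:
#'
#'   k = A - age_position + period_position
#'
#' @param age_position age-group position, 1..A (1 = youngest).
#' @param period_position period position, 1..P (1 = earliest).
#' @param A number of age groups.
#' @return integer cohort index in 1..(A + P - 1). Vectorised.
#' @export
cohort_index <- function(age_position, period_position, A) {
  if (any(age_position < 1L | age_position > A)) {
    stop("age_position out of range 1..", A)
  }
  if (any(period_position < 1L)) stop("period_position out of range")
  A - as.integer(age_position) + as.integer(period_position)
}

#' Birth-cohort label for an age group x period cell
#'
#' The synthetic cohort implied by crossing a 5-year age group with a 5-year
#' period spans roughly 10 birth years; it is conventionally labelled by its
#' central 5 years. With integer midpoints (bin start + 2) the label midpoint
#' is period midpoint minus age midpoint, and the labelled bin starts 2 years
#' earlier.
#'
#' @param age_start age-group start year(s).
#' @param period_start period bin start year(s).
#' @return integer start year(s) of the 5-year cohort label.
#' @export
cohort_label_start <- function(age_start, period_start) {
  bin_midpoint(as.integer(period_start)) - bin_midpoint(as.integer(age_start)) - 2L
}

#' Impute a missing calendar year from its nearest neighbours
#'
#' A missing year's value is replaced by the arithmetic mean of the k
#' available years nearest in calendar time, with distance ties broken toward
#' earlier years. The rule is applied independently per age group, and to
#' death counts and person-years alike, before period binning. It exists for
#' isolated single-year gaps in an otherwise complete national series (the
#' motivating case is a one-year gap in an ovarian-cancer series).
#'
#' @param series named numeric vector, names = available calendar years.
#' @param missing_year the year to impute.
#' @param k number of neighbouring years to average (default 4).
#' @return the imputed value (numeric scalar).
#' @export
impute_missing_year <- function(series, missing_year, k = 4L) {
  years <- as.integer(names(series))
  if (anyNA(years)) stop("series must be named by calendar year")
  avail <- years[!is.na(series)]
  if (length(avail) < k) {
    stop("need at least ", k, " available years to impute ", missing_year,
         " (have ", length(avail), ")")
  }
  d <- abs(avail - as.integer(missing_year))
  # order by distance, ties toward earlier years
  ord <- order(d, avail)
  take <- avail[ord[seq_len(k)]]
  mean(series[as.character(take)])
}

#' Age x period rate table
#'
#' The central container of the analysis: matched matrices of death counts
#' and person-years over an A x P grid of 5-year age groups (rows, youngest
#' first) and 5-year periods (columns, earliest first), for one
#' country/cancer stratum.
#'
#' @param deaths A x P matrix of non-negative death counts.
#' @param person_years A x P matrix of strictly positive person-years.
#' @param age_starts integer vector of A age-group starts.
#' @param period_starts integer vector of P period-bin starts.
#' @param country,cancer optional identifying labels.
#' @return an object of class `rate_table`.
#' @export
rate_table <- function(deaths, person_years, age_starts, period_starts,
                       country = NA_character_, cancer = NA_character_) {
  deaths <- as.matrix(deaths)
  person_years <- as.matrix(person_years)
  A <- length(age_starts)
  P <- length(period_starts)
  if (!all(dim(deaths) == c(A, P)) || !all(dim(person_years) == c(A, P))) {
    stop("deaths and person_years must both be ", A, " x ", P)
  }
  if (any(deaths < 0)) stop("negative death counts")
  if (any(person_years <= 0)) stop("person_years must be positive in every cell")
  if (any(diff(as.integer(period_starts)) != 5L)) {
    stop("period bins must be contiguous 5-year bins")
  }
  dimnames(deaths) <- dimnames(person_years) <-
    list(age = age_group_labels(age_starts),
         period = period_bin_labels(period_starts))
  structure(
    list(deaths = deaths, person_years = person_years,
         age_starts = as.integer(age_starts),
         period_starts = as.integer(period_starts),
         country = country, cancer = cancer),
    class = "rate_table")
}

#' @export
print.rate_table <- function(x, ...) {
  cat(sprintf("rate_table: %d age groups (%s..%s) x %d periods (%s..%s)\n",
              length(x$age_starts),
              rownames(x$deaths)[1], rownames(x$deaths)[length(x$age_starts)],
              length(x$period_starts),
              colnames(x$deaths)[1], colnames(x$deaths)[length(x$period_starts)]))
  if (!is.na(x$country)) cat("  country:", x$country, " cancer:", x$cancer, "\n")
  cat(sprintf("  total deaths %s over %.3g person-years\n",
              format(sum(x$deaths), big.mark = ","), sum(x$person_years)))
  invisible(x)
}

#' Bin per-year records into an age x period rate table
#'
#' Sums deaths and person-years over the calendar years of each 5-year
#' period bin. Years absent from the input are either imputed with
#' [impute_missing_year()] (applied per age group to deaths and person-years
#' separately) or raise an error naming the affected bin.
#'
#' @param deaths A x Y matrix of yearly death counts; columns named by
#'   calendar year. `NA` columns count as missing years.
#' @param person_years A x Y matrix of yearly population, same layout.
#' @param period_starts period bin starts covering the years to use.
#' @param impute if `TRUE`, missing years inside a bin are imputed; if
#'   `FALSE` (default) any missing year is an error.
#' @param k neighbours used by the imputation rule.
#' @param age_starts age-group starts (default twelve groups 20-79).
#' @param country,cancer passed to [rate_table()].
#' @return a `rate_table`; attribute `"imputed_years"` records which
#'   calendar years were filled in.
#' @export
bin_years <- function(deaths, person_years, period_starts,
                      impute = FALSE, k = 4L,
                      age_starts = age_group_starts(),
                      country = NA_character_, cancer = NA_character_) {
  deaths <- as.matrix(deaths)
  person_years <- as.matrix(person_years)
  stopifnot(nrow(deaths) == length(age_starts),
            all(dim(deaths) == dim(person_years)))
  years_have <- as.integer(colnames(deaths))
  if (anyNA(years_have)) stop("yearly matrices must have calendar-year column names")

  P <- length(period_starts)
  A <- length(age_starts)
  D <- matrix(0, A, P)
  N <- matrix(0, A, P)
  imputed <- integer(0)

  fill_year <- function(mat, yr) {
    j <- match(as.character(yr), colnames(mat))
    col_missing <- is.na(j) || all(is.na(mat[, j]))
    if (!col_missing) return(mat[, j])
    # impute each age group from its own yearly series
    vapply(seq_len(A), function(i) {
      s <- mat[i, ]
      names(s) <- colnames(mat)
      impute_missing_year(s[!is.na(s)], yr, k = k)
    }, numeric(1))
  }

  for (p in seq_len(P)) {
    yrs <- period_starts[p] + 0:4
    missing <- yrs[!(yrs %in% years_have) |
                     vapply(yrs, function(y) {
                       j <- match(as.character(y), colnames(deaths))
                       !is.na(j) && all(is.na(deaths[, j]))
                     }, logical(1))]
    if (length(missing) == length(yrs)) {
      stop("period bin ", period_bin_labels(period_starts[p]),
           " has no available years")
    }
    if (length(missing) > 0 && !impute) {
      stop("period bin ", period_bin_labels(period_starts[p]),
           " is missing year(s) ", paste(missing, collapse = ", "),
           " and imputation is disabled")
    }
    for (yr in yrs) {
      D[, p] <- D[, p] + fill_year(deaths, yr)
      N[, p] <- N[, p] + fill_year(person_years, yr)
    }
    imputed <- c(imputed, missing)
  }
  out <- rate_table(D, N, age_starts, period_starts,
                    country = country, cancer = cancer)
  attr(out, "imputed_years") <- imputed
  out
}

#' Age-specific mortality rates per 100,000 person-years
#'
#' @param table a [rate_table()].
#' @return A x P matrix of rates, `1e5 * deaths / person_years`.
#' @export
age_specific_rates <- function(table) {
  stopifnot(inherits(table, "rate_table"))
  1e5 * table$deaths / table$person_years
}

#' Segi (1960) world standard population, ages 20-79
#'
#' The world standard population weights proposed by Segi and modified by
#' Doll and colleagues, restricted to the twelve 5-year age groups 20-79
#' used here (out of the conventional 100,000 total, these groups carry
#' 59,000). [asmr()] renormalises over whichever groups are present, so the
#' absolute scale of the weights is irrelevant.
#'
#' @return named numeric vector of weights, names = age-group labels.
#' @export
segi_world_standard <- function() {
  w <- c(8000, 8000, 6000, 6000, 6000, 6000, 5000, 4000, 4000, 3000, 2000, 1000)
  names(w) <- age_group_labels(age_group_starts())
  w
}

#' Direct age-standardized rate
#'
#' Weighted average of age-specific rates with fixed standard-population
#' weights, the direct standardization method. Weights are renormalised over
#' the age groups present, so any positive rescaling of the standard gives
#' the same answer.
#'
#' @param rates_by_age named numeric vector of age-specific rates (names =
#'   age-group labels).
#' @param standard named weight vector covering every group in
#'   `rates_by_age`; default [segi_world_standard()].
#' @return the standardized rate (same units as the input rates).
#' @export
asmr <- function(rates_by_age, standard = segi_world_standard()) {
  if (is.null(names(rates_by_age))) stop("rates_by_age must be named by age group")
  miss <- setdiff(names(rates_by_age), names(standard))
  if (length(miss) > 0) {
    stop("standard population lacks weight(s) for group(s): ",
         paste(miss, collapse = ", "))
  }
  w <- standard[names(rates_by_age)]
  if (sum(w) <= 0) stop("total standard weight must be positive")
  sum(w * rates_by_age) / sum(w)
}

#' Yearly ASMR series from per-year matrices
#'
#' Computes, for each calendar year, age-specific rates per 100,000 and their
#' direct age-standardized summary.
#'
#' @param deaths A x Y yearly death counts (rows = age groups youngest
#'   first, columns named by year).
#' @param person_years matching yearly population matrix.
#' @param age_starts age-group starts for the rows.
#' @param standard standard population weights.
#' @return data.frame with columns `year` and `asmr`.
#' @export
asmr_series <- function(deaths, person_years,
                        age_starts = age_group_starts(),
                        standard = segi_world_standard()) {
  deaths <- as.matrix(deaths)
  person_years <- as.matrix(person_years)
  stopifnot(all(dim(deaths) == dim(person_years)))
  labs <- age_group_labels(age_starts)
  years <- as.integer(colnames(deaths))
  vals <- vapply(seq_along(years), function(j) {
    ok <- !is.na(deaths[, j]) & !is.na(person_years[, j]) & person_years[, j] > 0
    if (!any(ok)) return(NA_real_)
    r <- 1e5 * deaths[ok, j] / person_years[ok, j]
    names(r) <- labs[ok]
    asmr(r, standard)
  }, numeric(1))
  data.frame(year = years, asmr = vals)
}
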