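# Reader for WHO Mortality Database flat files ("Morticd" deaths files and
# "pop" population files). These are plain CSV with one row per
# country/year/sex(/cause) stratum and 26 age columns; ages 20-79 in the
# 5-year layout live in columns 10..21 (Deaths10..Deaths21 / Pop10..Pop21).

# columns of the 26-column age layout holding 5-year groups 20-24 .. 75-79
WHO_AGE2079_COLS <- 10:21

# age formats carrying full 5-year detail from age 20 upward
WHO_SUPPORTED_FRMATS <- c("00", "01")

WHO_SEX_CODES <- c(male = 1L, female = 2L, unspecified = 9L)

# minimal built-in country dictionary for the three study countries
#' WHO country codes for the built-in study countries
#' @return named integer vector (name = country, value = WHO code).
#' @export
who_country_codes <- function() {
  c(Japan = 3160L, `Republic of Korea` = 3325L, Singapore = 3350L)
}

#' ICD-10 cause-code sets for the studied cancers
#'
#' Built-in mapping: breast -> C50, cervical -> C53, ovarian -> C56. Matching
#' is by prefix, so 4-character codes such as "C509" match "C50". Other ICD
#' revisions carry no built-in map; supply `icd_codes` explicitly for them.
#'
#' @param cancer one of "breast", "cervical", "ovarian".
#' @return character vector of code prefixes.
#' @export
cause_codes <- function(cancer = c("breast", "cervical", "ovarian")) {
  cancer <- match.arg(cancer)
  switch(cancer, breast = "C50", cervical = "C53", ovarian = "C56")
}

normalize_frmat <- function(x) sprintf("%02d", as.integer(x))

match_cause <- function(codes, prefixes) {
  codes <- toupper(trimws(as.character(codes)))
  Reduce(`|`, lapply(toupper(prefixes), function(p) startsWith(codes, p)))
}

who_read_csv <- function(path) {
  if (!file.exists(path)) stop("cannot read WHO file: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

require_cols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    stop("WHO file ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "))
  }
}

drop_subnational_rows <- function(df) {
  for (col in c("Admin1", "SubDiv")) {
    if (col %in% names(df)) {
      v <- trimws(as.character(df[[col]]))
      df <- df[is.na(v) | v == "" | v == "0", , drop = FALSE]
    }
  }
  df
}

filter_frmat <- function(df, what) {
  fr <- normalize_frmat(df$Frmat)
  bad <- !(fr %in% WHO_SUPPORTED_FRMATS)
  if (any(bad)) {
    warning(sum(bad), " ", what, " row(s) rejected: age format(s) ",
            paste(unique(fr[bad]), collapse = ", "),
            " lack full 5-year detail for ages 20-79", call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  df
}

#' Read deaths from a WHO Mortality Database flat file
#'
#' Filters a "Morticd"-style deaths file to one country, one sex and a set of
#' cause-code prefixes, keeping only rows whose age format provides full
#' 5-year detail (Frmat 00 or 01). Rows with subnational Admin1/SubDiv codes
#' are dropped by default so that only national totals are counted. Duplicate
#' (year, cause) rows within the stratum are summed.
#'
#' @param path deaths file (CSV with columns Country, Year, Cause, Sex,
#'   Frmat, Deaths1..Deaths26; Admin1/SubDiv/List/IM_Frmat optional).
#' @param icd_codes cause-code prefixes, e.g. `cause_codes("breast")`.
#' @param country WHO numeric country code (see [who_country_codes()]).
#' @param sex sex to retain, `"female"` by default.
#' @param drop_subnational drop rows with non-empty Admin1/SubDiv.
#' @return data.frame with columns Country, Year, Cause, Sex, Frmat and
#'   Deaths1..Deaths26, sorted by year; zero matching rows raises a warning
#'   of class `"who_empty_result"` and returns the empty frame.
#' @export
read_who_deaths <- function(path, icd_codes, country,
                            sex = c("female", "male", "unspecified"),
                            drop_subnational = TRUE) {
  sex <- match.arg(sex)
  df <- who_read_csv(path)
  death_cols <- paste0("Deaths", 1:26)
  require_cols(df, c("Country", "Year", "Cause", "Sex", "Frmat", death_cols), path)
  if (drop_subnational) df <- drop_subnational_rows(df)
  df <- df[df$Country == country & df$Sex == WHO_SEX_CODES[[sex]], , drop = FALSE]
  df <- df[match_cause(df$Cause, icd_codes), , drop = FALSE]
  df <- filter_frmat(df, "deaths")

  if (nrow(df) == 0) {
    warning(warningCondition(
      paste0("no deaths rows match country=", country, ", sex=", sex,
             ", causes {", paste(icd_codes, collapse = ","), "} in ", path),
      class = "who_empty_result"))
    out <- df[, c("Country", "Year", "Cause", "Sex", "Frmat", death_cols)]
    return(out)
  }

  for (cc in death_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (anyNA(v)) {
      warning("missing-coded cells in ", cc, " treated as 0", call. = FALSE)
      v[is.na(v)] <- 0
    }
    df[[cc]] <- v
  }
  # sum duplicate (year, cause) rows within the stratum
  key <- interaction(df$Year, df$Cause, drop = TRUE)
  if (anyDuplicated(key)) {
    agg <- stats::aggregate(df[death_cols], by = list(Year = df$Year, Cause = df$Cause), FUN = sum)
    agg$Country <- country
    agg$Sex <- WHO_SEX_CODES[[sex]]
    agg$Frmat <- df$Frmat[match(paste(agg$Year, agg$Cause), paste(df$Year, df$Cause))]
    df <- agg
  }
  df <- df[order(df$Year, df$Cause), c("Country", "Year", "Cause", "Sex", "Frmat", death_cols)]
  rownames(df) <- NULL
  df
}

#' Read population from a WHO Mortality Database flat file
#'
#' Same conventions as [read_who_deaths()] but for the "pop" dialect (columns
#' Pop1..Pop26, no Cause). Duplicate year rows are summed.
#'
#' @inheritParams read_who_deaths
#' @param path population file.
#' @return data.frame with Country, Year, Sex, Frmat and Pop1..Pop26.
#' @export
read_who_population <- function(path, country,
                                sex = c("female", "male", "unspecified"),
                                drop_subnational = TRUE) {
  sex <- match.arg(sex)
  df <- who_read_csv(path)
  pop_cols <- paste0("Pop", 1:26)
  require_cols(df, c("Country", "Year", "Sex", "Frmat", pop_cols), path)
  if (drop_subnational) df <- drop_subnational_rows(df)
  df <- df[df$Country == country & df$Sex == WHO_SEX_CODES[[sex]], , drop = FALSE]
  df <- filter_frmat(df, "population")
  if (nrow(df) == 0) {
    warning(warningCondition(
      paste0("no population rows match country=", country, ", sex=", sex,
             " in ", path),
      class = "who_empty_result"))
    return(df[, c("Country", "Year", "Sex", "Frmat", pop_cols)])
  }
  for (cc in pop_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (anyNA(v)) {
      warning("missing-coded cells in ", cc, " treated as 0", call. = FALSE)
      v[is.na(v)] <- 0
    }
    df[[cc]] <- v
  }
  if (anyDuplicated(df$Year)) {
    agg <- stats::aggregate(df[pop_cols], by = list(Year = df$Year), FUN = sum)
    agg$Country <- country
    agg$Sex <- WHO_SEX_CODES[[sex]]
    agg$Frmat <- df$Frmat[match(agg$Year, df$Year)]
    df <- agg
  }
  df <- df[order(df$Year), c("Country", "Year", "Sex", "Frmat", pop_cols)]
  rownames(df) <- NULL
  df
}

#' Extract the twelve 20-79 age-group counts from a WHO row
#'
#' Maps the fixed 26-column age layout (column 1 = all ages, column 2 = age
#' 0, columns 7..25 = 5-year groups 5-9 .. 95+, column 26 = unknown age) to
#' the twelve 5-year groups 20-24 .. 75-79, which occupy columns 10..21.
#' Counts outside 20-79 (including the unknown-age column) are discarded.
#'
#' @param row one row of a frame from [read_who_deaths()] /
#'   [read_who_population()], or any list with the 26 age columns.
#' @param prefix `"Deaths"` or `"Pop"`.
#' @return named numeric vector of 12 counts (names = age-group labels).
#' @export
columns_to_age_groups <- function(row, prefix = c("Deaths", "Pop")) {
  prefix <- match.arg(prefix)
  fr <- normalize_frmat(row[["Frmat"]])
  if (!(fr %in% WHO_SUPPORTED_FRMATS)) {
    stop("unsupported age format '", fr,
         "': only formats 00/01 (full 5-year detail) are accepted")
  }
  cols <- paste0(prefix, WHO_AGE2079_COLS)
  v <- suppressWarnings(as.numeric(unlist(row[cols])))
  if (anyNA(v)) {
    warning("missing-coded age cells treated as 0", call. = FALSE)
    v[is.na(v)] <- 0
  }
  names(v) <- age_group_labels(age_group_starts())
  v
}

#' Assemble yearly age x year matrices from WHO records
#'
#' Converts reader output into the A x Y matrices consumed by [bin_years()]
#' and [asmr_series()]: rows = twelve age groups 20-79, columns = calendar
#' years. Deaths rows for multiple cause codes in the same year are summed
#' (they are disjoint subdivisions of one cause set).
#'
#' @param records frame from [read_who_deaths()] or [read_who_population()].
#' @param prefix `"Deaths"` or `"Pop"`.
#' @param years optional calendar years wanted; years with no record become
#'   `NA` columns (candidates for imputation).
#' @return 12 x length(years) numeric matrix with year column names.
#' @export
who_year_matrix <- function(records, prefix = c("Deaths", "Pop"), years = NULL) {
  prefix <- match.arg(prefix)
  if (is.null(years)) years <- sort(unique(records$Year))
  labs <- age_group_labels(age_group_starts())
  out <- matrix(NA_real_, nrow = length(labs), ncol = length(years),
                dimnames = list(age = labs, year = years))
  for (r in seq_len(nrow(records))) {
    yr <- as.character(records$Year[r])
    if (!(yr %in% colnames(out))) next
    v <- columns_to_age_groups(records[r, ], prefix = prefix)
    cur <- out[, yr]
    out[, yr] <- ifelse(is.na(cur), v, cur + v)
  }
  out
}

#' Write records in tidy long format
#'
#' Normalized long-format export (country, year, cause, age_group, deaths,
#' population), one row per age group and year.
#'
#' @param deaths_mat,pop_mat matrices from [who_year_matrix()].
#' @param path output CSV path.
#' @param country,cancer identifying labels.
#' @return the written data.frame, invisibly.
#' @export
write_long_format <- function(deaths_mat, pop_mat, path,
                              country = NA_character_, cancer = NA_character_) {
  stopifnot(all(dim(deaths_mat) == dim(pop_mat)))
  if (is.null(rownames(deaths_mat))) {
    rownames(deaths_mat) <-
      age_group_labels(age_group_starts())[seq_len(nrow(deaths_mat))]
  }
  long <- expand.grid(age_group = rownames(deaths_mat),
                      year = as.integer(colnames(deaths_mat)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$country <- country
  long$cause <- cancer
  long$deaths <- as.vector(deaths_mat)
  long$population <- as.vector(pop_mat)
  long <- long[, c("country", "year", "cause", "age_group", "deaths", "population")]
  utils::write.csv(long, path, row.names = FALSE)
  invisible(long)
}
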