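## Descriptive epidemiology: age-specific, crude and direct-standardized
## rates, triennial moving averages, and assembly of the Lexis grid.

#' Age-specific mortality rate
#'
#' rate = scale * deaths / person-years (default per 100,000).
#' @param deaths,personYears numeric vectors (recycled).
#' @param scale reporting scale, default 1e5.
#' @examples
#' ageSpecificRate(5, 250000)  # 2 per 100,000
#' @export
ageSpecificRate <- function(deaths, personYears, scale = 1e5) {
  n <- max(length(deaths), length(personYears))
  deaths <- rep_len(deaths, n); personYears <- rep_len(personYears, n)
  if (any(personYears == 0 & deaths > 0))
    stop("person-years is zero where deaths > 0: rate undefined")
  out <- scale * deaths / personYears
  zz <- personYears == 0 & deaths == 0
  if (any(zz)) {
    warning("zero person-years with zero deaths: rate set to 0")
    out[zz] <- 0
  }
  out
}

#' WHO world standard population weights
#'
#' The 2000-2025 world standard age distribution, packaged as 5-year
#' groups with 80+ collapsed, restricted to \code{minAge} and renormalized
#' to sum to one (the study population is ages 10 and over).
#'
#' @param minAge lower age bound; 0 keeps the full standard.
#' @return data.frame (age_group, age_start, weight) with weights summing
#'   to 1.
#' @export
whoStandardPopulation <- function(minAge = 10) {
  p <- system.file("extdata", "who_world_standard.csv", package = "lexisapc")
  s <- read.csv(p, stringsAsFactors = FALSE)
  s <- s[s$age_start >= minAge, ]
  data.frame(age_group = s$age_group, age_start = s$age_start,
             weight = s$weight_pct / sum(s$weight_pct),
             stringsAsFactors = FALSE)
}

#' Direct age standardization
#'
#' SAR = sum of weight x age-specific rate over the standard's age groups.
#' Weights are renormalized internally, so unnormalized standards give the
#' same answer.
#'
#' @param ageRates named numeric vector (names are age-group labels) or
#'   data.frame (age_group, rate).
#' @param standard data.frame (age_group, weight), e.g.
#'   \code{\link{whoStandardPopulation}()}.
#' @examples
#' directStandardize(c(a = 1, b = 3),
#'                   data.frame(age_group = c("a", "b"),
#'                              weight = c(0.25, 0.75)))  # 2.5
#' @export
directStandardize <- function(ageRates, standard) {
  if (is.data.frame(ageRates))
    ageRates <- setNames(ageRates$rate, ageRates$age_group)
  miss <- setdiff(standard$age_group, names(ageRates))
  if (length(miss))
    stop("age group(s) missing from rates: ", paste(miss, collapse = ", "))
  w <- standard$weight / sum(standard$weight)
  sum(w * ageRates[standard$age_group])
}

#' Centered moving average with partial end windows
#'
#' Triennial smoothing by default.  Interior points get the centered
#' window mean; each end gets the mean of the available partial window
#' (two terms for window 3), so the output has the input's length.  With
#' \code{endpoints = "trim"} the ends are NA instead.
#'
#' @param x numeric series, length >= window.
#' @param window odd window size, default 3.
#' @param endpoints "partial" (default) or "trim".
#' @examples
#' movingAverage(c(1, 2, 3, 4))  # 1.5 2.0 3.0 3.5
#' @export
movingAverage <- function(x, window = 3, endpoints = c("partial", "trim")) {
  endpoints <- match.arg(endpoints)
  stopifnot(window %% 2 == 1, window >= 1)
  n <- length(x)
  if (n < window)
    stop("series length ", n, " is shorter than the window ", window)
  h <- (window - 1) / 2
  out <- vapply(seq_len(n), function(i) {
    lo <- max(1, i - h); hi <- min(n, i + h)
    mean(x[lo:hi])
  }, numeric(1))
  if (endpoints == "trim" && h > 0)
    out[c(seq_len(h), n - seq_len(h) + 1)] <- NA_real_
  out
}

#' Assemble a Lexis table from corrected records and population
#'
#' Aggregates suicide-intent deaths of one mechanism and the person-years
#' to the 5-year age x 5-year period grid; the cohort index k = j - i + I
#' is attached per cell.
#'
#' @param records corrected death-record data.frame.
#' @param population data.frame (region, year, age_group, person_years).
#' @param mechanism "HSS", "AUT" or "FA".
#' @param map cause map.
#' @param ageStarts,periodStarts grid definition.
#' @return a \linkS4class{LexisTable}.
#' @export
buildLexis <- function(records, population, mechanism,
                       map = causeMap(),
                       ageStarts = seq(10, 80, by = 5),
                       periodStarts = seq(1980, 2015, by = 5)) {
  stopifnot(mechanism %in% c("HSS", "AUT", "FA"))
  validateDeathRecords(records, ageStarts, periodStarts)
  ageLabs <- ageGroupLabels(ageStarts)
  badAge <- setdiff(unique(population$age_group), ageLabs)
  if (length(badAge))
    stop("population age groups outside the grid: ",
         paste(badAge, collapse = ", "))
  yr <- range(periodStarts) + c(0, 4)
  badYr <- unique(population$year[population$year < yr[1] |
                                  population$year > yr[2]])
  if (length(badYr))
    stop("population years outside the grid: ",
         paste(sort(badYr), collapse = ", "))

  cls <- mapCause(records$cause_code, records$icd_revision, map)
  keep <- cls$in_scope & cls$intent == "suicide" &
    !is.na(cls$mechanism) & cls$mechanism == mechanism
  rec <- records[keep, , drop = FALSE]
  I <- length(ageStarts); J <- length(periodStarts)
  cellSum <- function(val, age, year) {
    i <- factor(match(age, ageLabs), levels = seq_len(I))
    j <- factor(findInterval(year, periodStarts), levels = seq_len(J))
    m <- tapply(val, list(i, j), sum)
    m[is.na(m)] <- 0
    unname(m)
  }
  D <- if (nrow(rec)) cellSum(rec$deaths, rec$age_group, rec$year) else
    matrix(0, I, J)
  N <- cellSum(population$person_years, population$age_group,
               population$year)
  LexisTable(D, N, ageStarts, periodStarts)
}

#' Quinquennial rate table with direct standardization
#'
#' Per-period aggregate rates (sum of deaths over sum of person-years,
#' per 100,000) plus a direct-standardized rate row computed from the
#' all-period age-specific rates — the layout of a period-by-region rate
#' table.
#'
#' @param lexis a \linkS4class{LexisTable}.
#' @param standard standard population, default WHO world standard 10+.
#' @return data.frame (period, rate) with a final "SAR" row.
#' @export
periodRateTable <- function(lexis, standard = whoStandardPopulation()) {
  D <- deaths(lexis); N <- personYears(lexis)
  per <- colSums(D) / colSums(N) * 1e5
  ageRates <- setNames(ageSpecificRate(rowSums(D), rowSums(N)),
                       ageGroups(lexis))
  sar <- directStandardize(ageRates, standard)
  data.frame(period = c(periods(lexis), "SAR"),
             rate = c(per, sar), stringsAsFactors = FALSE)
}
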