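#' Construct a LexisTable
#'
#' @param deaths,personYears numeric I x J matrices (ages in rows, oldest
#'   last; periods in columns, earliest first).
#' @param ageStarts,periodStarts lower bounds of the 5-year bins; defaults
#'   are the 15 x 8 design (ages 10-14 ... 80+, periods 1980-1984 ...
#'   2015-2019).
#' @return a \linkS4class{LexisTable}.
#' @examples
#' lx <- LexisTable(matrix(rpois(120, 20), 15, 8),
#'                  matrix(5e6, 15, 8))
#' nCohorts(lx)
#' @export
LexisTable <- function(deaths, personYears,
                       ageStarts = seq(10, 80, by = 5),
                       periodStarts = seq(1980, 2015, by = 5)) {
  deaths <- as.matrix(deaths); personYears <- as.matrix(personYears)
  stopifnot(all(dim(deaths) == dim(personYears)),
            nrow(deaths) == length(ageStarts),
            ncol(deaths) == length(periodStarts))
  ag <- ageGroupLabels(ageStarts); pd <- periodLabels5(periodStarts)
  dimnames(deaths) <- dimnames(personYears) <- list(ag, pd)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(deaths = deaths, personYears = personYears),
    rowData = S4Vectors::DataFrame(ageGroup = ag, ageStart = ageStarts),
    colData = S4Vectors::DataFrame(period = pd, periodStart = periodStarts))
  S4Vectors::metadata(se)$cohortLabels <- cohortLabels5(ageStarts, periodStarts)
  methods::new("LexisTable", se)
}

#' @describeIn LexisTable death-count matrix
#' @param x a LexisTable
#' @export
deaths <- function(x) SummarizedExperiment::assay(x, "deaths")

#' @describeIn LexisTable person-years matrix
#' @export
personYears <- function(x) SummarizedExperiment::assay(x, "personYears")

#' @describeIn LexisTable age-group labels (ascending)
#' @export
ageGroups <- function(x) SummarizedExperiment::rowData(x)$ageGroup

#' @describeIn LexisTable period labels (ascending)
#' @export
periods <- function(x) SummarizedExperiment::colData(x)$period

#' @describeIn LexisTable the K = I + J - 1 cohort labels
#' @export
cohortLabels <- function(x) S4Vectors::metadata(x)$cohortLabels

#' @describeIn LexisTable number of distinct birth cohorts on the grid
#' @export
nCohorts <- function(x) length(cohortLabels(x))

#' Cohort index matrix of a Lexis grid
#'
#' k(i, j) = j - i + I; constant along diagonals (k(i, j) = k(i+1, j+1)).
#' @param x a LexisTable
#' @return integer I x J matrix of cohort indices in 1..K.
#' @export
cohortIndex <- function(x) {
  I <- nrow(x); J <- ncol(x)
  outer(seq_len(I), seq_len(J), function(i, j) j - i + I)
}

#' Long-format view of a LexisTable
#'
#' One row per cell with age group, period, cohort label, deaths and
#' person-years — the CSV serialization schema.
#' @param x a LexisTable
#' @export
lexisToLong <- function(x) {
  I <- nrow(x); J <- ncol(x)
  k <- cohortIndex(x)
  data.frame(
    age_group = rep(ageGroups(x), J),
    period = rep(periods(x), each = I),
    cohort = cohortLabels(x)[as.vector(k)],
    deaths = as.vector(deaths(x)),
    person_years = as.vector(personYears(x)),
    stringsAsFactors = FALSE)
}

#' @exportMethod show
setMethod("show", "LexisTable", function(object) {
  cat("LexisTable:", nrow(object), "age groups x", ncol(object),
      "periods (", nCohorts(object), "cohorts )\n")
  cat("  total deaths:", round(sum(deaths(object)), 2),
      " total person-years:", format(sum(personYears(object)), big.mark = ","),
      "\n")
  cat("  ages:", ageGroups(object)[1], "...",
      ageGroups(object)[nrow(object)], "\n")
  cat("  periods:", periods(object)[1], "...",
      periods(object)[ncol(object)], "\n")
})
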