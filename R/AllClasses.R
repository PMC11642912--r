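#' @import methods
#' @importFrom stats glm poisson coef vcov offset pchisq qnorm AIC rpois
#'   rbinom rmultinom median quantile sd optim setNames aggregate
#' @importFrom utils read.csv write.csv
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors metadata DataFrame
NULL

#' LexisTable: deaths and person-years on an age x period grid
#'
#' A \code{SummarizedExperiment} with two assays, \code{deaths} and
#' \code{personYears}, rows indexed by 5-year age group (ascending) and
#' columns by 5-year calendar period.  Birth cohorts run along the
#' diagonals: cell (i, j) belongs to cohort k = j - i + I, so the grid
#' carries K = I + J - 1 synthetic 5-year cohorts (each actually spanning
#' ten birth years; labelled by 5-year bins as is conventional).
#'
#' @slot .  inherits all slots from \code{SummarizedExperiment};
#'   \code{rowData} holds \code{ageStart}, \code{colData} holds
#'   \code{periodStart}, and \code{metadata} holds the cohort labels.
#' @export
setClass("LexisTable", contains = "SummarizedExperiment")

setValidity("LexisTable", function(object) {
  msg <- character()
  a <- SummarizedExperiment::assayNames(object)
  if (!all(c("deaths", "personYears") %in% a))
    msg <- c(msg, "assays must include 'deaths' and 'personYears'")
  else {
    D <- SummarizedExperiment::assay(object, "deaths")
    N <- SummarizedExperiment::assay(object, "personYears")
    if (any(D < 0)) msg <- c(msg, "deaths must be non-negative")
    if (any(N < 0)) msg <- c(msg, "person-years must be non-negative")
    if (any(D > 0 & N <= 0))
      msg <- c(msg, "person-years must be positive wherever deaths > 0")
  }
  if (is.null(S4Vectors::metadata(object)$cohortLabels))
    msg <- c(msg, "metadata must carry cohortLabels")
  else if (length(S4Vectors::metadata(object)$cohortLabels) !=
           nrow(object) + ncol(object) - 1)
    msg <- c(msg, "number of cohort labels must equal I + J - 1")
  if (length(msg)) msg else TRUE
})

#' SyntheticScenario: a known APC surface plus degradation parameters
#'
#' Defines the generating truth for the synthetic vital-registration data:
#' per-age log baseline rates, an annual drift (log rate ratio per calendar
#' year), zero-slope period and cohort curvature vectors, per-cell
#' person-years, intent-misclassification fractions and registration
#' coverage by (region, decade).
#'
#' @slot region single region identifier (multi-region studies are a list
#'   of scenarios, one per region, fitted independently).
#' @slot mechanism one of "HSS", "AUT", "FA" — the true mechanism of the
#'   generated suicides.
#' @slot ageStarts,periodStarts grid definition (5-year bins).
#' @slot ageCurve numeric length-I log baseline rates (per person-year).
#' @slot annualDrift log rate ratio per calendar year.
#' @slot periodCurvature,cohortCurvature zero-slope curvature vectors
#'   (lengths J and K = I + J - 1); their least-squares slope against the
#'   category index must vanish or drift is not identified against them.
#' @slot populationBase person-years per (single calendar year, age group)
#'   cell: scalar or length-I vector.
#' @slot misclassFractions named numeric: probability that a true suicide
#'   is certified as "undetermined", "accident" or "assault" of the same
#'   mechanism; must sum to < 1.
#' @slot coverage data.frame (region, decade, coverage), coverage in (0,1].
#' @slot seed integer seed making generation reproducible.
#' @export
setClass("SyntheticScenario",
  representation(
    region = "character", mechanism = "character",
    ageStarts = "numeric", periodStarts = "numeric",
    ageCurve = "numeric", annualDrift = "numeric",
    periodCurvature = "numeric", cohortCurvature = "numeric",
    populationBase = "numeric", misclassFractions = "numeric",
    coverage = "data.frame", seed = "integer"))

setValidity("SyntheticScenario", function(object) {
  msg <- character()
  I <- length(object@ageStarts); J <- length(object@periodStarts)
  K <- I + J - 1
  if (length(object@ageCurve) != I)
    msg <- c(msg, sprintf("ageCurve must have length I = %d", I))
  if (length(object@periodCurvature) != J)
    msg <- c(msg, sprintf("periodCurvature must have length J = %d", J))
  if (length(object@cohortCurvature) != K)
    msg <- c(msg, sprintf("cohortCurvature must have length K = I + J - 1 = %d", K))
  slopeTol <- 1e-10
  if (length(object@periodCurvature) == J &&
      abs(sum(wlsSlopeWeights(seq_len(J), rep(1, J)) * object@periodCurvature)) > slopeTol)
    msg <- c(msg, "periodCurvature must have zero least-squares slope")
  if (length(object@cohortCurvature) == K &&
      abs(sum(wlsSlopeWeights(seq_len(K), rep(1, K)) * object@cohortCurvature)) > slopeTol)
    msg <- c(msg, "cohortCurvature must have zero least-squares slope")
  f <- object@misclassFractions
  if (!all(c("undetermined", "accident", "assault") %in% names(f)))
    msg <- c(msg, "misclassFractions must name undetermined, accident, assault")
  if (any(f < 0) || any(f >= 1) || sum(f) >= 1)
    msg <- c(msg, "misclassFractions must lie in [0,1) and sum to < 1")
  if (!all(c("region", "decade", "coverage") %in% names(object@coverage)))
    msg <- c(msg, "coverage needs columns region, decade, coverage")
  else if (any(object@coverage$coverage <= 0 | object@coverage$coverage > 1))
    msg <- c(msg, "coverage values must lie in (0, 1]")
  if (!(length(object@populationBase) %in% c(1L, I)) ||
      any(object@populationBase < 0))
    msg <- c(msg, "populationBase must be a non-negative scalar or length-I vector")
  if (!object@mechanism %in% c("HSS", "AUT", "FA"))
    msg <- c(msg, "mechanism must be one of HSS, AUT, FA")
  if (length(msg)) msg else TRUE
})

#' APCFit: estimable-function decomposition of a Poisson APC model
#'
#' @slot devianceTable six-row data.frame (model, resDev, resDf, AIC,
#'   pLRT) for the nested chain age / age-drift / age-cohort / APC /
#'   age-period / age-drift.
#' @slot ageCurve data.frame: longitudinal age trend (age slope plus
#'   period slope folded in) as fitted rates per 100,000 with 95% CI.
#' @slot drift list: annual rate ratio with CI from the full model, plus
#'   the age-drift-model estimate for comparison, and the trend class.
#' @slot periodRR,cohortRR data.frames of relative risks vs the reference
#'   category with 95% CIs; the reference row is exactly 1 with CI [1,1].
#' @slot options echo of reference labels, drift allocation, detrending
#'   weights; includes a dispersion diagnostic.
#' @slot glmFit the underlying full-model \code{glm} object.
#' @export
setClass("APCFit",
  representation(
    devianceTable = "data.frame", ageCurve = "data.frame",
    drift = "list", periodRR = "data.frame", cohortRR = "data.frame",
    options = "list", glmFit = "ANY"))
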