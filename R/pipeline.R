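## Orchestration: the correct -> rates -> fit pipeline, CSV/JSON
## serialization, and report arithmetic.

#' Percent change in proportional mortality between two periods
#'
#' 100 * (late - early) / early, sign preserved; shares are percentages.
#' @param shareEarly,shareLate cause shares (percent) in the early and
#'   late windows; shareEarly must be positive.
#' @examples
#' proportionalMortalityChange(12.14, 4.04)   # -66.72
#' @export
proportionalMortalityChange <- function(shareEarly, shareLate) {
  if (any(shareEarly <= 0) || any(shareEarly > 100) ||
      any(shareLate <= 0) || any(shareLate > 100))
    stop("shares must lie in (0, 100]")
  100 * (shareLate - shareEarly) / shareEarly
}

#' Proportional mortality of each mechanism within a year window
#'
#' Shares (percent) of suicide-intent deaths by mechanism among all
#' method-specific suicides in [yearFrom, yearTo].
#' @param records corrected death-record data.frame.
#' @param yearFrom,yearTo inclusive window.
#' @param map cause map.
#' @return named numeric vector of percent shares (HSS, AUT, FA).
#' @export
proportionalMortality <- function(records, yearFrom, yearTo,
                                  map = causeMap()) {
  cls <- mapCause(records$cause_code, records$icd_revision, map)
  keep <- cls$in_scope & cls$intent == "suicide" & !is.na(cls$mechanism) &
    records$year >= yearFrom & records$year <= yearTo
  tot <- tapply(records$deaths[keep], cls$mechanism[keep], sum)
  out <- setNames(rep(0, 3), c("HSS", "AUT", "FA"))
  out[names(tot)] <- tot
  100 * out / sum(out)
}

#' Two-stage record correction
#'
#' Garbage-code redistribution followed by coverage inflation — the order
#' mirrors the correction protocol (misclassification first, then
#' under-reporting).
#' @param records raw death-record data.frame.
#' @param coverage data.frame (region, decade, coverage).
#' @param map cause map.
#' @param ... passed to \code{\link{redistributeGarbage}}.
#' @return corrected records (audit attribute preserved).
#' @export
correctRecords <- function(records, coverage, map = causeMap(), ...) {
  red <- redistributeGarbage(records, map = map, ...)
  audit <- attr(red, "audit")
  out <- applyCoverage(red, coverage)
  attr(out, "audit") <- audit
  out
}

#' Serialize an APCFit to CSV tables plus a JSON manifest
#'
#' Writes deviance_table.csv, age_curve.csv, period_rr.csv,
#' cohort_rr.csv, drift.csv and manifest.json into \code{dir}.
#' @param fit an \linkS4class{APCFit}.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
writeApcFit <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, f) {
    p <- file.path(dir, f); write.csv(df, p, row.names = FALSE); p
  }
  d <- fit@drift
  paths <- c(
    w(devianceTable(fit), "deviance_table.csv"),
    w(ageCurve(fit), "age_curve.csv"),
    w(periodRR(fit), "period_rr.csv"),
    w(cohortRR(fit), "cohort_rr.csv"),
    w(data.frame(annualRR = d$annualRR, lo = d$lo, hi = d$hi,
                 trend = d$trend,
                 ageDriftModelRR = d$ageDriftModel$annualRR),
      "drift.csv"))
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(
    package = "lexisapc",
    version = as.character(utils::packageVersion("lexisapc")),
    options = fit@options,
    causeMapVersion = "cause_map_v1",
    standardPopulation = "who_world_standard",
    converged = fit@glmFit$converged),
    manifest, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(paths, manifest))
}

#' Run the whole pipeline on one region x mechanism
#'
#' simulate (or take records/population as given) -> correct -> rate
#' table -> Lexis grid -> APC fit, writing every serialized table into
#' \code{outDir}.  Identical configuration and seed give byte-identical
#' outputs.
#'
#' @param scenario a \linkS4class{SyntheticScenario}; if supplied,
#'   records/population are generated and degraded from it.
#' @param records,population,coverage inputs for the real-data route
#'   (ignored when \code{scenario} is given except \code{coverage}, which
#'   defaults to the scenario's own factors).
#' @param mechanism mechanism to analyse; defaults to the scenario's.
#' @param outDir output directory; NULL skips writing.
#' @param ... APC options passed to \code{\link{estimableDecomposition}}.
#' @return list (records, corrected, lexis, rateTable, fit, files).
#' @export
runPipeline <- function(scenario = NULL, records = NULL, population = NULL,
                        coverage = NULL, mechanism = NULL, outDir = NULL,
                        ...) {
  if (!is.null(scenario)) {
    sim <- simulateScenario(scenario)
    population <- sim$population
    records <- degradeRecords(sim$records, scenario)
    coverage <- coverage %||% scenario@coverage
    mechanism <- mechanism %||% scenario@mechanism
  }
  if (is.null(records) || is.null(population) || is.null(coverage) ||
      is.null(mechanism))
    stop("need either a scenario or records + population + coverage + mechanism")
  corrected <- correctRecords(records, coverage)
  lexis <- buildLexis(corrected, population, mechanism)
  rateTable <- periodRateTable(lexis)
  fit <- estimableDecomposition(lexis, ...)
  files <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    files <- writeApcFit(fit, outDir)
    rt <- file.path(outDir, "rates_table.csv")
    write.csv(rateTable, rt, row.names = FALSE)
    lx <- file.path(outDir, "lexis_long.csv")
    write.csv(lexisToLong(lexis), lx, row.names = FALSE)
    au <- file.path(outDir, "correction_audit.csv")
    write.csv(attr(corrected, "audit"), au, row.names = FALSE)
    files <- c(files, rt, lx, au)
  }
  list(records = records, corrected = corrected, lexis = lexis,
       rateTable = rateTable, fit = fit, files = files)
}

#' Read death records / population denominators from CSV
#' @param path CSV with the documented columns.
#' @export
readDeathRecords <- function(path) {
  validateDeathRecords(read.csv(path, stringsAsFactors = FALSE),
                       ageStarts = NULL, periodStarts = NULL)
}

#' @rdname readDeathRecords
#' @export
readPopulation <- function(path) {
  p <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("region", "year", "age_group", "person_years")
  miss <- setdiff(need, names(p))
  if (length(miss)) stop("population lacks columns: ",
                         paste(miss, collapse = ", "))
  if (any(p$person_years < 0)) stop("person-years must be non-negative")
  p
}
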