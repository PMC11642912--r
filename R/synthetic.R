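## Synthetic vital-registration data with a known APC surface.
## Emulates annual death-record tables and population denominators in the
## shape of a national mortality information system, then degrades them
## (intent misclassification, registration under-coverage) so the whole
## correction -> rates -> APC pipeline can be scored against ground truth.

## representative true-cause suicide codes emitted by the generator,
## by mechanism and ICD revision (revision 9 before 1996, 10 after —
## the transition year of the emulated registry)
suicideCodeFor <- function(mechanism, revision) {
  tab <- list(HSS = c("9" = "E953", "10" = "X70"),
              AUT = c("9" = "E950", "10" = "X60"),
              FA  = c("9" = "E955", "10" = "X72"))
  tab[[mechanism]][as.character(revision)]
}

icdRevisionOfYear <- function(year) ifelse(year < 1996, 9L, 10L)

#' Build a synthetic APC scenario
#'
#' Defaults mirror the emulated study design: a 15 x 8 Lexis grid (ages
#' 10-14 ... 80+, periods 1980-1984 ... 2015-2019, hence 22 cohorts), an
#' age curve rising from adolescence to a mid-life plateau around 1 death
#' per 100,000 person-years, an annual drift of log(1.02), mild zero-slope
#' period and cohort curvatures, one million female person-years per
#' (year, age group) cell, 15% of suicides mis-certified as undetermined
#' intent, 5% as accident and 2% as assault of the same mechanism, and
#' registration coverage rising from 0.80 in the 1980s to 0.95 in the
#' 2010s.
#'
#' @param region,mechanism identifiers carried into the records.
#' @param ageStarts,periodStarts grid definition.
#' @param ageCurve log baseline rates per person-year, length I.
#' @param annualDrift log rate ratio per calendar year.
#' @param periodCurvature,cohortCurvature raw curvature shapes; they are
#'   detrended (weighted mean and slope removed) on construction so the
#'   stored vectors satisfy the zero-slope invariant exactly.
#' @param populationBase person-years per (year, age group) cell.
#' @param misclassFractions named fractions for undetermined / accident /
#'   assault mis-certification.
#' @param coverage data.frame (region, decade, coverage).
#' @param seed integer seed.
#' @return a \linkS4class{SyntheticScenario}.
#' @export
syntheticScenario <- function(region = "R1", mechanism = "HSS",
                              ageStarts = seq(10, 80, by = 5),
                              periodStarts = seq(1980, 2015, by = 5),
                              ageCurve = NULL,
                              annualDrift = log(1.02),
                              periodCurvature = NULL,
                              cohortCurvature = NULL,
                              populationBase = 1e6,
                              misclassFractions = c(undetermined = 0.15,
                                                    accident = 0.05,
                                                    assault = 0.02),
                              coverage = NULL, seed = 20190101L) {
  I <- length(ageStarts); J <- length(periodStarts); K <- I + J - 1
  if (is.null(ageCurve)) {
    ## log rates per person-year: ~0.4/100k at 10-14 rising to ~1.4/100k
    ## mid-life, easing off at the oldest ages
    mid <- (ageStarts + 2) / 10
    ageCurve <- log(1e-5) + log(0.4 + 1.0 * exp(-((mid - 5.5)^2) / 8))
  }
  if (is.null(periodCurvature))
    periodCurvature <- 0.05 * sin(seq_len(J) * pi / 4)
  if (is.null(cohortCurvature))
    cohortCurvature <- 0.08 * cos(seq_len(K) * pi / 6)
  detrend <- function(x) as.vector(
    detrendOperator(seq_along(x), rep(1, length(x))) %*% x)
  if (is.null(coverage)) {
    dec <- sort(unique(decadeOfYear(seq(min(periodStarts),
                                        max(periodStarts) + 4))))
    cv <- seq(0.80, 0.95, length.out = length(dec))
    coverage <- data.frame(region = region, decade = dec, coverage = cv)
  }
  methods::new("SyntheticScenario",
    region = region, mechanism = mechanism,
    ageStarts = as.numeric(ageStarts), periodStarts = as.numeric(periodStarts),
    ageCurve = as.numeric(ageCurve), annualDrift = annualDrift,
    periodCurvature = detrend(periodCurvature),
    cohortCurvature = detrend(cohortCurvature),
    populationBase = populationBase,
    misclassFractions = misclassFractions[c("undetermined", "accident",
                                            "assault")],
    coverage = coverage, seed = as.integer(seed))
}

#' @exportMethod show
setMethod("show", "SyntheticScenario", function(object) {
  I <- length(object@ageStarts); J <- length(object@periodStarts)
  cat("SyntheticScenario:", object@region, "/", object@mechanism, "—",
      I, "ages x", J, "periods (", I + J - 1, "cohorts )\n")
  cat("  annual drift RR:", round(exp(object@annualDrift), 4),
      " misclass:", paste(names(object@misclassFractions),
                          object@misclassFractions, collapse = ", "), "\n")
  cat("  coverage:", paste(object@coverage$decade,
                           round(object@coverage$coverage, 2),
                           collapse = ", "), "\n")
})

## true log rate per person-year for each (age i, period j) Lexis cell;
## the cell's rate applies uniformly to its single-year components
scenarioLogRate <- function(scenario) {
  I <- length(scenario@ageStarts); J <- length(scenario@periodStarts)
  midYears <- scenario@periodStarts + 2
  anchor <- mean(midYears)
  k <- outer(seq_len(I), seq_len(J), function(i, j) j - i + I)
  eta <- outer(scenario@ageCurve, scenario@annualDrift * (midYears - anchor),
               `+`) +
    matrix(scenario@periodCurvature[rep(seq_len(J), each = I)], I, J) +
    matrix(scenario@cohortCurvature[k], I, J)
  if (any(!is.finite(exp(eta))))
    stop("non-finite rate: exp overflows for some cell; check the scenario")
  eta
}

#' Simulate death records and population denominators from a scenario
#'
#' For each Lexis cell the true death count is Poisson with mean
#' person-years x exp(mu + alpha_i + beta_j + gamma_k); counts are drawn
#' per single calendar year (the cell's log rate applies uniformly within
#' the cell) and emitted as annual records carrying the true-cause suicide
#' code of the scenario's mechanism.  Deterministic given the scenario
#' seed.
#'
#' @param scenario a \linkS4class{SyntheticScenario}.
#' @return list with \code{records} (region, year, age_group,
#'   icd_revision, cause_code, deaths) and \code{population} (region,
#'   year, age_group, person_years).
#' @export
simulateScenario <- function(scenario) {
  methods::validObject(scenario)
  if (any(scenario@populationBase < 0)) stop("negative person-years")
  I <- length(scenario@ageStarts); J <- length(scenario@periodStarts)
  eta <- scenarioLogRate(scenario)
  years <- seq(min(scenario@periodStarts), max(scenario@periodStarts) + 4)
  ageLabs <- ageGroupLabels(scenario@ageStarts)
  Nbase <- rep_len(scenario@populationBase, I)
  grid <- expand.grid(ageIdx = seq_len(I), year = years,
                      KEEP.OUT.ATTRS = FALSE)
  grid$periodIdx <- findInterval(grid$year, scenario@periodStarts)
  lam <- Nbase[grid$ageIdx] * exp(eta[cbind(grid$ageIdx, grid$periodIdx)])
  set.seed(scenario@seed)
  d <- rpois(nrow(grid), lam)
  rev <- icdRevisionOfYear(grid$year)
  records <- data.frame(
    region = scenario@region,
    year = grid$year,
    age_group = ageLabs[grid$ageIdx],
    icd_revision = rev,
    cause_code = vapply(rev, function(r)
      suicideCodeFor(scenario@mechanism, r), character(1)),
    deaths = as.numeric(d),
    stringsAsFactors = FALSE)
  population <- data.frame(
    region = scenario@region,
    year = grid$year,
    age_group = ageLabs[grid$ageIdx],
    person_years = Nbase[grid$ageIdx],
    stringsAsFactors = FALSE)
  list(records = records, population = population)
}

#' Degrade clean suicide records: misclassification then under-coverage
#'
#' Each suicide death is independently re-certified as the undetermined /
#' accident / assault code of the same mechanism with the scenario's
#' fractions (multinomial split per record row), then retained with
#' probability equal to the registration coverage of its (region, decade).
#' This is the exact inverse of the correction pipeline and deterministic
#' given the scenario seed.
#'
#' @param records clean suicide-coded records from
#'   \code{\link{simulateScenario}}.
#' @param scenario the generating \linkS4class{SyntheticScenario}.
#' @param map cause map used to pick target codes.
#' @return degraded death-record data.frame.
#' @export
degradeRecords <- function(records, scenario, map = causeMap()) {
  f <- scenario@misclassFractions
  if (any(f < 0) || any(f >= 1) || sum(f) >= 1)
    stop("misclassification fractions must lie in [0,1) and sum to < 1")
  cls <- mapCause(records$cause_code, records$icd_revision, map)
  if (!all(cls$intent == "suicide", na.rm = TRUE) || anyNA(cls$intent))
    stop("degradeRecords expects suicide-coded records only")
  ## target code per (mechanism, intent, revision): first code of the range
  targetCode <- function(mech, intent, rev) {
    r <- map[!is.na(map$mechanism) & map$mechanism == mech &
             map$intent == intent & map$icd_revision == rev, ]
    r$code_start[1]
  }
  probs <- c(suicide = 1 - sum(f), f)
  set.seed(scenario@seed + 1L)
  splits <- t(vapply(records$deaths,
                     function(n) as.numeric(rmultinom(1, n, probs)),
                     numeric(4)))
  colnames(splits) <- names(probs)
  pieces <- lapply(names(probs), function(int) {
    out <- records
    out$deaths <- splits[, int]
    if (int != "suicide")
      out$cause_code <- vapply(seq_len(nrow(out)), function(r)
        targetCode(cls$mechanism[r], int, out$icd_revision[r]), character(1))
    out[out$deaths > 0, , drop = FALSE]
  })
  deg <- do.call(rbind, pieces)
  ## binomial thinning by registration coverage
  key <- paste(deg$region, decadeOfYear(deg$year))
  fkey <- paste(scenario@coverage$region, scenario@coverage$decade)
  cov <- scenario@coverage$coverage[match(key, fkey)]
  if (anyNA(cov))
    stop("no coverage for stratum: ", paste(unique(key[is.na(cov)]),
                                            collapse = "; "))
  deg$deaths <- rbinom(nrow(deg), size = as.integer(deg$deaths), prob = cov)
  rownames(deg) <- NULL
  deg[order(deg$year, deg$age_group, deg$cause_code), ]
}

#' Read a scenario configuration from YAML
#'
#' Keys mirror the \code{\link{syntheticScenario}} arguments; coverage is
#' a list of (region, decade, coverage) entries.
#' @param path YAML file.
#' @export
readScenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$coverage))
    cfg$coverage <- do.call(rbind, lapply(cfg$coverage, as.data.frame))
  if (!is.null(cfg$misclassFractions))
    cfg$misclassFractions <- unlist(cfg$misclassFractions)
  do.call(syntheticScenario, cfg)
}
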