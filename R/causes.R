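## Cause-of-death mapping (mechanism x intent <-> ICD code ranges) and the
## two-stage record correction: proportional redistribution of garbage-coded
## deaths, then inflation for registration under-coverage.

#' Load the packaged mechanism x intent cause map
#'
#' Inclusive ICD-9 (E-code) and ICD-10 code ranges for suicide, accident,
#' assault, undetermined intent and sequelae of self-inflicted injury, for
#' the three mechanisms: hanging/strangulation/suffocation (HSS),
#' autointoxication (AUT) and firearm (FA).  Suicide ranges for HSS
#' (E953 / X70) and AUT (E950-E952 / X60-X69) are the natural completion of
#' the published firearm row and are flagged \code{source = "inferred"}.
#' Sequelae rows carry \code{mechanism = NA}: the code does not identify a
#' mechanism.
#'
#' @param path CSV override; defaults to the packaged table.
#' @return data.frame with columns mechanism, intent, icd_revision,
#'   code_start, code_end, source.
#' @export
causeMap <- function(path = system.file("extdata", "cause_map_v1.csv",
                                        package = "lexisapc")) {
  m <- read.csv(path, stringsAsFactors = FALSE,
                colClasses = c(mechanism = "character"))
  m$mechanism[m$mechanism %in% c("NA", "")] <- NA_character_
  stopifnot(all(c("mechanism", "intent", "icd_revision",
                  "code_start", "code_end") %in% names(m)))
  ## ranges within one (revision, mechanism, intent) must not overlap
  key <- paste(m$icd_revision, m$mechanism, m$intent)
  for (k in unique(key)) {
    s <- m[key == k, , drop = FALSE]
    if (nrow(s) > 1) {
      iv <- t(vapply(seq_len(nrow(s)), function(r)
        c(icdNumber(s$code_start[r]), icdNumber(s$code_end[r])), numeric(2)))
      o <- order(iv[, 1])
      if (any(iv[o, 1][-1] <= iv[o, 2][-nrow(s)]))
        stop("overlapping code ranges in cause map for ", k)
    }
  }
  m
}

## parse "X72" / "E955" -> list(letter, number); malformed codes rejected
icdParse <- function(code) {
  ok <- grepl("^[A-Z][0-9]{1,3}$", code)
  if (any(!ok))
    stop("malformed ICD code(s): ", paste(unique(code[!ok]), collapse = ", "))
  list(letter = substr(code, 1, 1),
       number = as.numeric(sub("^[A-Z]", "", code)))
}

## order-preserving scalarization: letter * 1000 + number
icdNumber <- function(code) {
  p <- icdParse(code)
  (match(p$letter, LETTERS)) * 1000 + p$number
}

#' Classify ICD codes into (mechanism, intent)
#'
#' @param code character vector of ICD-9 E-codes or ICD-10 external-cause
#'   codes (e.g. "E955", "X72", "Y20").
#' @param icdRevision 9 or 10 (scalar or vector).
#' @param map cause map, see \code{\link{causeMap}}.
#' @return data.frame (code, mechanism, intent, in_scope); codes outside
#'   every range get \code{in_scope = FALSE} and NA mechanism/intent.
#' @examples
#' mapCause(c("X72", "Y20", "A00"), 10)
#' @export
mapCause <- function(code, icdRevision, map = causeMap()) {
  n <- max(length(code), length(icdRevision))
  code <- rep_len(code, n); icdRevision <- rep_len(icdRevision, n)
  v <- icdNumber(code)
  lo <- icdNumber(map$code_start); hi <- icdNumber(map$code_end)
  out <- data.frame(code = code, mechanism = NA_character_,
                    intent = NA_character_, in_scope = FALSE,
                    stringsAsFactors = FALSE)
  for (r in seq_len(nrow(map))) {
    hit <- icdRevision == map$icd_revision[r] & v >= lo[r] & v <= hi[r]
    if (any(hit)) {
      out$mechanism[hit] <- map$mechanism[r]
      out$intent[hit] <- map$intent[r]
      out$in_scope[hit] <- TRUE
    }
  }
  out
}

#' Validate a death-record table
#'
#' Rows of (region, year, age_group, icd_revision, cause_code, deaths);
#' deaths are real-valued because redistribution produces fractional
#' counts.
#' @param records data.frame
#' @param ageStarts,periodStarts grid the records must fall on; NULL skips
#'   the range check.
#' @return the records, invisibly, after validation.
#' @export
validateDeathRecords <- function(records, ageStarts = seq(10, 80, by = 5),
                                 periodStarts = seq(1980, 2015, by = 5)) {
  need <- c("region", "year", "age_group", "icd_revision", "cause_code",
            "deaths")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "))
  if (any(records$deaths < 0)) stop("deaths must be non-negative")
  if (!is.null(ageStarts)) {
    badAge <- setdiff(unique(records$age_group), ageGroupLabels(ageStarts))
    if (length(badAge))
      stop("age groups outside the grid: ", paste(badAge, collapse = ", "))
  }
  if (!is.null(periodStarts)) {
    yr <- range(periodStarts) + c(0, 4)
    badYr <- unique(records$year[records$year < yr[1] | records$year > yr[2]])
    if (length(badYr))
      stop("years outside the grid: ", paste(sort(badYr), collapse = ", "))
  }
  invisible(records)
}

#' Redistribute garbage-coded deaths to determined intents
#'
#' Within each stratum (default region x period x age group x mechanism),
#' deaths whose intent is undetermined or sequelae — plus, optionally, a
#' fraction of accident and assault deaths — are reallocated across the
#' stratum's determined-intent deaths proportionally to their observed
#' distribution.  Suicide counts never decrease and each stratum's total
#' is conserved exactly.  Sequelae deaths carry no mechanism and are
#' redistributed within (region, period, age group) across all mechanisms.
#'
#' When a stratum holds garbage deaths but no determined deaths, strata are
#' progressively coarsened (drop age group, then period); if no determined
#' distribution exists even at (region, mechanism) level the garbage is
#' left in place unless \code{allowAllToSuicide = TRUE}, in which case it
#' is assigned to suicide of the same mechanism.  Every fallback is
#' recorded in the audit attached as \code{attr(result, "audit")}.
#'
#' @param records death-record data.frame (see
#'   \code{\link{validateDeathRecords}}).
#' @param map cause map.
#' @param strata stratification keys; \code{"period"} refers to the 5-year
#'   bin of \code{year}.
#' @param garbageIntents intents treated as garbage.
#' @param accidentFraction,assaultFraction optional fractions of accident /
#'   assault deaths also fed into the redistribution pool (0 by default;
#'   both behaviours are defensible and the choice is exposed).
#' @param allowAllToSuicide final-fallback switch, off by default.
#' @param periodStarts grid periods used to bin years.
#' @return corrected death-record data.frame (same rows, adjusted deaths),
#'   with an \code{audit} attribute listing per-stratum before/after.
#' @export
redistributeGarbage <- function(records, map = causeMap(),
                                strata = c("region", "period", "age_group",
                                           "mechanism"),
                                garbageIntents = c("undetermined", "sequelae"),
                                accidentFraction = 0, assaultFraction = 0,
                                allowAllToSuicide = FALSE,
                                periodStarts = seq(1980, 2015, by = 5)) {
  stopifnot(accidentFraction >= 0, accidentFraction < 1,
            assaultFraction >= 0, assaultFraction < 1)
  validateDeathRecords(records, ageStarts = NULL, periodStarts = NULL)
  cls <- mapCause(records$cause_code, records$icd_revision, map)
  rec <- records
  rec$mechanism <- cls$mechanism
  rec$intent <- cls$intent
  rec$period <- periodOfYear(rec$year, periodStarts)
  inScope <- cls$in_scope

  determined <- c("suicide", "accident", "assault")
  ## pool: garbage intents wholly; accident/assault partially if configured
  pool <- numeric(nrow(rec))
  g <- inScope & rec$intent %in% garbageIntents
  pool[g] <- rec$deaths[g]
  if (accidentFraction > 0) {
    a <- inScope & rec$intent == "accident"
    pool[a] <- pool[a] + accidentFraction * rec$deaths[a]
  }
  if (assaultFraction > 0) {
    a <- inScope & rec$intent == "assault"
    pool[a] <- pool[a] + assaultFraction * rec$deaths[a]
  }
  ## receiving weight: determined-intent deaths net of any pooled fraction
  recv <- numeric(nrow(rec))
  d <- inScope & rec$intent %in% determined
  recv[d] <- rec$deaths[d] - pool[d]

  keyFor <- function(keys) {
    if (!length(keys)) return(rep("(all)", nrow(rec)))
    do.call(paste, c(rec[, keys, drop = FALSE], sep = "\r"))
  }

  out <- rec$deaths - pool        # garbage removed from its source rows
  audit <- list()
  ## coarsening ladder per the fallback rule
  ladders <- list(strata,
                  setdiff(strata, "age_group"),
                  setdiff(strata, c("age_group", "period")))
  pending <- pool                 # garbage not yet placed, per source row

  ## distribute pending garbage of src rows pro-rata over recv within key
  allocate <- function(src, key, label) {
    recvTot <- rowsum(recv, key)
    tot <- recvTot[match(key[src], rownames(recvTot)), 1]
    ok <- !is.na(tot) & tot > 0
    src <- src[ok]
    if (!length(src)) return(invisible())
    give <- rowsum(pending[src], key[src])
    gv <- give[match(key, rownames(give)), 1]
    share <- recv / recvTot[match(key, rownames(recvTot)), 1]
    add <- ifelse(is.na(gv) | recv == 0, 0, gv * share)
    out <<- out + add
    if (nzchar(label))
      audit[[length(audit) + 1]] <<- data.frame(
        row = src, action = label, deaths = pending[src])
    pending[src] <<- 0
    invisible()
  }

  for (lvl in seq_along(ladders)) {
    if (!any(pending > 0)) break
    keys <- ladders[[lvl]]
    allocate(which(pending > 0 & !is.na(rec$mechanism)), keyFor(keys),
             if (lvl > 1) sprintf("coarsened to level %d", lvl) else "")
    allocate(which(pending > 0 & is.na(rec$mechanism)),
             keyFor(setdiff(keys, "mechanism")),
             sprintf("mechanism-less garbage pooled over mechanisms, level %d",
                     lvl))
  }
  ## final fallback for anything still pending
  left <- which(pending > 0)
  for (pr in left) {
    amt <- pending[pr]
    placed <- FALSE
    if (allowAllToSuicide && !is.na(rec$mechanism[pr])) {
      cand <- which(rec$intent == "suicide" & !is.na(rec$mechanism) &
                    rec$mechanism == rec$mechanism[pr] &
                    rec$region == rec$region[pr])
      if (length(cand)) {
        out[cand[1]] <- out[cand[1]] + amt
        audit[[length(audit) + 1]] <- data.frame(
          row = pr, action = "all-to-suicide fallback", deaths = amt)
        placed <- TRUE
      }
    }
    if (!placed) {
      out[pr] <- out[pr] + amt   # conservative: left unredistributed
      audit[[length(audit) + 1]] <- data.frame(
        row = pr, action = "left in place (no determined deaths)",
        deaths = amt)
      message("redistributeGarbage: stratum of row ", pr,
              " has no determined deaths; garbage left in place")
    }
  }
  pending[left] <- 0
  res <- records
  res$deaths <- out
  attr(res, "audit") <- if (length(audit)) do.call(rbind, audit) else
    data.frame(row = integer(), action = character(), deaths = numeric())
  res
}

#' Validate coverage factors
#' @param factors data.frame (region, decade, coverage).
#' @export
validateCoverage <- function(factors) {
  need <- c("region", "decade", "coverage")
  miss <- setdiff(need, names(factors))
  if (length(miss)) stop("coverage lacks columns: ",
                         paste(miss, collapse = ", "))
  bad <- factors$coverage <= 0 | factors$coverage > 1
  if (any(bad)) stop("coverage must lie in (0, 1]; offending rows: ",
                     paste(which(bad), collapse = ", "))
  invisible(factors)
}

#' Inflate death counts for registration under-coverage
#'
#' deaths' = deaths / coverage(region, decade).  Applied after garbage
#' redistribution, mirroring the correction order: misclassification first,
#' then under-reporting.
#'
#' @param records death-record data.frame.
#' @param factors data.frame (region, decade, coverage in (0, 1]).
#' @return records with inflated deaths.
#' @examples
#' rec <- data.frame(region = "R1", year = 1985, age_group = "20 to 24",
#'                   icd_revision = 9, cause_code = "E953", deaths = 8)
#' cov <- data.frame(region = "R1", decade = "1980s", coverage = 0.8)
#' applyCoverage(rec, cov)$deaths  # 10
#' @export
applyCoverage <- function(records, factors) {
  validateCoverage(factors)
  key <- paste(records$region, decadeOfYear(records$year))
  fkey <- paste(factors$region, factors$decade)
  idx <- match(key, fkey)
  if (anyNA(idx)) {
    missStrata <- unique(key[is.na(idx)])
    stop("no coverage factor for stratum: ",
         paste(missStrata, collapse = "; "))
  }
  records$deaths <- records$deaths / factors$coverage[idx]
  records
}
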