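## Grid vocabularies and small helpers shared across the pipeline.
## The study design is a 15 x 8 Lexis grid: 5-year age groups 10-14 ... 80+,
## quinquennia 1980-1984 ... 2015-2019, and K = I + J - 1 = 22 synthetic
## birth cohorts 1900-1904 ... 2005-2009.

#' Age-group labels for a 5-year grid
#'
#' @param ageStarts integer vector of lower bounds of the 5-year age groups;
#'   the last group is open-ended ("80 years or older" style).
#' @return character vector of labels.
#' @keywords internal
ageGroupLabels <- function(ageStarts = seq(10, 80, by = 5)) {
  n <- length(ageStarts)
  closed <- if (n > 1)
    paste(ageStarts[-n], "to", ageStarts[-n] + 4) else character(0)
  c(closed, paste(ageStarts[n], "years or older"))
}

#' Period labels for quinquennia
#' @param periodStarts integer vector of first calendar years of each period.
#' @keywords internal
periodLabels5 <- function(periodStarts = seq(1980, 2015, by = 5)) {
  paste(periodStarts, "to", periodStarts + 4)
}

#' Cohort labels along Lexis diagonals
#'
#' Cohort index k = j - i + I is constant along diagonals; label k is the
#' 5-year bin starting at \code{periodStarts[1] - ageStarts[I] + 5 (k - 1)}.
#' @keywords internal
cohortLabels5 <- function(ageStarts = seq(10, 80, by = 5),
                          periodStarts = seq(1980, 2015, by = 5)) {
  I <- length(ageStarts)
  J <- length(periodStarts)
  K <- I + J - 1
  starts <- periodStarts[1] - ageStarts[I] + 5 * (seq_len(K) - 1)
  paste(starts, "to", starts + 4)
}

#' Map a calendar year to its 5-year period label
#' @keywords internal
periodOfYear <- function(year, periodStarts = seq(1980, 2015, by = 5)) {
  starts <- periodStarts[findInterval(year, periodStarts)]
  bad <- year < periodStarts[1] | year > periodStarts[length(periodStarts)] + 4
  out <- paste(starts, "to", starts + 4)
  out[bad] <- NA_character_
  out
}

#' Map a calendar year to its decade label ("1980s")
#' @keywords internal
decadeOfYear <- function(year) {
  paste0(10 * (year %/% 10), "s")
}

## weighted least-squares slope of x against index t, and the detrending
## projector used by the estimable-function decomposition
wlsSlopeWeights <- function(t, w) {
  w <- w / sum(w)
  tb <- sum(w * t)
  w * (t - tb) / sum(w * (t - tb)^2)
}

## rows of the operator removing weighted mean and weighted linear trend:
## curv = (I - P_{1,t;w}) x
detrendOperator <- function(t, w) {
  n <- length(t)
  w <- w / sum(w)
  X <- cbind(1, t)
  ## weighted projection onto span{1, t}
  P <- X %*% solve(crossprod(X, w * X), t(X * w))
  diag(n) - P
}

`%||%` <- function(a, b) if (is.null(a)) b else a
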