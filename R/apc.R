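## Poisson age-period-cohort modelling identified through estimable
## functions.
##
## The full model  log E[D_ij] = log N_ij + mu + alpha_i + beta_j + gamma_k
## (k = j - i + I) is over-parameterized: adding a linear trend delta*i to
## age, -delta*j to period and delta*k to cohort leaves every fitted rate
## unchanged.  Only curvatures (detrended effects), the drift (sum of the
## period and cohort slopes, beta_L + gamma_L), the longitudinal age trend
## (alpha_L + beta_L) and the fitted rates are estimable.  This module
## fits the GLM by IRLS and reports exactly those functions, with
## delta-method Wald intervals on the log scale.

## long modelling frame for a LexisTable; cells with N = 0 are dropped
## with a warning (a Poisson rate is undefined there)
apcFrame <- function(lexis) {
  I <- nrow(lexis); J <- ncol(lexis)
  k <- cohortIndex(lexis)
  df <- data.frame(
    D = as.vector(deaths(lexis)),
    N = as.vector(personYears(lexis)),
    i = rep(seq_len(I), J),
    j = rep(seq_len(J), each = I),
    k = as.vector(k))
  if (any(df$N <= 0)) {
    warning(sum(df$N <= 0), " cell(s) with zero person-years excluded")
    df <- df[df$N > 0, , drop = FALSE]
  }
  df$A <- factor(df$i, levels = seq_len(I))
  df$P <- factor(df$j, levels = seq_len(J))
  df$C <- factor(df$k, levels = seq_len(I + J - 1))
  df
}

#' Fit a Poisson model on a Lexis grid
#'
#' Maximum-likelihood Poisson regression of death counts with log
#' person-years offset, fitted by iteratively reweighted least squares
#' (\code{stats::glm}).  Terms select the model space: \code{"age"} and
#' factor \code{"period"} / \code{"cohort"} effects, or \code{"drift"}
#' (a single linear effect of time, the slope being identical whether
#' carried by the period or the cohort index once age is in the model).
#'
#' @param lexis a \linkS4class{LexisTable}.
#' @param terms character subset of \code{c("age", "drift", "period",
#'   "cohort")}, or \code{"saturated"} for one parameter per cell.
#' @param driftIndex \code{"cohort"} or \code{"period"}: which index
#'   carries the linear drift term (same model space, same deviance).
#' @return the fitted \code{glm} object.
#' @export
fitApcGlm <- function(lexis, terms = c("age", "period", "cohort"),
                      driftIndex = c("cohort", "period")) {
  driftIndex <- match.arg(driftIndex)
  df <- apcFrame(lexis)
  if (identical(terms, "saturated")) {
    df$cell <- factor(seq_len(nrow(df)))
    rhs <- "cell"
  } else {
    stopifnot(all(terms %in% c("age", "drift", "period", "cohort")))
    parts <- character()
    if ("age" %in% terms) parts <- c(parts, "A")
    if ("period" %in% terms) parts <- c(parts, "P")
    if ("cohort" %in% terms) parts <- c(parts, "C")
    if ("drift" %in% terms && !all(c("period", "cohort") %in% terms))
      parts <- c(parts, if (driftIndex == "cohort") "k" else "j")
    if (!length(parts)) parts <- "1"
    rhs <- paste(parts, collapse = " + ")
  }
  ## corrected counts are fractional by design; the Poisson quasi-score
  ## is unchanged, so the non-integer warning carries no information here
  fit <- withCallingHandlers(
    glm(stats::as.formula(paste("D ~", rhs, "+ offset(log(N))")),
        family = poisson(), data = df,
        control = stats::glm.control(maxit = 100)),
    warning = function(w) {
      if (grepl("non-integer", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (!fit$converged)
    stop("IRLS did not converge after ", fit$control$maxit, " iterations")
  fit
}

#' Poisson deviance of observed vs fitted counts
#'
#' 2 * sum(D log(D / Dhat) - (D - Dhat)) with 0 log 0 = 0.
#' @param D observed counts.
#' @param Dhat fitted means.
#' @export
poissonDeviance <- function(D, Dhat) {
  t1 <- ifelse(D > 0, D * log(D / Dhat), 0)
  2 * sum(t1 - (D - Dhat))
}

#' Nested deviance table for the six APC submodels
#'
#' Fits, in order: (1) age; (2) age-drift (cohort-indexed); (3)
#' age-cohort; (4) age-period-cohort; (5) age-period; (6) age-drift
#' (period-indexed).  Rows (2) and (6) span the same model space and have
#' identical deviance.  Each row's likelihood-ratio p-value compares the
#' row's model with the preceding row's (the nesting runs
#' 1 < 2 < 3 < 4 > 5 > 6, so each successive pair is nested one way or
#' the other).
#'
#' AIC is deviance-based (residual deviance + 2 x parameters), which
#' ranks models identically to the likelihood AIC and stays defined for
#' the fractional counts produced by record correction.
#'
#' @param lexis a \linkS4class{LexisTable}.
#' @return data.frame (model, resDev, resDf, AIC, pLRT).
#' @export
nestedDevianceTable <- function(lexis) {
  specs <- list(
    list(name = "Age",               terms = "age",                    idx = "cohort"),
    list(name = "Age-drift",         terms = c("age", "drift"),        idx = "cohort"),
    list(name = "Age-Cohort",        terms = c("age", "cohort"),       idx = "cohort"),
    list(name = "Age-Period-Cohort", terms = c("age", "period", "cohort"), idx = "cohort"),
    list(name = "Age-Period",        terms = c("age", "period"),       idx = "period"),
    list(name = "Age-drift",         terms = c("age", "drift"),        idx = "period"))
  fits <- lapply(specs, function(s) fitApcGlm(lexis, s$terms, s$idx))
  dev <- vapply(fits, stats::deviance, numeric(1))
  dfr <- vapply(fits, stats::df.residual, numeric(1))
  ## deviance-based AIC (deviance + 2 * parameters): identical ranking to
  ## the likelihood AIC, and well-defined for fractional corrected counts
  npar <- vapply(fits, function(f) sum(!is.na(coef(f))), numeric(1))
  aic <- dev + 2 * npar
  p <- rep(NA_real_, 6)
  for (r in 2:6) {
    dDev <- abs(dev[r] - dev[r - 1]); dDf <- abs(dfr[r] - dfr[r - 1])
    p[r] <- if (dDf == 0) NA_real_ else pchisq(dDev, dDf, lower.tail = FALSE)
  }
  data.frame(model = vapply(specs, `[[`, character(1), "name"),
             resDev = dev, resDf = dfr, AIC = aic, pLRT = p,
             stringsAsFactors = FALSE)
}

## full coefficient vector / covariance with aliased coefficients fixed
## at zero (a valid representative; estimable functions are invariant)
coefFull <- function(fit) {
  b <- coef(fit)
  V0 <- vcov(fit)
  keep <- !is.na(b)
  V <- matrix(0, length(b), length(b), dimnames = list(names(b), names(b)))
  V[keep, keep] <- V0[names(b)[keep], names(b)[keep]]
  b[!keep] <- 0
  list(beta = b, V = V)
}

## indicator matrix picking factor-level coefficients: rows = levels,
## columns = model coefficients (baseline level row is all zero)
levelRows <- function(fit, prefix, nLevels) {
  nms <- names(coef(fit))
  M <- matrix(0, nLevels, length(nms), dimnames = list(NULL, nms))
  for (l in seq_len(nLevels)) {
    cn <- paste0(prefix, l)
    if (cn %in% nms) M[l, cn] <- 1
  }
  M
}

#' Estimable-function decomposition of the full APC fit
#'
#' Produces the identifiable summaries of the age-period-cohort surface:
#' \itemize{
#' \item \strong{drift}: the total linear time trend (sum of the period
#'   and cohort slopes under the chosen detrending weights), reported as
#'   annual rate ratio with a delta-method 95% CI, and classified as
#'   Upward / Downward / Stationary;
#' \item \strong{period and cohort rate ratios}: effects projected onto
#'   the orthogonal complement of \{constant, linear-in-index\}
#'   (curvatures), re-anchored so the reference category is exactly 1
#'   with a degenerate CI; under \code{driftTo = "cohort"} (default) the
#'   cohort curve carries the drift and the period curve is slope-free,
#'   and vice versa;
#' \item \strong{age curve}: the longitudinal age trend (age slope plus
#'   period slope folded in), as fitted rates per 100,000.
#' }
#' The three components sum to the full-model linear predictor cell by
#' cell, so fitted rates are invariant to every choice made here.
#'
#' @param lexis a \linkS4class{LexisTable}.
#' @param refPeriod,refCohort reference category labels.
#' @param driftTo "cohort" or "period": which curve carries the drift.
#' @param detrendWeights "uniform" or "personYears" inner product for the
#'   slope/curvature split.
#' @param level confidence level, default 0.95.
#' @return an \linkS4class{APCFit}.
#' @export
estimableDecomposition <- function(lexis,
                                   refPeriod = "2000 to 2004",
                                   refCohort = "1950 to 1954",
                                   driftTo = c("cohort", "period"),
                                   detrendWeights = c("uniform",
                                                      "personYears"),
                                   level = 0.95) {
  driftTo <- match.arg(driftTo)
  detrendWeights <- match.arg(detrendWeights)
  I <- nrow(lexis); J <- ncol(lexis); K <- I + J - 1
  perLabs <- periods(lexis); cohLabs <- cohortLabels(lexis)
  jr <- match(refPeriod, perLabs)
  kr <- match(refCohort, cohLabs)
  if (is.na(jr)) stop("reference period '", refPeriod, "' not on the grid")
  if (is.na(kr)) stop("reference cohort '", refCohort, "' not on the grid")

  fit <- fitApcGlm(lexis, c("age", "period", "cohort"))
  cf <- coefFull(fit)
  nms <- names(cf$beta)

  Ea <- levelRows(fit, "A", I)
  Ep <- levelRows(fit, "P", J)
  Ec <- levelRows(fit, "C", K)
  one <- function(col) { v <- numeric(length(nms)); names(v) <- nms
                         v[col] <- 1; v }

  wts <- function(n, marg) switch(detrendWeights,
    uniform = rep(1, n), personYears = marg)
  wp <- wts(J, colSums(personYears(lexis)))
  kIdx <- cohortIndex(lexis)
  margC <- vapply(seq_len(K), function(k)
    sum(personYears(lexis)[kIdx == k]), numeric(1))
  wc <- wts(K, margC)

  tP <- seq_len(J); tC <- seq_len(K)
  slopeP <- wlsSlopeWeights(tP, wp) %*% Ep      # 1 x p
  slopeC <- wlsSlopeWeights(tC, wc) %*% Ec
  driftRow <- (slopeP + slopeC) / 5             # per calendar year
  curvP <- detrendOperator(tP, wp) %*% Ep       # J x p
  curvC <- detrendOperator(tC, wc) %*% Ec       # K x p

  ## reported log-RR rows (anchored at the reference category)
  if (driftTo == "cohort") {
    rowsP <- curvP
    rowsC <- curvC + tC %o% as.vector(5 * driftRow)
  } else {
    rowsP <- curvP + tP %o% as.vector(5 * driftRow)
    rowsC <- curvC
  }
  rowsP <- sweep(rowsP, 2, rowsP[jr, ])
  rowsC <- sweep(rowsC, 2, rowsC[kr, ])

  ## age rows: eta_{i, j*} - P_{j*} - C_{k(i, j*)} for j* = reference
  ## period (any column gives the same rows; the decomposition is exact)
  X <- stats::model.matrix(fit)
  frame <- fit$model
  rowsA <- matrix(0, I, length(nms), dimnames = list(NULL, nms))
  for (i in seq_len(I)) {
    r <- which(frame$A == i & frame$P == jr)[1]
    if (is.na(r)) r <- which(frame$A == i)[1]  # N=0 cell at ref period
    jstar <- as.integer(as.character(frame$P[r]))
    kstar <- as.integer(as.character(frame$C[r]))
    rowsA[i, colnames(X)] <- X[r, ]
    rowsA[i, ] <- rowsA[i, ] - rowsP[jstar, ] - rowsC[kstar, ]
  }

  z <- qnorm(1 - (1 - level) / 2)
  summarize <- function(Mrows, labels) {
    est <- as.vector(Mrows %*% cf$beta)
    se <- sqrt(pmax(0, rowSums((Mrows %*% cf$V) * Mrows)))
    data.frame(label = labels, logEst = est, se = se,
               rr = exp(est), lo = exp(est - z * se),
               hi = exp(est + z * se), stringsAsFactors = FALSE)
  }
  sp <- summarize(rowsP, perLabs)
  sc <- summarize(rowsC, cohLabs)
  ## exact anchoring of the reference rows
  sp[jr, c("logEst", "se")] <- c(0, 0); sp[jr, c("rr", "lo", "hi")] <- 1
  sc[kr, c("logEst", "se")] <- c(0, 0); sc[kr, c("rr", "lo", "hi")] <- 1
  names(sp)[1] <- "period"; names(sc)[1] <- "cohort"

  sa <- summarize(rowsA, ageGroups(lexis))
  ageCurve <- data.frame(age_group = sa$label,
                         rate = 1e5 * sa$rr, lo = 1e5 * sa$lo,
                         hi = 1e5 * sa$hi, stringsAsFactors = FALSE)

  dEst <- as.vector(driftRow %*% cf$beta)
  dSe <- sqrt(max(0, as.vector(driftRow %*% cf$V %*% t(driftRow))))
  driftRR <- exp(dEst); driftCI <- exp(dEst + c(-1, 1) * z * dSe)

  ## age-drift-model estimate for comparison
  fitAD <- fitApcGlm(lexis, c("age", "drift"), driftIndex = "cohort")
  bAD <- unname(coef(fitAD)["k"]) / 5
  seAD <- sqrt(vcov(fitAD)["k", "k"]) / 5
  drift <- list(
    annualRR = driftRR, lo = driftCI[1], hi = driftCI[2],
    logAnnual = dEst, se = dSe,
    trend = classifyTrend(driftRR, driftCI[1], driftCI[2]),
    ageDriftModel = list(annualRR = exp(bAD),
                         lo = exp(bAD - z * seAD),
                         hi = exp(bAD + z * seAD)))

  opts <- list(refPeriod = refPeriod, refCohort = refCohort,
               driftTo = driftTo, detrendWeights = detrendWeights,
               level = level,
               dispersion = stats::deviance(fit) / stats::df.residual(fit))

  methods::new("APCFit",
    devianceTable = nestedDevianceTable(lexis),
    ageCurve = ageCurve, drift = drift,
    periodRR = sp[, c("period", "rr", "lo", "hi")],
    cohortRR = sc[, c("cohort", "rr", "lo", "hi")],
    options = opts, glmFit = fit)
}

#' Classify an annual drift trend from its confidence interval
#'
#' Upward if the CI lower bound exceeds 1, Downward if the upper bound is
#' below 1, Stationary otherwise.
#'
#' @param annualRR annual rate ratio point estimate.
#' @param lo,hi confidence bounds, 0 < lo <= annualRR <= hi.
#' @return "Upward", "Downward" or "Stationary".
#' @examples
#' classifyTrend(1.030, 1.020, 1.040)  # Upward
#' classifyTrend(0.998, 0.996, 1.001)  # Stationary
#' @export
classifyTrend <- function(annualRR, lo, hi) {
  if (any(lo > hi)) stop("inverted confidence interval")
  if (any(lo <= 0) || any(annualRR < lo) || any(annualRR > hi))
    stop("require 0 < lo <= annualRR <= hi")
  ifelse(lo > 1, "Upward", ifelse(hi < 1, "Downward", "Stationary"))
}

## ---- APCFit accessors ----

#' @describeIn estimableDecomposition six-model deviance table
#' @param object an APCFit
#' @export
devianceTable <- function(object) object@devianceTable

#' @describeIn estimableDecomposition drift summary (annual RR, CI, trend)
#' @export
driftEstimate <- function(object) object@drift

#' @describeIn estimableDecomposition period rate ratios vs reference
#' @export
periodRR <- function(object) object@periodRR

#' @describeIn estimableDecomposition cohort rate ratios vs reference
#' @export
cohortRR <- function(object) object@cohortRR

#' @describeIn estimableDecomposition longitudinal age curve per 100,000
#' @export
ageCurve <- function(object) object@ageCurve

#' Fitted cell rates (per person-year) of an APCFit's full model
#' @param object an APCFit
#' @return data.frame (i, j, k, fittedRate)
#' @export
fittedRates <- function(object) {
  fit <- object@glmFit
  fr <- fit$model
  data.frame(i = as.integer(as.character(fr$A)),
             j = as.integer(as.character(fr$P)),
             k = as.integer(as.character(fr$C)),
             fittedRate = fit$fitted.values / exp(fit$offset))
}

#' @exportMethod show
setMethod("show", "APCFit", function(object) {
  d <- object@drift
  cat("APCFit (Poisson age-period-cohort, estimable functions)\n")
  cat(sprintf("  drift: annual RR %.3f (%.3f-%.3f) — %s\n",
              d$annualRR, d$lo, d$hi, d$trend))
  cat("  references: period", object@options$refPeriod, "| cohort",
      object@options$refCohort, "\n")
  cat("  drift carried by:", object@options$driftTo,
      "| detrending weights:", object@options$detrendWeights, "\n")
  cat("  dispersion (dev/df):", round(object@options$dispersion, 3), "\n")
  cat("  deviance table:\n")
  print(object@devianceTable, digits = 4, row.names = FALSE)
})
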