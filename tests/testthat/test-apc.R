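test_that("saturated and one-parameter Poisson fits match closed forms", {
  lx <- surfaceLexis(I = 4, J = 3, seed = 8)
  sat <- fitApcGlm(lx, "saturated")
  expect_lt(deviance(sat), 1e-8)

  ## intercept-only on a 2-cell table: MLE rate = sum(D)/sum(N)
  lx2 <- LexisTable(matrix(c(2, 4), 1, 2), matrix(c(100, 100), 1, 2),
                    ageStarts = 10, periodStarts = c(1980, 1985))
  f0 <- fitApcGlm(lx2, character(0))
  expect_equal(unname(exp(coef(f0))), 0.03, tolerance = 1e-8)
  Dhat <- c(3, 3)
  expect_equal(deviance(f0),
               2 * sum(c(2, 4) * log(c(2, 4) / Dhat)), tolerance = 1e-8)
  expect_equal(deviance(f0), poissonDeviance(c(2, 4), Dhat),
               tolerance = 1e-10)
})

test_that("an age-only simulation recovers its age coefficients", {
  sc <- quickScenario(annualDrift = 0, periodCurvature = rep(0, 8),
                      cohortCurvature = rep(0, 22),
                      populationBase = 5e6, seed = 17L)
  sim <- simulateScenario(sc)
  lx <- buildLexis(sim$records, sim$population, "HSS")
  fit <- fitApcGlm(lx, "age")
  b <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  truthContrast <- sc@ageCurve - sc@ageCurve[1]
  est <- c(0, b[paste0("A", 2:15)])
  ses <- c(0, se[paste0("A", 2:15)])
  cover <- abs(est - truthContrast) <= 3 * pmax(ses, 1e-12)
  expect_true(all(cover[-1]))
})

test_that("the six-model deviance ladder satisfies the nesting inequalities", {
  lx <- surfaceLexis(seed = 12)
  dt <- nestedDevianceTable(lx)
  expect_equal(dt$model,
               c("Age", "Age-drift", "Age-Cohort", "Age-Period-Cohort",
                 "Age-Period", "Age-drift"))
  dev <- setNames(dt$resDev, make.unique(dt$model))
  expect_gte(dev["Age"], dev["Age-drift"])
  expect_gte(dev["Age-drift"], dev["Age-Cohort"])
  expect_gte(dev["Age-Cohort"], dev["Age-Period-Cohort"])
  expect_gte(dev["Age-drift.1"], dev["Age-Period"])
  expect_gte(dev["Age-Period"], dev["Age-Period-Cohort"])
  ## the two age-drift rows span the same model space
  expect_equal(unname(dev["Age-drift"]), unname(dev["Age-drift.1"]),
               tolerance = 1e-8)
  ## residual df: APC model has IJ - (I + J + K - 3) parameters
  expect_equal(dt$resDf[4], 120 - (15 + 8 + 22 - 3))
  expect_true(all(dt$pLRT[-1] >= 0 & dt$pLRT[-1] <= 1))
})

test_that("drift LRT has power under drift and level without it", {
  ## type-I error: age-only truth, drift test should rarely reject
  rejNull <- 0; rejDrift <- 0
  nRep <- 25
  for (s in seq_len(nRep)) {
    scN <- quickScenario(annualDrift = 0, periodCurvature = rep(0, 8),
                         cohortCurvature = rep(0, 22), seed = 100L + s)
    simN <- simulateScenario(scN)
    lxN <- buildLexis(simN$records, simN$population, "HSS")
    f1 <- fitApcGlm(lxN, "age"); f2 <- fitApcGlm(lxN, c("age", "drift"))
    p <- pchisq(deviance(f1) - deviance(f2), 1, lower.tail = FALSE)
    rejNull <- rejNull + (p < 0.05)

    scD <- quickScenario(annualDrift = log(1.04),
                         periodCurvature = rep(0, 8),
                         cohortCurvature = rep(0, 22), seed = 200L + s)
    simD <- simulateScenario(scD)
    lxD <- buildLexis(simD$records, simD$population, "HSS")
    g1 <- fitApcGlm(lxD, "age"); g2 <- fitApcGlm(lxD, c("age", "drift"))
    pD <- pchisq(deviance(g1) - deviance(g2), 1, lower.tail = FALSE)
    rejDrift <- rejDrift + (pD < 0.05)
  }
  expect_lte(rejNull, 4)          # ~5% nominal level, generous slack
  expect_equal(rejDrift, nRep)    # 4%/year drift: essentially sure rejection
})

test_that("reference categories anchor at exactly 1 with degenerate CIs", {
  lx <- surfaceLexis(seed = 3)
  fit <- estimableDecomposition(lx)
  pr <- periodRR(fit); cr <- cohortRR(fit)
  i <- which(pr$period == "2000 to 2004")
  expect_identical(unname(unlist(pr[i, c("rr", "lo", "hi")])), c(1, 1, 1))
  j <- which(cr$cohort == "1950 to 1954")
  expect_identical(unname(unlist(cr[j, c("rr", "lo", "hi")])), c(1, 1, 1))
  ## all CIs contain their point estimates
  expect_true(all(pr$lo <= pr$rr & pr$rr <= pr$hi))
  expect_true(all(cr$lo <= cr$rr & cr$rr <= cr$hi))
  ## alternative references anchor there instead
  fit2 <- estimableDecomposition(lx, refPeriod = "1980 to 1984",
                                 refCohort = "1990 to 1994")
  expect_equal(periodRR(fit2)$rr[1], 1)
  expect_error(estimableDecomposition(lx, refPeriod = "1880 to 1884"),
               "not on the grid")
})

test_that("fitted rates are invariant to every identification choice", {
  lx <- surfaceLexis(seed = 19)
  base <- estimableDecomposition(lx)
  variants <- list(
    estimableDecomposition(lx, driftTo = "period"),
    estimableDecomposition(lx, detrendWeights = "personYears"),
    estimableDecomposition(lx, refPeriod = "1985 to 1989",
                           refCohort = "1965 to 1969"))
  fr0 <- fittedRates(base)$fittedRate
  for (v in variants)
    expect_lt(max(abs(fittedRates(v)$fittedRate - fr0) / fr0), 1e-8)
  ## decomposition reconstructs the full-model linear predictor:
  ## age curve (per 1e5) x period RR x cohort RR = fitted rate
  k <- cohortIndex(lx)
  recon <- outer(ageCurve(base)$rate / 1e5, periodRR(base)$rr) *
    matrix(cohortRR(base)$rr[k], nrow(lx), ncol(lx))
  full <- matrix(0, nrow(lx), ncol(lx))
  fr <- fittedRates(base)
  full[cbind(fr$i, fr$j)] <- fr$fittedRate
  expect_lt(max(abs(recon - full) / full), 1e-8)
})

test_that("reported curvatures are slope-free under the chosen weights", {
  lx <- surfaceLexis(seed = 23)
  for (wts in c("uniform", "personYears")) {
    fitC <- estimableDecomposition(lx, driftTo = "cohort",
                                   detrendWeights = wts)
    w <- if (wts == "uniform") rep(1, 8) else colSums(personYears(lx))
    slope <- sum(wlsSlopeWeights(1:8, w) * log(periodRR(fitC)$rr))
    expect_lt(abs(slope), 1e-8)

    fitP <- estimableDecomposition(lx, driftTo = "period",
                                   detrendWeights = wts)
    kIdx <- cohortIndex(lx)
    wc <- if (wts == "uniform") rep(1, 22) else
      vapply(1:22, function(k) sum(personYears(lx)[kIdx == k]), numeric(1))
    slopeC <- sum(wlsSlopeWeights(1:22, wc) * log(cohortRR(fitP)$rr))
    expect_lt(abs(slopeC), 1e-8)

    ## drift equals the linear component carried by the drifted curve
    d5 <- 5 * driftEstimate(fitC)$logAnnual
    slopeDrifted <- sum(wlsSlopeWeights(1:22, wc) * log(cohortRR(fitC)$rr))
    expect_equal(slopeDrifted, d5, tolerance = 1e-8)
  }
})

test_that("pure drift data yield flat curvatures and a recovered drift", {
  sc <- quickScenario(annualDrift = log(1.03), periodCurvature = rep(0, 8),
                      cohortCurvature = rep(0, 22), populationBase = 2e6,
                      seed = 29L)
  sim <- simulateScenario(sc)
  lx <- buildLexis(sim$records, sim$population, "HSS")
  fit <- estimableDecomposition(lx)
  d <- driftEstimate(fit)
  expect_lt(abs(d$logAnnual - log(1.03)), 3 * d$se)
  ## period curvature RRs hover near 1
  pr <- periodRR(fit)
  expect_true(all(pr$lo <= 1.05 & pr$hi >= 0.95))
  ## age-drift model agrees closely with the full-model drift here
  expect_equal(d$ageDriftModel$annualRR, d$annualRR, tolerance = 0.01)
})

test_that("trend classification follows the CI-vs-1 rule", {
  expect_equal(classifyTrend(1.030, 1.020, 1.040), "Upward")
  expect_equal(classifyTrend(0.998, 0.996, 1.001), "Stationary")
  expect_equal(classifyTrend(0.963, 0.948, 0.971), "Downward")
  expect_equal(classifyTrend(1.0, 1.0, 1.0), "Stationary")
  expect_error(classifyTrend(1.0, 1.1, 0.9), "inverted")
  expect_error(classifyTrend(2.0, 0.5, 1.5), "lo <= annualRR <= hi")
})

test_that("IRLS matches a direct likelihood maximization on a toy grid", {
  lx <- surfaceLexis(I = 3, J = 3, N = 1e6, seed = 41)
  fit <- fitApcGlm(lx, c("age", "period", "cohort"))
  devIRLS <- deviance(fit)
  devOracle <- oracleApcDeviance(lx)
  expect_lt(abs(devIRLS - devOracle), 1e-6)
})

test_that("zero person-years cells are excluded with a warning", {
  lx <- surfaceLexis(seed = 6)
  D <- deaths(lx); N <- personYears(lx)
  D[3, 4] <- 0; N[3, 4] <- 0
  lx2 <- LexisTable(D, N)
  expect_warning(fit <- fitApcGlm(lx2), "zero person-years")
  expect_equal(stats::nobs(fit), 119)
})
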