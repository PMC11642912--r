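test_that("ICD codes map to the published mechanism/intent table", {
  cases <- data.frame(
    code = c("X72", "X74", "E955",        # firearm suicide
             "Y20", "E983",               # HSS undetermined
             "W75", "X45", "E860",        # accidents
             "X91", "X85", "X95",         # assaults
             "Y10", "Y19", "Y22", "E980", # undetermined
             "Y87", "E959"),              # sequelae
    rev = c(10, 10, 9, 10, 9, 10, 10, 9, 10, 10, 10, 10, 10, 10, 9, 10, 9),
    mech = c("FA", "FA", "FA", "HSS", "HSS", "HSS", "AUT", "AUT",
             "HSS", "AUT", "FA", "AUT", "AUT", "FA", "AUT", NA, NA),
    intent = c("suicide", "suicide", "suicide", "undetermined",
               "undetermined", "accident", "accident", "accident",
               "assault", "assault", "assault", "undetermined",
               "undetermined", "undetermined", "undetermined",
               "sequelae", "sequelae"),
    stringsAsFactors = FALSE)
  got <- mapCause(cases$code, cases$rev)
  expect_equal(got$mechanism, cases$mech)
  expect_equal(got$intent, cases$intent)
  expect_true(all(got$in_scope))
})

test_that("codes outside every range are flagged not-in-scope", {
  got <- mapCause(c("A00", "X99", "W10", "E800"), c(10, 10, 10, 9))
  expect_false(any(got$in_scope))
  expect_true(all(is.na(got$mechanism)))
})

test_that("malformed codes are rejected by name", {
  expect_error(mapCause("banana", 10), "banana")
  expect_error(mapCause(c("X72", "72X"), 10), "72X")
})

test_that("inferred suicide rows are flagged in the packaged map", {
  m <- causeMap()
  inf <- m[m$source == "inferred", ]
  expect_setequal(unique(inf$mechanism), c("HSS", "AUT"))
  expect_true(all(inf$intent == "suicide"))
})

test_that("proportional redistribution matches the hand calculation", {
  ## suicide 10, assault 30, accident 10, undetermined 5 in one stratum:
  ## corrected suicide = 10 + 5 * 10/50 = 11
  rec <- garbageRecords()[1:4, ]
  out <- redistributeGarbage(rec)
  cls <- mapCause(out$cause_code, out$icd_revision)
  expect_equal(out$deaths[cls$intent == "suicide"], 11)
  expect_equal(out$deaths[cls$intent == "assault"], 33)
  expect_equal(out$deaths[cls$intent == "accident"], 11)
  expect_equal(out$deaths[cls$intent == "undetermined"], 0)
  ## conservation to 1e-9
  expect_equal(sum(out$deaths), sum(rec$deaths), tolerance = 1e-12)
})

test_that("nothing changes when a stratum holds no garbage", {
  rec <- garbageRecords()[c(1, 2, 3), ]   # determined intents only
  out <- redistributeGarbage(rec)
  expect_equal(out$deaths, rec$deaths)
  expect_equal(nrow(attr(out, "audit")), 0)
})

test_that("suicide counts never decrease under default redistribution", {
  set.seed(31)
  codes10 <- c("X70", "X60", "X72", "W75", "X45", "W32", "X91", "X85",
               "X93", "Y20", "Y10", "Y22", "Y87")
  rec <- expand.grid(year = c(1998, 2004), age_group = c("20 to 24",
                                                         "55 to 59"),
                     cause_code = codes10, stringsAsFactors = FALSE)
  rec$region <- "R1"; rec$icd_revision <- 10
  rec$deaths <- rpois(nrow(rec), 6)
  out <- redistributeGarbage(rec)
  cls <- mapCause(rec$cause_code, rec$icd_revision)
  sui <- cls$intent == "suicide"
  expect_true(all(out$deaths[sui] >= rec$deaths[sui]))
  expect_equal(sum(out$deaths), sum(rec$deaths), tolerance = 1e-9)
})

test_that("strata with garbage but no determined deaths fall back and log", {
  rec <- data.frame(region = "R1",
                    year = c(1985, 1997),
                    age_group = c("20 to 24", "30 to 34"),
                    icd_revision = c(9, 10),
                    cause_code = c("E983", "X70"),
                    deaths = c(4, 6), stringsAsFactors = FALSE)
  ## garbage in 1985 (period 1985-1989) has no determined deaths at any
  ## ladder level sharing its period; coarsening drops period, reaching
  ## the 1997 suicide row
  expect_message(out <- redistributeGarbage(
    rec, strata = c("region", "period", "age_group", "mechanism")),
    NA)
  audit <- attr(out, "audit")
  expect_true(any(grepl("coarsened", audit$action)))
  expect_equal(sum(out$deaths), 10, tolerance = 1e-12)
  expect_equal(out$deaths[2], 10)  # all garbage reached the suicide row

  ## with no determined deaths anywhere: conservative default keeps it
  lone <- rec[1, ]
  expect_message(out2 <- redistributeGarbage(lone), "left in place")
  expect_equal(out2$deaths, 4)
})

test_that("sequelae deaths redistribute across mechanisms", {
  rec <- data.frame(region = "R1", year = 1997,
                    age_group = "40 to 44", icd_revision = 10,
                    cause_code = c("X70", "X60", "Y87"),
                    deaths = c(6, 2, 4), stringsAsFactors = FALSE)
  out <- redistributeGarbage(rec)
  ## 4 sequelae split 6:2 over the two suicide rows
  expect_equal(out$deaths, c(6 + 3, 2 + 1, 0), tolerance = 1e-12)
})

test_that("coverage inflation follows deaths / coverage by region-decade", {
  rec <- data.frame(region = c("R1", "R1", "R2"),
                    year = c(1985, 1995, 1985),
                    age_group = "20 to 24", icd_revision = 9,
                    cause_code = "E953",
                    deaths = c(8, 8, 8), stringsAsFactors = FALSE)
  fac <- data.frame(region = c("R1", "R1", "R2"),
                    decade = c("1980s", "1990s", "1980s"),
                    coverage = c(0.8, 1.0, 0.5))
  out <- applyCoverage(rec, fac)
  expect_equal(out$deaths, c(10, 8, 16))
})

test_that("invalid or missing coverage is rejected naming the stratum", {
  rec <- garbageRecords()[1, ]
  expect_error(applyCoverage(rec, data.frame(region = "R1",
                                             decade = "1980s",
                                             coverage = 0)),
               "\\(0, 1\\]")
  expect_error(applyCoverage(rec, data.frame(region = "R1",
                                             decade = "1990s",
                                             coverage = 0.9)),
               "R1 1980s")
})

test_that("correction round-trip has small bias at large counts", {
  ## >= 1e5 simulated deaths, known fractions and coverage
  sc <- quickScenario(ageCurve = rep(log(2e-4), 15), seed = 13L)
  sim <- simulateScenario(sc)
  expect_gt(sum(sim$records$deaths), 1e5)
  deg <- degradeRecords(sim$records, sc)
  corr <- correctRecords(deg, sc@coverage)
  truth <- sum(sim$records$deaths)
  ## coverage inversion undoes the binomial thinning in expectation and
  ## redistribution conserves stratum totals, so the corrected grand
  ## total tracks the generated total
  expect_lt(abs(sum(corr$deaths) - truth) / truth, 0.02)
  ## the suicide-coded share recovers the undetermined pool (15%) on top
  ## of the surviving 78%, pro-rata against the 7% accident/assault
  cls <- mapCause(corr$cause_code, corr$icd_revision)
  recovered <- sum(corr$deaths[cls$intent == "suicide"])
  f <- sc@misclassFractions
  expShare <- (1 - sum(f)) + f["undetermined"] * (1 - sum(f)) /
    (1 - f["undetermined"])
  expect_lt(abs(recovered / truth - expShare), 0.02)
})
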