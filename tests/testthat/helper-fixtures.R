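## Shared fixtures, built in code.

## small scenario for fast simulation-based tests
quickScenario <- function(seed = 1L, ...) {
  syntheticScenario(seed = as.integer(seed), ...)
}

## a deterministic Lexis grid with a known smooth surface (no sampling):
## deaths = N * exp(surface), useful for exact invariance checks
surfaceLexis <- function(I = 15, J = 8, N = 5e6,
                         drift = log(1.02), seed = NULL) {
  ageStarts <- seq(10, length.out = I, by = 5)
  periodStarts <- seq(1980, length.out = J, by = 5)
  K <- I + J - 1
  k <- outer(seq_len(I), seq_len(J), function(i, j) j - i + I)
  age <- log(1e-5) + 0.3 * sin(seq_len(I) / 3)
  pc <- 0.04 * cos(seq_len(J))
  cc <- 0.06 * sin(seq_len(K) / 2)
  eta <- outer(age, 5 * drift * (seq_len(J) - mean(seq_len(J))), `+`) +
    matrix(pc[rep(seq_len(J), each = I)], I, J) + matrix(cc[k], I, J)
  D <- N * exp(eta)
  if (!is.null(seed)) { set.seed(seed); D <- matrix(rpois(I * J, D), I, J) }
  LexisTable(D, matrix(N, I, J), ageStarts, periodStarts)
}

## raw record table exercising garbage codes across strata
garbageRecords <- function() {
  data.frame(
    region = "R1",
    year = c(1985, 1985, 1985, 1985, 1997),
    age_group = "20 to 24",
    icd_revision = c(9, 9, 9, 9, 10),
    cause_code = c("E953", "E963", "E913", "E983", "X70"),
    deaths = c(10, 30, 10, 5, 7),
    stringsAsFactors = FALSE)
}

## the published drift / CI triplets and their trend labels, by region
## and mechanism (HSS = hanging/strangulation/suffocation,
## AUT = autointoxication, FA = firearm)
publishedDriftTable <- function() {
  data.frame(
    region = rep(c("North", "Northeast", "Southeast", "South", "Midwest"),
                 each = 3),
    mechanism = rep(c("HSS", "AUT", "FA"), 5),
    rr = c(1.030, 0.980, 0.963,
           1.037, 1.029, 0.964,
           1.029, 0.992, 0.980,
           0.998, 0.981, 0.966,
           1.042, 0.976, 0.957),
    lo = c(1.020, 0.975, 0.948,
           1.034, 1.027, 0.959,
           1.027, 0.990, 0.977,
           0.996, 0.979, 0.963,
           1.030, 0.973, 0.951),
    hi = c(1.040, 0.984, 0.971,
           1.040, 1.032, 0.970,
           1.031, 0.994, 0.983,
           1.001, 0.984, 0.970,
           1.046, 0.979, 0.963),
    trend = c("Upward", "Downward", "Downward",
              "Upward", "Upward", "Downward",
              "Upward", "Downward", "Downward",
              "Stationary", "Downward", "Downward",
              "Upward", "Downward", "Downward"),
    stringsAsFactors = FALSE)
}

## direct maximization of the Poisson APC log-likelihood, independent of
## the IRLS route: optimizes over an identified parameterization
## (intercept, age levels 2..I, period levels 2..J, cohort levels 2..K-1
## with the last cohort dropped to absorb the APC linear dependence)
oracleApcDeviance <- function(lexis) {
  I <- nrow(lexis); J <- ncol(lexis); K <- I + J - 1
  D <- as.vector(deaths(lexis)); N <- as.vector(personYears(lexis))
  i <- rep(seq_len(I), J); j <- rep(seq_len(J), each = I)
  k <- j - i + I
  ## design: mu + a_i (i>=2) + p_j (j>=2) + c_k (2 <= k <= K-1)
  X <- cbind(1,
             outer(i, 2:I, `==`) * 1,
             outer(j, 2:J, `==`) * 1,
             outer(k, 2:(K - 1), `==`) * 1)
  nll <- function(b) {
    lam <- N * exp(pmin(X %*% b, 50))
    sum(lam) - sum(D * log(lam))
  }
  gr <- function(b) {
    lam <- as.vector(N * exp(pmin(X %*% b, 50)))
    as.vector(t(X) %*% (lam - D))
  }
  b0 <- c(log(sum(D) / sum(N)), rep(0, ncol(X) - 1))
  op <- optim(b0, nll, gr, method = "BFGS",
              control = list(maxit = 2000, reltol = 1e-14))
  lam <- as.vector(N * exp(X %*% op$par))
  poissonDeviance(D, lam)
}
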