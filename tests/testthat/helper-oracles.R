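# Independent oracles used across tests: hand-written sum-of-squares ANOVA
# and normal-equation OLS, plus a small synthetic config for fast runs.

bruteForceAnovaF <- function(biomass, labels) {
  labels <- factor(labels)
  grand <- mean(biomass)
  groups <- split(biomass, labels)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- length(groups) - 1L
  df2 <- length(biomass) - length(groups)
  f <- (ssb / df1) / (ssw / df2)
  list(f = f, df1 = df1, df2 = df2,
       p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

bruteForceOLS <- function(y) {
  x <- seq_along(y)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  yhat <- X %*% beta
  ssr <- sum((yhat - mean(y))^2)
  sse <- sum((y - yhat)^2)
  r2 <- ssr / (ssr + sse)
  df2 <- length(y) - 2L
  f <- (ssr / 1) / (sse / df2)
  list(slope = beta[2], intercept = beta[1], r2 = r2, f = f)
}

# scaled-down jurisdiction for fast end-to-end runs
smallConfig <- function(seed = 1L, ...) {
  SyntheticConfig(nrow = 60, ncol = 130, seed = seed, ...)
}

# micro activity: one stratum, 100 ha lost over the period, nothing else
microActivity <- function(tp = 10) {
  ActivitySummary(
    afd = data.frame(stratum = 1L, type = "agriculture", ha = 100),
    awd = c(peat = 0, mangrove = 0),
    ar = c(fiber = 0, oilpalm = 0, native = 0),
    asl = 0, harvestVolume = NA_real_,
    annualLoss = rep(10, tp), tp = tp)
}

# parameter table with every uncertainty switched off
certainParameters <- function() {
  p <- defaultParameters()
  p$mode <- "empirical"
  p$sem <- 0
  p
}

# switch on uncertainty for a single named parameter, by category
withUncertainty <- function(params, name, category) {
  params$mode[params$name == name] <- "category"
  params$category[params$name == name] <- category
  params
}
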