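oneStratum <- data.frame(stratum = 1L, mean = 150, sem = 0)

test_that("SEM assignment converts category percent errors at 95% CI", {
  expect_equal(assignSem(100, "category", "Medium"), 100 * 0.20 / 1.96)
  expect_equal(assignSem(1, "category", "VeryHigh"), 1 / 1.96)
  expect_equal(assignSem(5, "empirical", sem = 7.07), 7.07)
  expect_error(assignSem(5, "category", NA), "category")
  expect_error(assignSem(5, "empirical"), "SEM")
})

test_that("degenerate SEMs give a zero-width CI at the deterministic flux", {
  act <- microActivity()
  det <- computeFlux(act, oneStratum, certainParameters())
  mc <- suppressWarnings(runMonteCarlo(act, oneStratum, certainParameters(),
                                       n = 500, seed = 4L))
  s <- mcSummary(mc)
  net <- s[s$component == "net", ]
  expect_equal(net$mean, det@dC)
  expect_equal(net$hi - net$lo, 0)
})

test_that("a single 20% CI95 parameter propagates to ~20% output CI", {
  act <- microActivity()
  params <- withUncertainty(certainParameters(), "afd_multiplier", "Medium")
  mc <- runMonteCarlo(act, oneStratum, params, n = 1e5, seed = 8L)
  rel <- mcSummary(mc)
  rel <- rel$relHalfWidth[rel$component == "net"]
  expect_lt(abs(rel - 20), 1)
})

test_that("two independent parameters combine in quadrature", {
  act <- microActivity()
  params <- withUncertainty(certainParameters(), "afd_multiplier", "Low")
  strata <- data.frame(stratum = 1L, mean = 150,
                       sem = 150 * 0.20 / 1.96)       # 20% CI95 empirical
  mc <- runMonteCarlo(act, strata, params, n = 1e5, seed = 8L)
  rel <- mcSummary(mc)
  rel <- rel$relHalfWidth[rel$component == "net"]
  expect_lt(abs(rel - sqrt(10^2 + 20^2)), 2)
})

test_that("fixed seed gives bit-identical Monte Carlo results", {
  act <- microActivity()
  a <- runMonteCarlo(act, oneStratum, n = 2000, seed = 123L)
  b <- runMonteCarlo(act, oneStratum, n = 2000, seed = 123L)
  expect_identical(a@draws, b@draws)
  expect_identical(mcSummary(a), mcSummary(b))
})

test_that("percentile-CI estimator noise shrinks roughly as 1/sqrt(n)", {
  act <- microActivity()
  params <- withUncertainty(certainParameters(), "afd_multiplier", "Medium")
  hiAt <- function(n, seeds) vapply(seeds, function(s) {
    mc <- runMonteCarlo(act, oneStratum, params, n = n, seed = s)
    mcCI(mc)["hi"]
  }, numeric(1))
  sd3 <- stats::sd(hiAt(1e3, 1:25))
  sd4 <- stats::sd(hiAt(1e4, 1:25))
  sd5 <- stats::sd(hiAt(1e5, 1:12))
  # two decades of n: slope of log(sd) vs log(n) near -1/2
  slope <- stats::coef(stats::lm(log(c(sd3, sd4, sd5)) ~ log(c(1e3, 1e4, 1e5))))[2]
  expect_lt(abs(slope + 0.5), 0.2)
})

test_that("a lone uncertain group captures all attributed uncertainty", {
  act <- microActivity()
  params <- withUncertainty(certainParameters(), "afd_multiplier", "Medium")
  att <- attributeUncertainty(act, oneStratum, params, n = 2e4, seed = 5L)
  tab <- attributionTable(att)
  expect_equal(tab$percent[tab$group == "Forest loss"], 100)
  expect_true(all(tab$percent[tab$group != "Forest loss"] == 0))
  expect_equal(sum(tab$percent), 100)
})

test_that("equal independent groups split the uncertainty about 50/50", {
  act <- microActivity()
  params <- withUncertainty(certainParameters(), "afd_multiplier", "Low")
  strata <- data.frame(stratum = 1L, mean = 150,
                       sem = 150 * 0.10 / 1.96)      # same 10% CI95
  att <- attributeUncertainty(act, strata, params, n = 1e5, seed = 6L)
  tab <- attributionTable(att)
  pForest <- tab$percent[tab$group == "Forest loss"]
  pCd <- tab$percent[tab$group == "Aboveground live C"]
  expect_lt(abs(pForest - 50), 5)
  expect_lt(abs(pCd - 50), 5)
  expect_equal(sum(tab$percent), 100)
})

test_that("fixing every group removes all CI width", {
  act <- microActivity()
  strata <- data.frame(stratum = 1L, mean = 150, sem = 3)
  params <- defaultParameters()
  mc <- runMonteCarlo(act, strata, params, n = 5000, seed = 9L,
                      fixGroups = c(unique(params$group),
                                    "Aboveground live C"))
  ci <- mcCI(mc)
  expect_equal(unname(ci["hi"] - ci["lo"]), 0)
})

test_that("attribution is invariant to parameter order within groups", {
  act <- microActivity()
  params <- defaultParameters()
  set.seed(1)
  shuffled <- params[sample(nrow(params)), ]
  a <- attributeUncertainty(act, oneStratum, params, n = 5000, seed = 7L)
  b <- attributeUncertainty(act, oneStratum, shuffled, n = 5000, seed = 7L)
  ta <- attributionTable(a); tb <- attributionTable(b)
  tb <- tb[match(ta$group, tb$group), ]
  expect_equal(ta$percent, tb$percent)
})

test_that("out-of-range redraw failure names the offending parameter", {
  p <- defaultParameters()[1, ]
  p$value <- -5; p$lower <- 0; p$mode <- "empirical"; p$sem <- 0.01
  expect_error(drawParameters(p, 10), p$name)
})
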