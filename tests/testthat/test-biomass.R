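test_that("module ANOVA matches the brute-force sum-of-squares oracle", {
  set.seed(101)
  for (rep in 1:5) {
    k <- sample(3:6, 1)
    n <- sample(5:15, k, replace = TRUE)   # total n <= 100
    labels <- rep(letters[seq_len(k)], n)
    biomass <- stats::rnorm(sum(n), mean = 100 + 40 * as.integer(factor(labels)),
                            sd = 25)
    samples <- data.frame(stratum = labels, biomass = biomass)
    got <- compareStratifications(samples, "stratum")
    oracle <- bruteForceAnovaF(biomass, labels)
    expect_equal(got$f, oracle$f, tolerance = 1e-9)
    expect_equal(got$p, oracle$p, tolerance = 1e-9)
    expect_equal(got$df1, oracle$df1)
    expect_equal(got$df2, oracle$df2)
  }
})

test_that("indistinguishable candidates are lumped; separated ones retained", {
  set.seed(7)
  x <- stats::rnorm(30, 100, 10)
  same <- data.frame(stratum = rep(c("a", "b"), each = 30), biomass = c(x, x))
  expect_length(retainedStrata(evaluateStrata(same)), 1L)

  sep <- data.frame(
    stratum = rep(c("lo", "mid", "hi"), each = 30),
    biomass = stats::rnorm(90, rep(c(50, 150, 300), each = 30), 10))
  res <- evaluateStrata(sep)
  expect_length(retainedStrata(res), 3L)
  oracle <- bruteForceAnovaF(sep$biomass, sep$stratum)
  expect_equal(res@f, oracle$f, tolerance = 1e-9)
  expect_gt(res@f, stats::qf(0.999, 2, 87))
})

test_that("the default synthetic jurisdiction yields a 13-class system", {
  land <- generateLandscape(SyntheticConfig())
  fp <- generateFootprints(land)
  res <- evaluateStrata(fp)
  expect_length(retainedStrata(res), 13L)
})

test_that("lumping is a coarsening: never more strata than candidates", {
  set.seed(42)
  for (rep in 1:5) {
    k <- sample(3:8, 1)
    means <- sort(stats::runif(k, 40, 260))
    samples <- data.frame(
      stratum = rep(paste0("s", seq_len(k)), each = 20),
      biomass = stats::rnorm(20 * k, rep(means, each = 20), 40))
    res <- evaluateStrata(samples)
    expect_lte(length(retainedStrata(res)), k)
    # every sample maps to exactly one final stratum
    expect_false(anyNA(strataAssignment(res)))
    # all retained pairs differ significantly
    if (nrow(res@tukey)) expect_true(all(res@tukey$p <= 0.05))
  }
})

test_that("stratification ranking puts the true labels above random ones", {
  land <- generateLandscape(smallConfig(seed = 13L))
  fp <- generateFootprints(land, nPerStratum = 100)
  set.seed(1)
  fp$random <- sample(fp$stratum)
  ranked <- compareStratifications(fp, c("stratum", "random"))
  expect_equal(ranked$stratification[1], "stratum")
  expect_gt(ranked$f[1], ranked$f[2])
  # duplicate stratifications tie; permuting class ids leaves F unchanged
  fp$copy <- fp$stratum
  fp$permuted <- 14 - fp$stratum
  r2 <- compareStratifications(fp, c("stratum", "copy", "permuted"))
  expect_equal(r2$f[1], r2$f[2])
  expect_equal(r2$f[1], r2$f[3])
})

test_that("single-class stratification has undefined F", {
  d <- data.frame(biomass = stats::rnorm(20), one = "A")
  expect_true(is.na(compareStratifications(d, "one")$f))
})

test_that("stratum means, SEMs and conservation", {
  got <- fitStratumMeans(data.frame(stratum = "a", biomass = c(100, 120)))
  expect_equal(got$mean, 110)
  # SEM = sample sd / sqrt(n) = sqrt(200)/sqrt(2) = 10
  expect_equal(got$sem, stats::sd(c(100, 120)) / sqrt(2))
  expect_equal(got$sem, 10)
  expect_equal(got$n, 2L)
  # single-valued stratum: SEM 0
  s0 <- fitStratumMeans(data.frame(stratum = "a", biomass = c(50, 50, 50)))
  expect_equal(s0$sem, 0)
  # n-weighted grand mean equals overall mean
  set.seed(3)
  samples <- data.frame(stratum = rep(c("a", "b", "c"), c(5, 9, 20)),
                        biomass = stats::runif(34, 20, 300))
  tab <- fitStratumMeans(samples)
  expect_equal(sum(tab$mean * tab$n) / sum(tab$n), mean(samples$biomass))
})

test_that("benchmark map assigns stratum means and flags unmapped ids", {
  st <- RasterGrid(matrix(c(0, 1, 1, 2), 2, 2))
  tab <- data.frame(stratum = c(1, 2), mean = c(150, 80))
  bm <- buildBenchmarkMap(st, tab)
  v <- gridValues(bm)
  expect_true(is.na(v[1, 1]))
  expect_equal(v[2, 1], 150)
  expect_equal(v[2, 2], 80)
  expect_error(buildBenchmarkMap(st, tab[1, ]), "2")
  # uniform single-stratum landscape: constant map
  uni <- buildBenchmarkMap(RasterGrid(matrix(1L, 3, 3)),
                           data.frame(stratum = 1, mean = 99))
  expect_true(all(gridValues(uni) == 99))
})

test_that("lumping to one grand mean shifts jurisdiction stock when loss is biased", {
  # high-biomass strata lost disproportionately: stratified emissions differ
  # from grand-mean emissions
  land <- generateLandscape(smallConfig(seed = 21L))
  cfgStrata <- land@config@strata
  afd <- land@activityTruth@afd
  road <- afd$type == "logging_road"
  byStratum <- tapply(afd$ha[!road], afd$stratum[!road], sum)
  cd <- setNames(cfgStrata$mean, cfgStrata$stratum)
  stratified <- sum(byStratum * cd[names(byStratum)])
  grand <- sum(byStratum) * mean(cfgStrata$mean)
  expect_gt(abs(grand - stratified) / stratified, 0.02)
})
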