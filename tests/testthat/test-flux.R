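baseInputs <- function(...) {
  inp <- list(rootShoot = 0, necromassFraction = 0, burnedFraction = 0,
              combustionCompleteness = 0, charcoalFraction = 0,
              extractionFraction = 0, decayRate = 0.24, productHalfLife = 5)
  utils::modifyList(inp, list(...))
}

test_that("cohort decay fractions follow the linear model", {
  expect_equal(decayFractionInWindow(1, 0.24, 10), 1)      # min(1, 0.24*9)
  expect_equal(decayFractionInWindow(10, 0.24, 10), 0)     # no time left
  expect_equal(decayFractionInWindow(7, 0.24, 10), 0.72)
  expect_equal(cohortMeanDecay(0.24, 10),
               (5 * 1 + 0.96 + 0.72 + 0.48 + 0.24 + 0) / 10)
  expect_error(decayFractionInWindow(0, 0.24, 10), "1..tp")
  expect_error(decayFractionInWindow(11, 0.24, 10), "1..tp")
  expect_error(decayFractionInWindow(3, 0, 10), "positive")
})

test_that("loss factor reproduces its limiting cases", {
  # full combustion, nothing else: everything emits
  expect_equal(lossFactor(baseInputs(burnedFraction = 1,
                                     combustionCompleteness = 1), 10), 1)
  # no burning: equals the cohort-mean decay fraction
  expect_equal(lossFactor(baseInputs(), 10), 0.74)
  # adding roots r with otherwise full emission: 1 + r
  expect_equal(lossFactor(baseInputs(burnedFraction = 1,
                                     combustionCompleteness = 1,
                                     rootShoot = 0.37), 10), 1.37)
  expect_error(lossFactor(baseInputs(burnedFraction = 1.2), 10), "0, 1")
})

test_that("loss factor is monotone in burning, decay, roots and necromass", {
  base <- lossFactor(baseInputs(burnedFraction = 0.4,
                                combustionCompleteness = 0.5), 10)
  up <- function(...) lossFactor(baseInputs(burnedFraction = 0.4,
                                            combustionCompleteness = 0.5,
                                            ...), 10)
  expect_gte(up(burnedFraction = 0.8), base)
  expect_gte(up(decayRate = 0.4), base)
  expect_gte(up(rootShoot = 0.3), base)
  expect_gte(up(necromassFraction = 0.2), base)
})

test_that("forest loss emissions multiply area, stock and factor", {
  expect_equal(forestLossEmissions(c(s1 = 90), c(s1 = 150), 0.74), 9990)
  expect_equal(forestLossEmissions(c(s1 = 90), c(s1 = 150), 0), 0)
  # linear in area
  two <- forestLossEmissions(c(a = 20, b = 30), c(a = 100, b = 200), 0.5)
  expect_equal(forestLossEmissions(c(a = 40, b = 60), c(a = 100, b = 200),
                                   0.5), 2 * two)
  expect_error(forestLossEmissions(c(zz = 1), c(a = 100), 1), "mismatch")
})

test_that("wetland soil rules: mangrove layers and peat drainage cap", {
  soil <- list(peatDepth = 200, peatCDensity = 5, drainageDepth = 60,
               peatLossFraction = 1,
               mangroveTopStock = 100, mangroveRemainderStock = 200,
               mangroveTopLossFraction = 0.75,
               mangroveRemainderLossFraction = 0.35)
  expect_equal(wetlandSoilEmissions(c(mangrove = 10), soil),
               10 * (0.75 * 100 + 0.35 * 200))      # 1450
  # peat shallower than drainage: limited to actual depth
  shallow <- utils::modifyList(soil, list(peatDepth = 40))
  expect_equal(wetlandSoilEmissions(c(peat = 1), shallow), 40 * 5)
  expect_equal(wetlandSoilEmissions(c(peat = 1), soil), 60 * 5)
  expect_equal(wetlandSoilEmissions(c(peat = 0, mangrove = 0), soil), 0)
  expect_error(wetlandSoilEmissions(c(bog = 1), soil), "unknown wetland")
})

test_that("logging components sum and vanish without activity", {
  none <- loggingEmissions(0, list(fellingEF = 28.3, skiddingEF = 10.2),
                           roadAfd = numeric(), roadCd = numeric(),
                           roadLfd = 1, harvestVolume = 0)
  expect_equal(none$total, 0)
  got <- loggingEmissions(10, list(fellingEF = 28.3, skiddingEF = 10.2),
                          roadAfd = c(s1 = 9), roadCd = c(s1 = 150),
                          roadLfd = 0.74, harvestVolume = 319,
                          woodDensity = 0.57, carbonFraction = 0.47,
                          productHalfLife = 5, tp = 10)
  expect_equal(got$felling, 283)
  expect_equal(got$skidding, 102)
  expect_equal(got$haul, 9 * 150 * 0.74 / 10)
  expect_equal(got$total,
               got$felling + got$skidding + got$haul + got$products)
})

test_that("sequestration honours rates, types and the accumulation convention", {
  rates <- list(fiber = 9.8, oilpalm = 2.97, native = 3.85)
  # 100 ha of fiber accruing for one year over a one-year period
  one <- sequestration(c(fiber = 100), rates, tp = 1, accumYears = 1)
  expect_equal(one$regrowth, 980)
  expect_equal(sequestration(c(fiber = 0), rates, asl = 0, sfsl = 0)$total, 0)
  # native vs oil palm typing changes the result by the rate ratio
  nat <- sequestration(c(native = 50), rates, tp = 10)
  oil <- sequestration(c(oilpalm = 50), rates, tp = 10)
  expect_equal(nat$regrowth / oil$regrowth, 3.85 / 2.97)
  expect_error(sequestration(c(bamboo = 1), rates), "unknown regrowth")
})

test_that("net flux identity and CO2 conversion round-trip", {
  fx <- netFlux(300, 50)
  expect_equal(fx@dC, 250)
  expect_equal(fx@co2, 250 * 44 / 12)
  expect_equal(fx@co2 / MGC_TO_CO2, fx@dC)          # exact round-trip
  expect_equal(3 * MGC_TO_CO2, 11)                  # 3 MgC -> 11 MgCO2
  z <- netFlux(120, 0)
  expect_equal(z@dC, z@dCl)
  # printed-scale check: gross 9.73 - seq 0.82 = net 8.91 (Tg CO2/yr)
  expect_equal(9.73 - 0.82, 8.91)
})

test_that("flux terms are homogeneous of degree 1 in their areas", {
  act <- microActivity()
  strata <- data.frame(stratum = 1L, mean = 150, sem = 0)
  f1 <- computeFlux(act, strata)
  act2 <- ActivitySummary(
    afd = data.frame(stratum = 1L, type = "agriculture", ha = 200),
    annualLoss = rep(20, 10), tp = 10)
  f2 <- computeFlux(act2, strata, defaultParameters())
  expect_equal(f2@dCl, 2 * f1@dCl)
  # gross >= each component; net = gross - seq by construction
  land <- generateLandscape(smallConfig(seed = 51L))
  fp <- generateFootprints(land, nPerStratum = 60)
  strataTab <- fitStratumMeans(fp)
  fx <- computeFlux(land@activityTruth, strataTab)
  emis <- fluxComponents(fx)[c("biomassLoss", "wetlandSoil", "loggingFelling",
                               "loggingSkidding", "loggingHaul",
                               "loggingProducts")]
  expect_true(all(fx@dCl >= emis - 1e-9))
  expect_equal(fx@dC, fx@dCl - fx@dCg)
})
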