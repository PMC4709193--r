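#' Molecular-weight ratio converting carbon mass to CO2 mass
#' @export
MGC_TO_CO2 <- 44 / 12

#' Annual net and gross carbon flux with component breakdown
#'
#' Result of the gain-loss flux equation: annual carbon stock loss (dCl),
#' annual gain (dCg), their net difference dC = dCl - dCg, the CO2
#' equivalent (x 44/12), and the per-component breakdown.  All values are
#' annual rates; carbon terms in MgC/yr.
#'
#' @slot dCl annual gross carbon stock loss, MgC/yr
#' @slot dCg annual gross carbon gain, MgC/yr
#' @slot dC net flux, MgC/yr
#' @slot co2 net flux, MgCO2/yr
#' @slot components named numeric breakdown, MgC/yr
#' @export
setClass("FluxResult",
  representation(dCl = "numeric", dCg = "numeric", dC = "numeric",
                 co2 = "numeric", components = "numeric"))

setValidity("FluxResult", function(object) {
  msg <- NULL
  if (!isTRUE(all.equal(object@dC, object@dCl - object@dCg)))
    msg <- c(msg, "dC must equal dCl - dCg exactly")
  if (!isTRUE(all.equal(object@co2, object@dC * MGC_TO_CO2)))
    msg <- c(msg, "co2 must equal dC * 44/12")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "FluxResult", function(object) {
  cat(sprintf("FluxResult (annual): gross %.4g - sequestration %.4g = net %.4g MgC/yr\n",
              object@dCl, object@dCg, object@dC))
  cat(sprintf("  net CO2: %.4g MgCO2/yr\n", object@co2))
  if (length(object@components)) {
    cat("  components (MgC/yr):\n")
    for (nm in names(object@components))
      cat(sprintf("    %-18s %.4g\n", nm, object@components[[nm]]))
  }
})

#' @describeIn FluxResult net flux in MgC/yr
#' @param x a FluxResult
#' @export
netCarbon <- function(x) x@dC

#' @describeIn FluxResult component breakdown in MgC/yr
#' @export
fluxComponents <- function(x) x@components

#' Fraction of a dead-wood cohort emitted within the reference period
#'
#' Dead wood created by clearing in year t (end-of-year convention) decays
#' linearly at \code{rate} per year, so the fraction emitted by the end of
#' the tp-year reference period is min(1, rate * (tp - t)).  A cohort
#' created in the final year has no decay time left and emits nothing
#' within the window.
#'
#' @param t cohort year index, 1..tp
#' @param rate linear decay rate, fraction of the initial pool per year
#' @param tp reference period length, years
#' @return fraction of the cohort's carbon emitted within the period
#' @export
decayFractionInWindow <- function(t, rate, tp) {
  if (any(t < 1 | t > tp)) stop("cohort year t must lie in 1..tp")
  if (any(rate <= 0)) stop("decay rate must be positive")
  pmin(1, rate * (tp - t))
}

#' Mean emitted fraction over uniform annual clearing cohorts
#'
#' Averages \code{\link{decayFractionInWindow}} over cohorts t = 1..tp,
#' the convention used when clearing is spread uniformly across the
#' reference period.  Vectorized over \code{rate}.
#'
#' @inheritParams decayFractionInWindow
#' @export
cohortMeanDecay <- function(rate, tp) {
  remain <- tp - seq_len(tp)          # 9, 8, ..., 0 for tp = 10
  rowMeans(pmin(outer(rate, remain), 1))
}

#' Mean within-window emitted fraction for wood products
#'
#' Wood products decay first-order with the given half-life; cohorts enter
#' at the end of each harvest/clearing year and the emitted fraction is
#' averaged over uniform annual cohorts.
#'
#' @param halfLife product half-life, years
#' @param tp reference period length, years
#' @export
productEmittedFraction <- function(halfLife, tp) {
  k <- log(2) / halfLife
  remain <- tp - seq_len(tp)
  rowMeans(1 - exp(-outer(k, remain)))
}

#' Process-based forest loss factor LFd
#'
#' Emissions per hectare of forest loss as a proportion of the stratum's
#' aboveground live carbon Cd_h.  The committed pool (relative to one unit
#' of aboveground live carbon) is aboveground live retained on site after
#' roundwood extraction, plus roots (root:shoot) and necromass.  Of that
#' on-site pool, the burned-and-combusted share emits immediately except
#' for the recalcitrant charcoal fraction; everything else decays linearly
#' at \code{decayRate} averaged over uniform clearing cohorts.  Extracted
#' roundwood follows the first-order wood-product schedule.  All
#' arguments are vectorized for Monte Carlo use.
#'
#' @param inputs list with elements rootShoot, necromassFraction,
#'   burnedFraction, combustionCompleteness, charcoalFraction,
#'   extractionFraction, decayRate, productHalfLife (each scalar or a
#'   vector of draws)
#' @param tp reference period length, years
#' @return dimensionless proportion of Cd_h emitted per ha of loss
#' @export
lossFactor <- function(inputs, tp) {
  fr <- inputs[c("rootShoot", "necromassFraction", "burnedFraction",
                 "combustionCompleteness", "charcoalFraction",
                 "extractionFraction")]
  for (nm in names(fr))
    if (any(fr[[nm]] < 0 | fr[[nm]] > 1))
      stop("loss-factor fraction out of [0, 1]: ", nm)
  e <- inputs$extractionFraction
  onsite <- (1 - e) + inputs$rootShoot + inputs$necromassFraction
  burnEmit <- inputs$burnedFraction * inputs$combustionCompleteness
  decayed <- cohortMeanDecay(inputs$decayRate, tp)
  onsiteEmitted <- burnEmit * (1 - inputs$charcoalFraction) +
    (1 - burnEmit) * decayed
  onsite * onsiteEmitted + e * productEmittedFraction(inputs$productHalfLife, tp)
}

#' Forest loss emissions over the reference period
#'
#' Sum over strata of AFd_h x Cd_h x LFd_h (Mg C over the period; divide
#' by tp for the annual rate).
#'
#' @param afd named numeric: ha lost per stratum over the period
#' @param cd named numeric (or matrix with strata as rows, draws as
#'   columns): aboveground live carbon MgC/ha per stratum
#' @param lfd loss factor (scalar or draw vector), proportion of Cd_h
#' @return MgC emitted over the period (vector over draws if cd/lfd are)
#' @export
forestLossEmissions <- function(afd, cd, lfd) {
  if (is.matrix(cd)) {
    if (!all(names(afd) %in% rownames(cd)))
      stop("stratum mismatch between AFd and Cd")
    as.numeric(crossprod(cd[names(afd), , drop = FALSE], afd)) * lfd
  } else {
    if (!all(names(afd) %in% names(cd)))
      stop("stratum mismatch between AFd and Cd")
    sum(afd * cd[names(afd)]) * lfd
  }
}

#' Soil carbon emissions from wetland forest loss
#'
#' Mangrove loss emits 75% of the top-layer (default 30 cm) soil carbon
#' stock and 35% of the remainder; cleared peat is assumed drained and
#' burned, emitting 100% of the carbon in the drained layer, whose depth
#' is the smaller of the drainage depth (default 60 cm) and the peat
#' depth.  Soil parameters may be scalars or Monte Carlo draw vectors.
#'
#' @param awd named numeric: ha of wetland forest lost by type
#'   (peat, mangrove)
#' @param soil list with peatDepth, peatCDensity (MgC/ha per cm),
#'   drainageDepth, peatLossFraction, mangroveTopStock,
#'   mangroveRemainderStock, mangroveTopLossFraction,
#'   mangroveRemainderLossFraction
#' @return MgC emitted for the given areas
#' @export
wetlandSoilEmissions <- function(awd, soil) {
  unknown <- setdiff(names(awd), c("peat", "mangrove"))
  if (length(unknown))
    stop("unknown wetland type: ", paste(unknown, collapse = ", "))
  peatEF <- soil$peatLossFraction * soil$peatCDensity *
    pmin(soil$drainageDepth, soil$peatDepth)
  mangEF <- soil$mangroveTopLossFraction * soil$mangroveTopStock +
    soil$mangroveRemainderLossFraction * soil$mangroveRemainderStock
  peatA <- if ("peat" %in% names(awd)) awd[["peat"]] else 0
  mangA <- if ("mangrove" %in% names(awd)) awd[["mangrove"]] else 0
  peatA * peatEF + mangA * mangEF
}

#' Selective-logging degradation emissions by component
#'
#' Felling and skidding emissions are per-hectare factors applied to the
#' annual logged area; haul-road emissions reuse the forest-loss
#' calculation over road-labelled pixels; wood products removed from the
#' concession decay on the first-order product schedule.
#'
#' @param asl annual legally logged area, ha/yr
#' @param factors list with fellingEF, skiddingEF (MgC/ha)
#' @param roadAfd named numeric: road-labelled loss ha per stratum over
#'   the period
#' @param roadCd stratum means as in \code{\link{forestLossEmissions}}
#' @param roadLfd loss factor for road loss
#' @param harvestVolume annual harvest volume, m3/yr
#' @param woodDensity Mg/m3
#' @param carbonFraction fraction of dry mass that is carbon
#' @param productHalfLife years
#' @param tp reference period length, years
#' @return named list of annual MgC/yr components: felling, skidding,
#'   haul, products, total
#' @export
loggingEmissions <- function(asl, factors, roadAfd, roadCd, roadLfd,
                             harvestVolume = 0, woodDensity = 0.57,
                             carbonFraction = 0.47, productHalfLife = 5,
                             tp = 10) {
  felling <- asl * factors$fellingEF
  skidding <- asl * factors$skiddingEF
  haul <- if (length(roadAfd))
    forestLossEmissions(roadAfd, roadCd, roadLfd) / tp else 0 * roadLfd
  vol <- if (is.na(harvestVolume)) 0 else harvestVolume
  products <- vol * woodDensity * carbonFraction *
    productEmittedFraction(productHalfLife, tp)
  list(felling = felling, skidding = skidding, haul = haul,
       products = products, total = felling + skidding + haul + products)
}

#' Annual carbon sequestration from regrowth and post-logging response
#'
#' Each regrowth cohort accrues its type's sequestration rate for the
#' years between detection and the end of the period; with a non-annual
#' gain band the cohort-mean convention (accumYears = tp/2) is used.  The
#' post-logging growth response SFsl accrues on logged cohorts under the
#' same convention.
#'
#' @param ar named numeric: regrowth ha over the period by type
#'   (fiber, oilpalm, native)
#' @param rates list with fiber, oilpalm, native (MgC/ha/yr; may be draw
#'   vectors)
#' @param asl annual legally logged area, ha/yr
#' @param sfsl post-logging sequestration rate, MgC/ha/yr
#' @param tp reference period length, years
#' @param accumYears mean accumulation years per cohort (default tp/2)
#' @return named list of annual MgC/yr: regrowth, logging, total
#' @export
sequestration <- function(ar, rates, asl = 0, sfsl = 0, tp = 10,
                          accumYears = tp / 2) {
  unknown <- setdiff(names(ar), c("fiber", "oilpalm", "native"))
  if (length(unknown))
    stop("unknown regrowth type: ", paste(unknown, collapse = ", "))
  getA <- function(t) if (t %in% names(ar)) ar[[t]] else 0
  regrowth <- (getA("fiber") * rates$fiber + getA("oilpalm") * rates$oilpalm +
               getA("native") * rates$native) * accumYears / tp
  logging <- asl * tp * sfsl * accumYears / tp
  list(regrowth = regrowth, logging = logging, total = regrowth + logging)
}

#' Combine gross loss and gain into a FluxResult
#'
#' @param dCl annual gross carbon stock loss, MgC/yr
#' @param dCg annual gross carbon gain, MgC/yr
#' @param components optional named numeric breakdown (MgC/yr)
#' @return a \linkS4class{FluxResult}
#' @export
netFlux <- function(dCl, dCg, components = numeric()) {
  dC <- dCl - dCg
  new("FluxResult", dCl = dCl, dCg = dCg, dC = dC, co2 = dC * MGC_TO_CO2,
      components = components)
}

# Vectorized evaluation of the full flux equation.
# par: list of parameter vectors (length 1 or n) named as in
# defaultParameters(); cd: stratum-mean matrix (strata x n) or named
# vector.  Returns a list of component vectors, annual MgC/yr.
.fluxKernel <- function(par, activity, cd, accumYears = NULL) {
  tp <- activity@tp
  if (is.null(accumYears)) accumYears <- tp / 2
  lfd <- lossFactor(list(
    rootShoot = par$root_shoot,
    necromassFraction = par$necromass_fraction,
    burnedFraction = par$burned_fraction,
    combustionCompleteness = par$combustion_completeness,
    charcoalFraction = par$charcoal_fraction,
    extractionFraction = par$extraction_fraction,
    decayRate = par$decay_rate,
    productHalfLife = par$product_half_life), tp)
  afd <- activity@afd
  road <- afd$type == "logging_road"
  afdBy <- tapply(afd$ha[!road], afd$stratum[!road], sum)
  roadBy <- tapply(afd$ha[road], afd$stratum[road], sum)
  afdV <- stats::setNames(as.numeric(afdBy), names(afdBy))
  roadV <- stats::setNames(as.numeric(roadBy), names(roadBy))
  biomassLoss <- if (length(afdV))
    forestLossEmissions(afdV, cd, lfd) / tp * par$afd_multiplier
    else 0 * lfd
  soil <- wetlandSoilEmissions(activity@awd, list(
    peatDepth = par$peat_depth_cm,
    peatCDensity = par$peat_c_density,
    drainageDepth = par$drainage_depth_cm,
    peatLossFraction = par$peat_loss_fraction,
    mangroveTopStock = par$mangrove_top_stock,
    mangroveRemainderStock = par$mangrove_remainder_stock,
    mangroveTopLossFraction = par$mangrove_top_loss_fraction,
    mangroveRemainderLossFraction = par$mangrove_remainder_loss_fraction)) /
    tp * par$awd_multiplier
  asl <- activity@asl * par$asl_multiplier
  logg <- loggingEmissions(asl,
    list(fellingEF = par$felling_ef, skiddingEF = par$skidding_ef),
    roadV, cd, lfd,
    harvestVolume = if (is.na(activity@harvestVolume)) 0 else
      activity@harvestVolume,
    woodDensity = par$wood_density, carbonFraction = par$carbon_fraction,
    productHalfLife = par$product_half_life, tp = tp)
  logg$haul <- logg$haul * par$afd_multiplier
  loggingTotal <- logg$felling + logg$skidding + logg$haul + logg$products
  seq <- sequestration(activity@ar,
    list(fiber = par$sfr_fiber, oilpalm = par$sfr_oilpalm,
         native = par$sfr_native),
    asl = asl, sfsl = par$sfsl, tp = tp, accumYears = accumYears)
  seq$regrowth <- seq$regrowth * par$ar_multiplier
  grossSeq <- seq$regrowth + seq$logging
  gross <- biomassLoss + soil + loggingTotal
  list(biomassLoss = biomassLoss, wetlandSoil = soil,
       loggingFelling = logg$felling, loggingSkidding = logg$skidding,
       loggingHaul = logg$haul, loggingProducts = logg$products,
       logging = loggingTotal,
       grossEmissions = gross,
       seqRegrowth = seq$regrowth, seqLogging = seq$logging,
       grossSequestration = grossSeq,
       net = gross - grossSeq)
}

#' Deterministic flux equation evaluation at parameter means
#'
#' Evaluates the full gain-loss equation (forest loss with the
#' process-based loss factor, wetland soil, logging degradation,
#' sequestration) at the parameter-table means.
#'
#' @param activity an \linkS4class{ActivitySummary}
#' @param strata data.frame with columns stratum, mean (MgC/ha)
#' @param params parameter table (see \code{\link{defaultParameters}})
#' @param accumYears regrowth accumulation years per cohort
#'   (default tp/2)
#' @return a \linkS4class{FluxResult} with full component breakdown
#' @export
computeFlux <- function(activity, strata, params = defaultParameters(),
                        accumYears = NULL) {
  par <- as.list(.paramVector(params))
  cd <- stats::setNames(strata$mean, as.character(strata$stratum))
  k <- .fluxKernel(par, activity, cd, accumYears)
  netFlux(k$grossEmissions, k$grossSequestration,
          components = c(biomassLoss = k$biomassLoss,
                         wetlandSoil = k$wetlandSoil,
                         loggingFelling = k$loggingFelling,
                         loggingSkidding = k$loggingSkidding,
                         loggingHaul = k$loggingHaul,
                         loggingProducts = k$loggingProducts,
                         seqRegrowth = k$seqRegrowth,
                         seqLogging = k$seqLogging))
}
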