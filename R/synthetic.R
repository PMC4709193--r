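#' Configuration of a synthetic jurisdiction
#'
#' Defines the study conditions for a simulated forest jurisdiction: grid
#' size and pixel size, reference period, the biomass stratum system
#' (labels, true means, spread, relative extents), annual loss fractions
#' per disturbance type, gain rate and placement, wetland substrate
#' assignment, logging intensity, and the single seed that drives every
#' sub-generator (landscape +0, footprints +1, logging records +2).
#'
#' @slot nrow,ncol grid dimensions in pixels
#' @slot pixelSize pixel edge length, m
#' @slot tp reference period, years
#' @slot strata data.frame(stratum, disturbance, elevation, substrate,
#'   mean, cv, weight): true mean aboveground carbon (MgC/ha),
#'   multiplicative coefficient of variation, relative area weight
#' @slot lossRates named numeric: annual loss fraction of forest pixels by
#'   disturbance type (oil_palm, agriculture, fiber, mining)
#' @slot roadsPerYear new haul-road corridors per year (2 x 10 pixels,
#'   inside the logging concession)
#' @slot gainRate annual gain fraction of forest pixels over the source
#'   period
#' @slot gainSourceYears length of the gain-band source period, years
#' @slot gainPlacement "on-loss", "non-forest" or "mixed"
#' @slot nPermits number of selective-logging permits
#' @slot aslAnnual legally logged area, ha/yr
#' @slot volPerHa harvest volume per logged hectare, m3/ha
#' @slot completeness fraction of permit-years with logging records
#' @slot seed integer seed driving all sub-generators
#' @export
setClass("SyntheticConfig",
  representation(nrow = "numeric", ncol = "numeric", pixelSize = "numeric",
                 tp = "numeric", strata = "data.frame",
                 lossRates = "numeric", roadsPerYear = "numeric",
                 gainRate = "numeric", gainSourceYears = "numeric",
                 gainPlacement = "character", nPermits = "numeric",
                 aslAnnual = "numeric", volPerHa = "numeric",
                 completeness = "numeric", seed = "numeric"))

setValidity("SyntheticConfig", function(object) {
  msg <- NULL
  if (object@tp < 1) msg <- c(msg, "tp must be >= 1")
  if (any(object@lossRates < 0) || object@gainRate < 0 ||
      object@roadsPerYear < 0 || object@aslAnnual < 0)
    msg <- c(msg, "rates and areas must be non-negative")
  if (sum(object@lossRates) * object@tp > 1)
    msg <- c(msg, "requested loss exceeds the forest area")
  if (object@completeness < 0 || object@completeness > 1)
    msg <- c(msg, "completeness must lie in [0, 1]")
  if (!object@gainPlacement %in% c("on-loss", "non-forest", "mixed"))
    msg <- c(msg, "gainPlacement must be on-loss/non-forest/mixed")
  if (is.null(msg)) TRUE else msg
})

#' Default 13-class biomass stratum system of the synthetic jurisdiction
#'
#' Disturbance (primary / non-primary / secondary), elevation class
#' (lowland < 100 m / highland) and substrate (high fertility, low
#' fertility, peat, mangrove) combine into 13 classes with well-separated
#' true means, ordered as observed in Bornean dipterocarp landscapes:
#' primary > non-primary > secondary, highland > lowland, basic > acidic,
#' wetland lowest for a given disturbance class.
#'
#' @return the stratum data.frame used by \code{\link{SyntheticConfig}}
#' @export
defaultStrata <- function() {
  data.frame(
    stratum = 1:13,
    disturbance = c(rep("primary", 6), rep("nonprimary", 5),
                    rep("secondary", 2)),
    elevation = c("highland", "highland", "lowland", "lowland", "lowland",
                  "lowland", "highland", "highland", "lowland", "lowland",
                  "lowland", "lowland", "lowland"),
    substrate = c("highfert", "lowfert", "highfert", "lowfert", "peat",
                  "mangrove", "highfert", "lowfert", "highfert", "lowfert",
                  "peat", "lowfert", "mangrove"),
    mean = c(260, 235, 210, 185, 160, 138, 118, 100, 84, 68, 54, 40, 28),
    cv = 0.20,
    weight = 1,
    stringsAsFactors = FALSE)
}

#' Construct a SyntheticConfig
#'
#' Defaults describe a scaled-down tropical frontier jurisdiction: a
#' 120 x 195 pixel grid of 30 m pixels (the bottom 10% of rows non-forest),
#' 13 biomass classes in equal column bands, a 10-year reference period,
#' 0.7%/yr total forest loss split over oil palm, small-scale agriculture,
#' fiber plantations and mining, gain at 0.2%/yr over a 12-year source
#' band, and a logging concession harvesting 6.5 ha/yr at 31.9 m3/ha with
#' records for 57% of permit-years.
#'
#' @param nrow,ncol,pixelSize,tp,strata,lossRates,roadsPerYear,gainRate
#'   see \linkS4class{SyntheticConfig}
#' @param gainSourceYears,gainPlacement,nPermits,aslAnnual,volPerHa see
#'   \linkS4class{SyntheticConfig}
#' @param completeness,seed see \linkS4class{SyntheticConfig}
#' @export
SyntheticConfig <- function(nrow = 120, ncol = 195, pixelSize = 30, tp = 10,
                            strata = defaultStrata(),
                            lossRates = c(oil_palm = 0.0020,
                                          agriculture = 0.0035,
                                          fiber = 0.0012,
                                          mining = 0.0003),
                            roadsPerYear = 1, gainRate = 0.002,
                            gainSourceYears = 12, gainPlacement = "mixed",
                            nPermits = 20, aslAnnual = 6.5, volPerHa = 31.9,
                            completeness = 0.57, seed = 1L) {
  new("SyntheticConfig", nrow = nrow, ncol = ncol, pixelSize = pixelSize,
      tp = tp, strata = strata, lossRates = lossRates,
      roadsPerYear = roadsPerYear, gainRate = gainRate,
      gainSourceYears = gainSourceYears, gainPlacement = gainPlacement,
      nPermits = nPermits, aslAnnual = aslAnnual, volPerHa = volPerHa,
      completeness = completeness, seed = seed)
}

#' True annual fluxes of a synthetic jurisdiction
#'
#' Ground truth computed from the generated landscape at the true
#' parameter values: annual gross emissions, gross sequestration and net
#' flux (MgC/yr), with the per-component breakdown.  By construction
#' net = gross - sequestration exactly.
#'
#' @slot grossEmissions,grossSequestration,net annual MgC/yr
#' @slot components named numeric component breakdown, MgC/yr
#' @export
setClass("TruthRecord",
  representation(grossEmissions = "numeric", grossSequestration = "numeric",
                 net = "numeric", components = "numeric"))

setValidity("TruthRecord", function(object) {
  if (!isTRUE(all.equal(object@net,
                        object@grossEmissions - object@grossSequestration)))
    return("net must equal gross emissions - gross sequestration")
  TRUE
})

setMethod("show", "TruthRecord", function(object) {
  cat(sprintf("TruthRecord: gross %.4g - seq %.4g = net %.4g MgC/yr\n",
              object@grossEmissions, object@grossSequestration, object@net))
})

#' @describeIn TruthRecord true net annual flux, MgC/yr
#' @param x a TruthRecord
#' @export
trueNet <- function(x) x@net

#' A generated synthetic jurisdiction
#'
#' @slot config the \linkS4class{SyntheticConfig} used
#' @slot rasters named list of aligned \linkS4class{RasterGrid} layers:
#'   lossYear, gain, canopy2000, stratum, zone, permit, concession, peat,
#'   mangrove, attribution
#' @slot truth the \linkS4class{TruthRecord}
#' @slot activityTruth the true \linkS4class{ActivitySummary}
#' @export
setClass("JurisdictionLandscape",
  representation(config = "SyntheticConfig", rasters = "list",
                 truth = "TruthRecord", activityTruth = "ActivitySummary"))

setMethod("show", "JurisdictionLandscape", function(object) {
  cfg <- object@config
  cat(sprintf("JurisdictionLandscape: %d x %d pixels @ %g m, tp = %g yr\n",
              cfg@nrow, cfg@ncol, cfg@pixelSize, cfg@tp))
  cat(sprintf("  layers: %s\n", paste(names(object@rasters), collapse = ", ")))
  show(object@truth)
})

#' @describeIn JurisdictionLandscape a named raster layer
#' @param x a JurisdictionLandscape
#' @param name layer name
#' @export
landscapeRaster <- function(x, name) {
  if (!name %in% names(x@rasters)) stop("no such layer: ", name)
  x@rasters[[name]]
}

#' @describeIn JurisdictionLandscape the true flux record
#' @export
landscapeTruth <- function(x) x@truth

# Deterministic layout helpers ------------------------------------------

.layout <- function(cfg) {
  nr <- cfg@nrow; nc <- cfg@ncol
  forestRows <- seq_len(round(nr * 0.9))
  nonforestRows <- setdiff(seq_len(nr), forestRows)
  nfr <- length(forestRows)
  aplRows <- forestRows[seq_len(round(nfr * 0.3))]
  hpRows <- forestRows[(round(nfr * 0.3) + 1):round(nfr * 0.85)]
  hlRows <- forestRows[(round(nfr * 0.85) + 1):nfr]
  # stratum column bands proportional to weight
  w <- cfg@strata$weight / sum(cfg@strata$weight)
  edges <- round(cumsum(c(0, w)) * nc)
  bands <- lapply(seq_len(nrow(cfg@strata)), function(i)
    if (edges[i] < edges[i + 1]) (edges[i] + 1):edges[i + 1] else integer())
  list(forestRows = forestRows, nonforestRows = nonforestRows,
       aplRows = aplRows, hpRows = hpRows, hlRows = hlRows,
       bands = bands,
       htiCols = seq_len(round(nc * 0.2)),
       haCols = (round(nc * 0.4) + 1):nc,
       hguCols = seq_len(round(nc * 0.5)),
       pkpRows = intersect(seq(round(nr * 0.15), round(nr * 0.45)),
                           forestRows),
       pkpCols = (nc - round(nc * 0.12) + 1):nc)
}

#' Generate the synthetic jurisdiction
#'
#' Builds the aligned raster bundle (loss-year, gain, canopy-2000,
#' stratum, zone, permit, concession, wetland masks, disturbance
#' attribution), places loss pixels uniformly over years 1..tp within
#' each disturbance type's eligible zone, carves haul-road corridors
#' inside the logging concession, places the gain band, and computes the
#' \linkS4class{TruthRecord} from the placed activity at the true
#' parameter values.
#'
#' @param config a \linkS4class{SyntheticConfig}
#' @param params parameter table used for the truth computation (defaults
#'   to \code{\link{defaultParameters}})
#' @return a \linkS4class{JurisdictionLandscape}
#' @export
generateLandscape <- function(config, params = defaultParameters()) {
  validObject(config)
  set.seed(config@seed)
  cfg <- config
  nr <- cfg@nrow; nc <- cfg@ncol; tp <- cfg@tp
  px <- cfg@pixelSize^2 / 1e4
  L <- .layout(cfg)

  stratum <- matrix(0L, nr, nc)
  for (i in seq_len(nrow(cfg@strata)))
    stratum[L$forestRows, L$bands[[i]]] <- cfg@strata$stratum[i]
  canopy <- matrix(0L, nr, nc); canopy[stratum > 0] <- 1L

  zone <- matrix(0L, nr, nc)
  zone[L$aplRows, ] <- 1L; zone[L$hpRows, ] <- 2L; zone[L$hlRows, ] <- 3L

  permit <- matrix(0L, nr, nc)
  permit[L$aplRows, L$hguCols] <- 1L                       # HGU
  permit[L$hpRows, L$htiCols] <- 2L                        # HTI
  permit[L$hpRows, L$haCols] <- 3L                         # HA
  pk <- permit[L$pkpRows, L$pkpCols]
  pk[pk == 0L] <- 4L                                       # PKP2B fills gaps
  permit[L$pkpRows, L$pkpCols] <- pk
  nfc <- L$nonforestRows            # permits reach into the regrowth band
  permit[nfc, seq_len(round(nc * 0.3))] <- 1L
  permit[nfc, (round(nc * 0.3) + 1):round(nc * 0.5)] <- 2L
  concession <- matrix(0L, nr, nc); concession[permit == 3L] <- 1L

  peatStrata <- cfg@strata$stratum[cfg@strata$substrate == "peat"]
  mangStrata <- cfg@strata$stratum[cfg@strata$substrate == "mangrove"]
  peat <- matrix(0L, nr, nc); peat[stratum %in% peatStrata] <- 1L
  mang <- matrix(0L, nr, nc); mang[stratum %in% mangStrata] <- 1L

  lossYear <- matrix(0L, nr, nc)
  attribution <- matrix(0L, nr, nc)
  attrCodes <- stats::setNames(seq_along(.knownAttributions),
                               .knownAttributions)
  nForest <- sum(canopy == 1L)

  # haul-road corridors: 2 x 10 pixels inside the concession
  roadLen <- 10L
  if (cfg@roadsPerYear > 0) {
    for (y in seq_len(tp)) for (k in seq_len(cfg@roadsPerYear)) {
      placed <- FALSE
      for (try in 1:200) {
        r <- sample(L$hpRows[L$hpRows <= max(L$hpRows) - 1L], 1L)
        c0 <- sample(L$haCols[L$haCols <= nc - roadLen + 1L], 1L)
        rows <- r:(r + 1L); cols <- c0:(c0 + roadLen - 1L)
        if (all(concession[rows, cols] == 1L) &&
            all(lossYear[rows, cols] == 0L)) {
          lossYear[rows, cols] <- y
          attribution[rows, cols] <- attrCodes[["logging_road"]]
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("grid too small to place haul-road corridors")
    }
  }

  eligibleFor <- function(type) {
    el <- canopy == 1L & lossYear == 0L
    switch(type,
      oil_palm = el & zone == 1L,
      fiber = el & permit == 2L,
      mining = {
        m <- matrix(FALSE, nr, nc); m[L$pkpRows, L$pkpCols] <- TRUE
        el & m
      },
      agriculture = el)
  }
  for (type in c("oil_palm", "fiber", "mining", "agriculture")) {
    rate <- cfg@lossRates[[type]]
    nPerYear <- round(rate * nForest)
    if (nPerYear == 0) next
    idx <- which(eligibleFor(type))
    if (length(idx) < nPerYear * tp)
      stop("grid too small to place requested ", type, " loss")
    pick <- sample(idx, nPerYear * tp)
    lossYear[pick] <- rep(seq_len(tp), each = nPerYear)
    attribution[pick] <- attrCodes[[type]]
  }

  gain <- matrix(0L, nr, nc)
  nGain <- round(cfg@gainRate * nForest * cfg@gainSourceYears)
  if (nGain > 0) {
    lossIdx <- which(lossYear > 0 & lossYear <= ceiling(tp / 2))
    nfIdx <- which(canopy == 0L)
    fromLoss <- switch(cfg@gainPlacement,
                       "on-loss" = nGain, "non-forest" = 0L,
                       "mixed" = round(nGain / 2))
    fromLoss <- min(fromLoss, length(lossIdx))
    fromNf <- nGain - fromLoss
    if (fromNf > length(nfIdx))
      stop("grid too small to place requested gain")
    if (fromLoss > 0) gain[sample(lossIdx, fromLoss)] <- 1L
    if (fromNf > 0) gain[sample(nfIdx, fromNf)] <- 1L
  }

  mk <- function(m) RasterGrid(m, pixelSize = cfg@pixelSize)
  rasters <- list(lossYear = mk(lossYear), gain = mk(gain),
                  canopy2000 = mk(canopy), stratum = mk(stratum),
                  zone = mk(zone), permit = mk(permit),
                  concession = mk(concession), peat = mk(peat),
                  mangrove = mk(mang), attribution = mk(attribution))

  # --- truth from the placed activity at true parameter values ---
  afd <- extractLoss(rasters$lossYear, rasters$stratum,
                     rasters$attribution, period = seq_len(tp))
  annual <- attr(afd, "annualLoss")
  lossSel <- lossYear > 0
  awd <- c(peat = sum(lossSel & peat == 1L) * px,
           mangrove = sum(lossSel & mang == 1L) * px)
  ar <- annualizeGain(rasters$gain, rasters$permit,
                      sourceYears = cfg@gainSourceYears, refYears = tp)
  activity <- ActivitySummary(afd = afd, awd = awd, ar = ar,
                              asl = cfg@aslAnnual,
                              harvestVolume = cfg@aslAnnual * cfg@volPerHa,
                              annualLoss = annual, tp = tp)
  strataTab <- data.frame(stratum = cfg@strata$stratum,
                          mean = cfg@strata$mean)
  fx <- computeFlux(activity, strataTab, params)
  truth <- new("TruthRecord", grossEmissions = fx@dCl,
               grossSequestration = fx@dCg, net = fx@dC,
               components = fx@components)

  new("JurisdictionLandscape", config = cfg, rasters = rasters,
      truth = truth, activityTruth = activity)
}

#' Sample lidar-footprint style biomass estimates from the landscape
#'
#' Footprints are drawn only from pixels forested in 2000 with no
#' intervening forest loss during the screening window (loss-year indices
#' 1..\code{screenThrough} excluded), mirroring the screening applied to
#' spaceborne-lidar footprint estimates.  Noise is multiplicative
#' lognormal with unit mean, so sample means are unbiased for the true
#' stratum means.
#'
#' @param landscape a \linkS4class{JurisdictionLandscape}
#' @param nPerStratum footprints per stratum (>= 2)
#' @param noiseCV multiplicative coefficient of variation (0 = exact)
#' @param screenThrough last loss-year index treated as intervening loss
#' @param seed seed (default: config seed + 1)
#' @return data.frame(x, y, stratum, disturbance, elevation, substrate,
#'   biomass); strata with no eligible pixels are omitted with a warning
#' @export
generateFootprints <- function(landscape, nPerStratum = 300,
                               noiseCV = 0.20, screenThrough = 9,
                               seed = landscape@config@seed + 1L) {
  if (nPerStratum < 2) stop("nPerStratum must be >= 2")
  set.seed(seed)
  cfg <- landscape@config
  st <- gridValues(landscapeRaster(landscape, "stratum"))
  ly <- gridValues(landscapeRaster(landscape, "lossYear"))
  eligible <- st > 0 & (ly == 0 | ly > screenThrough)
  out <- list()
  for (i in seq_len(nrow(cfg@strata))) {
    sid <- cfg@strata$stratum[i]
    idx <- which(eligible & st == sid)
    if (!length(idx)) {
      warning("stratum ", sid, " has no eligible pixels; omitted")
      next
    }
    pick <- sample(idx, nPerStratum, replace = TRUE)
    rc <- arrayInd(pick, dim(st))
    mu <- cfg@strata$mean[i]
    cv <- cfg@strata$cv[i]
    noise <- if (noiseCV > 0 && cv > 0) {
      s <- sqrt(log(1 + noiseCV^2))
      stats::rlnorm(nPerStratum, meanlog = -s^2 / 2, sdlog = s)
    } else rep(1, nPerStratum)
    out[[length(out) + 1L]] <- data.frame(
      x = rc[, 2], y = rc[, 1], stratum = sid,
      disturbance = cfg@strata$disturbance[i],
      elevation = cfg@strata$elevation[i],
      substrate = cfg@strata$substrate[i],
      biomass = mu * noise, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Generate government-style logging records
#'
#' One row per permit-year with harvested area (ha) and volume (m3);
#' annual intensity is split evenly over permits.  Only a
#' \code{completeness} fraction of permit-years is retained (seeded
#' subsample), emulating incomplete archives.
#'
#' @param config a \linkS4class{SyntheticConfig}
#' @param seed seed (default: config seed + 2)
#' @return data.frame(permit, year, ha, volume_m3)
#' @export
generateLoggingRecords <- function(config, seed = config@seed + 2L) {
  set.seed(seed)
  full <- expand.grid(permit = seq_len(config@nPermits),
                      year = seq_len(config@tp))
  full$ha <- config@aslAnnual / config@nPermits
  full$volume_m3 <- full$ha * config@volPerHa
  keep <- sort(sample(nrow(full), round(config@completeness * nrow(full))))
  full[keep, , drop = FALSE]
}
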