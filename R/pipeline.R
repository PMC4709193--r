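#' Map stratum-raster ids to lumped stratum means
#'
#' After ANOVA/Tukey lumping, several raster ids may share a final
#' stratum; this helper expands the lumped means back to one record per
#' raster id so the benchmark map and flux equation can stay on the raster
#' id vocabulary.
#'
#' @param footprints footprint table used for evaluation (column stratum
#'   = raster id)
#' @param strat a \linkS4class{StratificationResult} from
#'   \code{\link{evaluateStrata}} run on \code{footprints}
#' @return data.frame(stratum, finalStratum, mean, sem, n) with one row
#'   per raster id
#' @export
lumpedStratumMeans <- function(footprints, strat) {
  fp <- footprints
  fp$final <- as.character(strataAssignment(strat))
  means <- fitStratumMeans(fp, by = "final")
  idMap <- unique(data.frame(stratum = fp$stratum, final = fp$final,
                             stringsAsFactors = FALSE))
  m <- merge(idMap, means, by.x = "final", by.y = "stratum")
  data.frame(stratum = m$stratum, finalStratum = m$final, mean = m$mean,
             sem = m$sem, n = m$n, stringsAsFactors = FALSE)[order(m$stratum), ]
}

# Per-cell (zone x permit x type) ledger assembly from the landscape
# rasters and fitted strata.  Gross emissions use the same loss factor for
# every cell; wetland soil is added to the cells whose loss pixels sit on
# wetland; logging felling/skidding/products and sequestration attach to
# the concession's skidding/felling row; regrowth sequestration is
# allocated to cells by the zone x permit of the gain pixels.
.ledgerCells <- function(landscape, strata, activity,
                         params = defaultParameters(), accumYears = NULL) {
  cfg <- landscape@config
  tp <- cfg@tp
  px <- pixelAreaHa(landscapeRaster(landscape, "lossYear"))
  par <- as.list(.paramVector(params))
  if (is.null(accumYears)) accumYears <- tp / 2
  zoneNames <- c("1" = "APL", "2" = "HP/HPT", "3" = "HL", "0" = "APL")
  permitNames <- c("0" = "None", "1" = "HGU", "2" = "HTI", "3" = "HA",
                   "4" = "PKP2B")
  typeNames <- c(oil_palm = "Oil Palm", agriculture = "Agriculture / Other",
                 fiber = "Fiber Plantation", mining = "Mining",
                 logging_road = "Logging Roads")

  ly <- gridValues(landscapeRaster(landscape, "lossYear"))
  st <- gridValues(landscapeRaster(landscape, "stratum"))
  zn <- gridValues(landscapeRaster(landscape, "zone"))
  pm <- gridValues(landscapeRaster(landscape, "permit"))
  at <- gridValues(landscapeRaster(landscape, "attribution"))
  pt <- gridValues(landscapeRaster(landscape, "peat"))
  mg <- gridValues(landscapeRaster(landscape, "mangrove"))
  gn <- gridValues(landscapeRaster(landscape, "gain"))

  lfd <- lossFactor(list(
    rootShoot = par$root_shoot, necromassFraction = par$necromass_fraction,
    burnedFraction = par$burned_fraction,
    combustionCompleteness = par$combustion_completeness,
    charcoalFraction = par$charcoal_fraction,
    extractionFraction = par$extraction_fraction,
    decayRate = par$decay_rate,
    productHalfLife = par$product_half_life), tp)
  cd <- stats::setNames(strata$mean, as.character(strata$stratum))
  peatEF <- par$peat_loss_fraction * par$peat_c_density *
    min(par$drainage_depth_cm, par$peat_depth_cm)
  mangEF <- par$mangrove_top_loss_fraction * par$mangrove_top_stock +
    par$mangrove_remainder_loss_fraction * par$mangrove_remainder_stock

  sel <- which(ly > 0)
  key <- paste(zn[sel], pm[sel], at[sel], sep = "|")
  cells <- list()
  for (k in unique(key)) {
    i <- sel[key == k]
    parts <- strsplit(k, "|", fixed = TRUE)[[1L]]
    typeLab <- typeNames[[.knownAttributions[as.integer(parts[3])] ]]
    grossC <- sum(cd[as.character(st[i])] * px) * lfd / tp   # MgC/yr
    soilC <- (sum(pt[i] == 1) * px * peatEF +
              sum(mg[i] == 1) * px * mangEF) / tp
    cells[[k]] <- data.frame(
      zone = zoneNames[[parts[1]]], permit = permitNames[[parts[2]]],
      type = typeLab, areaDisturbed = length(i) * px / tp,
      regrowth = 0, grossC = grossC + soilC, seqC = 0,
      stringsAsFactors = FALSE)
  }
  cells <- do.call(rbind, cells)

  # regrowth: allocate gain pixels to zone x permit, sequestration by type
  gsel <- which(gn > 0)
  if (length(gsel)) {
    scale <- tp / cfg@gainSourceYears
    gkey <- paste(zn[gsel], pm[gsel], sep = "|")
    for (k in unique(gkey)) {
      i <- gsel[gkey == k]
      parts <- strsplit(k, "|", fixed = TRUE)[[1L]]
      permitLab <- permitNames[[parts[2]]]
      rate <- switch(permitLab, HTI = par$sfr_fiber, HGU = par$sfr_oilpalm,
                     par$sfr_native)
      arHa <- length(i) * px * scale
      seqC <- arHa * rate * accumYears / tp
      zoneLab <- zoneNames[[parts[1]]]
      hit <- which(cells$zone == zoneLab & cells$permit == permitLab)
      if (length(hit)) {
        w <- cells$areaDisturbed[hit] / sum(cells$areaDisturbed[hit])
        cells$regrowth[hit] <- cells$regrowth[hit] + w * arHa / tp
        cells$seqC[hit] <- cells$seqC[hit] + w * seqC
      } else {
        cells <- rbind(cells, data.frame(
          zone = zoneLab, permit = permitLab, type = "Regrowth only",
          areaDisturbed = 0, regrowth = arHa / tp, grossC = 0, seqC = seqC,
          stringsAsFactors = FALSE))
      }
    }
  }

  # logging felling/skidding/products + post-logging sequestration on the
  # concession's skidding/felling row
  asl <- activity@asl
  vol <- if (is.na(activity@harvestVolume)) 0 else activity@harvestVolume
  fellC <- asl * par$felling_ef + asl * par$skidding_ef +
    vol * par$wood_density * par$carbon_fraction *
      productEmittedFraction(par$product_half_life, tp)
  seqSl <- asl * tp * par$sfsl * accumYears / tp
  slRow <- data.frame(zone = "HP/HPT", permit = "HA",
                      type = "Skidding/Felling", areaDisturbed = asl,
                      regrowth = 0, grossC = fellC, seqC = seqSl,
                      stringsAsFactors = FALSE)
  cells <- rbind(cells, slRow)

  toTg <- MGC_TO_CO2 / 1e6
  data.frame(zone = cells$zone, permit = cells$permit, type = cells$type,
             areaDisturbed = cells$areaDisturbed, regrowth = cells$regrowth,
             gross = cells$grossC * toTg, seq = cells$seqC * toTg,
             stringsAsFactors = FALSE)
}

#' Run the full accounting pipeline on a synthetic jurisdiction
#'
#' Executes every stage end to end: landscape generation, footprint
#' sampling, ANOVA/Tukey stratum evaluation, stratum-mean fitting and
#' benchmark map construction, activity extraction (loss cross-tab,
#' haul-road relabelling via the morphological width rule, gain
#' annualization, logging-record summarization), deterministic flux
#' computation, Monte Carlo uncertainty propagation, and ledger assembly.
#' Every stage is driven by the config seed, so a fixed config yields
#' identical outputs.
#'
#' @param config a \linkS4class{SyntheticConfig}
#' @param params parameter table
#' @param nPerStratum footprints per stratum
#' @param noiseCV footprint noise level
#' @param nMC Monte Carlo iterations
#' @param attribution also run group-wise uncertainty attribution
#'   (re-runs the Monte Carlo once per group)
#' @return list with landscape, footprints, stratification, strata,
#'   benchmarkMap, activity, flux, mc, ledger, attribution (or NULL) and
#'   a manifest (seed, sizes, parameter hash)
#' @export
runPipeline <- function(config = SyntheticConfig(),
                        params = defaultParameters(),
                        nPerStratum = 300, noiseCV = 0.20, nMC = 2e4,
                        attribution = FALSE) {
  land <- generateLandscape(config, params)
  fp <- generateFootprints(land, nPerStratum = nPerStratum,
                           noiseCV = noiseCV)
  strat <- evaluateStrata(fp, by = "stratum")
  strata <- lumpedStratumMeans(fp, strat)
  bmap <- buildBenchmarkMap(landscapeRaster(land, "stratum"), strata)

  lossYear <- landscapeRaster(land, "lossYear")
  roads <- classifyLoggingRoads(lossYear, landscapeRaster(land, "concession"))
  att <- gridValues(landscapeRaster(land, "attribution"))
  attFixed <- att
  attFixed[gridValues(roads) == 1L] <- 5L          # road label wins
  attR <- RasterGrid(attFixed, pixelSize = pixelSize(lossYear))

  afd <- extractLoss(lossYear, landscapeRaster(land, "stratum"), attR,
                     period = seq_len(config@tp))
  ly <- gridValues(lossYear)
  px <- pixelAreaHa(lossYear)
  awd <- c(peat = sum(ly > 0 & gridValues(landscapeRaster(land, "peat")) == 1) * px,
           mangrove = sum(ly > 0 &
                          gridValues(landscapeRaster(land, "mangrove")) == 1) * px)
  ar <- annualizeGain(landscapeRaster(land, "gain"),
                      landscapeRaster(land, "permit"),
                      sourceYears = config@gainSourceYears,
                      refYears = config@tp)
  recs <- generateLoggingRecords(config)
  logSum <- summarizeLoggingRecords(recs, tp = config@tp,
                                    nPermits = config@nPermits,
                                    completeness = config@completeness)
  activity <- ActivitySummary(afd = afd, awd = awd, ar = ar,
                              asl = logSum$asl,
                              harvestVolume = as.numeric(logSum$volume),
                              annualLoss = attr(afd, "annualLoss"),
                              tp = config@tp)
  flux <- computeFlux(activity, strata, params)
  mc <- runMonteCarlo(activity, strata, params, n = nMC,
                      seed = config@seed + 3L)
  attr <- if (attribution)
    attributeUncertainty(activity, strata, params, n = nMC,
                         seed = config@seed + 4L) else NULL
  ledger <- buildLedger(.ledgerCells(land, strata, activity, params))
  manifest <- list(seed = config@seed,
                   grid = c(config@nrow, config@ncol),
                   tp = config@tp, nFootprints = nrow(fp), nMC = nMC,
                   nStrataFinal = length(retainedStrata(strat)),
                   parameterHash = sum(params$value * seq_len(nrow(params))),
                   version = as.character(utils::packageVersion("juriflux")))
  list(landscape = land, footprints = fp, stratification = strat,
       strata = strata, benchmarkMap = bmap, activity = activity,
       flux = flux, mc = mc, ledger = ledger, attribution = attr,
       manifest = manifest)
}
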