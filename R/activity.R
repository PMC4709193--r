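#' Annualized activity data for the gain-loss equation
#'
#' Holds the activity-side quantities of the flux equation: forest area
#' lost over the reference period per biomass stratum and disturbance
#' attribution (AFd_h), wetland forest area lost by soil type (AWd),
#' regrowth area by type (Ar), the annual legal logging rate (Asl) with
#' harvest volume, and the annual loss series used for trend testing.
#'
#' @slot afd data.frame(stratum, type, ha): forest area lost over the
#'   period, cross-tabulated by stratum and disturbance attribution;
#'   attribution "logging_road" marks haul-road loss
#' @slot awd named numeric, ha of wetland forest lost over the period
#'   (names in peat/mangrove)
#' @slot ar named numeric, ha of regrowth over the period by type
#'   (fiber/oilpalm/native)
#' @slot asl annual legally logged area, ha/yr
#' @slot harvestVolume annual harvest volume, m3/yr (NA if unrecorded)
#' @slot annualLoss ha lost per year, length tp
#' @slot tp reference period length, years
#' @export
setClass("ActivitySummary",
  representation(afd = "data.frame", awd = "numeric", ar = "numeric",
                 asl = "numeric", harvestVolume = "numeric",
                 annualLoss = "numeric", tp = "numeric"))

setValidity("ActivitySummary", function(object) {
  msg <- NULL
  if (object@tp < 1) msg <- c(msg, "tp must be >= 1")
  if (any(object@afd$ha < 0) || any(object@awd < 0) || any(object@ar < 0) ||
      any(object@asl < 0) || any(object@annualLoss < 0))
    msg <- c(msg, "areas must be non-negative")
  if (length(object@annualLoss) &&
      !isTRUE(all.equal(sum(object@annualLoss), sum(object@afd$ha))))
    msg <- c(msg, "annual loss series must sum to total loss area")
  if (sum(object@awd) > sum(object@afd$ha) + 1e-6)
    msg <- c(msg, "wetland loss cannot exceed total loss")
  if (is.null(msg)) TRUE else msg
})

#' Construct an ActivitySummary
#' @param afd data.frame(stratum, type, ha)
#' @param awd named numeric (peat, mangrove), ha over period
#' @param ar named numeric (fiber, oilpalm, native), ha over period
#' @param asl annual logged area, ha/yr
#' @param harvestVolume annual harvest volume, m3/yr
#' @param annualLoss ha/yr per year of the period
#' @param tp reference period, years
#' @export
ActivitySummary <- function(afd, awd = c(peat = 0, mangrove = 0),
                            ar = c(fiber = 0, oilpalm = 0, native = 0),
                            asl = 0, harvestVolume = NA_real_,
                            annualLoss = numeric(), tp = 10) {
  new("ActivitySummary", afd = afd, awd = awd, ar = ar, asl = asl,
      harvestVolume = harvestVolume, annualLoss = annualLoss, tp = tp)
}

setMethod("show", "ActivitySummary", function(object) {
  cat(sprintf("ActivitySummary over tp = %g yr\n", object@tp))
  cat(sprintf("  forest loss: %.1f ha (%.1f ha/yr) in %d stratum x type cells\n",
              sum(object@afd$ha), sum(object@afd$ha) / object@tp,
              nrow(object@afd)))
  cat(sprintf("  wetland loss: peat %.1f ha, mangrove %.1f ha\n",
              object@awd[["peat"]], object@awd[["mangrove"]]))
  cat(sprintf("  regrowth: %.1f ha; logging: %.1f ha/yr\n",
              sum(object@ar), object@asl))
})

.knownAttributions <- c("oil_palm", "agriculture", "fiber", "mining",
                        "logging_road")

#' Cross-tabulate forest loss by stratum and disturbance attribution
#'
#' Converts loss pixels within the reference period into AFd_h: pixel
#' counts times pixel area, split by biomass stratum and disturbance
#' attribution.  The loss-year band uses 0 = no loss and 1..tp = year
#' index within the reference period; loss outside \code{period} is
#' excluded.
#'
#' @param lossYear \linkS4class{RasterGrid} of loss-year indices
#' @param stratum \linkS4class{RasterGrid} of stratum ids (0 = non-forest)
#' @param attribution \linkS4class{RasterGrid} of disturbance codes, or a
#'   character-coded matrix via \code{attrCodes}
#' @param period integer years (indices) to include, default all years
#' @param attrCodes named integer vector mapping codes in
#'   \code{attribution} to attribution labels
#' @return data.frame(stratum, type, ha) plus the annual loss series as
#'   attribute "annualLoss"
#' @export
extractLoss <- function(lossYear, stratum, attribution,
                        period = NULL,
                        attrCodes = stats::setNames(seq_along(.knownAttributions),
                                                    .knownAttributions)) {
  checkAligned(lossYear, stratum, attribution)
  ly <- gridValues(lossYear)
  if (is.null(period)) period <- seq_len(max(0, max(ly)))
  px <- pixelAreaHa(lossYear)
  sel <- ly %in% period & ly > 0
  codes <- gridValues(attribution)[sel]
  unknown <- setdiff(unique(codes), c(0, unname(attrCodes)))
  if (length(unknown))
    stop("unknown attribution codes: ", paste(unknown, collapse = ", "))
  lab <- names(attrCodes)[match(codes, attrCodes)]
  st <- gridValues(stratum)[sel]
  if (!length(st)) {
    afd <- data.frame(stratum = integer(), type = character(), ha = numeric())
    attr(afd, "annualLoss") <- rep(0, length(period))
    return(afd)
  }
  tab <- as.data.frame(table(stratum = st, type = lab),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, ]
  afd <- data.frame(stratum = as.integer(tab$stratum), type = tab$type,
                    ha = tab$Freq * px, stringsAsFactors = FALSE)
  ann <- sapply(period, function(y) sum(ly == y) * px)
  attr(afd, "annualLoss") <- ann
  afd
}

#' Annualize forest gain onto the reference period and type it by permit
#'
#' When the gain band covers a longer source period than the reference
#' period, the same annual gain rate is assumed:
#' Ar(ref) = total gain area x (ref length / source length).  Gain pixels
#' inside a fiber permit are typed fiber, inside an oil-palm permit oil
#' palm, all others native regrowth.
#'
#' @param gain binary \linkS4class{RasterGrid} of gain pixels
#' @param permit \linkS4class{RasterGrid} of permit codes (see
#'   \code{permitCodes})
#' @param sourceYears length of the gain-band source period (years)
#' @param refYears length of the reference period (years)
#' @param permitCodes named integer vector with at least fiber and oilpalm
#' @return named numeric: ha attributed to the reference period by type
#' @export
annualizeGain <- function(gain, permit, sourceYears, refYears,
                          permitCodes = c(fiber = 2L, oilpalm = 1L)) {
  stopifnot(sourceYears > 0)
  checkAligned(gain, permit)
  g <- gridValues(gain) > 0
  px <- pixelAreaHa(gain)
  scale <- refYears / sourceYears
  pm <- gridValues(permit)
  fiber <- sum(g & pm == permitCodes[["fiber"]]) * px * scale
  oilpalm <- sum(g & pm == permitCodes[["oilpalm"]]) * px * scale
  native <- sum(g) * px * scale - fiber - oilpalm
  c(fiber = fiber, oilpalm = oilpalm, native = native)
}

#' Label haul-road loss inside logging concessions
#'
#' Loss pixels inside licensed logging concessions that form corridors
#' three pixels wide or less (90 m on a 30 m grid) are labelled logging
#' roads; wider loss patches (or the wide cores of mixed patches) are
#' labelled conversion.  The width rule is applied as a morphological
#' opening with a 4x4 box structuring element: whatever the opening
#' removes is at most 3 pixels wide and becomes road.
#'
#' @param lossYear \linkS4class{RasterGrid} of loss-year indices
#' @param concession binary \linkS4class{RasterGrid} concession mask
#' @return \linkS4class{RasterGrid}: 0 = no in-concession loss,
#'   1 = road, 2 = conversion
#' @export
classifyLoggingRoads <- function(lossYear, concession) {
  checkAligned(lossYear, concession)
  loss <- gridValues(lossYear) > 0
  inside <- loss & gridValues(concession) > 0
  kern <- matrix(1, 4, 4)
  opened <- EBImage::opening(EBImage::Image(inside * 1), kern)
  opened <- as.matrix(EBImage::imageData(opened)) > 0
  lab <- matrix(0L, nrow(inside), ncol(inside))
  lab[inside & !opened] <- 1L   # removed by opening: <= 3 px wide
  lab[inside & opened] <- 2L
  RasterGrid(lab, pixelSize = pixelSize(lossYear))
}

#' Summarize government logging records into an annual harvest rate
#'
#' Records are permit-year rows with harvested area (ha) and volume (m3).
#' Completeness is the fraction of all permit-years with records.  Under
#' the default "observed-mean" convention the mean per recorded
#' permit-year is multiplied by the total number of permit-years and
#' divided by the period length (unbiased when recorded permit-years are
#' representative); "proportional-total" divides the recorded total by
#' the completeness fraction instead (identical when completeness is the
#' recorded fraction).
#'
#' @param records data.frame(permit, year, ha, volume_m3)
#' @param tp reference period, years
#' @param nPermits number of permits in force
#' @param completeness fraction of permit-years with records
#' @param scaleUp "observed-mean" or "proportional-total"
#' @return list(asl = ha/yr, volume = m3/yr, nRecords)
#' @export
summarizeLoggingRecords <- function(records, tp, nPermits,
                                    completeness = 1,
                                    scaleUp = c("observed-mean",
                                                "proportional-total")) {
  scaleUp <- match.arg(scaleUp)
  if (nrow(records) == 0L) {
    warning("no logging records; Asl = 0")
    return(list(asl = 0, volume = 0, nRecords = 0L))
  }
  totalPY <- nPermits * tp
  if (scaleUp == "observed-mean") {
    asl <- mean(records$ha) * totalPY / tp
    vol <- if (all(is.na(records$volume_m3))) NA_real_ else
      mean(records$volume_m3, na.rm = TRUE) * totalPY / tp
  } else {
    asl <- sum(records$ha) / completeness / tp
    vol <- if (all(is.na(records$volume_m3))) NA_real_ else
      sum(records$volume_m3, na.rm = TRUE) / completeness / tp
  }
  if (any(is.na(records$volume_m3)) && !all(is.na(records$volume_m3)))
    attr(vol, "partial") <- TRUE
  list(asl = asl, volume = vol, nRecords = nrow(records))
}

#' Ordinary least-squares trend test on an annual activity series
#'
#' Regresses annual area on the year index and reports slope, R^2 and the
#' overall F test, as used to check for a linear trend in loss or logging
#' activity over the reference period.
#'
#' @param series numeric vector of annual areas (ha/yr)
#' @return list(slope, intercept, r2, f, df1, df2, p)
#' @export
trendTest <- function(series) {
  if (length(series) < 3L) stop("series must have length >= 3")
  if (stats::sd(series) < 1e-12 * (abs(mean(series)) + 1))   # constant series
    return(list(slope = 0, intercept = mean(series), r2 = 0,
                f = 0, df1 = 1, df2 = length(series) - 2L, p = 1))
  year <- seq_along(series)
  fit <- stats::lm(series ~ year)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = sm$r.squared,
       f = unname(fstat[1]), df1 = unname(fstat[2]), df2 = unname(fstat[3]),
       p = unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)))
}
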