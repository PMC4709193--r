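#' Zone x permit x disturbance-type flux ledger
#'
#' Tabular summary of emissions and area change by spatial-plan zone
#' (APL / HP-HPT / HL), permit type (HGU, PKP2B, HA, HTI, none) and
#' disturbance type, with gross emissions, gross sequestration, net flux
#' (Tg CO2/yr) and percent-of-net shares, plus a totals row.
#'
#' @slot rows data.frame of ledger rows (sorted by zone, then net
#'   descending)
#' @slot totals one-row data.frame of column totals
#' @export
setClass("FluxLedger",
  representation(rows = "data.frame", totals = "data.frame"))

setValidity("FluxLedger", function(object) {
  r <- object@rows
  msg <- NULL
  if (any(abs(r$net - (r$gross - r$seq)) > 0.021))
    msg <- c(msg, "row net must equal gross - sequestration (within rounding)")
  if (nrow(r) && abs(sum(r$percentNet) - 100) > 0.5)
    msg <- c(msg, "percent column must sum to 100 (within rounding)")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "FluxLedger", function(object) {
  cat("FluxLedger (Tg CO2/yr):\n")
  r <- rbind(object@rows, object@totals)
  print(data.frame(zone = r$zone, permit = r$permit, type = r$type,
                   gross = round(r$gross, 2), seq = round(r$seq, 2),
                   net = round(r$net, 2), pct = round(r$percentNet, 1)),
        row.names = FALSE)
})

#' @describeIn FluxLedger ledger rows
#' @param x a FluxLedger
#' @export
ledgerRows <- function(x) x@rows

#' @describeIn FluxLedger totals row
#' @export
ledgerTotals <- function(x) x@totals

#' Build a flux ledger from attribution cells
#'
#' Input rows carry zone, permit and disturbance-type labels with their
#' areas and gross emission / sequestration fluxes (Tg CO2/yr).  Net is
#' taken from the input when present (reported ledgers carry
#' independently rounded nets), otherwise computed as gross - seq.
#' Rows are sorted by zone then net descending, percent shares are
#' computed on net, and a totals row is appended.
#'
#' @param cells data.frame with columns zone, permit, type, gross, seq,
#'   optionally net, landArea, forestArea, areaDisturbed, regrowth
#' @return a \linkS4class{FluxLedger}
#' @export
buildLedger <- function(cells) {
  need <- c("zone", "permit", "type", "gross", "seq")
  miss <- setdiff(need, names(cells))
  if (length(miss)) stop("unlabeled ledger cell: missing column(s) ",
                         paste(miss, collapse = ", "))
  if (any(is.na(cells$zone) | is.na(cells$type)))
    stop("unlabeled ledger cell: NA zone or type")
  r <- cells
  for (cn in c("landArea", "forestArea", "areaDisturbed", "regrowth"))
    if (!cn %in% names(r)) r[[cn]] <- NA_real_
  if (!"net" %in% names(r) || all(is.na(r$net))) r$net <- r$gross - r$seq
  r$percentNet <- 100 * r$net / sum(r$net)
  r <- r[order(r$zone, -r$net), , drop = FALSE]
  tot <- data.frame(zone = "Total", permit = "", type = "",
                    gross = sum(r$gross), seq = sum(r$seq),
                    net = sum(r$net),
                    landArea = sum(r$landArea), forestArea = sum(r$forestArea),
                    areaDisturbed = sum(r$areaDisturbed),
                    regrowth = sum(r$regrowth),
                    percentNet = sum(r$percentNet),
                    stringsAsFactors = FALSE)
  cols <- c("zone", "permit", "type", "landArea", "forestArea",
            "areaDisturbed", "regrowth", "gross", "seq", "net", "percentNet")
  new("FluxLedger", rows = r[, cols], totals = tot[, cols])
}

#' Reported Berau jurisdictional ledger, 2001-2010
#'
#' The published zone x permit x disturbance emissions ledger for the
#' Regency of Berau (East Kalimantan), as printed: twelve rows with areas
#' (ha, ha/yr), gross emissions, gross sequestration and net emissions in
#' Tg CO2/yr, and the printed percent-of-net shares.
#'
#' @return data.frame of ledger cells suitable for
#'   \code{\link{buildLedger}}
#' @export
berauLedgerCells <- function() {
  path <- system.file("extdata", "berau_ledger.csv", package = "juriflux",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Reported Berau flux components, 2001-2010
#'
#' Named vector of the published jurisdiction-level quantities (Tg CO2/yr
#' unless stated): total gross emissions and sequestration, the forest
#' loss, tree-biomass, wetland-soil and logging components (felling,
#' skidding, haul roads, wood products, post-logging regrowth), the year
#' 2000 forest carbon stock (TgC) and CI half-widths.
#'
#' @return named numeric vector
#' @export
berauReported <- function() {
  path <- system.file("extdata", "berau_reported.csv", package = "juriflux",
                      mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(d$value, d$name)
}

#' Derived percentage shares and ratios from a jurisdictional ledger
#'
#' Computes the headline shares of a jurisdictional flux report: the
#' forest-loss share of gross emissions, regrowth offsets of forest-loss
#' and logging emissions, the APL-zone share of net emissions, the
#' oil-palm share within APL, the production-forest subtotal, the largest
#' single row's share, the annual stock-loss rate, and the gross
#' emissions : sequestration ratio.
#'
#' @param ledger a \linkS4class{FluxLedger}
#' @param reported named vector as from \code{\link{berauReported}}
#'   (components not derivable from the ledger alone)
#' @return named numeric vector (percentages in percent, ratio unitless)
#' @export
derivedShares <- function(ledger, reported) {
  r <- ledgerRows(ledger)
  tot <- ledgerTotals(ledger)
  apl <- r$zone == "APL"
  prod <- r$zone == "HP/HPT"
  oilApl <- apl & r$type == "Oil Palm"
  oilHgu <- oilApl & r$permit == "HGU"
  stockLossC <- reported[["biomass_loss_gross"]] / MGC_TO_CO2
  c(forest_loss_share = 100 * reported[["forest_loss_gross"]] /
      reported[["gross_total"]],
    regrowth_offset = 100 * reported[["regrowth_seq"]] /
      reported[["forest_loss_gross"]],
    logging_offset = 100 * reported[["logging_regrowth_seq"]] /
      reported[["logging_gross"]],
    apl_share = 100 * sum(r$net[apl]) / tot$net,
    oilpalm_apl_share = 100 * sum(r$net[oilApl]) / sum(r$net[apl]),
    production_subtotal = sum(r$net[prod]),
    oilpalm_hgu_share = 100 * sum(r$net[oilHgu]) / tot$net,
    stock_loss_rate = 100 * stockLossC / reported[["stock_2000_tgc"]],
    emissions_seq_ratio = tot$gross / tot$seq)
}
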