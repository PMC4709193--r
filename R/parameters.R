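#' Uncertainty categories for emission-equation parameters
#'
#' Parameters without enough local data for an empirical standard error are
#' assigned a default percent error at the 95% confidence level by
#' category: Very High 100%, High 50%, Medium 20%, Low 10%.  The percent
#' error is converted to a standard error of the mean by dividing by 1.96.
#'
#' @format named numeric vector of percent errors at the 95% CI
#' @export
uncertaintyCategories <- c(VeryHigh = 100, High = 50, Medium = 20, Low = 10)

#' Convert a parameter specification to its sampling SEM
#'
#' Category mode: SEM = mean * (percent error / 100) / 1.96 (central limit
#' conversion of a 95% half-width to a standard error).  Empirical mode:
#' the supplied SEM is passed through unchanged.
#'
#' @param mean parameter mean
#' @param mode "category" or "empirical"
#' @param category one of "VeryHigh", "High", "Medium", "Low" (category mode)
#' @param sem empirical standard error of the mean (empirical mode)
#' @return the SEM used for Monte Carlo sampling
#' @export
assignSem <- function(mean, mode = c("category", "empirical"),
                      category = NA_character_, sem = NA_real_) {
  mode <- match.arg(mode)
  if (mode == "empirical") {
    if (is.na(sem)) stop("empirical mode requires an SEM")
    if (sem < 0) stop("SEM must be non-negative")
    return(sem)
  }
  if (is.na(category) || !category %in% names(uncertaintyCategories))
    stop("category mode requires a category in ",
         paste(names(uncertaintyCategories), collapse = "/"))
  abs(mean) * (uncertaintyCategories[[category]] / 100) / 1.96
}

#' Default emission-equation parameter table
#'
#' One row per scalar input of the gain-loss flux equation, with its mean,
#' units, uncertainty mode (empirical SEM or a default category), sampling
#' truncation bounds, and the attribution group used for uncertainty
#' source analysis.  Values not printed in a jurisdictional report are
#' literature-plausible defaults; see the methods vignette for rationale.
#'
#' Multiplier rows (mean 1) carry the uncertainty of the activity datasets
#' (loss, wetland-loss, regrowth and logging areas) so that every variable
#' of the flux equation has a defined distribution.
#'
#' @return data.frame with columns name, value, units, mode, category,
#'   sem, lower, upper, group
#' @export
defaultParameters <- function() {
  p <- function(name, value, units, category, group,
                lower = 0, upper = Inf, mode = "category", sem = NA_real_) {
    data.frame(name = name, value = value, units = units, mode = mode,
               category = category, sem = sem, lower = lower, upper = upper,
               group = group, stringsAsFactors = FALSE)
  }
  rbind(
    p("decay_rate",        0.24, "1/yr",      "High",     "Decay"),
    p("product_half_life", 5,    "yr",        "High",     "Decay", lower = 0.5),
    p("root_shoot",        0.37, "fraction",  "Medium",   "Roots",      upper = 1),
    p("necromass_fraction",0.10, "fraction",  "High",     "Necromass",  upper = 1),
    p("burned_fraction",   0.60, "fraction",  "High",     "Fire",       upper = 1),
    p("combustion_completeness", 0.42, "fraction", "High", "Fire",      upper = 1),
    p("charcoal_fraction", 0.08, "fraction",  "VeryHigh", "Fire",       upper = 1),
    p("extraction_fraction", 0.15, "fraction", "High",    "Other",      upper = 1),
    p("wood_density",      0.57, "Mg/m3",     "Low",      "Other"),
    p("carbon_fraction",   0.47, "fraction",  "Low",      "Other",      upper = 1),
    p("felling_ef",        28.3, "MgC/ha",    "Medium",   "Logging"),
    p("skidding_ef",       10.2, "MgC/ha",    "Medium",   "Logging"),
    p("sfsl",              0.368, "MgC/ha/yr", "High",    "Logging"),
    p("sfr_fiber",         9.8,  "MgC/ha/yr", "Medium",   "Regrowth rate"),
    p("sfr_oilpalm",       2.97, "MgC/ha/yr", "Medium",   "Regrowth rate"),
    p("sfr_native",        3.85, "MgC/ha/yr", "Medium",   "Regrowth rate"),
    p("peat_depth_cm",     200,  "cm",        "High",     "Wetland soil carbon"),
    p("peat_c_density",    5,    "MgC/ha/cm", "High",     "Wetland soil carbon"),
    p("drainage_depth_cm", 60,   "cm",        "High",     "Wetland soil carbon"),
    p("peat_loss_fraction", 1.0, "fraction",  "Low",      "Wetland soil carbon", upper = 1),
    p("mangrove_top_stock", 110, "MgC/ha",    "High",     "Wetland soil carbon"),
    p("mangrove_remainder_stock", 250, "MgC/ha", "VeryHigh", "Wetland soil carbon"),
    p("mangrove_top_loss_fraction", 0.75, "fraction", "High", "Wetland soil carbon", upper = 1),
    p("mangrove_remainder_loss_fraction", 0.35, "fraction", "VeryHigh", "Wetland soil carbon", upper = 1),
    p("afd_multiplier",    1, "ratio", "Low",    "Forest loss"),
    p("awd_multiplier",    1, "ratio", "Medium", "Wetland soil carbon"),
    p("ar_multiplier",     1, "ratio", "High",   "Regrowth area"),
    p("asl_multiplier",    1, "ratio", "Medium", "Logging")
  )
}

.checkParameterTable <- function(params) {
  need <- c("name", "value", "mode", "category", "sem", "lower", "upper", "group")
  miss <- setdiff(need, names(params))
  if (length(miss)) stop("parameter table lacks columns: ",
                         paste(miss, collapse = ", "))
  bad <- params$mode == "category" & !params$category %in% names(uncertaintyCategories)
  bad <- bad | (params$mode == "empirical" & is.na(params$sem))
  if (any(bad)) stop("unresolvable parameter spec for: ",
                     paste(params$name[bad], collapse = ", "))
  if (anyDuplicated(params$name)) stop("duplicate parameter names")
  invisible(TRUE)
}

#' Sampling SEM for every row of a parameter table
#' @param params parameter table (see \code{\link{defaultParameters}})
#' @return named numeric vector of SEMs
#' @export
parameterSems <- function(params) {
  .checkParameterTable(params)
  sems <- mapply(function(v, m, cat, s) assignSem(v, m, cat, s),
                 params$value, params$mode, params$category, params$sem)
  stats::setNames(as.numeric(sems), params$name)
}

#' Write / read the flat parameter file
#'
#' Tab-separated key-value text, one line per parameter, with the columns
#' of \code{\link{defaultParameters}}.
#'
#' @param params parameter table
#' @param path file path
#' @export
writeParameterFile <- function(params, path) {
  .checkParameterTable(params)
  utils::write.table(params, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeParameterFile
#' @export
readParameterFile <- function(path) {
  params <- utils::read.delim(path, stringsAsFactors = FALSE)
  params$category <- as.character(params$category)
  .checkParameterTable(params)
  params
}

# Truncated-normal draws by redraw: out-of-range draws are resampled, so
# the retained distribution is the normal conditioned on [lower, upper].
.rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf,
                        maxRetry = 1000L, what = "parameter") {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  tries <- 0L
  while (length(bad)) {
    tries <- tries + 1L
    if (tries > maxRetry)
      stop("could not draw valid values for ", what,
           " within the retry budget")
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
  }
  x
}

#' Draw Monte Carlo samples for every parameter
#'
#' Normal distributions truncated to each parameter's physical bounds
#' (non-negative for areas and rates, [0, 1] for fractions); out-of-range
#' draws are redrawn.
#'
#' @param params parameter table
#' @param n number of iterations
#' @param fixGroups character vector of attribution groups to hold at their
#'   means (used by \code{\link{attributeUncertainty}})
#' @return list of numeric vectors of length n, named by parameter
#' @export
drawParameters <- function(params, n, fixGroups = character()) {
  sems <- parameterSems(params)
  ord <- order(params$name)   # canonical draw order: independent of row order
  out <- vector("list", nrow(params))
  names(out) <- params$name[ord]
  for (j in seq_along(ord)) {
    i <- ord[j]
    sd <- if (params$group[i] %in% fixGroups) 0 else sems[[i]]
    out[[j]] <- .rtruncnorm(n, params$value[i], sd,
                            params$lower[i], params$upper[i],
                            what = params$name[i])
  }
  out
}

.paramVector <- function(params) stats::setNames(params$value, params$name)
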