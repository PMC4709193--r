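#' Outcome of ANOVA/Tukey stratum evaluation
#'
#' Records the lump/split decisions taken while evaluating candidate
#' biomass strata against footprint samples, the final assignment of every
#' sample, and the one-way ANOVA statistics of the final stratification.
#'
#' @slot assignment factor of final stratum labels, one per input sample
#' @slot strata character vector of retained stratum labels
#' @slot f overall one-way ANOVA F statistic of the final stratification
#' @slot df1,df2 numerator / denominator degrees of freedom
#' @slot p overall ANOVA p value
#' @slot tukey data.frame of final pairwise Tukey comparisons
#' @slot log character vector describing each lumping step
#' @export
setClass("StratificationResult",
  representation(assignment = "factor", strata = "character",
                 f = "numeric", df1 = "numeric", df2 = "numeric",
                 p = "numeric", tukey = "data.frame", log = "character"))

setValidity("StratificationResult", function(object) {
  if (!all(levels(object@assignment) %in% object@strata))
    return("every sample must map to a retained stratum")
  TRUE
})

setMethod("show", "StratificationResult", function(object) {
  cat(sprintf("StratificationResult: %d strata retained, F(%g, %g) = %.2f, P = %.3g\n",
              length(object@strata), object@df1, object@df2,
              object@f, object@p))
  if (length(object@log)) cat(paste0("  ", object@log, "\n"), sep = "")
})

#' @describeIn StratificationResult final stratum label per sample
#' @param x a StratificationResult
#' @export
strataAssignment <- function(x) x@assignment

#' @describeIn StratificationResult retained stratum labels
#' @export
retainedStrata <- function(x) x@strata

.anovaStats <- function(biomass, labels) {
  labels <- factor(labels)
  if (nlevels(labels) < 2L)
    return(list(f = NA_real_, df1 = NA_real_, df2 = NA_real_, p = NA_real_))
  fit <- stats::aov(biomass ~ labels)
  tab <- summary(fit)[[1L]]
  list(f = tab[1, "F value"], df1 = tab[1, "Df"], df2 = tab[2, "Df"],
       p = tab[1, "Pr(>F)"], fit = fit)
}

#' Evaluate candidate biomass strata, lumping non-significant pairs
#'
#' Candidate strata are tested with one-way ANOVA and Tukey's multiple
#' comparison test on footprint biomass samples.  While any retained pair
#' fails to differ significantly (alpha = 0.05), the non-significant pair
#' with the smallest absolute mean difference is lumped and the test is
#' re-run, so the final partition is a coarsening of the candidates in
#' which all retained pairs differ significantly.
#'
#' @param samples data.frame with columns biomass (MgC/ha) and the label
#'   column named by \code{by}
#' @param by name of the candidate stratum label column
#' @param alpha significance level for Tukey pairwise tests
#' @return a \linkS4class{StratificationResult}
#' @export
evaluateStrata <- function(samples, by = "stratum", alpha = 0.05) {
  labels <- factor(as.character(samples[[by]]))
  if (nlevels(labels) < 2L) stop("need at least 2 candidate strata")
  if (any(table(labels) < 2L)) stop("each candidate stratum needs >= 2 samples")
  biomass <- samples$biomass
  log <- character()
  if (stats::var(biomass) == 0) {
    lab <- factor(rep(paste(levels(labels), collapse = "+"), length(biomass)))
    return(new("StratificationResult", assignment = lab,
               strata = levels(lab), f = NA_real_, df1 = NA_real_,
               df2 = NA_real_, p = NA_real_,
               tukey = data.frame(),
               log = "degenerate: zero variance, all strata lumped"))
  }
  repeat {
    st <- .anovaStats(biomass, labels)
    if (nlevels(labels) < 2L) {
      tk <- data.frame()
      break
    }
    hsd <- stats::TukeyHSD(st$fit, conf.level = 1 - alpha)$labels
    tk <- data.frame(pair = rownames(hsd), diff = hsd[, "diff"],
                     p = hsd[, "p adj"], row.names = NULL,
                     stringsAsFactors = FALSE)
    ns <- tk[tk$p > alpha, , drop = FALSE]
    if (nrow(ns) == 0L) break
    merge <- ns[which.min(abs(ns$diff)), ]
    ab <- strsplit(merge$pair, "-", fixed = TRUE)[[1L]]
    newLab <- paste(sort(ab), collapse = "+")
    log <- c(log, sprintf("lumped %s and %s (p = %.3f, |diff| = %.2f)",
                          ab[1], ab[2], merge$p, abs(merge$diff)))
    lv <- levels(labels)
    lv[lv %in% ab] <- newLab
    levels(labels) <- lv
  }
  st <- .anovaStats(biomass, labels)
  new("StratificationResult", assignment = labels,
      strata = levels(labels),
      f = if (is.null(st$f)) NA_real_ else st$f,
      df1 = st$df1, df2 = st$df2, p = st$p, tukey = tk, log = log)
}

#' Compare competing stratifications by ANOVA F
#'
#' Each stratification is a label column assigning every sample a class;
#' the one-way ANOVA F statistic of biomass on the labels is the ranking
#' criterion (higher F = stronger stratification).  A stratification with
#' a single class has no defined F and is reported as NA.
#'
#' @param samples data.frame with a biomass column and one column per
#'   stratification
#' @param columns character vector of stratification column names
#' @return data.frame(stratification, f, df1, df2, p) sorted by
#'   descending F (NAs last)
#' @export
compareStratifications <- function(samples, columns) {
  res <- lapply(columns, function(cn) {
    st <- .anovaStats(samples$biomass, samples[[cn]])
    data.frame(stratification = cn, f = st$f, df1 = st$df1, df2 = st$df2,
               p = st$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(-out$f, na.last = TRUE), , drop = FALSE]
}

#' Per-stratum mean aboveground carbon with SEM
#'
#' Arithmetic mean, SEM = sd/sqrt(n) and sample count per final stratum.
#' Strata with fewer than 2 samples are excluded with a warning.
#'
#' @param samples data.frame with columns biomass and the label column
#'   named by \code{by}
#' @param by stratum label column name
#' @return data.frame(stratum, mean, sem, n)
#' @export
fitStratumMeans <- function(samples, by = "stratum") {
  labels <- as.character(samples[[by]])
  counts <- table(labels)
  small <- names(counts)[counts < 2L]
  if (length(small)) {
    warning("excluding strata with < 2 samples: ",
            paste(small, collapse = ", "))
    keep <- !labels %in% small
    samples <- samples[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  if (!nrow(samples)) stop("no stratum has >= 2 samples")
  agg <- do.call(rbind, lapply(split(samples$biomass, labels), function(x) {
    data.frame(mean = mean(x), sem = stats::sd(x) / sqrt(length(x)),
               n = length(x))
  }))
  data.frame(stratum = rownames(agg), mean = agg$mean, sem = agg$sem,
             n = agg$n, row.names = NULL, stringsAsFactors = FALSE)
}

#' Build the stratify-and-multiply benchmark biomass map
#'
#' Every forested pixel receives its stratum's mean aboveground carbon
#' stock; non-forest pixels (stratum id 0) receive NA (written as the
#' raster's no-data value).
#'
#' @param stratum \linkS4class{RasterGrid} of stratum ids (0 = non-forest)
#' @param strata data.frame(stratum, mean) as from
#'   \code{\link{fitStratumMeans}}
#' @return \linkS4class{RasterGrid} of MgC/ha
#' @export
buildBenchmarkMap <- function(stratum, strata) {
  ids <- gridValues(stratum)
  present <- setdiff(unique(as.vector(ids)), 0)
  unmapped <- setdiff(as.character(present), as.character(strata$stratum))
  if (length(unmapped))
    stop("no stratum record for raster id(s): ",
         paste(unmapped, collapse = ", "))
  lut <- stats::setNames(strata$mean, as.character(strata$stratum))
  out <- matrix(NA_real_, nrow(ids), ncol(ids))
  fore <- ids != 0
  out[fore] <- lut[as.character(ids[fore])]
  RasterGrid(out, pixelSize = pixelSize(stratum))
}
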