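# Per-locus methylation summaries: individual means, variability
# classification, high/low phenotype calls, distribution shape.

#' Per-individual mean methylation at a locus
#'
#' Arithmetic mean over the locus's CpGs, one value per individual, ordered
#' stably by individual id.
#'
#' @param mt a \linkS4class{MethylationTable}.
#' @param locus locus id.
#' @return Named numeric vector of means (percent).
#' @export
individualMeans <- function(mt, locus) {
  d <- mt@data[mt@data$locus == locus, , drop = FALSE]
  if (!nrow(d)) stop("unknown locus: ", locus)
  m <- tapply(d$percent, d$individual, mean)
  m <- m[order(names(m))]
  setNames(as.numeric(m), names(m))
}

#' Classify a locus's methylation variability
#'
#' A locus is \code{variable} if the spread (max minus min) of individual
#' means exceeds the variability threshold (default 10 percentage points).
#' Nonvariable loci are subtyped by their group mean: \code{hypermethylated}
#' (>= \code{hyperMean}), \code{hypomethylated} (<= \code{hypoMean}) or
#' \code{intermediate-nonvariable}. The spread interpretation (range of
#' means, not statistical variance) is configurable via \code{measure}.
#'
#' @param means numeric vector of per-individual means (n >= 2).
#' @param th a \linkS4class{VmThresholds}.
#' @param measure \code{"range"} (default) or \code{"variance"}.
#' @return One of "variable", "hypermethylated", "hypomethylated",
#'   "intermediate-nonvariable".
#' @export
classifyVariability <- function(means, th = vmThresholds(),
                                measure = c("range", "variance")) {
  measure <- match.arg(measure)
  if (length(means) < 2L) stop("need at least 2 individuals")
  spread <- if (measure == "range") diff(range(means)) else var(means)
  if (spread > th@variabilitySpread) return("variable")
  gm <- mean(means)
  if (gm >= th@hyperMean) "hypermethylated"
  else if (gm <= th@hypoMean) "hypomethylated"
  else "intermediate-nonvariable"
}

#' High/low methylation phenotype call
#'
#' High iff the mean exceeds the cutoff strictly; a value exactly at the
#' cutoff is low (high means >60%).
#'
#' @param x methylation mean(s), percent in [0, 100].
#' @param th a \linkS4class{VmThresholds}.
#' @return Character vector "high"/"low".
#' @export
thresholdClassify <- function(x, th = vmThresholds()) {
  if (any(x < 0 | x > 100)) stop("methylation percent outside [0, 100]")
  ifelse(x > th@highLowCutoff, "high", "low")
}

#' Distribution summary of per-individual methylation means
#'
#' Median and quartiles (linear interpolation), the adjusted Fisher-Pearson
#' skewness coefficient G1 = n/((n-1)(n-2)) * sum(((x - mean)/sd)^3), and a
#' normality flag from the Shapiro-Wilk test at the given alpha.
#'
#' @param means numeric vector, n >= 3.
#' @param alpha significance level for the normality flag.
#' @return List: median, q1, q3, skewness, normal (logical), shapiroP.
#' @export
distributionSummary <- function(means, alpha = 0.05) {
  n <- length(means)
  if (n < 3L) stop("need at least 3 values for skewness")
  s <- sd(means)
  skew <- if (s == 0) 0 else
    n / ((n - 1) * (n - 2)) * sum(((means - mean(means)) / s)^3)
  shp <- if (n >= 3 && s > 0 && n <= 5000) shapiro.test(means)$p.value else NA_real_
  list(median = as.numeric(median(means)),
       q1 = as.numeric(quantile(means, 0.25)),
       q3 = as.numeric(quantile(means, 0.75)),
       skewness = skew,
       normal = if (is.na(shp)) NA else shp >= alpha,
       shapiroP = shp)
}
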