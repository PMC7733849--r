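# Genetic-background-effect (GBE) typing from reciprocal hybrids:
# Kruskal-Wallis across B6/BC/CB, Dunn's post hoc pairwise z tests, and the
# maternal / zygotic / maternal+zygotic / none decision table.

#' Kruskal-Wallis test on a list of groups
#'
#' Tie-corrected H on midranks with a chi-square reference (k - 1 df).
#' Degenerate all-identical input returns H = 0, p = 1.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2).
#' @return List with \code{H} and \code{p}.
#' @export
kruskalWallis <- function(groups) {
  stopifnot(length(groups) >= 2L, all(lengths(groups) >= 2L))
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1L) return(list(H = 0, p = 1))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- kruskal.test(x, g)
  list(H = unname(kt$statistic), p = kt$p.value)
}

#' Dunn's post hoc pairwise comparisons on midranks
#'
#' For each pair (i, j), z = (rbar_i - rbar_j) / sqrt(S2 (1/n_i + 1/n_j))
#' with the tie-corrected pooled variance
#' S2 = N(N+1)/12 - sum(t^3 - t) / (12 (N - 1)); two-sided normal p-values
#' adjusted across comparisons (Bonferroni-style multiplication by default).
#'
#' @param groups named list of numeric vectors.
#' @param adjustment "bonferroni" (default), "holm" or "none".
#' @return data.frame with columns pair, z, p, pAdj.
#' @export
dunnPosthoc <- function(groups, adjustment = c("bonferroni", "holm", "none")) {
  adjustment <- match.arg(adjustment)
  k <- length(groups)
  stopifnot(k >= 2L)
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_len(k), lengths(groups))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- lengths(groups)
  ties <- table(x)
  S2 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(k, 2)
  res <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    if (S2 <= 0) return(c(z = 0, p = 1))
    z <- (rbar[i] - rbar[j]) / sqrt(S2 * (1 / n[i] + 1 / n[j]))
    c(z = unname(z), p = 2 * pnorm(-abs(unname(z))))
  })
  nm <- if (is.null(names(groups))) as.character(seq_len(k)) else names(groups)
  out <- data.frame(pair = paste(nm[pairs[1, ]], nm[pairs[2, ]], sep = "-"),
                    z = res["z", ], p = res["p", ],
                    stringsAsFactors = FALSE)
  out$pAdj <- switch(adjustment,
                     bonferroni = pmin(1, out$p * nrow(out)),
                     holm = stats::p.adjust(out$p, "holm"),
                     none = out$p)
  rownames(out) <- NULL
  out
}

#' Classify the genetic-background-effect category of a locus
#'
#' Decision table on the three adjusted Dunn p-values (BC-B6, CB-B6, BC-CB):
#' \itemize{
#'   \item maternal: exactly one of the vs-B6 comparisons significant AND
#'     BC-CB significant;
#'   \item zygotic: both vs-B6 comparisons significant, BC-CB not;
#'   \item maternal+zygotic: both vs-B6 and BC-CB significant;
#'   \item none: anything else (in particular neither vs-B6 significant).
#' }
#' Direction is the sign of the median difference of the shifted hybrid
#' group(s) against B6.
#'
#' @param pBCvB6,pCBvB6,pBCvCB adjusted p-values.
#' @param alpha significance level.
#' @param medians optional named numeric (B6, BC, CB) used for direction.
#' @return List with \code{category} and \code{direction} (hyper/hypo/NA).
#' @export
classifyGbe <- function(pBCvB6, pCBvB6, pBCvCB, alpha = 0.05,
                        medians = NULL) {
  sBC <- pBCvB6 < alpha
  sCB <- pCBvB6 < alpha
  sHH <- pBCvCB < alpha
  category <- if (sBC && sCB && sHH) "maternal+zygotic"
  else if (sBC && sCB) "zygotic"
  else if (xor(sBC, sCB) && sHH) "maternal"
  else "none"
  direction <- NA_character_
  if (!is.null(medians) && category != "none") {
    shifted <- c(if (sBC) medians[["BC"]], if (sCB) medians[["CB"]])
    direction <- if (mean(shifted) > medians[["B6"]]) "hyper" else "hypo"
  }
  list(category = category, direction = direction)
}

#' Per-locus GBE scan over a methylation table
#'
#' Runs Kruskal-Wallis and Dunn's post hoc test per locus on the B6/BC/CB
#' per-individual means and applies the GBE decision table.
#'
#' @param mt a \linkS4class{MethylationTable}.
#' @param groups data.frame with columns \code{individual} and \code{group}
#'   (levels exactly B6, BC, CB).
#' @param alpha significance level.
#' @param adjustment Dunn adjustment passed to \code{\link{dunnPosthoc}}.
#' @return data.frame, one row per locus: H, p, the three adjusted Dunn
#'   p-values, category, direction.
#' @export
gbeScan <- function(mt, groups, alpha = 0.05, adjustment = "bonferroni") {
  stopifnot(setequal(unique(groups$group), c("B6", "BC", "CB")))
  loci <- unique(mt@data$locus)
  out <- lapply(loci, function(lc) {
    m <- individualMeans(mt, lc)
    gl <- lapply(c("B6", "BC", "CB"), function(gp)
      unname(m[intersect(names(m), groups$individual[groups$group == gp])]))
    names(gl) <- c("B6", "BC", "CB")
    stopifnot(all(lengths(gl) >= 2L))
    kw <- kruskalWallis(gl)
    dn <- dunnPosthoc(gl, adjustment = adjustment)
    pget <- function(a, b) {
      hit <- dn$pAdj[dn$pair %in% c(paste(a, b, sep = "-"),
                                    paste(b, a, sep = "-"))]
      hit[1]
    }
    meds <- vapply(gl, median, numeric(1))
    cl <- classifyGbe(pget("BC", "B6"), pget("CB", "B6"), pget("BC", "CB"),
                      alpha = alpha, medians = as.list(meds))
    data.frame(locus = lc, H = kw$H, p = kw$p,
               pBCvB6 = pget("BC", "B6"), pCBvB6 = pget("CB", "B6"),
               pBCvCB = pget("BC", "CB"),
               category = cl$category, direction = cl$direction,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
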