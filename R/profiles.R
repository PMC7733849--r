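# Anchored, strand-aware coverage metaprofiles: element bodies rescaled to a
# fixed pseudolength by exact area-weighted rebinning of the step function,
# with fixed-width unscaled flanks.

# cumulative-integral function of a bedGraph-style step track on one
# chromosome; continuous coordinates (bp p covers (p-1, p])
.stepIntegral <- function(starts, ends, values, limit) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]; values <- values[o]
  knots <- sort(unique(c(0, starts - 1, ends, limit)))
  knots <- knots[knots >= 0]
  mids <- (knots[-1] + knots[-length(knots)]) / 2
  idx <- findInterval(mids, starts - 1)
  segVal <- numeric(length(mids))
  inCov <- idx >= 1 & idx <= length(ends)
  inCov[inCov] <- mids[inCov] <= ends[idx[inCov]]
  segVal[inCov] <- values[idx[inCov]]
  Fv <- c(0, cumsum(diff(knots) * segVal))
  stats::approxfun(knots, Fv, rule = 2)
}

.binMeans <- function(Ffun, edges) {
  Fv <- Ffun(edges)
  diff(Fv) / diff(edges)
}

#' Anchored coverage matrix over stranded elements
#'
#' Each element body is linearly rescaled to \code{pseudolength} bins by
#' area-weighted integration of the coverage step function (so the mean of
#' the body bins equals the length-weighted mean coverage of the element
#' exactly); flanks are copied at 1-bp resolution. Minus-strand rows are
#' reversed so the column axis always runs 5' to 3'. Positions not covered
#' by the track count as 0. Elements shorter than 2 bp are rejected.
#'
#' @param track \code{GRanges} with a \code{score} column (bedGraph
#'   semantics: sorted, non-overlapping).
#' @param elements stranded \code{GRanges} (BED6-like); names become row
#'   names.
#' @param th a \linkS4class{VmThresholds} (pseudolength and flank are used).
#' @return An \linkS4class{AnchoredMatrix}.
#' @export
anchoredMatrix <- function(track, elements, th = vmThresholds()) {
  if (any(GenomicRanges::width(elements) < 2L))
    stop("elements shorter than 2 bp are not rescalable")
  P <- th@pseudolength
  Fk <- th@flank
  funs <- list()
  getF <- function(cn, limit) {
    if (is.null(funs[[cn]])) {
      sel <- as.character(GenomicRanges::seqnames(track)) == cn
      funs[[cn]] <<- .stepIntegral(GenomicRanges::start(track)[sel],
                                   GenomicRanges::end(track)[sel],
                                   track$score[sel], limit)
    }
    funs[[cn]]
  }
  rows <- lapply(seq_along(elements), function(i) {
    el <- elements[i]
    cn <- as.character(GenomicRanges::seqnames(el))
    s <- GenomicRanges::start(el); e <- GenomicRanges::end(el)
    Ffun <- getF(cn, e + Fk + 1)
    left <- .binMeans(Ffun, seq(s - 1 - Fk, s - 1, by = 1))
    body <- .binMeans(Ffun, seq(s - 1, e, length.out = P + 1))
    right <- .binMeans(Ffun, seq(e, e + Fk, by = 1))
    row <- c(left, body, right)
    if (as.character(GenomicRanges::strand(el)) == "-") row <- rev(row)
    row
  })
  mat <- do.call(rbind, rows)
  rn <- names(elements)
  if (is.null(rn) || !length(rn)) rn <- paste0("el", seq_along(elements))
  rownames(mat) <- rn
  new("AnchoredMatrix", mat = mat, flank = as.integer(Fk),
      pseudolength = as.integer(P),
      strand = as.character(GenomicRanges::strand(elements)))
}

#' Column-wise mean profile with SE and 95% CI
#'
#' @param x an \linkS4class{AnchoredMatrix} or numeric matrix.
#' @return data.frame: bin, mean, se, ciLow, ciHigh. With a single row the
#'   SE and CI are NA (flagged via the \code{seDefined} attribute).
#' @export
meanProfile <- function(x) {
  m <- if (methods::is(x, "AnchoredMatrix")) x@mat else x
  mu <- colMeans(m)
  if (nrow(m) >= 2L) {
    se <- apply(m, 2, sd) / sqrt(nrow(m))
    out <- data.frame(bin = seq_along(mu), mean = mu, se = se,
                      ciLow = mu - 1.96 * se, ciHigh = mu + 1.96 * se)
    attr(out, "seDefined") <- TRUE
  } else {
    out <- data.frame(bin = seq_along(mu), mean = mu, se = NA_real_,
                      ciLow = NA_real_, ciHigh = NA_real_)
    attr(out, "seDefined") <- FALSE
  }
  rownames(out) <- NULL
  out
}

#' Group-wise profiles and a difference profile
#'
#' @param x an \linkS4class{AnchoredMatrix}.
#' @param groups character vector assigning each row to a group.
#' @param compare length-2 character: difference computed as
#'   mean(compare[1]) - mean(compare[2]); defaults to the first two groups.
#' @return List: \code{profiles} (named list of \code{\link{meanProfile}}
#'   frames) and \code{difference} (numeric per column).
#' @export
groupCompare <- function(x, groups, compare = NULL) {
  stopifnot(length(groups) == nrow(x@mat))
  gs <- unique(groups)
  if (is.null(compare)) compare <- gs[seq_len(min(2, length(gs)))]
  if (!all(compare %in% gs)) stop("unknown group id: ",
                                  paste(setdiff(compare, gs), collapse = ", "))
  if (any(table(factor(groups, levels = gs)) == 0)) stop("empty group")
  profiles <- lapply(gs, function(g)
    meanProfile(x@mat[groups == g, , drop = FALSE]))
  names(profiles) <- gs
  diffP <- if (length(compare) == 2)
    profiles[[compare[1]]]$mean - profiles[[compare[2]]]$mean else NULL
  list(profiles = profiles, difference = diffP)
}
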