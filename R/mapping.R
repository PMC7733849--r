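# Backcross modifier mapping: phenotype-stratified SNP intersection, interval
# assembly, cross-experiment combination, segregation and pedigree tests.

#' Phenotype-stratified SNP intersection filter
#'
#' A marker is a candidate iff its call is heterozygous (BC) in ALL highly
#' methylated individuals AND homozygous-B6 (BB) in ALL lowly methylated
#' individuals. Markers with any missing call among labelled individuals are
#' excluded from candidacy; they count as filter-violating (and hence usable
#' as outer interval bounds) only if their non-missing calls already violate
#' the filter. Homozygous-CAST calls, impossible in a B6 backcross, are
#' reported as genotyping errors (and violate the filter).
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param labels named character vector ("high"/"low") over individuals; all
#'   named individuals must be columns of \code{gm}.
#' @return List: \code{candidates} (marker data.frame), \code{status}
#'   (per-marker "candidate"/"violating"/"non-informative"),
#'   \code{ccErrors} (data.frame of homozygous-CAST calls).
#' @export
candidateSnps <- function(gm, labels) {
  hi <- names(labels)[labels == "high"]
  lo <- names(labels)[labels == "low"]
  if (!length(hi) || !length(lo)) stop("empty high or low group")
  miss <- setdiff(c(hi, lo), colnames(gm@calls))
  if (length(miss)) stop("labelled individuals absent from matrix: ",
                         paste(miss, collapse = ", "))
  H <- gm@calls[, hi, drop = FALSE]
  L <- gm@calls[, lo, drop = FALSE]
  hiOK <- rowSums(H == "BC", na.rm = TRUE) +
    rowSums(is.na(H)) == length(hi)
  loOK <- rowSums(L == "BB", na.rm = TRUE) +
    rowSums(is.na(L)) == length(lo)
  anyNA <- rowSums(is.na(H)) + rowSums(is.na(L)) > 0
  violating <- !(hiOK & loOK)            # a non-missing call breaks the filter
  candidate <- hiOK & loOK & !anyNA
  status <- ifelse(candidate, "candidate",
                   ifelse(violating, "violating", "non-informative"))
  cc <- which(gm@calls[, c(hi, lo), drop = FALSE] == "CC", arr.ind = TRUE)
  ccErrors <- if (nrow(cc)) {
    data.frame(marker = gm@markers$id[cc[, 1]],
               individual = c(hi, lo)[cc[, 2]], stringsAsFactors = FALSE)
  } else data.frame(marker = character(0), individual = character(0))
  list(candidates = gm@markers[candidate, , drop = FALSE],
       status = setNames(status, gm@markers$id),
       ccErrors = ccErrors)
}

#' Assemble mapped interval(s) from candidate markers
#'
#' Per chromosome carrying candidates: the inner bounds span the candidate
#' marker positions ([min, max]; a single candidate gives a 1-bp interval);
#' the outer bounds extend, exclusively, to the nearest flanking marker that
#' violated the filter (or to the chromosome/map end when none exists).
#' Candidates on more than one chromosome yield one interval pair each,
#' flagged multi-locus.
#'
#' @param snpResult result of \code{\link{candidateSnps}}.
#' @param gm the \linkS4class{GenotypeMatrix} the filter ran on.
#' @param chromLengths optional named lengths used when no violating marker
#'   flanks the candidates (default: the outermost marker position).
#' @return A \code{GRanges} with two ranges (boundsKind inner/outer) per
#'   candidate chromosome; metadata columns \code{boundsKind},
#'   \code{nCandidates}, \code{multiLocus}.
#' @export
assembleInterval <- function(snpResult, gm, chromLengths = NULL) {
  cand <- snpResult$candidates
  if (!nrow(cand)) stop("no candidate markers to assemble an interval from")
  chroms <- unique(cand$chrom)
  multi <- length(chroms) > 1L
  grl <- lapply(chroms, function(cn) {
    mk <- gm@markers[gm@markers$chrom == cn, , drop = FALSE]
    st <- snpResult$status[mk$id]
    cpos <- mk$pos[st == "candidate"]
    innerStart <- min(cpos); innerEnd <- max(cpos)
    failPos <- mk$pos[st == "violating"]
    leftFail <- failPos[failPos < innerStart]
    rightFail <- failPos[failPos > innerEnd]
    outerStart <- if (length(leftFail)) max(leftFail) + 1 else 1
    outerEnd <- if (length(rightFail)) min(rightFail) - 1 else {
      if (!is.null(chromLengths) && cn %in% names(chromLengths))
        chromLengths[[cn]] else max(mk$pos)
    }
    gr <- GenomicRanges::GRanges(cn, IRanges::IRanges(
      start = c(innerStart, outerStart), end = c(innerEnd, outerEnd)))
    gr$boundsKind <- c("inner", "outer")
    gr$nCandidates <- length(cpos)
    gr$multiLocus <- multi
    gr
  })
  do.call(c, grl)
}

#' Intersect two mapped intervals
#'
#' @param a,b single-range \code{GRanges} on the same chromosome.
#' @return Their intersection as a \code{GRanges}; disjoint inputs are a
#'   mapping conflict and raise an error.
#' @export
combineExperiments <- function(a, b) {
  stopifnot(length(a) == 1L, length(b) == 1L)
  if (as.character(GenomicRanges::seqnames(a)) !=
      as.character(GenomicRanges::seqnames(b)))
    stop("mapping conflict: intervals on different chromosomes")
  s <- max(GenomicRanges::start(a), GenomicRanges::start(b))
  e <- min(GenomicRanges::end(a), GenomicRanges::end(b))
  if (s > e) stop("mapping conflict: disjoint intervals")
  GenomicRanges::GRanges(GenomicRanges::seqnames(a), IRanges::IRanges(s, e))
}

#' Interval length in megabases, printed style
#'
#' The difference of the printed genome-browser coordinates divided by 1e6,
#' rounded half-up to one decimal (so chr4:141964197-148393136 prints 6.4).
#'
#' @param gr a single-range \code{GRanges}.
#' @return Length in Mb, one decimal.
#' @export
intervalLengthMb <- function(gr) {
  stopifnot(length(gr) == 1L)
  mb <- (GenomicRanges::end(gr) - GenomicRanges::start(gr)) / 1e6
  floor(mb * 10 + 0.5) / 10
}

#' Exact binomial test of 1:1 phenotype segregation
#'
#' @param nHigh,nLow phenotype counts (sum >= 1).
#' @param alpha significance level for the verdict.
#' @return List: nHigh, nLow, p (two-sided exact vs 0.5), consistent.
#' @export
segregationTest <- function(nHigh, nLow, alpha = 0.05) {
  stopifnot(nHigh + nLow >= 1)
  p <- binom.test(nHigh, nHigh + nLow, 0.5)$p.value
  list(nHigh = nHigh, nLow = nLow, p = p, consistent = p >= alpha)
}

#' Pedigree consistency with a single dominant modifier locus
#'
#' Families are offspring groups sharing a phenotyped parent (the other
#' parent being an untyped inbred mate). Checks: (a) offspring of highly
#' methylated parents segregate ~1:1 (pooled exact binomial at \code{alpha};
#' per-family binomials are Bonferroni-corrected across high families so
#' that many small families do not raise false alarms); (b) offspring of
#' lowly methylated parents are all lowly methylated; (c) the rules hold in
#' every generation. Phenotyped individuals with no phenotyped parent are
#' excluded with a warning.
#'
#' @param ped a \linkS4class{Pedigree}.
#' @param classes named character vector ("high"/"low") of phenotypes.
#' @param alpha significance level.
#' @return List: \code{consistent}, \code{families} (per-family detail),
#'   \code{pooledHigh} (pooled segregation among offspring of high parents),
#'   \code{byGeneration}.
#' @export
pedigreeConsistency <- function(ped, classes, alpha = 0.05) {
  df <- as.data.frame(ped)
  ph <- df[df$id %in% names(classes), , drop = FALSE]
  parentTyped <- ph$dam %in% names(classes) | ph$sire %in% names(classes)
  orphan <- ph$id[!parentTyped & !(is.na(ph$dam) & is.na(ph$sire))]
  offspring <- ph[parentTyped, , drop = FALSE]
  if (length(orphan))
    warning(length(orphan), " phenotyped individual(s) without a typed parent excluded")
  if (!nrow(offspring))
    return(list(consistent = NA, families = NULL, pooledHigh = NULL,
                byGeneration = NULL))
  offspring$parent <- ifelse(offspring$sire %in% names(classes),
                             offspring$sire, offspring$dam)
  fams <- split(offspring, offspring$parent)
  nHighFams <- sum(vapply(fams, function(f)
    unname(classes[f$parent[1]]) == "high", logical(1)))
  famAlpha <- alpha / max(1L, nHighFams)
  famDetail <- do.call(rbind, lapply(fams, function(f) {
    if (!nrow(f)) return(NULL)
    pc <- unname(classes[f$parent[1]])
    nH <- sum(classes[f$id] == "high")
    nL <- sum(classes[f$id] == "low")
    ok <- if (pc == "high") binom.test(nH, nH + nL, 0.5)$p.value >= famAlpha
          else nH == 0
    data.frame(parent = f$parent[1], parentClass = pc,
               generation = f$generation[1], nHigh = nH, nLow = nL,
               consistent = ok, stringsAsFactors = FALSE)
  }))
  rownames(famDetail) <- NULL
  hiOff <- famDetail[famDetail$parentClass == "high", , drop = FALSE]
  pooled <- if (nrow(hiOff))
    segregationTest(sum(hiOff$nHigh), sum(hiOff$nLow), alpha) else NULL
  byGen <- tapply(famDetail$consistent, famDetail$generation, all)
  list(consistent = all(famDetail$consistent) &&
         (is.null(pooled) || pooled$consistent),
       families = famDetail, pooledHigh = pooled,
       byGeneration = byGen)
}

#' Map the modifier locus from genotypes and phenotype classes
#'
#' Convenience wrapper: runs the SNP-intersection filter, assembles the
#' mapped interval(s), and tests 1:1 segregation of the phenotype classes.
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param labels named "high"/"low" phenotype vector.
#' @param chromLengths optional named chromosome lengths for outer bounds.
#' @param alpha significance level for the segregation verdict.
#' @return List: \code{snps}, \code{intervals} (GRanges),
#'   \code{segregation}, \code{lengthsMb} per interval.
#' @export
mapModifier <- function(gm, labels, chromLengths = NULL, alpha = 0.05) {
  snps <- candidateSnps(gm, labels)
  intervals <- assembleInterval(snps, gm, chromLengths)
  seg <- segregationTest(sum(labels == "high"), sum(labels == "low"), alpha)
  lens <- vapply(seq_along(intervals), function(i)
    intervalLengthMb(intervals[i]), numeric(1))
  list(snps = snps, intervals = intervals, segregation = seg,
       lengthsMb = setNames(lens, paste(GenomicRanges::seqnames(intervals),
                                        intervals$boundsKind)))
}
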