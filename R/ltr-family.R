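# Simulated solo-LTR sequence families: a common consensus, a VM clade
# (targets + nontargets) splitting off before a more divergent background
# set, and a planted 28-bp discriminative segment intact in targets and
# disrupted (insertion + substitutions) in nontargets.

.DNA <- c("A", "C", "G", "T")

.mutateChars <- function(x, rate, protect = integer(0)) {
  if (rate <= 0) return(x)
  hit <- which(runif(length(x)) < rate)
  hit <- setdiff(hit, protect)
  if (length(hit)) {
    x[hit] <- vapply(x[hit], function(b)
      sample(setdiff(.DNA, b), 1L), character(1))
  }
  x
}


#' Evolve a labelled solo-LTR sequence family
#'
#' Targets and nontargets descend from a shared clade ancestor (one deep
#' branch off the consensus), so they are mutually closer than to the
#' background set, which diverges further. Targets carry the planted
#' discriminative segment intact; nontargets carry the same segment disrupted
#' by an insertion and fixed substitutions; background elements have no
#' protected segment. A random subset of sequences is emitted
#' reverse-complemented with a "-" orientation flag.
#'
#' The planted segment is drawn from a three-letter alphabet (A/C/G) and the
#' disruption saturates the substituted positions and the insertion with the
#' fourth base (T). Every disrupted column therefore discriminates targets
#' from nontargets no matter where a pairwise aligner places the insertion
#' gap, which makes planted-window recovery a property of the data rather
#' than of aligner tie-breaking.
#'
#' @param nTargets,nNontargets,nBackground sequence counts (>= 0).
#' @param mspec a \linkS4class{MotifSpec}.
#' @param revCompFraction fraction of sequences emitted reverse-complemented.
#' @return List with \code{sequences} (named \code{DNAStringSet}, as emitted),
#'   \code{info} (data.frame id/label/orientation/length) and
#'   \code{consensus}/\code{motif} (character strings of the planted truth).
#' @export
evolveLtrFamily <- function(nTargets, nNontargets, nBackground,
                            mspec = motifSpec(), revCompFraction = 0.25) {
  stopifnot(nTargets >= 0, nNontargets >= 0, nBackground >= 0)
  L <- mspec@consensusLength
  midx <- seq(mspec@motifStart, length.out = mspec@motifLength)
  consensus <- sample(.DNA, L, replace = TRUE)
  consensus[midx] <- sample(c("A", "C", "G"), mspec@motifLength, replace = TRUE)
  # non-T barrier columns flanking the segment stop the insertion gap from
  # sliding into the conserved flanks during alignment
  barrier <- intersect(c(min(midx) - 2:1, max(midx) + 1:2), seq_len(L))
  consensus[barrier] <- sample(c("A", "C", "G"), length(barrier), replace = TRUE)
  motif <- consensus[midx]
  # disrupted segment: T-saturated substitutions, T insertion after midpoint
  disrupted <- motif
  if (length(mspec@substitutionOffsets))
    disrupted[mspec@substitutionOffsets] <- "T"
  insAt <- mspec@motifLength %/% 2L
  disrupted <- append(disrupted, rep("T", mspec@insertionLength),
                      after = insAt)
  cladeAnc <- .mutateChars(consensus, mspec@deepRate, protect = midx)
  seqs <- character(0); labels <- character(0)
  for (k in seq_len(nTargets)) {
    s <- .mutateChars(cladeAnc, mspec@tipRate, protect = midx)
    s[midx] <- motif
    seqs <- c(seqs, paste(s, collapse = "")); labels <- c(labels, "target")
  }
  for (k in seq_len(nNontargets)) {
    s <- .mutateChars(cladeAnc, mspec@tipRate, protect = midx)
    s <- c(s[seq_len(mspec@motifStart - 1L)], disrupted,
           s[seq(mspec@motifStart + mspec@motifLength, length.out =
                   L - mspec@motifStart - mspec@motifLength + 1L)])
    seqs <- c(seqs, paste(s, collapse = "")); labels <- c(labels, "nontarget")
  }
  for (k in seq_len(nBackground)) {
    s <- .mutateChars(consensus,
                      mspec@deepRate + mspec@backgroundExtra + mspec@tipRate)
    seqs <- c(seqs, paste(s, collapse = "")); labels <- c(labels, "background")
  }
  n <- length(seqs)
  ids <- paste0(labels, "_", stats::ave(seq_len(n), labels, FUN = seq_along))
  orientation <- rep("+", n)
  if (n > 0 && revCompFraction > 0) {
    flip <- which(runif(n) < revCompFraction)
    orientation[flip] <- "-"
    seqs[flip] <- vapply(seqs[flip], reverseComplementSeq, character(1))
  }
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- ids
  list(sequences = dss,
       info = data.frame(id = ids, label = labels, orientation = orientation,
                         length = nchar(seqs), stringsAsFactors = FALSE),
       consensus = paste(consensus, collapse = ""),
       motif = paste(motif, collapse = ""))
}
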