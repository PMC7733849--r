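#' @import methods
#' @importFrom stats median pnorm pchisq pbeta quantile rbeta rbinom rnorm rpois
#'   runif sd var setNames shapiro.test binom.test kruskal.test phyper pt
#' @importFrom utils read.csv write.csv head tail
#' @useDynLib vmiap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Genome specification for the breeding simulator
#'
#' Describes the simulated karyotype: chromosome names with physical (bp) and
#' genetic (Morgan) lengths, an informative-marker map, and the hidden
#' ground-truth position of the trans-acting modifier locus together with the
#' strain that carries the modifier allele.
#'
#' @slot chromosomes data.frame with columns \code{name}, \code{lengthBp},
#'   \code{lengthM} (genetic length in Morgans).
#' @slot markers data.frame with columns \code{chrom}, \code{pos}, \code{id};
#'   positions strictly increasing within each chromosome.
#' @slot modifierChrom,modifierPos chromosome and bp position of the modifier.
#' @slot modifierStrain strain carrying the dominant modifier allele.
#' @export
setClass("GenomeSpec", representation(
  chromosomes = "data.frame",
  markers = "data.frame",
  modifierChrom = "character",
  modifierPos = "numeric",
  modifierStrain = "character"
))

setValidity("GenomeSpec", function(object) {
  ch <- object@chromosomes
  if (!all(c("name", "lengthBp", "lengthM") %in% names(ch)))
    return("chromosomes needs columns name, lengthBp, lengthM")
  if (any(ch$lengthBp <= 0)) return("physical lengths must be positive")
  if (any(ch$lengthM < 0)) return("genetic lengths must be >= 0")
  if (anyDuplicated(ch$name)) return("duplicated chromosome names")
  mk <- object@markers
  if (nrow(mk)) {
    if (!all(mk$chrom %in% ch$name)) return("marker on undeclared chromosome")
    for (cn in unique(mk$chrom)) {
      p <- mk$pos[mk$chrom == cn]
      if (any(diff(p) <= 0)) return("marker positions must strictly increase")
      if (any(p < 1 | p > ch$lengthBp[ch$name == cn]))
        return("marker position outside chromosome")
    }
  }
  if (!object@modifierChrom %in% ch$name)
    return("modifier locus on undeclared chromosome")
  if (object@modifierPos < 1 ||
      object@modifierPos > ch$lengthBp[ch$name == object@modifierChrom])
    return("modifier position outside its chromosome")
  TRUE
})

#' A simulated individual with ancestry-painted chromosomes
#'
#' Each chromosome is carried as a pair of haplotype "paintings": ordered
#' segments tagged with the founder strain they descend from. Segments tile
#' the chromosome exactly (no gap, no overlap); the painting of haplotype h on
#' chromosome c is \code{paintings[[c]][[h]]}, a list with numeric \code{end}
#' (segment right endpoints, last one equal to the chromosome length) and
#' character \code{strain} per segment.
#'
#' @slot id,sex,generation identifiers; generation is F0/F1/N1/N2/... .
#' @slot dam,sire parent ids (\code{NA} for founders).
#' @slot damStrain founder strain of the mother's line (maternal-effect
#'   phenotyping uses this).
#' @slot paintings per-chromosome list of two haplotype paintings.
#' @slot modifierAlleles number (0-2) of haplotypes carrying the modifier
#'   allele, i.e. painted with the modifier strain at the modifier locus.
#' @export
setClass("Individual", representation(
  id = "character", sex = "character", generation = "character",
  dam = "character", sire = "character", damStrain = "character",
  paintings = "list", modifierAlleles = "integer"
))

#' A pedigree: an ordered collection of individuals
#' @slot individuals list of \linkS4class{Individual}; ids unique.
#' @export
setClass("Pedigree", representation(individuals = "list"))

setValidity("Pedigree", function(object) {
  ids <- vapply(object@individuals, function(i) i@id, character(1))
  if (anyDuplicated(ids)) return("duplicated individual ids")
  TRUE
})

#' Locus-specific methylation model
#'
#' Per-individual methylation at a locus is one Beta-distributed "locus draw"
#' (on 0-100%), selected among three states, plus independent per-CpG
#' measurement noise:
#' baseline (variable, mean 45% by default), high (modifier-induced
#' hypermethylation, mean 80%), and boosted (both maternal and zygotic
#' conditions met under the maternal+zygotic mode, mean 90%).
#'
#' @slot baseline,high,boost length-2 Beta shape parameters (a, b).
#' @slot effectMode one of \code{"zygotic"}, \code{"maternal"},
#'   \code{"maternal+zygotic"}, \code{"none"}.
#' @slot noiseSd per-CpG measurement noise, percentage points.
#' @slot nCpgs number of CpGs assayed at the locus.
#' @slot modifierStrain strain whose allele (or oocyte) induces the high state.
#' @export
setClass("MethylationModel", representation(
  baseline = "numeric", high = "numeric", boost = "numeric",
  effectMode = "character", noiseSd = "numeric", nCpgs = "integer",
  modifierStrain = "character"
))

setValidity("MethylationModel", function(object) {
  if (!object@effectMode %in% c("zygotic", "maternal", "maternal+zygotic", "none"))
    return("unknown effect mode")
  if (object@noiseSd < 0) return("noise sd must be >= 0")
  if (object@nCpgs < 1) return("need at least one CpG")
  if (length(object@baseline) != 2 || any(object@baseline <= 0))
    return("baseline must be two positive Beta shapes")
  TRUE
})

#' Specification of a simulated LTR family with a planted discriminative motif
#'
#' @slot consensusLength length of the ancestral LTR consensus (bp).
#' @slot motifStart,motifLength position and length of the planted
#'   discriminative segment (default 28 bp) within the consensus.
#' @slot insertionLength length of the insertion disrupting the segment in
#'   nontargets.
#' @slot substitutionOffsets 1-based offsets within the segment that are
#'   substituted in nontargets.
#' @slot deepRate,tipRate,backgroundExtra per-branch substitution rates for the
#'   deep split, terminal branches, and the extra divergence of background
#'   elements outside the VM clade.
#' @export
setClass("MotifSpec", representation(
  consensusLength = "integer", motifStart = "integer", motifLength = "integer",
  insertionLength = "integer", substitutionOffsets = "integer",
  deepRate = "numeric", tipRate = "numeric", backgroundExtra = "numeric"
))

setValidity("MotifSpec", function(object) {
  if (object@motifStart + object@motifLength - 1L > object@consensusLength)
    return("motif segment does not fit within the consensus")
  if (length(object@substitutionOffsets) + object@insertionLength < 1)
    return("disruption must change at least one position inside the segment")
  if (length(object@substitutionOffsets) &&
      any(object@substitutionOffsets < 1 |
          object@substitutionOffsets > object@motifLength))
    return("substitution offsets outside the segment")
  TRUE
})

#' Numeric thresholds used across the pipeline
#'
#' Central container for every tunable cutoff: the variability spread (>10
#' percentage points of range classifies a locus as variably methylated), the
#' 60% high/low phenotype cutoff, the 90% sequence-identity candidate filter,
#' the 5% FDR, the 200-800 bp solo-LTR length filter, the 500-bp anchored
#' pseudolength and flanks, and the 0.05 significance level.
#'
#' @export
setClass("VmThresholds", representation(
  variabilitySpread = "numeric", highLowCutoff = "numeric",
  identityMin = "numeric", fdrQ = "numeric",
  njLenMin = "numeric", njLenMax = "numeric",
  pseudolength = "integer", flank = "integer", alpha = "numeric",
  hyperMean = "numeric", hypoMean = "numeric",
  concordanceMin = "numeric"
))

setValidity("VmThresholds", function(object) {
  if (object@highLowCutoff <= 0 || object@highLowCutoff >= 100)
    return("cutoff must lie in (0, 100)")
  vals <- c(object@variabilitySpread, object@identityMin, object@fdrQ,
            object@njLenMin, object@njLenMax, object@pseudolength,
            object@flank, object@alpha)
  if (any(vals <= 0)) return("all thresholds must be positive")
  TRUE
})

#' Long-format per-CpG methylation table
#'
#' Records of (locus, individual, cpg index, methylation percent in [0,100]).
#'
#' @slot data data.frame with columns \code{locus}, \code{individual},
#'   \code{cpg}, \code{percent}.
#' @export
setClass("MethylationTable", representation(data = "data.frame"))

setValidity("MethylationTable", function(object) {
  d <- object@data
  if (!all(c("locus", "individual", "cpg", "percent") %in% names(d)))
    return("need columns locus, individual, cpg, percent")
  if (nrow(d) && (any(d$percent < 0) || any(d$percent > 100)))
    return("percent outside [0,100]")
  TRUE
})

#' Biallelic SNP genotype matrix over a marker map
#'
#' Calls are \code{"BB"} (homozygous B6), \code{"BC"} (heterozygous),
#' \code{"CC"} (homozygous CAST) or \code{NA} (missing).
#'
#' @slot markers data.frame (\code{chrom}, \code{pos}, \code{id}), positions
#'   sorted within chromosome.
#' @slot calls character matrix, rows = markers, columns = individuals.
#' @export
setClass("GenotypeMatrix", representation(
  markers = "data.frame", calls = "matrix"
))

setValidity("GenotypeMatrix", function(object) {
  if (nrow(object@markers) != nrow(object@calls))
    return("markers and call rows disagree")
  ok <- object@calls %in% c("BB", "BC", "CC") | is.na(object@calls)
  if (!all(ok)) return("invalid genotype call")
  for (cn in unique(object@markers$chrom)) {
    p <- object@markers$pos[object@markers$chrom == cn]
    if (any(diff(p) < 0)) return("marker positions unsorted within chromosome")
  }
  TRUE
})

#' A labelled gapped alignment of LTR sequences
#'
#' @slot aln character vector of equal-length gapped sequences (alphabet
#'   A, C, G, T, -, N), named by sequence id.
#' @slot labels per-sequence label, e.g. target/nontarget or VM/nonVM.
#' @slot orientation per-sequence original strand ("+" or "-"); contraoriented
#'   input is reverse complemented before alignment.
#' @export
setClass("LabelledAlignment", representation(
  aln = "character", labels = "character", orientation = "character"
))

setValidity("LabelledAlignment", function(object) {
  if (length(unique(nchar(object@aln))) > 1)
    return("alignment rows differ in length")
  if (length(object@labels) != length(object@aln))
    return("one label per sequence required")
  if (length(object@aln) &&
      grepl("[^ACGTN-]", paste(object@aln, collapse = "")))
    return("alphabet restricted to A, C, G, T, -, N")
  TRUE
})

#' Anchored, strand-oriented coverage matrix
#'
#' Rows are elements; columns are \code{flank} upstream 1-bp bins, the element
#' body rescaled to \code{pseudolength} bins, and \code{flank} downstream 1-bp
#' bins, oriented 5' to 3' (minus-strand rows are reversed).
#'
#' @slot mat numeric matrix of binned mean coverage.
#' @slot flank,pseudolength bin counts of the three blocks.
#' @slot strand per-row original strand.
#' @export
setClass("AnchoredMatrix", representation(
  mat = "matrix", flank = "integer", pseudolength = "integer",
  strand = "character"
))

setValidity("AnchoredMatrix", function(object) {
  if (ncol(object@mat) != 2L * object@flank + object@pseudolength)
    return("column count must be flank + pseudolength + flank")
  TRUE
})
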