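#' Construct a GenomeSpec
#'
#' @param chromosomes data.frame with \code{name}, \code{lengthBp},
#'   \code{lengthM}.
#' @param markers data.frame with \code{chrom}, \code{pos} and optionally
#'   \code{id}; marker ids default to \code{chrom_pos}.
#' @param modifierChrom,modifierPos hidden ground-truth modifier position.
#' @param modifierStrain strain carrying the modifier allele.
#' @return A \linkS4class{GenomeSpec}.
#' @export
genomeSpec <- function(chromosomes, markers,
                       modifierChrom, modifierPos,
                       modifierStrain = "CAST") {
  markers <- as.data.frame(markers)
  if (is.null(markers$id))
    markers$id <- paste0(markers$chrom, "_", markers$pos)
  markers <- markers[order(match(markers$chrom, chromosomes$name), markers$pos), ,
                     drop = FALSE]
  rownames(markers) <- NULL
  new("GenomeSpec", chromosomes = as.data.frame(chromosomes),
      markers = markers, modifierChrom = modifierChrom,
      modifierPos = as.numeric(modifierPos), modifierStrain = modifierStrain)
}

#' Default two-chromosome genome for backcross simulations
#'
#' A compact stand-in for the mapping design: a 156-Mb chromosome ("chr4",
#' 0.8 Morgans) that carries the modifier at 145 Mb, plus a 195-Mb neutral
#' chromosome ("chr1", 1.0 Morgans). Informative markers every
#' \code{markerSpacing} bp emulate a strain-informative SNP panel; the panel
#' also covers the modifier position itself (dense arrays tile the locus),
#' which makes true-locus recovery under error-free phenotyping a structural
#' guarantee of the intersection filter.
#'
#' @param markerSpacing marker spacing in bp (default 1 Mb).
#' @return A \linkS4class{GenomeSpec}.
#' @export
defaultGenomeSpec <- function(markerSpacing = 1e6) {
  chroms <- data.frame(name = c("chr1", "chr4"),
                       lengthBp = c(195e6, 156e6),
                       lengthM = c(1.0, 0.8))
  mk <- do.call(rbind, lapply(seq_len(nrow(chroms)), function(i) {
    pos <- seq(markerSpacing / 2, chroms$lengthBp[i], by = markerSpacing)
    if (chroms$name[i] == "chr4") pos <- sort(unique(c(pos, 145e6)))
    data.frame(chrom = chroms$name[i], pos = pos)
  }))
  genomeSpec(chroms, mk, modifierChrom = "chr4", modifierPos = 145e6)
}

#' Construct a MethylationModel
#'
#' Defaults emulate a categorical methylation phenotype: a variable baseline
#' Beta(9,11) scaled to percent (mean 45%) against a modifier-induced high
#' state Beta(24,6) (mean 80%), separated by the 60% cutoff, with a boosted
#' state Beta(45,5) (mean 90%) when maternal and zygotic conditions co-occur.
#'
#' @param baseline,high,boost Beta shape pairs for the three states.
#' @param effectMode zygotic, maternal, maternal+zygotic or none.
#' @param noiseSd per-CpG measurement noise (percentage points).
#' @param nCpgs CpGs per locus.
#' @param modifierStrain strain inducing the high state.
#' @return A \linkS4class{MethylationModel}.
#' @export
methylationModel <- function(baseline = c(9, 11), high = c(24, 6),
                             boost = c(45, 5), effectMode = "zygotic",
                             noiseSd = 1.5, nCpgs = 6L,
                             modifierStrain = "CAST") {
  new("MethylationModel", baseline = baseline, high = high, boost = boost,
      effectMode = effectMode, noiseSd = noiseSd, nCpgs = as.integer(nCpgs),
      modifierStrain = modifierStrain)
}

#' Construct a MotifSpec
#'
#' The default plants a 28-bp discriminative segment in a 500-bp consensus
#' (the typical solo-LTR length of the modelled subclass);
#' nontargets carry a 4-bp insertion after segment position 14 plus a
#' deterministic substitution at every segment position (an insertion and
#' SNPs saturating the modifier binding site), so every segment column
#' discriminates targets from nontargets regardless of how the aligner
#' places the insertion gap.
#'
#' @param consensusLength,motifStart,motifLength consensus geometry (bp).
#' @param insertionLength disruption insertion length (bp).
#' @param substitutionOffsets offsets within the segment substituted in
#'   nontargets.
#' @param deepRate,tipRate,backgroundExtra per-branch substitution rates.
#' @return A \linkS4class{MotifSpec}.
#' @export
motifSpec <- function(consensusLength = 500L, motifStart = 237L,
                      motifLength = 28L, insertionLength = 4L,
                      substitutionOffsets = seq_len(motifLength),
                      deepRate = 0.03, tipRate = 0.005,
                      backgroundExtra = 0.08) {
  new("MotifSpec", consensusLength = as.integer(consensusLength),
      motifStart = as.integer(motifStart), motifLength = as.integer(motifLength),
      insertionLength = as.integer(insertionLength),
      substitutionOffsets = as.integer(substitutionOffsets),
      deepRate = deepRate, tipRate = tipRate, backgroundExtra = backgroundExtra)
}

#' Construct the pipeline threshold set
#'
#' Defaults follow the field conventions for this assay family: >10
#' percentage-point spread marks a locus variably methylated; 60% methylation
#' separates high from low phenotypes; 90% identity selects sequence
#' candidates; 5% FDR; 200-800 bp solo-LTR length filter; 500-bp anchored
#' pseudolength and flanks; alpha = 0.05.
#'
#' @param variabilitySpread,highLowCutoff,identityMin,fdrQ,njLenMin,njLenMax
#'   numeric thresholds, see description.
#' @param pseudolength,flank anchored-profile geometry (bp).
#' @param alpha significance level.
#' @param hyperMean,hypoMean nonvariable subtype boundaries (group mean).
#' @param concordanceMin concordance fraction needed for a target verdict.
#' @return A \linkS4class{VmThresholds}.
#' @export
vmThresholds <- function(variabilitySpread = 10, highLowCutoff = 60,
                         identityMin = 90, fdrQ = 0.05,
                         njLenMin = 200, njLenMax = 800,
                         pseudolength = 500L, flank = 500L, alpha = 0.05,
                         hyperMean = 80, hypoMean = 20,
                         concordanceMin = 0.9) {
  new("VmThresholds", variabilitySpread = variabilitySpread,
      highLowCutoff = highLowCutoff, identityMin = identityMin, fdrQ = fdrQ,
      njLenMin = njLenMin, njLenMax = njLenMax,
      pseudolength = as.integer(pseudolength), flank = as.integer(flank),
      alpha = alpha, hyperMean = hyperMean, hypoMean = hypoMean,
      concordanceMin = concordanceMin)
}

#' Construct a MethylationTable
#' @param data data.frame with columns locus, individual, cpg, percent.
#' @return A \linkS4class{MethylationTable}.
#' @export
methylationTable <- function(data) {
  data <- as.data.frame(data)
  data$locus <- as.character(data$locus)
  data$individual <- as.character(data$individual)
  data$cpg <- as.integer(data$cpg)
  rownames(data) <- NULL
  new("MethylationTable", data = data)
}

#' Construct a GenotypeMatrix
#' @param markers data.frame (chrom, pos, id).
#' @param calls character matrix markers x individuals with entries
#'   BB/BC/CC/NA.
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
genotypeMatrix <- function(markers, calls) {
  markers <- as.data.frame(markers)
  if (is.null(markers$id)) markers$id <- paste0(markers$chrom, "_", markers$pos)
  o <- order(markers$chrom, markers$pos)
  markers <- markers[o, , drop = FALSE]
  calls <- calls[o, , drop = FALSE]
  rownames(markers) <- NULL
  rownames(calls) <- markers$id
  new("GenotypeMatrix", markers = markers, calls = calls)
}

#' Construct a Pedigree
#' @param individuals list of \linkS4class{Individual}.
#' @return A \linkS4class{Pedigree}.
#' @export
pedigree <- function(individuals = list()) {
  new("Pedigree", individuals = individuals)
}

# ---- accessors and show methods ----

#' Number of modifier-carrying haplotypes of an individual
#' @param x an \linkS4class{Individual}.
#' @return Integer 0-2.
#' @export
modifierAlleles <- function(x) x@modifierAlleles

#' Individuals of a pedigree as a list
#' @param x a \linkS4class{Pedigree}.
#' @return List of \linkS4class{Individual}.
#' @export
pedIndividuals <- function(x) x@individuals

#' Pedigree table view
#'
#' @param x a \linkS4class{Pedigree}.
#' @param row.names,optional,... ignored, present for the generic.
#' @return data.frame with one row per individual.
#' @export
as.data.frame.Pedigree <- function(x, row.names = NULL, optional = FALSE, ...) {
  do.call(rbind, lapply(x@individuals, function(i) {
    data.frame(id = i@id, sex = i@sex, generation = i@generation,
               dam = i@dam, sire = i@sire, damStrain = i@damStrain,
               modifierAlleles = i@modifierAlleles,
               stringsAsFactors = FALSE)
  }))
}

#' Methylation records as a data.frame
#' @param x a \linkS4class{MethylationTable}.
#' @param row.names,optional,... ignored, present for the generic.
#' @return The underlying long-format data.frame.
#' @export
as.data.frame.MethylationTable <- function(x, row.names = NULL,
                                           optional = FALSE, ...) x@data

setMethod("show", "GenomeSpec", function(object) {
  cat("GenomeSpec:", nrow(object@chromosomes), "chromosome(s),",
      nrow(object@markers), "marker(s)\n")
  cat("  modifier locus:", object@modifierChrom, "@",
      format(object@modifierPos, big.mark = ","),
      sprintf("(%s-derived)\n", object@modifierStrain))
})

setMethod("show", "Individual", function(object) {
  cat(sprintf("Individual %s [%s, %s] dam=%s sire=%s damStrain=%s modifierAlleles=%d\n",
              object@id, object@sex, object@generation, object@dam,
              object@sire, object@damStrain, object@modifierAlleles))
})

setMethod("show", "Pedigree", function(object) {
  gens <- table(vapply(object@individuals, function(i) i@generation,
                       character(1)))
  cat("Pedigree with", length(object@individuals), "individuals:",
      paste(names(gens), as.integer(gens), sep = "=", collapse = ", "), "\n")
})

setMethod("show", "MethylationTable", function(object) {
  d <- object@data
  cat("MethylationTable:", length(unique(d$locus)), "locus/loci,",
      length(unique(d$individual)), "individual(s),", nrow(d), "records\n")
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@calls), "markers x",
      ncol(object@calls), "individuals\n")
})

setMethod("show", "LabelledAlignment", function(object) {
  cat("LabelledAlignment:", length(object@aln), "sequences x",
      if (length(object@aln)) nchar(object@aln[1]) else 0, "columns;",
      "labels:", paste(names(table(object@labels)),
                       as.integer(table(object@labels)),
                       sep = "=", collapse = ", "), "\n")
})

setMethod("show", "AnchoredMatrix", function(object) {
  cat("AnchoredMatrix:", nrow(object@mat), "elements x", ncol(object@mat),
      sprintf("bins (flank %d + body %d + flank %d)\n",
              object@flank, object@pseudolength, object@flank))
})

setMethod("show", "MethylationModel", function(object) {
  cat(sprintf("MethylationModel[%s]: baseline Beta(%g,%g), high Beta(%g,%g), boost Beta(%g,%g), noise %g pp, %d CpGs\n",
              object@effectMode, object@baseline[1], object@baseline[2],
              object@high[1], object@high[2], object@boost[1], object@boost[2],
              object@noiseSd, object@nCpgs))
})

setMethod("show", "VmThresholds", function(object) {
  cat(sprintf("VmThresholds: spread>%g, cutoff %g%%, identity>=%g%%, q=%g, NJ len [%g,%g], pseudolength %d, flank %d, alpha %g\n",
              object@variabilitySpread, object@highLowCutoff,
              object@identityMin, object@fdrQ, object@njLenMin,
              object@njLenMax, object@pseudolength, object@flank,
              object@alpha))
})
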