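# Phenotype simulation: locus-specific Beta methylation states driven by
# modifier genotype and/or maternal strain, plus the two standard crossing
# designs (reciprocal F1 hybrids; serial B6 backcross).

.methylationState <- function(ind, model) {
  carrier <- ind@modifierAlleles >= 1L
  maternal <- identical(ind@damStrain, model@modifierStrain)
  switch(model@effectMode,
         "zygotic" = if (carrier) "high" else "baseline",
         "maternal" = if (maternal) "high" else "baseline",
         "maternal+zygotic" = {
           if (carrier && maternal) "boost"
           else if (carrier || maternal) "high"
           else "baseline"
         },
         "none" = "baseline",
         stop("unknown effect mode: ", model@effectMode))
}

#' Draw per-CpG methylation percentages for one individual at one locus
#'
#' One Beta-distributed locus draw (state chosen by the effect mode and the
#' individual's modifier genotype / maternal strain) plus independent Gaussian
#' per-CpG measurement noise, clamped to [0, 100].
#'
#' @param ind an \linkS4class{Individual}.
#' @param model a \linkS4class{MethylationModel}.
#' @return Numeric vector of length \code{nCpgs}.
#' @export
assignMethylation <- function(ind, model) {
  st <- .methylationState(ind, model)
  sh <- slot(model, if (st == "baseline") "baseline" else
                    if (st == "high") "high" else "boost")
  draw <- rbeta(1L, sh[1], sh[2]) * 100
  cpgs <- draw + rnorm(model@nCpgs, 0, model@noiseSd)
  pmin(pmax(cpgs, 0), 100)
}

#' Methylation model of a categorical index locus
#'
#' The mapping design requires an unambiguous phenotype: baseline and
#' modifier-induced distributions that do not overlap at the 60% cutoff
#' (baseline Beta(100,125), mean ~44%, sd ~3.3 pp; high Beta(120,30), mean
#' 80%, sd ~3.3 pp). The generic \code{\link{methylationModel}} defaults
#' describe a typical variably methylated locus instead; this tighter model
#' emulates the index locus selected for mapping precisely because its
#' methylation states are separable.
#'
#' @param ... overrides passed to \code{\link{methylationModel}}.
#' @return A \linkS4class{MethylationModel}.
#' @export
indexLocusModel <- function(...) {
  args <- list(...)
  defaults <- list(baseline = c(100, 125), high = c(120, 30),
                   boost = c(45, 5), effectMode = "zygotic")
  do.call(methylationModel, utils::modifyList(defaults, args))
}

.methylateCohort <- function(individuals, models, locusIds = names(models)) {
  rows <- lapply(seq_along(models), function(l) {
    do.call(rbind, lapply(individuals, function(ind) {
      v <- assignMethylation(ind, models[[l]])
      data.frame(locus = locusIds[l], individual = ind@id,
                 cpg = seq_along(v), percent = v, stringsAsFactors = FALSE)
    }))
  })
  methylationTable(do.call(rbind, rows))
}

#' Simulate the reciprocal-hybrid design (B6, BC, CB groups)
#'
#' Generates \code{nPerGroup} pure B6 individuals, BC F1 hybrids (B6 dam x
#' CAST sire) and CB F1 hybrids (CAST dam x B6 sire), then draws methylation
#' at each modelled locus. All F1s carry one CAST haplotype genome-wide, so
#' zygotic effects hit both hybrid groups while maternal effects split them.
#'
#' @param models named list of \linkS4class{MethylationModel}, one per locus.
#' @param spec a \linkS4class{GenomeSpec}.
#' @param nPerGroup individuals per group.
#' @return List with \code{methylation} (a \linkS4class{MethylationTable}),
#'   \code{groups} (data.frame individual/group) and \code{pedigree}.
#' @export
simulateReciprocalF1 <- function(models, spec = defaultGenomeSpec(),
                                 nPerGroup = 50L) {
  b6F <- simulateFounder("B6", spec, id = "B6_F", sex = "F")
  b6M <- simulateFounder("B6", spec, id = "B6_M", sex = "M")
  caF <- simulateFounder("CAST", spec, id = "CAST_F", sex = "F")
  caM <- simulateFounder("CAST", spec, id = "CAST_M", sex = "M")
  b6 <- cross(b6F, b6M, nPerGroup, spec, idPrefix = "B6")
  bc <- cross(b6F, caM, nPerGroup, spec, idPrefix = "BC")
  cb <- cross(caF, b6M, nPerGroup, spec, idPrefix = "CB")
  all <- c(b6, bc, cb)
  groups <- data.frame(
    individual = vapply(all, function(i) i@id, character(1)),
    group = rep(c("B6", "BC", "CB"), each = nPerGroup),
    stringsAsFactors = FALSE)
  list(methylation = .methylateCohort(all, models),
       groups = groups,
       pedigree = pedigree(c(list(b6F, b6M, caF, caM), all)))
}

#' Simulate a serial B6 backcross with phenotype-based sire selection
#'
#' Emulates the mapping design: a BC F1 male (B6 dam x CAST sire) is crossed
#' to B6 females to produce N1; highly and lowly methylated N1 males are
#' backcrossed again to produce N2; highly methylated N2 males produce N3.
#' N3 individuals are genotyped on the marker panel and phenotyped at the
#' index locus.
#'
#' @param model \linkS4class{MethylationModel} of the index locus (zygotic
#'   dominant by default).
#' @param spec a \linkS4class{GenomeSpec}.
#' @param nN1 N1 litter size.
#' @param nHighSires,nLowSires N1 males of each phenotype selected as N2
#'   sires.
#' @param nN2PerSire N2 offspring per selected sire.
#' @param nN3 total N3 individuals (offspring of highly methylated N2 males).
#' @param cutoff high/low classification cutoff (percent).
#' @param phenotype \code{"methylation"} draws methylation and classifies at
#'   the cutoff; \code{"allele"} is error-free phenotyping by modifier
#'   genotype.
#' @param missingRate genotype no-call rate for the N3 panel.
#' @return List: \code{pedigree}, \code{n1}, \code{n2}, \code{n3} individual
#'   lists, \code{classes} (named high/low for all phenotyped individuals),
#'   \code{genotypes} (\linkS4class{GenotypeMatrix} of N3),
#'   \code{truth} (modifier chrom/pos/strain).
#' @export
simulateBackcrossDesign <- function(model = indexLocusModel(),
                                    spec = defaultGenomeSpec(),
                                    nN1 = 40L, nHighSires = 3L, nLowSires = 3L,
                                    nN2PerSire = 8L, nN3 = 47L, cutoff = 60,
                                    phenotype = c("methylation", "allele"),
                                    missingRate = 0) {
  phenotype <- match.arg(phenotype)
  classify <- function(ind) {
    if (phenotype == "allele") {
      if (ind@modifierAlleles >= 1L) "high" else "low"
    } else {
      if (mean(assignMethylation(ind, model)) > cutoff) "high" else "low"
    }
  }
  b6F <- simulateFounder("B6", spec, id = "B6_F", sex = "F")
  caM <- simulateFounder("CAST", spec, id = "CAST_M", sex = "M")
  f1 <- cross(b6F, caM, 1L, spec, idPrefix = "F1")[[1]]
  f1@sex <- "M"
  n1 <- cross(b6F, f1, nN1, spec, idPrefix = "N1")
  cls1 <- setNames(vapply(n1, classify, character(1)),
                   vapply(n1, function(i) i@id, character(1)))
  classes <- c(setNames(classify(f1), f1@id), cls1)
  hi <- n1[cls1 == "high"]
  lo <- n1[cls1 == "low"]
  if (length(hi) < nHighSires || length(lo) < nLowSires)
    stop("not enough N1 individuals of each phenotype to select sires")
  sires2 <- c(hi[seq_len(nHighSires)], lo[seq_len(nLowSires)])
  n2 <- list()
  for (s in sires2) {
    s@sex <- "M"
    n2 <- c(n2, cross(b6F, s, nN2PerSire, spec,
                      idPrefix = paste0("N2.", s@id)))
  }
  cls2 <- vapply(n2, classify, character(1))
  names(cls2) <- vapply(n2, function(i) i@id, character(1))
  classes <- c(classes, cls2)
  hi2 <- n2[cls2 == "high"]
  if (!length(hi2)) stop("no highly methylated N2 males to breed from")
  n3 <- list()
  k <- 1L
  while (length(n3) < nN3) {
    s <- hi2[[((k - 1L) %% length(hi2)) + 1L]]
    s@sex <- "M"
    litter <- cross(b6F, s, min(8L, nN3 - length(n3)), spec,
                    idPrefix = paste0("N3.", s@id, ".", k))
    n3 <- c(n3, litter)
    k <- k + 1L
  }
  cls3 <- vapply(n3, classify, character(1))
  names(cls3) <- vapply(n3, function(i) i@id, character(1))
  classes <- c(classes, cls3)
  ped <- pedigree(c(list(b6F, caM, f1), n1, n2, n3))
  list(pedigree = ped, n1 = n1, n2 = n2, n3 = n3, classes = classes,
       genotypes = genotypeIndividuals(n3, spec, missingRate = missingRate),
       truth = list(chrom = spec@modifierChrom, pos = spec@modifierPos,
                    strain = spec@modifierStrain))
}
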