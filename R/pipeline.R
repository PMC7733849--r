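# Config-driven orchestration of the full inference chain:
# simulate -> classify -> gbe -> map -> targets -> phylo -> profiles,
# emitting one JSON report plus re-readable intermediate files.

#' Default pipeline configuration
#'
#' A plain list (round-trippable through YAML) with the seed, enabled stages,
#' thresholds, design sizes and output directory.
#'
#' @param seed mandatory integer seed; every stochastic stage derives from it.
#' @param outdir output directory for intermediate files and the report.
#' @param stages character vector of enabled stages, in dependency order.
#' @param nPerGroup reciprocal-design group size.
#' @param markerSpacing marker spacing (bp) of the simulated SNP panel.
#' @param nN3 N3 individuals genotyped for mapping.
#' @param nTargets,nNontargets,nBackground LTR family composition.
#' @param thresholds named list overriding \code{\link{vmThresholds}} slots.
#' @return Named list.
#' @export
vmConfig <- function(seed, outdir = tempfile("vmiap_run_"),
                     stages = c("simulate", "classify", "gbe", "map",
                                "targets", "phylo", "profiles"),
                     nPerGroup = 50L, markerSpacing = 2e6, nN3 = 47L,
                     nTargets = 6L, nNontargets = 3L, nBackground = 20L,
                     thresholds = list()) {
  list(seed = as.integer(seed), outdir = outdir, stages = as.character(stages),
       nPerGroup = as.integer(nPerGroup), markerSpacing = markerSpacing,
       nN3 = as.integer(nN3), nTargets = as.integer(nTargets),
       nNontargets = as.integer(nNontargets),
       nBackground = as.integer(nBackground), thresholds = thresholds)
}

#' Read / write a pipeline configuration as YAML
#' @param config a configuration list from \code{\link{vmConfig}}.
#' @param path YAML file path.
#' @export
writeConfigYaml <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname writeConfigYaml
#' @export
readConfigYaml <- function(path) yaml::read_yaml(path)

.thFromConfig <- function(config) {
  do.call(vmThresholds, config$thresholds)
}

.logStage <- function(stage, ...) {
  message(sprintf("[vmiap:%s] %s", stage, paste0(...)))
}

#' Run the full pipeline
#'
#' Executes the enabled stages in dependency order on a fully simulated
#' data set, writing every intermediate file in its plain-text interchange
#' format and one JSON report. With the simulation manifest present the
#' report includes a ground-truth comparison (mapped interval vs the true
#' modifier position). Deterministic: the same config produces a
#' byte-identical report.
#'
#' @param config list from \code{\link{vmConfig}} (or read from YAML).
#' @return The report, invisibly; written to \code{outdir/report.json}.
#' @export
runPipeline <- function(config) {
  stopifnot(!is.null(config$seed))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  th <- .thFromConfig(config)
  stages <- config$stages
  report <- list()
  state <- new.env(parent = emptyenv())

  need <- function(what, stage) {
    if (is.null(state[[what]]))
      stop("stage '", stage, "' needs missing upstream output '", what, "'")
    state[[what]]
  }

  if ("simulate" %in% stages) {
    .logStage("simulate", "seed ", config$seed)
    spec <- defaultGenomeSpec(markerSpacing = config$markerSpacing)
    models <- list(
      L_zygotic = methylationModel(effectMode = "zygotic"),
      L_maternal = methylationModel(effectMode = "maternal"),
      L_both = methylationModel(effectMode = "maternal+zygotic"),
      L_none = methylationModel(effectMode = "none"))
    recip <- simulateReciprocalF1(models, spec, nPerGroup = config$nPerGroup)
    bc <- simulateBackcrossDesign(indexLocusModel(), spec, nN3 = config$nN3)
    fam <- evolveLtrFamily(config$nTargets, config$nNontargets,
                           config$nBackground)
    chromT <- c(chrT = 2000 * (length(fam$sequences) + 2))
    el <- GenomicRanges::GRanges(
      "chrT",
      IRanges::IRanges(start = 2000 * seq_along(fam$sequences),
                       width = fam$info$length),
      strand = fam$info$orientation)
    names(el) <- fam$info$id
    track <- synthCoverage(el, chromT,
                           enriched = fam$info$label != "background")
    writePedigreeCsv(recip$pedigree, file.path(config$outdir, "pedigree_f1.csv"))
    writeMethylationCsv(recip$methylation,
                        file.path(config$outdir, "methylation_f1.csv"))
    utils::write.csv(recip$groups, file.path(config$outdir, "groups_f1.csv"),
                     row.names = FALSE, quote = FALSE)
    writePedigreeCsv(bc$pedigree, file.path(config$outdir, "pedigree_bc.csv"))
    writeGenotypeCsv(bc$genotypes, file.path(config$outdir, "genotypes_n3.csv"))
    utils::write.csv(data.frame(individual = names(bc$classes),
                                class = unname(bc$classes)),
                     file.path(config$outdir, "phenotypes_bc.csv"),
                     row.names = FALSE, quote = FALSE)
    writeLtrFasta(fam, file.path(config$outdir, "ltrs.fa"))
    writeElementsBed(el, file.path(config$outdir, "elements.bed"))
    writeCoverageBedGraph(track, file.path(config$outdir, "coverage.bedgraph"))
    manifest <- list(seed = config$seed,
                     modifier = list(chrom = bc$truth$chrom,
                                     pos = bc$truth$pos,
                                     strain = bc$truth$strain),
                     effectModes = lapply(models, function(m) m@effectMode),
                     motif = fam$motif)
    writeManifest(manifest, file.path(config$outdir, "manifest.json"))
    state$spec <- spec
    state$recip <- recip
    state$bc <- bc
    state$fam <- fam
    state$elements <- el
    state$track <- track
    state$manifest <- manifest
    report$simulate <- list(
      nIndividualsF1 = nrow(recip$groups),
      nN3 = length(bc$n3),
      nLtr = length(fam$sequences),
      modifier = manifest$modifier)
  }

  if ("classify" %in% stages) {
    .logStage("classify", "variability + phenotype calls")
    mt <- readMethylationCsv(file.path(config$outdir, "methylation_f1.csv"))
    bc <- need("bc", "classify")
    loci <- unique(mt@data$locus)
    variability <- vapply(loci, function(lc)
      classifyVariability(individualMeans(mt, lc), th), character(1))
    classes <- bc$classes[names(bc$classes) %in%
                            vapply(bc$n3, function(i) i@id, character(1))]
    state$variability <- variability
    report$classify <- list(
      variability = as.list(variability),
      nHighN3 = sum(classes == "high"), nLowN3 = sum(classes == "low"))
  }

  if ("gbe" %in% stages) {
    recip <- need("recip", "gbe")
    .logStage("gbe", "Kruskal-Wallis + Dunn scan")
    gbe <- gbeScan(recip$methylation, recip$groups, alpha = th@alpha)
    utils::write.csv(gbe, file.path(config$outdir, "gbe_results.csv"),
                     row.names = FALSE, quote = FALSE)
    state$gbe <- gbe
    report$gbe <- setNames(as.list(gbe$category), gbe$locus)
  }

  if ("map" %in% stages) {
    bc <- need("bc", "map")
    spec <- need("spec", "map")
    .logStage("map", "SNP-intersection mapping")
    n3ids <- vapply(bc$n3, function(i) i@id, character(1))
    mm <- mapModifier(bc$genotypes, bc$classes[n3ids],
                      chromLengths = setNames(spec@chromosomes$lengthBp,
                                              spec@chromosomes$name),
                      alpha = th@alpha)
    outer <- mm$intervals[mm$intervals$boundsKind == "outer"]
    contained <- length(outer) == 1 &&
      as.character(GenomicRanges::seqnames(outer)) == bc$truth$chrom &&
      GenomicRanges::start(outer) <= bc$truth$pos &&
      GenomicRanges::end(outer) >= bc$truth$pos
    state$mapping <- mm
    report$map <- list(
      intervals = lapply(seq_along(mm$intervals), function(i) {
        gr <- mm$intervals[i]
        list(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             kind = gr$boundsKind, lengthMb = intervalLengthMb(gr))
      }),
      segregationP = mm$segregation$p,
      segregationConsistent = mm$segregation$consistent,
      truthContained = contained)
  }

  if ("targets" %in% stages) {
    fam <- need("fam", "targets")
    bc <- need("bc", "targets")
    .logStage("targets", "identity, alignment, window scan, concordance")
    vm <- fam$info$label != "background"
    ids <- fam$info$id[vm]
    idSeqs <- as.character(fam$sequences[vm])
    idx <- ids[fam$info$label[vm] == "target"][1]
    # orientation-normalized identity to the index locus
    norm <- ifelse(fam$info$orientation[vm] == "-",
                   vapply(idSeqs, reverseComplementSeq, character(1)), idSeqs)
    identity <- vapply(norm, percentIdentity, numeric(1),
                       b = norm[which(ids == idx)])
    names(identity) <- ids
    la <- alignMultiple(setNames(idSeqs, ids),
                        labels = fam$info$label[vm],
                        orientation = fam$info$orientation[vm])
    win <- divergentWindowScan(la)
    # methylation-state concordance over N2 individuals
    n2ids <- vapply(bc$n2, function(i) i@id, character(1))
    indexClasses <- bc$classes[n2ids]
    conc <- lapply(seq_along(ids), function(k) {
      mdl <- if (fam$info$label[vm][k] == "target") indexLocusModel()
             else methylationModel(effectMode = "none")
      cls <- vapply(bc$n2, function(ind)
        thresholdClassify(mean(assignMethylation(ind, mdl)), th), character(1))
      names(cls) <- n2ids
      concordanceTest(indexClasses, cls, threshold = th@concordanceMin)
    })
    names(conc) <- ids
    # group comparison with two-stage FDR: high vs low carriers per locus
    hi <- n2ids[indexClasses == "high"]; lo <- n2ids[indexClasses == "low"]
    pairs <- lapply(seq_along(ids), function(k) {
      mdl <- if (fam$info$label[vm][k] == "target") indexLocusModel()
             else methylationModel(effectMode = "none")
      means <- vapply(bc$n2, function(ind)
        mean(assignMethylation(ind, mdl)), numeric(1))
      names(means) <- n2ids
      list(a = unname(means[hi]), b = unname(means[lo]))
    })
    names(pairs) <- ids
    tb <- ttestBky(pairs, q = th@fdrQ)
    state$targets <- list(identity = identity, windows = win,
                          concordance = conc, ttest = tb)
    report$targets <- list(
      identity = as.list(round(identity, 1)),
      topWindowLength = if (nrow(win)) win$lengthConsensus[1] else NA,
      verdicts = lapply(conc, `[[`, "verdict"),
      discoveries = setNames(as.list(tb$discovery), tb$locus))
  }

  if ("phylo" %in% stages) {
    fam <- need("fam", "phylo")
    .logStage("phylo", "NJ tree + clade enrichment")
    kept <- lengthFilter(fam$sequences, th)
    keptInfo <- fam$info[fam$info$id %in% names(kept), , drop = FALSE]
    la <- alignMultiple(setNames(as.character(kept), names(kept)),
                        labels = keptInfo$label,
                        orientation = keptInfo$orientation)
    D <- pDistanceMatrix(la)
    tree <- neighborJoining(D)
    ape::write.tree(tree, file.path(config$outdir, "ltr_nj.nwk"))
    vmLeaves <- keptInfo$id[keptInfo$label %in% c("target", "nontarget")]
    enr <- subtreeEnrichment(tree, vmLeaves, nPerm = 1000L)
    state$phylo <- list(tree = tree, enrichment = enr)
    report$phylo <- list(nLeaves = length(tree$tip.label),
                         vmInBestClade = enr$vmInClade,
                         bestCladeSize = enr$cladeSize,
                         hypergeomP = enr$hypergeomP, permP = enr$permP)
  }

  if ("profiles" %in% stages) {
    .logStage("profiles", "anchored metaprofiles")
    track <- readCoverageBedGraph(file.path(config$outdir, "coverage.bedgraph"))
    el <- readElementsBed(file.path(config$outdir, "elements.bed"))
    fam <- need("fam", "profiles")
    am <- anchoredMatrix(track, el, th)
    grp <- ifelse(fam$info$label == "background", "background", "VM")
    gc <- groupCompare(am, grp, compare = c("VM", "background"))
    utils::write.table(am@mat, file.path(config$outdir, "anchored_matrix.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    nb <- am@pseudolength
    body <- gc$difference[am@flank + seq_len(nb)]
    q3 <- mean(body[seq(3 * nb %/% 4 + 1, nb)])
    q1 <- mean(body[seq_len(nb %/% 4)])
    report$profiles <- list(
      meanDifference = mean(gc$difference),
      threePrimeQuarterMean = q3, fivePrimeQuarterMean = q1,
      threePrimeBiased = q3 > q1)
  }

  report <- c(list(seed = config$seed,
                   package = as.character(utils::packageVersion("vmiap")),
                   stages = stages),
              report)
  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
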