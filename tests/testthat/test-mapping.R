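# SNP-intersection mapping, interval arithmetic, segregation, pedigree rules.

grOf <- function(chrom, s, e) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(s, e))
}

test_that("the intersection filter keeps strictly concordant markers", {
  markers <- data.frame(chrom = "chr4", pos = c(10, 20, 30) * 1e3)
  calls <- rbind(
    c("BC", "BC", "BC", "BB", "BB", "BB"),   # concordant
    c("BC", "BC", "BC", "BC", "BB", "BB"),   # one low het
    c("BC", NA,   "BC", "BB", "BB", "BB"))   # missing in a high individual
  colnames(calls) <- paste0("i", 1:6)
  gm <- genotypeMatrix(markers, calls)
  labels <- setNames(rep(c("high", "low"), each = 3), paste0("i", 1:6))
  res <- candidateSnps(gm, labels)
  expect_identical(unname(res$status), c("candidate", "violating",
                                         "non-informative"))
  expect_identical(res$candidates$pos, 1e4)
  expect_error(candidateSnps(gm, labels[labels == "high"]), "empty")
})

test_that("homozygous-CAST calls are reported as genotyping errors", {
  markers <- data.frame(chrom = "chr4", pos = c(1, 2))
  calls <- rbind(c("BC", "CC"), c("BC", "BB"))
  colnames(calls) <- c("h1", "l1")
  gm <- genotypeMatrix(markers, calls)
  res <- candidateSnps(gm, c(h1 = "high", l1 = "low"))
  expect_identical(res$ccErrors$individual, "l1")
  expect_identical(unname(res$status[1]), "violating")
})

test_that("the filter equals a brute-force double loop on random matrices", {
  set.seed(1)
  for (i in 1:300) {
    cs <- randomGenotypeCase()
    hi <- names(cs$labels)[cs$labels == "high"]
    lo <- names(cs$labels)[cs$labels == "low"]
    got <- cs$gm@markers$id %in% candidateSnps(cs$gm, cs$labels)$candidates$id
    expect_identical(got, naiveCandidateFilter(cs$gm@calls, hi, lo))
  }
})

test_that("candidate selection ignores individual and marker order", {
  set.seed(2)
  cs <- randomGenotypeCase(nMarkers = 30, missingRate = 0.1)
  res1 <- candidateSnps(cs$gm, cs$labels)
  pm <- sample(nrow(cs$gm@calls)); pi <- sample(ncol(cs$gm@calls))
  gm2 <- genotypeMatrix(cs$gm@markers[pm, ], cs$gm@calls[pm, pi])
  res2 <- candidateSnps(gm2, cs$labels[pi])
  expect_identical(sort(res1$candidates$id), sort(res2$candidates$id))
})

test_that("interval assembly uses candidate span and flanking failures", {
  markers <- data.frame(chrom = "chr4", pos = c(5, 10, 20, 30, 40) * 1e3)
  calls <- cbind(h1 = c("BB", "BC", "BC", "BC", "BB"),
                 l1 = c("BB", "BB", "BB", "BB", "BC"))
  gm <- genotypeMatrix(markers, calls)
  res <- candidateSnps(gm, c(h1 = "high", l1 = "low"))
  gr <- assembleInterval(res, gm)
  inner <- gr[gr$boundsKind == "inner"]
  outer <- gr[gr$boundsKind == "outer"]
  expect_equal(GenomicRanges::start(inner), 1e4)
  expect_equal(GenomicRanges::end(inner), 3e4)
  expect_equal(GenomicRanges::start(outer), 5e3 + 1)   # exclusive of failures
  expect_equal(GenomicRanges::end(outer), 4e4 - 1)
  # outer always contains inner
  expect_true(GenomicRanges::start(outer) <= GenomicRanges::start(inner) &&
              GenomicRanges::end(outer) >= GenomicRanges::end(inner))
})

test_that("a single candidate yields a 1-bp inner interval", {
  markers <- data.frame(chrom = "chr4", pos = c(100, 200, 300))
  calls <- cbind(h1 = c("BB", "BC", "BB"), l1 = c("BB", "BB", "BC"))
  gm <- genotypeMatrix(markers, calls)
  gr <- assembleInterval(candidateSnps(gm, c(h1 = "high", l1 = "low")), gm)
  inner <- gr[gr$boundsKind == "inner"]
  expect_equal(GenomicRanges::width(inner), 1)
})

test_that("combining experiments intersects printed-style intervals", {
  a <- grOf("chr4", 141964197, 149000000)
  b <- grOf("chr4", 140000000, 148393136)
  comb <- combineExperiments(a, b)
  expect_equal(GenomicRanges::start(comb), 141964197)
  expect_equal(GenomicRanges::end(comb), 148393136)
  expect_equal(combineExperiments(a, a), a)                 # idempotent
  nested <- grOf("chr4", 142000000, 143000000)
  expect_equal(combineExperiments(a, nested), nested)       # nested
  expect_error(combineExperiments(a, grOf("chr4", 1, 2)), "disjoint")
  expect_error(combineExperiments(a, grOf("chr1", 141964197, 149000000)),
               "different chromosomes")
})

test_that("interval lengths print like genome-browser coordinates", {
  expect_equal(intervalLengthMb(grOf("chr4", 141964197, 148393136)), 6.4)
  expect_equal(intervalLengthMb(grOf("chr4", 145383918, 147853419)), 2.5)
  expect_equal(intervalLengthMb(grOf("chr4", 100, 100)), 0.0)
})

test_that("segregation test gives exact binomial verdicts", {
  s <- segregationTest(10, 10)
  expect_equal(s$p, 1)
  expect_true(s$consistent)
  s2 <- segregationTest(20, 0)
  expect_equal(s2$p, 2 * 0.5^20, tolerance = 1e-12)
  expect_false(s2$consistent)
  s3 <- segregationTest(23, 24)     # the N3 design counts
  expect_true(s3$consistent)
})

test_that("pedigree consistency accepts a dominant single-locus backcross", {
  set.seed(3)
  spec <- tinySpec()
  bc <- simulateBackcrossDesign(spec = spec, nN1 = 30, phenotype = "allele")
  # the F1 is phenotyped but its founder parents are not: excluded with warning
  expect_warning(res <- pedigreeConsistency(bc$pedigree, bc$classes),
                 "without a typed parent")
  expect_true(res$consistent)
  expect_true(all(res$byGeneration))
  # offspring of low parents must all be low
  lowFams <- res$families[res$families$parentClass == "low", ]
  expect_true(all(lowFams$nHigh == 0))
})

test_that("phenotyping errors break the low-parent rule", {
  set.seed(4)
  spec <- tinySpec()
  bc <- simulateBackcrossDesign(spec = spec, nN1 = 30, phenotype = "allele")
  classes <- bc$classes
  flip <- sample(seq_along(classes), round(0.2 * length(classes)))
  classes[flip] <- ifelse(classes[flip] == "high", "low", "high")
  res <- suppressWarnings(pedigreeConsistency(bc$pedigree, classes))
  expect_false(res$consistent)
})

test_that("phenotyped individuals without typed parents are excluded", {
  set.seed(5)
  spec <- tinySpec()
  bc <- simulateBackcrossDesign(spec = spec, nN1 = 20, phenotype = "allele")
  n1ids <- vapply(bc$n1, function(i) i@id, character(1))
  expect_warning(pedigreeConsistency(bc$pedigree, bc$classes[n1ids]),
                 "without a typed parent")
})

test_that("adding a correctly phenotyped individual never widens the interval", {
  set.seed(6)
  spec <- defaultGenomeSpec(markerSpacing = 4e6)
  for (r in 1:20) {
    bc <- simulateBackcrossDesign(spec = spec, nN1 = 30, nN3 = 20,
                                  phenotype = "allele")
    ids <- vapply(bc$n3, function(i) i@id, character(1))
    sub <- candidateSnps(
      genotypeMatrix(bc$genotypes@markers, bc$genotypes@calls[, ids[1:19]]),
      bc$classes[ids[1:19]])
    full <- candidateSnps(bc$genotypes, bc$classes[ids])
    if (!nrow(sub$candidates) || !nrow(full$candidates)) next
    grSub <- assembleInterval(sub, bc$genotypes)
    grFull <- assembleInterval(full, bc$genotypes)
    oS <- grSub[grSub$boundsKind == "outer" &
                  as.character(GenomicRanges::seqnames(grSub)) == "chr4"]
    oF <- grFull[grFull$boundsKind == "outer" &
                   as.character(GenomicRanges::seqnames(grFull)) == "chr4"]
    expect_true(GenomicRanges::start(oF) >= GenomicRanges::start(oS))
    expect_true(GenomicRanges::end(oF) <= GenomicRanges::end(oS))
  }
})

test_that("error-free phenotyping always recovers the true locus", {
  set.seed(7)
  spec <- defaultGenomeSpec(markerSpacing = 4e6)
  for (r in 1:20) {
    bc <- simulateBackcrossDesign(spec = spec, nN1 = 30, phenotype = "allele")
    ids <- vapply(bc$n3, function(i) i@id, character(1))
    mm <- mapModifier(bc$genotypes, bc$classes[ids],
                      chromLengths = setNames(spec@chromosomes$lengthBp,
                                              spec@chromosomes$name))
    outer <- mm$intervals[mm$intervals$boundsKind == "outer" &
        as.character(GenomicRanges::seqnames(mm$intervals)) == bc$truth$chrom]
    expect_length(outer, 1)
    expect_true(GenomicRanges::start(outer) <= bc$truth$pos &&
                GenomicRanges::end(outer) >= bc$truth$pos)
  }
})

test_that("genotype CSV round-trips including missing calls", {
  set.seed(8)
  cs <- randomGenotypeCase(missingRate = 0.2)
  f <- tempfile(fileext = ".csv")
  writeGenotypeCsv(cs$gm, f)
  back <- readGenotypeCsv(f)
  expect_identical(unname(back@calls), unname(cs$gm@calls))
  expect_equal(back@markers$pos, cs$gm@markers$pos)
})
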