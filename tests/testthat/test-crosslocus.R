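# Sequence identity, multiple alignment, window scan, concordance, BKY FDR.

test_that("reverse complement is correct and involutive", {
  expect_identical(reverseComplementSeq("ACGT"), "ACGT")
  expect_identical(reverseComplementSeq("AAAC"), "GTTT")
  expect_identical(reverseComplementSeq("ANT"), "ANT")
  # independent implementation: complement by chartr, then reverse
  rcOracle <- function(x) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
  }
  set.seed(1)
  for (i in 1:200) {
    x <- paste(sample(c("A", "C", "G", "T"), sample(5:60, 1), TRUE),
               collapse = "")
    expect_identical(reverseComplementSeq(reverseComplementSeq(x)), x)
    expect_identical(reverseComplementSeq(x), rcOracle(x))
  }
})

test_that("percent identity matches closed-form substitution counts", {
  expect_equal(percentIdentity("ACGTACGT", "ACGTACGT"), 100)
  expect_equal(percentIdentity("AAAA", "AATA"), 75)
  expect_error(percentIdentity("", "ACGT"), "empty")
  set.seed(2)
  for (i in 1:50) {
    L <- 200
    a <- sample(c("A", "C", "G", "T"), L, TRUE)
    nSub <- sample(0:10, 1)
    pos <- sample(L, nSub)
    b <- a
    for (p in pos) b[p] <- sample(setdiff(c("A", "C", "G", "T"), a[p]), 1)
    sa <- paste(a, collapse = ""); sb <- paste(b, collapse = "")
    expect_equal(percentIdentity(sa, sb), round(100 * (L - nSub) / L, 1))
    expect_equal(percentIdentity(sa, sb), percentIdentity(sb, sa))  # symmetry
  }
})

test_that("percent identity agrees with Biostrings on substitution-only pairs", {
  set.seed(3)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  for (i in 1:20) {
    a <- paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
    b <- strsplit(a, "")[[1]]
    pos <- sample(150, 6)
    for (p in pos) b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1)
    b <- paste(b, collapse = "")
    al <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                        substitutionMatrix = mat,
                                        gapOpening = 2, gapExtension = 1)
    expect_equal(percentIdentity(a, b), round(Biostrings::pid(al, "PID1"), 1))
  }
})

test_that("progressive alignment handles identical and inserted sequences", {
  s <- c(x = "ACGTACGTACGTACGTACGT", y = "ACGTACGTACGTACGTACGT")
  la <- alignMultiple(s)
  expect_false(any(grepl("-", la@aln)))
  expect_identical(unname(la@aln[1]), unname(la@aln[2]))
  # a planted 4-bp insertion becomes one 4-column gap block in other rows
  base <- paste(rep(c("A", "C", "G", "T"), 10), collapse = "")
  withIns <- paste0(substr(base, 1, 20), "TTTT", substr(base, 21, 40))
  la2 <- alignMultiple(c(a = base, b = base, c = withIns))
  expect_equal(nchar(la2@aln[[1]]), 44)
  gaps <- gregexpr("-+", la2@aln[["a"]])[[1]]
  expect_equal(attr(gaps, "match.length"), 4)
  expect_false(grepl("-", la2@aln[["c"]]))
  # column count is at least the longest input
  set.seed(4)
  seqs <- vapply(1:5, function(i)
    paste(sample(c("A", "C", "G", "T"), sample(30:40, 1), TRUE), collapse = ""),
    character(1))
  names(seqs) <- paste0("s", 1:5)
  la3 <- alignMultiple(seqs)
  expect_gte(nchar(la3@aln[[1]]), max(nchar(seqs)))
  expect_identical(names(la3@aln), names(seqs))   # input order kept
})

test_that("contraoriented sequences are normalized before alignment", {
  base <- "ACCGTTGACATGCATGCAAGGT"
  la <- alignMultiple(c(f = base, r = reverseComplementSeq(base)),
                      orientation = c("+", "-"))
  expect_identical(unname(la@aln[["f"]]), base)
  expect_identical(unname(la@aln[["r"]]), base)
})

test_that("window scan scores columns by group discrimination", {
  mkLa <- function(rows, labels) {
    new("LabelledAlignment", aln = rows, labels = labels,
        orientation = rep("+", length(rows)))
  }
  # identical sequences: nothing discriminates
  la0 <- mkLa(rep("ACGTACGTACGT", 4),
              c("target", "target", "nontarget", "nontarget"))
  expect_equal(nrow(divergentWindowScan(la0, minLen = 1)), 0)
  expect_error(divergentWindowScan(mkLa(rep("ACGT", 2), rep("target", 2))),
               "both target and nontarget")
  # two hit clusters separated by 2 low columns merge into one window
  t1 <- "AAAAAAAAAAAAAA"
  n1 <- "AATTAATTAAAAAA"   # hits at 3,4 and 7,8; gap columns 5,6
  la1 <- mkLa(c(t1, t1, n1, n1),
              c("target", "target", "nontarget", "nontarget"))
  w1 <- divergentWindowScan(la1, minScore = 0.5, minLen = 1)
  expect_equal(nrow(w1), 1)
  expect_equal(c(w1$startCol, w1$endCol), c(3, 8))
  # separated by 3 low columns: two windows
  n2 <- "AATTAAATTAAAAA"   # hits at 3,4 and 8,9; gap columns 5,6,7
  la2 <- mkLa(c(t1, t1, n2, n2),
              c("target", "target", "nontarget", "nontarget"))
  w2 <- divergentWindowScan(la2, minScore = 0.5, minLen = 1)
  expect_equal(nrow(w2), 2)
})

test_that("the planted 28-bp divergent segment is recovered exactly", {
  hits <- 0
  for (s in 1:20) {
    set.seed(100 + s)
    fam <- evolveLtrFamily(6, 3, 0)
    vm <- fam$info$label != "background"
    la <- alignMultiple(setNames(as.character(fam$sequences[vm]),
                                 fam$info$id[vm]),
                        labels = fam$info$label[vm],
                        orientation = fam$info$orientation[vm])
    w <- divergentWindowScan(la)
    hits <- hits + (nrow(w) > 0 && w$lengthConsensus[1] == 28)
  }
  expect_gte(hits, 19)
})

test_that("window scan is invariant to row permutation within labels", {
  set.seed(5)
  fam <- evolveLtrFamily(5, 3, 0)
  vm <- fam$info$label != "background"
  la <- alignMultiple(setNames(as.character(fam$sequences[vm]),
                               fam$info$id[vm]),
                      labels = fam$info$label[vm],
                      orientation = fam$info$orientation[vm])
  perm <- sample(length(la@aln))
  la2 <- new("LabelledAlignment", aln = la@aln[perm],
             labels = la@labels[perm], orientation = la@orientation[perm])
  expect_equal(divergentWindowScan(la), divergentWindowScan(la2))
})

test_that("concordance fractions behave at the extremes and under the null", {
  idx <- setNames(rep(c("high", "low"), 10), paste0("i", 1:20))
  expect_equal(concordanceTest(idx, idx),
               list(fraction = 1, n = 20, verdict = "target"))
  expect_error(concordanceTest(idx, setNames("high", "other")), "no shared")
  set.seed(6)
  n <- 10000
  a <- setNames(sample(c("high", "low"), n, TRUE), paste0("x", 1:n))
  b <- setNames(sample(c("high", "low"), n, TRUE), paste0("x", 1:n))
  ct <- concordanceTest(a, b)
  expect_lt(abs(ct$fraction - 0.5), 3 * sqrt(0.25 / n))
  expect_identical(ct$verdict, "nontarget")
})

test_that("motif-intact loci get target verdicts, disrupted loci do not", {
  set.seed(7)
  spec <- tinySpec()
  bc <- simulateBackcrossDesign(spec = spec, nN1 = 30, nN2PerSire = 8,
                                phenotype = "allele")
  n2ids <- vapply(bc$n2, function(i) i@id, character(1))
  idxClasses <- bc$classes[n2ids]
  verdicts <- vapply(c(rep(TRUE, 6), rep(FALSE, 2)), function(intact) {
    mdl <- if (intact) indexLocusModel() else methylationModel(effectMode = "none")
    cls <- vapply(bc$n2, function(ind)
      thresholdClassify(mean(assignMethylation(ind, mdl))), character(1))
    names(cls) <- n2ids
    concordanceTest(idxClasses, cls)$verdict
  }, character(1))
  expect_identical(verdicts, c(rep("target", 6), rep("nontarget", 2)))
})

test_that("pooled t matches t.test and handles degenerate input", {
  tb0 <- ttestBky(list(a = list(a = c(1, 2, 3), b = c(1, 2, 3)),
                       b = list(a = c(5, 5), b = c(5, 5))))
  expect_equal(tb0$p, c(1, 1))
  expect_false(any(tb0$discovery))
  set.seed(8)
  for (i in 1:50) {
    x <- rnorm(sample(3:10, 1)); y <- rnorm(sample(3:10, 1), mean = runif(1, 0, 2))
    ours <- vmiap:::.pooledT(x, y)
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("BKY discoveries are a superset of BH at q/(1+q)", {
  set.seed(9)
  q <- 0.05
  for (i in 1:200) {
    m <- sample(c(10, 50, 100), 1)
    p <- c(runif(m - 5), rbeta(5, 0.1, 10))[sample(m)]
    bky <- bkyDiscoveries(p, q)
    bh <- p.adjust(p, "BH") <= q / (1 + q)
    expect_true(all(bky[bh]))
  }
})

test_that("BKY finds strongly shifted loci with high power", {
  set.seed(10)
  td <- replicate(100, {
    pairs <- lapply(1:20, function(k) {
      shift <- if (k <= 5) 3 else 0
      list(a = rnorm(10, shift), b = rnorm(10))
    })
    names(pairs) <- paste0("L", 1:20)
    res <- ttestBky(pairs, q = 0.05)
    sum(res$discovery[1:5])
  })
  expect_gte(mean(td), 4.5)
})
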