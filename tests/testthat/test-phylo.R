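# Length filter, p-distances, neighbor joining, clade enrichment.

test_that("length filter keeps the inclusive 200-800 bp window", {
  th <- vmThresholds()
  seqs <- setNames(vapply(c(150, 200, 500, 800, 900), function(L)
    paste(rep("A", L), collapse = ""), character(1)),
    paste0("s", 1:5))
  kept <- lengthFilter(seqs, th)
  expect_identical(names(kept), c("s2", "s3", "s4"))
  expect_identical(lengthFilter(character(0), th), character(0))
  inRange <- seqs[2:4]
  expect_identical(lengthFilter(inRange, th), inRange)
  dss <- Biostrings::DNAStringSet(seqs)
  expect_identical(names(lengthFilter(dss, th)), c("s2", "s3", "s4"))
})

test_that("p-distances use pairwise deletion and match a column loop", {
  expect_true(all(pDistanceMatrix(c(a = "ACGT", b = "ACGT")) == 0))
  D <- pDistanceMatrix(c(a = "AAAA", b = "AATT"))
  expect_equal(D["a", "b"], 0.5)
  # gap columns are dropped pairwise
  D2 <- pDistanceMatrix(c(a = "A-CG", b = "ATC-"))
  expect_equal(D2["a", "b"], 0)     # comparable columns: 1 and 3, both equal
  expect_error(pDistanceMatrix(c(a = "A--", b = "-AA")), "no comparable")
  set.seed(1)
  for (i in 1:50) {
    n <- sample(3:6, 1); L <- 40
    rows <- vapply(seq_len(n), function(k) {
      x <- sample(c("A", "C", "G", "T", "-"), L, TRUE,
                  prob = c(rep(0.23, 4), 0.08))
      paste(x, collapse = "")
    }, character(1))
    names(rows) <- paste0("t", seq_len(n))
    D <- pDistanceMatrix(rows)
    mat <- do.call(rbind, strsplit(rows, ""))
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      mism <- 0; comp <- 0
      for (j in 1:L) {
        if (mat[a, j] != "-" && mat[b, j] != "-") {
          comp <- comp + 1
          if (mat[a, j] != mat[b, j]) mism <- mism + 1
        }
      }
      expect_equal(D[a, b], mism / comp)
      expect_equal(D[a, b], D[b, a])
    }
  }
})

test_that("NJ reproduces the additive 4-taxon tree exactly", {
  D <- matrix(c(0, 2, 4, 4,
                2, 0, 4, 4,
                4, 4, 0, 2,
                4, 4, 2, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighborJoining(D)
  expect_s3_class(tr, "phylo")
  expect_equal(phangorn::RF.dist(tr, ape::nj(D)), 0)
  # path lengths reproduce the input distances (limbs 1,1,1,1; internal 2)
  expect_equal(ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]], D,
               tolerance = 1e-12)
  expect_false(attr(tr, "negativeClamped"))
  expect_error(neighborJoining(D[1:2, 1:2]), "at least 3")
})

test_that("the 3-taxon tree uses the closed-form limb lengths", {
  D <- matrix(c(0, 3, 4,
                3, 0, 5,
                4, 5, 0), 3, 3, dimnames = list(c("a", "b", "c"),
                                                c("a", "b", "c")))
  tr <- neighborJoining(D)
  len <- setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])],
                  tr$tip.label)
  expect_equal(len[["a"]], 1)
  expect_equal(len[["b"]], 2)
  expect_equal(len[["c"]], 3)
})

test_that("NJ is consistent on random additive matrices", {
  set.seed(2)
  for (i in 1:20) {
    cs <- randomAdditiveCase(n = sample(8:16, 1))
    tr <- neighborJoining(cs$D)
    expect_equal(phangorn::RF.dist(tr, cs$tree), 0)
    got <- ape::cophenetic.phylo(tr)
    expect_equal(got[rownames(cs$D), colnames(cs$D)], cs$D, tolerance = 1e-9)
    # independent implementation agrees on additive input
    expect_equal(phangorn::RF.dist(tr, ape::nj(cs$D)), 0)
  }
})

test_that("NJ topology ignores taxon ordering", {
  set.seed(3)
  cs <- randomAdditiveCase(10)
  perm <- sample(10)
  tr1 <- neighborJoining(cs$D)
  tr2 <- neighborJoining(cs$D[perm, perm])
  expect_equal(phangorn::RF.dist(tr1, tr2), 0)
})

test_that("newick serialization is byte-stable through a round trip", {
  set.seed(4)
  cs <- randomAdditiveCase(8)
  tr <- neighborJoining(cs$D)
  f1 <- tempfile(fileext = ".nwk"); f2 <- tempfile(fileext = ".nwk")
  ape::write.tree(tr, f1)
  tr2 <- ape::read.tree(f1)
  ape::write.tree(tr2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("a perfect VM clade reaches the closed-form hypergeometric floor", {
  # two tight blocks far apart: the VM block forms one exact clade
  n <- 10; k <- 4
  D <- matrix(8, n, n)
  D[1:k, 1:k] <- 1
  D[(k + 1):n, (k + 1):n] <- 1
  diag(D) <- 0
  dimnames(D) <- list(paste0("t", 1:n), paste0("t", 1:n))
  tr <- neighborJoining(D)
  set.seed(5)
  enr <- subtreeEnrichment(tr, paste0("t", 1:k), nPerm = 200)
  expect_identical(sort(enr$bestClade), sort(paste0("t", 1:k)))
  expect_equal(enr$hypergeomP, 1 / choose(n, k))
  expect_lt(enr$permP, 0.05)
})

test_that("a single VM leaf is its own best clade with permutation p 1", {
  set.seed(6)
  cs <- randomAdditiveCase(8)
  tr <- neighborJoining(cs$D)
  enr <- subtreeEnrichment(tr, tr$tip.label[1], nPerm = 100)
  expect_identical(enr$bestClade, tr$tip.label[1])
  expect_equal(enr$cladeSize, 1)
  expect_equal(enr$permP, 1)   # every relabelling achieves the same minimum
})

test_that("permutation p-values are valid (super-uniform) under random labels", {
  # the +1-corrected permutation p of a clade-search minimum is discrete and
  # conservative, so P(p <= t) <= t; check that coverage bound empirically
  # and that the p-values still spread over the unit interval
  set.seed(7)
  ps <- replicate(100, {
    cs <- randomAdditiveCase(10)
    tr <- neighborJoining(cs$D)
    enr <- subtreeEnrichment(tr, sample(tr$tip.label, 3), nPerm = 99)
    enr$permP
  })
  for (t in c(0.05, 0.2, 0.5)) {
    expect_lte(mean(ps <= t), t + 3 * sqrt(t * (1 - t) / length(ps)))
  }
  expect_gt(stats::sd(ps), 0.1)
})
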