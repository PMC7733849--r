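# Shared fixtures: compact genomes and brute-force oracles used across tests.

# one-chromosome genome with the modifier at the midpoint
tinySpec <- function(lengthBp = 1e8, lengthM = 1, spacing = 1e7) {
  pos <- sort(unique(c(seq(spacing / 2, lengthBp, by = spacing), lengthBp / 2)))
  genomeSpec(
    data.frame(name = "chr4", lengthBp = lengthBp, lengthM = lengthM),
    data.frame(chrom = "chr4", pos = pos),
    modifierChrom = "chr4", modifierPos = lengthBp / 2)
}

# naive per-individual means by explicit double loop
naiveIndividualMeans <- function(df, locus) {
  d <- df[df$locus == locus, ]
  inds <- sort(unique(d$individual))
  out <- numeric(length(inds))
  for (i in seq_along(inds)) {
    v <- d$percent[d$individual == inds[i]]
    out[i] <- sum(v) / length(v)
  }
  names(out) <- inds
  out
}

# brute-force tie-corrected Kruskal-Wallis H from the rank formula
naiveKruskalH <- function(groups) {
  x <- unlist(groups)
  N <- length(x)
  # midranks by explicit counting
  r <- vapply(x, function(v) sum(x < v) + (sum(x == v) + 1) / 2, numeric(1))
  idx <- rep(seq_along(groups), lengths(groups))
  H <- 12 / (N * (N + 1)) *
    sum(vapply(seq_along(groups), function(g) {
      n <- sum(idx == g)
      n * (mean(r[idx == g]) - (N + 1) / 2)^2
    }, numeric(1)))
  tt <- table(x)
  H / (1 - sum(tt^3 - tt) / (N^3 - N))
}

# brute-force Dunn z for one pair, same midranks computed by counting
naiveDunnZ <- function(groups, i, j) {
  x <- unlist(groups)
  N <- length(x)
  r <- vapply(x, function(v) sum(x < v) + (sum(x == v) + 1) / 2, numeric(1))
  idx <- rep(seq_along(groups), lengths(groups))
  tt <- table(x)
  S2 <- N * (N + 1) / 12 - sum(tt^3 - tt) / (12 * (N - 1))
  (mean(r[idx == i]) - mean(r[idx == j])) /
    sqrt(S2 * (1 / sum(idx == i) + 1 / sum(idx == j)))
}

# brute-force SNP-intersection filter by explicit double loop
naiveCandidateFilter <- function(calls, hi, lo) {
  keep <- logical(nrow(calls))
  for (m in seq_len(nrow(calls))) {
    ok <- TRUE
    for (ind in hi) {
      v <- calls[m, ind]
      if (is.na(v) || v != "BC") { ok <- FALSE; break }
    }
    if (ok) for (ind in lo) {
      v <- calls[m, ind]
      if (is.na(v) || v != "BB") { ok <- FALSE; break }
    }
    keep[m] <- ok
  }
  keep
}

# random genotype matrix + labels for filter oracle checks
randomGenotypeCase <- function(nMarkers = 20, nInd = 12, missingRate = 0.05) {
  markers <- data.frame(chrom = "chr1",
                        pos = sort(sample.int(1e6, nMarkers)))
  inds <- paste0("i", seq_len(nInd))
  calls <- matrix(sample(c("BB", "BC", "CC"), nMarkers * nInd, TRUE,
                         prob = c(0.45, 0.45, 0.1)),
                  nMarkers, nInd, dimnames = list(NULL, inds))
  calls[runif(length(calls)) < missingRate] <- NA
  labels <- setNames(sample(rep(c("high", "low"), length.out = nInd)), inds)
  list(gm = genotypeMatrix(markers, calls), labels = labels)
}

# reciprocal-design per-individual means drawn through the breeding simulator
simulateGbeGroups <- function(mode, nPerGroup = 50, spec = tinySpec()) {
  models <- list(L = methylationModel(effectMode = mode))
  sim <- simulateReciprocalF1(models, spec, nPerGroup = nPerGroup)
  m <- individualMeans(sim$methylation, "L")
  lapply(c("B6", "BC", "CB"), function(g)
    unname(m[sim$groups$individual[sim$groups$group == g]])) |>
    setNames(c("B6", "BC", "CB"))
}

# random additive tree and its exact leaf distance matrix
randomAdditiveCase <- function(n = 12) {
  tr <- ape::rtree(n, rooted = FALSE, br = function(k) runif(k, 0.05, 1))
  D <- ape::cophenetic.phylo(tr)
  D <- D[order(rownames(D)), order(colnames(D))]
  list(tree = tr, D = D)
}
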