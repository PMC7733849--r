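# Solo-LTR phylogenetics: length filter, p-distances, neighbor joining
# (Saitou-Nei with the Studier-Keppler Q criterion), and VM-clade enrichment.

#' Filter sequences by length
#'
#' Retains sequences with length between the NJ length bounds, inclusive
#' (defaults 200-800 bp, the usual solo-LTR window).
#'
#' @param seqs named character vector or \code{DNAStringSet}.
#' @param th a \linkS4class{VmThresholds}.
#' @return The retained subset, same type as the input.
#' @export
lengthFilter <- function(seqs, th = vmThresholds()) {
  len <- if (methods::is(seqs, "XStringSet")) Biostrings::width(seqs)
         else nchar(as.character(seqs))
  seqs[len >= th@njLenMin & len <= th@njLenMax]
}

#' Pairwise p-distance matrix from a gapped alignment
#'
#' d(i, j) = mismatches / columns where both rows are ungapped (pairwise
#' deletion). A pair with no comparable column is an error.
#'
#' @param aln a \linkS4class{LabelledAlignment}, or a named character vector
#'   of equal-length gapped sequences.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
pDistanceMatrix <- function(aln) {
  s <- if (methods::is(aln, "LabelledAlignment")) aln@aln else {
    nms <- names(aln)
    x <- as.character(aln)
    names(x) <- nms
    x
  }
  mat <- .charMatrix(s)
  n <- nrow(mat)
  D <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  if (!is.null(names(s))) dimnames(D) <- list(names(s), names(s))
  ung <- mat != "-"
  for (i in seq_len(max(0, n - 1L))) for (j in seq(i + 1L, n)) {
    both <- ung[i, ] & ung[j, ]
    if (!any(both)) stop("no comparable columns between sequences ", i, " and ", j)
    d <- mean(mat[i, both] != mat[j, both])
    D[i, j] <- D[j, i] <- d
  }
  D
}

.fmtLen <- function(x) sprintf("%.10g", x)

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration using the Studier-Keppler Q criterion, with a
#' deterministic tie-break (lowest index pair) and the standard limb-length
#' formulas; negative limb estimates are clamped to zero and flagged in the
#' \code{negativeClamped} attribute.
#'
#' @param D symmetric distance matrix with taxon dimnames, n >= 3.
#' @return An unrooted \code{ape::phylo} tree.
#' @export
neighborJoining <- function(D) {
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  stopifnot(isSymmetric(unname(D)), all(diag(D) == 0))
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  reps <- labels
  clamped <- FALSE
  clampLen <- function(x) {
    if (x < 0) { clamped <<- TRUE; 0 } else x
  }
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    best <- c(NA_integer_, NA_integer_); bestQ <- Inf
    for (i in seq_len(m - 1L)) for (j in seq(i + 1L, m)) {
      if (Q[i, j] < bestQ) { bestQ <- Q[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    li <- clampLen(D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2)))
    lj <- clampLen(D[i, j] - (D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))))
    newRep <- paste0("(", reps[i], ":", .fmtLen(li), ",",
                     reps[j], ":", .fmtLen(lj), ")")
    newD <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], newD[keep]),
                c(newD[keep], 0))
    reps <- c(reps[keep], newRep)
    rownames(D2) <- colnames(D2) <- reps
    D <- D2
  }
  la <- clampLen((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  lb <- clampLen((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  lc <- clampLen((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- paste0("(", reps[1], ":", .fmtLen(la), ",",
                reps[2], ":", .fmtLen(lb), ",",
                reps[3], ":", .fmtLen(lc), ");")
  tr <- ape::read.tree(text = nwk)
  attr(tr, "negativeClamped") <- clamped
  tr
}

#' VM-label enrichment of the best clade of a tree
#'
#' The tree is midpoint rooted solely to enumerate clades; every clade
#' (including single leaves) is scored by the hypergeometric upper tail of
#' its VM-label count, and the clade minimizing that p is reported. The
#' primary significance measure is a permutation p-value: labels are
#' shuffled over the leaves and the clade search repeated per permutation,
#' correcting for the search multiplicity.
#'
#' @param tree an \code{ape::phylo}.
#' @param vmLeaves character vector of VM-labelled leaf names (>= 1).
#' @param nPerm number of label permutations.
#' @return List: bestClade (leaf names), cladeSize, vmInClade,
#'   hypergeomP (descriptive), permP, nPerm.
#' @export
subtreeEnrichment <- function(tree, vmLeaves, nPerm = 1000L) {
  stopifnot(length(vmLeaves) >= 1L)
  if (!all(vmLeaves %in% tree$tip.label))
    stop("VM leaves absent from tree: ",
         paste(setdiff(vmLeaves, tree$tip.label), collapse = ", "))
  rooted <- phangorn::midpoint(tree)
  n <- length(rooted$tip.label)
  nodes <- c(seq_len(n), n + seq_len(rooted$Nnode))
  desc <- phangorn::Descendants(rooted, nodes, type = "tips")
  # drop the root clade (all leaves): uninformative
  desc <- desc[lengths(desc) < n]
  C <- do.call(rbind, lapply(desc, function(ix) {
    v <- logical(n); v[ix] <- TRUE; v
  }))
  k <- rowSums(C)
  K <- length(vmLeaves)
  vm <- rooted$tip.label %in% vmLeaves
  minP <- function(vmInd) {
    x <- as.numeric(C %*% vmInd)
    p <- phyper(x - 1, K, n - K, k, lower.tail = FALSE)
    list(p = min(p), idx = which.min(p))
  }
  obs <- minP(vm)
  hits <- 0L
  for (b in seq_len(nPerm)) {
    perm <- sample(vm)
    if (minP(perm)$p <= obs$p) hits <- hits + 1L
  }
  best <- desc[[obs$idx]]
  list(bestClade = rooted$tip.label[best],
       cladeSize = length(best),
       vmInClade = sum(vm[best]),
       hypergeomP = obs$p,
       permP = (1 + hits) / (nPerm + 1),
       nPerm = nPerm)
}
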