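# Sequence-based target prediction: orientation normalization, global
# alignment identity, progressive multiple alignment, discriminative-window
# scanning, methylation-state concordance, pooled t tests with two-stage FDR.

#' Reverse complement of a nucleotide sequence
#'
#' Standard complement, reversed; N maps to N.
#'
#' @param x a character string or \code{DNAString}-coercible sequence.
#' @return Character string.
#' @export
reverseComplementSeq <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(as.character(x))))
}

#' Global-alignment percent identity between two sequences
#'
#' Deterministic Needleman-Wunsch global alignment (match +1, mismatch -1,
#' gap open -2, extend -1); identity is matches over aligned columns,
#' reported to one decimal.
#'
#' @param a,b nonempty sequences (character or \code{DNAString}-coercible).
#' @return Percent identity, one decimal.
#' @export
percentIdentity <- function(a, b) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (!nchar(a) || !nchar(b)) stop("empty sequence")
  al <- .nwAlignPair(a, b)
  ca <- strsplit(al$a, "")[[1]]
  cb <- strsplit(al$b, "")[[1]]
  round(100 * sum(ca == cb & ca != "-") / length(ca), 1)
}

.charMatrix <- function(strings) {
  do.call(rbind, strsplit(strings, ""))
}

.profileOf <- function(mat) {
  syms <- c("A", "C", "G", "T", "-", "N")
  t(vapply(syms, function(s) {
    if (nrow(mat) == 1L) as.numeric(mat[1, ] == s) else colMeans(mat == s)
  }, numeric(ncol(mat))))
}

.mergeAlignments <- function(A, B) {
  path <- .profileAlignPath(.profileOf(A), .profileOf(B))
  fromA <- path %in% c(1L, 2L)
  fromB <- path %in% c(1L, 3L)
  out <- matrix("-", nrow(A) + nrow(B), length(path))
  out[seq_len(nrow(A)), fromA] <- A
  out[nrow(A) + seq_len(nrow(B)), fromB] <- B
  rownames(out) <- c(rownames(A), rownames(B))
  out
}

#' Progressive multiple alignment of LTR sequences
#'
#' Orientation is normalized first (sequences flagged "-" are reverse
#' complemented). A UPGMA guide tree is computed from pairwise global-
#' alignment identities and profiles are merged progressively with the same
#' scoring scheme. Input order does not affect the result: sequences are
#' processed in lexicographic id order.
#'
#' @param seqs named character vector or \code{DNAStringSet} (>= 2 sequences).
#' @param labels optional per-sequence labels (e.g. target/nontarget).
#' @param orientation optional per-sequence "+"/"-" flags.
#' @return A \linkS4class{LabelledAlignment} (rows in input id order).
#' @export
alignMultiple <- function(seqs, labels = NULL, orientation = NULL) {
  nms <- names(seqs)
  s <- toupper(as.character(seqs))
  names(s) <- nms
  n <- length(s)
  stopifnot(n >= 2L)
  if (is.null(names(s)) || anyDuplicated(names(s)))
    names(s) <- paste0("seq", seq_len(n))
  if (is.null(labels)) labels <- rep("seq", n)
  if (is.null(orientation)) orientation <- rep("+", n)
  names(labels) <- names(orientation) <- names(s)
  flip <- orientation == "-"
  s[flip] <- vapply(s[flip], reverseComplementSeq, character(1))
  ord <- order(names(s))
  s <- s[ord]
  # guide tree from pairwise identities
  D <- matrix(0, n, n, dimnames = list(names(s), names(s)))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    d <- 1 - percentIdentity(s[i], s[j]) / 100
    D[i, j] <- D[j, i] <- d
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  blocks <- vector("list", n)  # leaf alignments by negative index
  merged <- vector("list", max(1L, nrow(hc$merge)))
  getBlock <- function(k) {
    if (k < 0) {
      m <- matrix(strsplit(s[[-k]], "")[[1]], nrow = 1)
      rownames(m) <- names(s)[-k]
      m
    } else merged[[k]]
  }
  if (n == 2L) {
    al <- .nwAlignPair(s[1], s[2])
    M <- rbind(strsplit(al$a, "")[[1]], strsplit(al$b, "")[[1]])
    rownames(M) <- names(s)
  } else {
    for (r in seq_len(nrow(hc$merge))) {
      merged[[r]] <- .mergeAlignments(getBlock(hc$merge[r, 1]),
                                      getBlock(hc$merge[r, 2]))
    }
    M <- merged[[nrow(hc$merge)]]
  }
  M <- M[names(labels), , drop = FALSE]   # restore input order
  aln <- apply(M, 1, paste, collapse = "")
  new("LabelledAlignment", aln = aln,
      labels = unname(labels[rownames(M)]),
      orientation = unname(orientation[rownames(M)]))
}

# per-column discrimination score between target and nontarget rows
.columnScores <- function(mat, isTarget) {
  vapply(seq_len(ncol(mat)), function(j) {
    tc <- mat[isTarget, j]
    nc <- mat[!isTarget, j]
    if (length(unique(tc)) == 1L && all(nc != tc[1])) return(1)
    between <- mean(outer(tc, nc, "!="))
    mism <- function(v) {
      m <- length(v)
      if (m < 2L) return(c(0, 0))
      tab <- table(v)
      c((m^2 - sum(tab^2)) / 2, choose(m, 2))
    }
    wt <- mism(tc); wn <- mism(nc)
    within <- if (wt[2] + wn[2] > 0) (wt[1] + wn[1]) / (wt[2] + wn[2]) else 0
    min(1, max(0, between - within))
  }, numeric(1))
}

#' Scan a labelled alignment for target/nontarget divergent windows
#'
#' Each alignment column gets a discrimination score: 1 when all target rows
#' share one state and every nontarget row differs from it, otherwise the
#' between-group mismatch rate minus the within-group mismatch rate, clamped
#' to [0, 1]. Columns scoring >= \code{minScore} seed windows; runs separated
#' by fewer than \code{mergeGap} low-scoring columns are merged. Windows are
#' reported with their consensus-frame length (columns where more than half
#' of the target rows are ungapped) and must reach \code{minLen}; ranking is
#' by length x mean score.
#'
#' @param la a \linkS4class{LabelledAlignment} with target and nontarget rows.
#' @param minScore minimum column/window score (default 0.5).
#' @param minLen minimum ungapped consensus length (bp).
#' @param mergeGap runs separated by fewer than this many low columns merge.
#' @return data.frame of windows: startCol, endCol, lengthConsensus, score.
#' @export
divergentWindowScan <- function(la, minScore = 0.5, minLen = 10L,
                                mergeGap = 3L) {
  labs <- la@labels
  if (!all(c("target", "nontarget") %in% labs))
    stop("alignment must contain both target and nontarget rows")
  mat <- .charMatrix(la@aln)
  isT <- labs == "target"
  sc <- .columnScores(mat, isT)
  hit <- sc >= minScore
  if (!any(hit)) {
    return(data.frame(startCol = integer(0), endCol = integer(0),
                      lengthConsensus = integer(0), score = numeric(0)))
  }
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge runs separated by < mergeGap low-scoring columns
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) for (i in seq(2, nrow(runs))) {
    if (runs$start[i] - merged$end[nrow(merged)] - 1L < mergeGap)
      merged$end[nrow(merged)] <- runs$end[i]
    else merged <- rbind(merged, runs[i, ])
  }
  consFrame <- colMeans(mat[isT, , drop = FALSE] != "-") > 0.5
  out <- do.call(rbind, lapply(seq_len(nrow(merged)), function(i) {
    cols <- seq(merged$start[i], merged$end[i])
    data.frame(startCol = merged$start[i], endCol = merged$end[i],
               lengthConsensus = sum(consFrame[cols]),
               score = mean(sc[cols]))
  }))
  out <- out[out$score >= minScore & out$lengthConsensus >= minLen, ,
             drop = FALSE]
  out[order(-(out$lengthConsensus * out$score)), , drop = FALSE]
}

#' Cross-locus methylation-state concordance
#'
#' Fraction of shared individuals whose high/low class at the candidate locus
#' equals their class at the index locus; verdict "target" iff the fraction
#' reaches \code{threshold}.
#'
#' @param indexClasses,candidateClasses named "high"/"low" vectors.
#' @param threshold concordance fraction for a target verdict (default 0.9).
#' @return List: fraction, n, verdict.
#' @export
concordanceTest <- function(indexClasses, candidateClasses, threshold = 0.9) {
  shared <- intersect(names(indexClasses), names(candidateClasses))
  if (!length(shared)) stop("no shared individuals")
  fr <- mean(indexClasses[shared] == candidateClasses[shared])
  list(fraction = fr, n = length(shared),
       verdict = if (fr >= threshold) "target" else "nontarget")
}

# pooled-variance unpaired two-sample t test; zero-variance equal means -> p 1
.pooledT <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / df
  d <- mean(a) - mean(b)
  if (sp2 == 0) {
    return(list(t = if (d == 0) 0 else sign(d) * Inf,
                df = df, p = if (d == 0) 1 else 0))
  }
  t <- d / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Benjamini-Krieger-Yekutieli two-stage step-up discoveries
#'
#' Stage 1 runs a linear (BH) step-up at q' = q/(1+q) to estimate the number
#' of true nulls m0 = m - r1; stage 2 reruns the step-up at q' m / m0. No
#' stage-1 rejections means no discoveries; m0 = 0 means all discovered.
#'
#' @param p numeric vector of p-values.
#' @param q target false discovery rate (default 0.05).
#' @return Logical discovery vector.
#' @export
bkyDiscoveries <- function(p, q = 0.05) {
  m <- length(p)
  bh <- function(p, level) {
    o <- order(p)
    thr <- level * seq_len(m) / m
    k <- which(p[o] <= thr)
    rej <- logical(m)
    if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
    rej
  }
  qp <- q / (1 + q)
  r1 <- sum(bh(p, qp))
  if (r1 == 0) return(logical(m))
  m0 <- m - r1
  if (m0 == 0) return(rep(TRUE, m))
  bh(p, qp * m / m0)
}

#' Per-locus unpaired t tests with two-stage BKY FDR
#'
#' Classic pooled-variance (or Welch) unpaired two-sample t per locus,
#' discoveries by the two-stage Benjamini-Krieger-Yekutieli step-up at FDR
#' \code{q}.
#'
#' @param pairs named list; each element a list with numeric \code{a} and
#'   \code{b} (the two groups at that locus, each n >= 2).
#' @param q target FDR.
#' @param welch use Welch's t instead of the pooled-variance t.
#' @return data.frame: locus, t, df, p, discovery.
#' @export
ttestBky <- function(pairs, q = 0.05, welch = FALSE) {
  stopifnot(length(pairs) >= 2L)
  res <- lapply(pairs, function(pr) {
    stopifnot(length(pr$a) >= 2L, length(pr$b) >= 2L)
    if (welch) {
      tt <- tryCatch(stats::t.test(pr$a, pr$b),
                     error = function(e) list(statistic = 0,
                                              parameter = NA, p.value = 1))
      list(t = unname(tt$statistic), df = unname(tt$parameter),
           p = tt$p.value)
    } else .pooledT(pr$a, pr$b)
  })
  p <- vapply(res, `[[`, numeric(1), "p")
  data.frame(locus = names(pairs),
             t = vapply(res, `[[`, numeric(1), "t"),
             df = vapply(res, function(r) as.numeric(r$df), numeric(1)),
             p = p, discovery = bkyDiscoveries(p, q),
             stringsAsFactors = FALSE, row.names = NULL)
}
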