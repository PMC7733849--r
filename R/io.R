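# Readers and writers for the pipeline's plain-text interchange formats:
# pedigree / genotype / methylation CSV, labelled FASTA, BED6, bedGraph,
# and the ground-truth JSON manifest. Numeric CSV fields are written with
# full precision so read(write(x)) round-trips exactly.

.fullPrec <- function(x) sprintf("%.17g", x)

#' @rdname vmiapIO
#' @param ped a \linkS4class{Pedigree}.
#' @export
writePedigreeCsv <- function(ped, path) {
  write.csv(as.data.frame(ped), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname vmiapIO
#' @export
readPedigreeCsv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE,
           colClasses = c(id = "character", dam = "character",
                          sire = "character"))
}

#' @rdname vmiapIO
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @export
writeGenotypeCsv <- function(gm, path) {
  df <- cbind(gm@markers[, c("chrom", "pos", "id")],
              as.data.frame(gm@calls, stringsAsFactors = FALSE))
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname vmiapIO
#' @export
readGenotypeCsv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  calls <- as.matrix(df[, setdiff(names(df), c("chrom", "pos", "id")),
                        drop = FALSE])
  genotypeMatrix(df[, c("chrom", "pos", "id")], calls)
}

#' @rdname vmiapIO
#' @param mt a \linkS4class{MethylationTable}.
#' @export
writeMethylationCsv <- function(mt, path) {
  d <- mt@data
  d$percent <- .fullPrec(d$percent)
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname vmiapIO
#' @export
readMethylationCsv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE,
                colClasses = c(locus = "character", individual = "character",
                               cpg = "integer", percent = "numeric"))
  methylationTable(d)
}

#' @rdname vmiapIO
#' @param family result of \code{\link{evolveLtrFamily}}, or a
#'   \code{DNAStringSet} plus \code{info}.
#' @export
writeLtrFasta <- function(family, path) {
  dss <- family$sequences
  names(dss) <- paste(family$info$id, family$info$label,
                      family$info$orientation, sep = "|")
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' @rdname vmiapIO
#' @export
readLtrFasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(dss), "|", fixed = TRUE)
  info <- data.frame(id = vapply(parts, `[`, "", 1),
                     label = vapply(parts, `[`, "", 2),
                     orientation = vapply(parts, `[`, "", 3),
                     length = Biostrings::width(dss),
                     stringsAsFactors = FALSE)
  names(dss) <- info$id
  list(sequences = dss, info = info)
}

#' @rdname vmiapIO
#' @param elements stranded \code{GRanges}.
#' @export
writeElementsBed <- function(elements, path) {
  if (is.null(names(elements))) names(elements) <- paste0("el", seq_along(elements))
  if (is.null(elements$score)) elements$score <- 0
  rtracklayer::export(elements, path, format = "BED")
  invisible(path)
}

#' @rdname vmiapIO
#' @export
readElementsBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  names(gr) <- gr$name
  gr
}

#' @rdname vmiapIO
#' @param track \code{GRanges} with a \code{score} column.
#' @export
writeCoverageBedGraph <- function(track, path) {
  rtracklayer::export(track, path, format = "bedGraph")
  invisible(path)
}

#' @rdname vmiapIO
#' @export
readCoverageBedGraph <- function(path) {
  rtracklayer::import(path, format = "bedGraph")
}

#' Pipeline file I/O
#'
#' Plain-text readers/writers for the pipeline's interchange formats. CSV
#' numeric fields are emitted at full precision so round-trips are exact.
#'
#' @param path file path.
#' @param manifest named list (ground truth: modifier locus, effect modes,
#'   seeds).
#' @name vmiapIO
#' @export
writeManifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname vmiapIO
#' @export
readManifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
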