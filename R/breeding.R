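# Breeding simulator: founders, Poisson-crossover meiosis on ancestry-painted
# chromosomes, crosses, genotyping, and the reciprocal-F1 / backcross designs.

# strain at position(s) on one haplotype painting (list(end, strain))
.strainAt <- function(hap, pos) {
  idx <- findInterval(pos, hap$end, left.open = TRUE) + 1L
  hap$strain[idx]
}

.mergeSegments <- function(ends, strains) {
  if (length(ends) <= 1L) return(list(end = ends, strain = strains))
  keep <- c(strains[-length(strains)] != strains[-1], TRUE)
  list(end = ends[keep], strain = strains[keep])
}

.founderStrain <- function(ind) {
  s <- unique(unlist(lapply(ind@paintings, function(ch)
    c(ch[[1]]$strain, ch[[2]]$strain))))
  if (length(s) == 1L) s else "mixed"
}

.countModifierAlleles <- function(paintings, spec) {
  ch <- paintings[[spec@modifierChrom]]
  sum(vapply(ch, function(h)
    .strainAt(h, spec@modifierPos) == spec@modifierStrain, logical(1)))
}

.newIndividual <- function(id, sex, generation, dam, sire, damStrain,
                           paintings, spec) {
  new("Individual", id = id, sex = sex, generation = generation,
      dam = dam, sire = sire, damStrain = damStrain, paintings = paintings,
      modifierAlleles = as.integer(.countModifierAlleles(paintings, spec)))
}

#' Simulate an inbred founder
#'
#' Both haplotypes of every chromosome are painted entirely with the founder
#' strain; the modifier allele count is 2 if the strain carries the modifier
#' and 0 otherwise.
#'
#' @param strain one of \code{"B6"}, \code{"CAST"}, \code{"129"}.
#' @param spec a \linkS4class{GenomeSpec}.
#' @param id,sex,generation identifiers for the new individual.
#' @return An \linkS4class{Individual}.
#' @export
simulateFounder <- function(strain, spec, id = paste0(strain, "_1"),
                            sex = "F", generation = "F0") {
  if (!strain %in% c("B6", "CAST", "129"))
    stop("unknown strain label: ", strain)
  paintings <- lapply(seq_len(nrow(spec@chromosomes)), function(i) {
    P <- spec@chromosomes$lengthBp[i]
    hap <- list(end = P, strain = strain)
    list(hap, hap)
  })
  names(paintings) <- spec@chromosomes$name
  .newIndividual(id, sex, generation, NA_character_, NA_character_,
                 strain, paintings, spec)
}

#' One meiosis: produce a recombinant gamete painting
#'
#' Per chromosome the crossover count is Poisson with mean equal to the
#' genetic length in Morgans (no interference), breakpoint positions are
#' uniform on the physical length (linear genetic-physical map), and the
#' gamete alternates between the two parental haplotypes at the breakpoints.
#'
#' @param parent an \linkS4class{Individual}.
#' @param spec a \linkS4class{GenomeSpec}.
#' @return A per-chromosome list of haplotype paintings.
#' @export
meiosis <- function(parent, spec) {
  out <- lapply(seq_len(nrow(spec@chromosomes)), function(i) {
    P <- spec@chromosomes$lengthBp[i]
    L <- spec@chromosomes$lengthM[i]
    haps <- parent@paintings[[spec@chromosomes$name[i]]]
    nxo <- rpois(1L, L)
    breaks <- if (nxo > 0) sort(runif(nxo, 0, P)) else numeric(0)
    src <- sample.int(2L, 1L)
    ends <- numeric(0); strains <- character(0)
    lo <- 0
    for (b in c(breaks, P)) {
      if (b > lo) {
        h <- haps[[src]]
        i1 <- sum(h$end <= lo) + 1L
        i2 <- sum(h$end < b) + 1L
        segEnds <- pmin(h$end[i1:i2], b)
        ends <- c(ends, segEnds)
        strains <- c(strains, h$strain[i1:i2])
      }
      lo <- b
      src <- 3L - src
    }
    .mergeSegments(ends, strains)
  })
  names(out) <- spec@chromosomes$name
  out
}

.generationLabel <- function(dam, sire) {
  g <- c(dam@generation, sire@generation)
  if (all(g == "F0")) return("F1")
  f0 <- g == "F0"
  if (sum(f0) == 1L) {
    other <- g[!f0]
    if (other == "F1") return("N1")
    m <- regmatches(other, regexec("^N([0-9]+)$", other))[[1]]
    if (length(m)) return(paste0("N", as.integer(m[2]) + 1L))
  }
  "IC"
}

#' Cross two individuals
#'
#' Each offspring is formed from independent dam and sire gametes. The
#' offspring's \code{damStrain} records the founder strain of its mother
#' (or "mixed" for hybrid dams) and the generation label is derived from the
#' parents (F0 x F0 = F1, F1 x F0 = N1, Nk x F0 = Nk+1, otherwise IC).
#'
#' @param dam,sire parent \linkS4class{Individual}s.
#' @param nOffspring litter size (>= 1).
#' @param spec a \linkS4class{GenomeSpec}.
#' @param idPrefix prefix for offspring ids.
#' @return List of \linkS4class{Individual}.
#' @export
cross <- function(dam, sire, nOffspring, spec, idPrefix = "ind") {
  stopifnot(nOffspring >= 1)
  damStrain <- .founderStrain(dam)
  gen <- .generationLabel(dam, sire)
  lapply(seq_len(nOffspring), function(k) {
    mat <- meiosis(dam, spec)
    pat <- meiosis(sire, spec)
    paintings <- lapply(spec@chromosomes$name, function(cn)
      list(mat[[cn]], pat[[cn]]))
    names(paintings) <- spec@chromosomes$name
    .newIndividual(paste0(idPrefix, "_", k),
                   sex = sample(c("F", "M"), 1L), generation = gen,
                   dam = dam@id, sire = sire@id, damStrain = damStrain,
                   paintings = paintings, spec = spec)
  })
}

#' Genotype an individual at the marker map
#'
#' The call at a marker is read deterministically off the two ancestry
#' paintings: BB (both haplotypes B6), BC (one B6, one CAST), CC (both CAST);
#' other strain combinations give NA.
#'
#' @param ind an \linkS4class{Individual}.
#' @param spec a \linkS4class{GenomeSpec}.
#' @param markers optional marker data.frame (default the spec's map).
#' @return Named character vector of calls, one per marker.
#' @export
genotypeAt <- function(ind, spec, markers = NULL) {
  if (is.null(markers)) markers <- spec@markers
  out <- character(nrow(markers))
  for (cn in unique(markers$chrom)) {
    sel <- markers$chrom == cn
    pos <- markers$pos[sel]
    haps <- ind@paintings[[cn]]
    s1 <- .strainAt(haps[[1]], pos)
    s2 <- .strainAt(haps[[2]], pos)
    nB6 <- (s1 == "B6") + (s2 == "B6")
    nCA <- (s1 == "CAST") + (s2 == "CAST")
    call <- rep(NA_character_, length(pos))
    call[nB6 == 2] <- "BB"
    call[nCA == 2] <- "CC"
    call[nB6 == 1 & nCA == 1] <- "BC"
    out[sel] <- call
  }
  names(out) <- markers$id
  out
}

#' Genome fraction derived from a given strain
#'
#' @param ind an \linkS4class{Individual}.
#' @param spec a \linkS4class{GenomeSpec}.
#' @param strain strain to measure (default CAST).
#' @return Fraction of the diploid genome painted with \code{strain}.
#' @export
castFraction <- function(ind, spec, strain = "CAST") {
  tot <- 2 * sum(spec@chromosomes$lengthBp)
  got <- sum(vapply(spec@chromosomes$name, function(cn) {
    sum(vapply(ind@paintings[[cn]], function(h) {
      w <- diff(c(0, h$end))
      sum(w[h$strain == strain])
    }, numeric(1)))
  }, numeric(1)))
  got / tot
}

#' Genotype a set of individuals into a GenotypeMatrix
#'
#' @param individuals list of \linkS4class{Individual}.
#' @param spec a \linkS4class{GenomeSpec}.
#' @param missingRate per-call probability of masking a call to NA (emulates
#'   array no-calls); default 0.
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
genotypeIndividuals <- function(individuals, spec, missingRate = 0) {
  calls <- vapply(individuals, genotypeAt, character(nrow(spec@markers)),
                  spec = spec)
  colnames(calls) <- vapply(individuals, function(i) i@id, character(1))
  if (missingRate > 0) {
    mask <- matrix(runif(length(calls)) < missingRate, nrow = nrow(calls))
    calls[mask] <- NA_character_
  }
  genotypeMatrix(spec@markers, calls)
}
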