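---
title: "Methods: simulating and mapping trans-acting modifiers of variably methylated IAPs"
author: "vmiap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and mapping trans-acting modifiers of variably methylated IAPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific setting

Variably methylated IAPs (VM-IAPs) are murine endogenous retroviruses whose
DNA methylation differs between genetically identical individuals but is
uniform across tissues of one animal, pointing to a stochastic decision in
early development. When a second inbred strain contributes a haploid genome
— without contributing the element itself — the methylation distribution of
the element can shift, revealing a *trans*-acting, strain-specific modifier.
The canonical way to find such a modifier is classical forward genetics:
reciprocal F1 hybrids to type the effect, serial backcrosses to reveal
Mendelian segregation of a categorical methylation phenotype, a dense
strain-informative SNP panel to intersect genotype with phenotype, and
sequence analysis (identity, discriminative alignment windows, phylogeny,
chromatin metaprofiles) to delimit and characterize the modifier's targets.
`vmiap` implements that chain end to end, and pairs it with a generative
simulator so that every inferential step has a ground truth to be tested
against.

# The breeding and phenotype simulator

## Meiosis and ancestry

Chromosomes are carried as *ancestry paintings*: ordered segments tagged
with the founder strain they descend from, tiling each chromosome exactly.
Meiosis draws a crossover count per chromosome from Poisson(genetic length
in Morgans), places breakpoints uniformly on the physical length (a linear
genetic–physical map), and alternates between the two parental haplotypes.
Two deliberate simplifications:

* **No crossover interference.** The Poisson model is the simplest process
  whose marginal recombination fractions are correct, and interval-recovery
  testing only depends on those marginals.
* **No obligate crossover.** Chromosomes may transmit intact; enforcing one
  crossover would distort the Poisson counts and is unnecessary at the map
  resolutions simulated here.

Sex chromosomes are not modelled; every locus is autosomal, as is the
modifier being emulated. Genotypes (BB / BC / CC) are read deterministically
off the paintings, so marker genotype is always recoverable from ancestry —
an invariant the tests exercise against an independent linear scan.

## Methylation phenotypes

Per locus and individual, one Beta-distributed "locus draw" on the 0–100%
scale is selected among three states, then independent Gaussian per-CpG
noise (default 1.5 percentage points, 6 CpGs) is added and values are
clamped to [0, 100]:

| state | default | mean | role |
|---|---|---|---|
| baseline | Beta(9, 11) | 45% | variable methylation in the pure-strain population |
| high | Beta(24, 6) | 80% | modifier-induced hypermethylation |
| boosted | Beta(45, 5) | 90% | maternal *and* zygotic conditions both met |

The effect mode decides which individuals reach the high state: *zygotic*
(carries ≥1 modifier allele), *maternal* (mother of the modifier strain),
*maternal+zygotic* (either; both conditions together give the boosted
state), or *none*. The boosted state exists because without it the two
reciprocal hybrid groups would be statistically identical whenever all F1s
carry the modifier, and the maternal+zygotic category — which requires the
BC and CB distributions to differ from the pure strain *and* from each
other — could never be recovered.

Note that the generic baseline and high states deliberately overlap a
little at the 60% cutoff: Beta(9, 11) has about 8.8% of its mass above 60%.
That is realistic for a typical VM-IAP but would defeat a strict
intersection filter. The mapping design therefore uses
`indexLocusModel()` — baseline Beta(100, 125), high Beta(120, 30) — whose
states do not overlap at 60%, emulating precisely the property for which a
categorical index locus is selected in a real mapping experiment. A fourth,
tight profile (Beta(180, 20), mean 90%, sd ≈ 2 pp) represents the bulk of
heavily methylated, *non*-variable IAPs in variability-classification
tests; draws from the 80%-state Beta(24, 6) are too dispersed (sd ≈ 7 pp)
to be nonvariable under the 10-point range rule, and are not meant to be.

## LTR families and the planted segment

Simulated solo-LTR families descend from a random 500-bp consensus (the
typical solo-LTR length of the modelled subclass). Targets and nontargets
share a clade ancestor one deep branch (substitution rate 0.03/site) off
the consensus, with short terminal branches (0.005/site); background
elements diverge further (an extra 0.08/site). A 28-bp discriminative
segment is planted mid-consensus: intact in targets, disrupted in
nontargets by a 4-bp insertion plus substitutions.

One generator design choice deserves emphasis. The planted segment is drawn
from a three-letter alphabet (A/C/G) and the disruption saturates the
substituted positions and the insertion with the fourth base (T), with
non-T "barrier" columns immediately flanking the segment. The reason is
alignment ambiguity: a sparsely substituted disruption lets a global
aligner slide the insertion gap to manufacture chance matches inside the
segment, fragmenting the discriminative window and making exact 28-bp
recovery a property of aligner tie-breaking rather than of the data. With
the saturated design every disrupted column discriminates targets from
nontargets no matter where the gap is placed, so window recovery tests a
property of the scan, not of the aligner. Sparser disruptions (the
realistic "insertion plus a few SNPs" pattern) remain expressible through
`motifSpec(substitutionOffsets = ...)`.

## Coverage tracks

`synthCoverage()` lays Poisson background (default mean 5 per 10-bp bin)
over the declared chromosomes and adds an additive enrichment block
(default height 20) over the 3'-proximal fraction (default 0.4) of each
enriched element, respecting strand; overlapping blocks sum. This emulates
the promoter-like chromatin signal that appears at the 3' end of targeted
elements when their repressor is absent.

## What the simulator does *not* emulate

Read-level bisulphite conversion, pyrogram signal processing, realistic
mouse genetic maps, selection and lethality, X-linkage, copy-number
variation of the elements, and correlated phenotyping error. Passing tests
therefore demonstrate correctness of the inference chain under the stated
generative assumptions, not robustness to every artefact of real data.

# The analysis chain

## Variability and phenotype classification

The ">10% variability across individuals" rule is interpreted as a range —
the spread between the highest and lowest per-individual mean exceeding 10
percentage points — rather than a statistical variance; the variance
interpretation is available via `classifyVariability(measure =
"variance")`. Nonvariable loci are subtyped by group mean (≥80%
hypermethylated, ≤20% hypomethylated), package-defined conveniences rather
than field constants. The high/low phenotype cutoff is strict: exactly 60%
classifies low, so "high" means >60%.

## GBE typing

Kruskal–Wallis (tie-corrected, chi-square reference with k−1 df; delegated
to `stats::kruskal.test` and oracle-tested against the rank formula) is
followed by Dunn's post hoc z tests on the shared midranks with the
tie-corrected pooled variance. The post hoc adjustment is Bonferroni-style
multiplication by the number of comparisons (3), matching the common
implementation in the plotting software family used for this assay;
`holm` and `none` are available. The decision table: both hybrid groups
shifted against the pure strain with no BC–CB difference is *zygotic*;
exactly one shifted plus a BC–CB difference is *maternal*; everything
significant is *maternal+zygotic*; anything else (including the ambiguous
one-sided case with no BC–CB difference) falls back to *none*, the
conservative call. α defaults to 0.05 — figure stars in this literature
are display conventions, not decision rules.

## Mapping

A marker passes the intersection filter iff it is heterozygous in all
highly methylated and homozygous-B6 in all lowly methylated individuals.
Missingness is handled conservatively: a marker with any missing call among
labelled individuals cannot be a candidate, but it still serves as an outer
bound if its non-missing calls already violate the filter.
Homozygous-CAST calls — impossible in a B6 backcross — are reported as
genotyping errors, never silently dropped. Both interval flavours are
reported, since a printed interval may refer to either: *inner* (candidate
span) and *outer* (exclusive flanking-failure bounds). All coordinates are
GRanges, 1-based and fully closed, so printed genome-browser coordinates
are used verbatim; interval lengths are the coordinate difference divided
by 10⁶, rounded half-up to one decimal, matching the printed "6.4-Mb"
style. The simulated marker panel includes a marker at the modifier
position itself, which is what turns "error-free phenotyping recovers the
true locus" into a structural guarantee: that marker can never be
eliminated, so the candidate set is never empty and always spans the truth.

## Target prediction

Percent identity uses a deterministic global Needleman–Wunsch alignment
(match +1, mismatch −1, gap open −2, extend −1, Rcpp implementation with a
fixed diagonal-first tie-break) — a local BLAT-style aligner would give
indistinguishable identities on near-identical LTRs, and determinism aids
testing. The multiple aligner is progressive: a UPGMA guide tree from
pairwise identities, then profile–profile alignment under the same scoring
scheme, processed in lexicographic id order so input order is irrelevant.
Identity is computed over the full sequence (the trimmed-region alternative
is not the default). The window scan scores each column 1 when all target
rows share a state every nontarget row lacks, otherwise by the clamped
between-minus-within mismatch rate; hit runs separated by fewer than 3
low-scoring columns merge (preventing fragmentation by isolated noisy
columns), windows must reach a mean score of 0.5 and a 10-bp
consensus-frame length (columns where >50% of target rows are ungapped),
and ranking is by length × score. Concordance calls a candidate a target
when ≥90% of shared individuals agree with their index-locus class. Group
tests are classic pooled-variance unpaired t tests (Welch available), with
discoveries by the canonical two-stage step-up: stage 1 at q′ = q/(1+q)
estimates the number of true nulls m₀, stage 2 reruns the linear step-up at
q′·m/m₀. This q′-based second stage is the published form of the adaptive
procedure (and what the usual software implements); it always discovers a
superset of the plain linear step-up at q′.

## Phylogeny

Distances are raw p-distances with pairwise deletion (a Jukes–Cantor
correction changes nothing for tree topology at these divergences and is
not applied by default); pairs with no comparable column are an error, not
a zero. Neighbor joining follows Saitou–Nei with the Studier–Keppler Q
criterion, a lowest-index tie-break, standard limb-length formulas, and
negative limb estimates clamped to zero with a flag. The clade enrichment
test midpoint-roots the tree *only* to enumerate clades; the reported
quantity is a permutation p-value in which the full clade search is
repeated per label shuffle (so the search multiplicity is corrected
exactly), with the hypergeometric tail of the best clade reported as a
descriptive statistic. The +1-corrected permutation p of a search minimum
is discrete and conservative — valid (super-uniform) rather than exactly
uniform under the null, which is what the calibration test checks.

## Metaprofiles

Anchored matrices rescale each element body to a 500-bp pseudolength by
area-weighted integration of the coverage step function — not point
sampling — so the mean of the body bins equals the element's
length-weighted mean coverage exactly (to floating point). Flanks of 500 bp
are copied at 1-bp resolution (the bin size is 1 bp for exactness);
minus-strand rows are reversed so the column axis runs 5'→3'. Elements
shorter than 2 bp are rejected rather than upscaled. The CI multiplier is
fixed at 1.96, the large-n normal approximation implied by "95% CI".

# Determinism and problem sizes

Every stochastic function consumes the R session RNG; `runPipeline()` seeds
it once from the mandatory config seed and executes stages in a fixed
order, so identical configs produce byte-identical reports. The test suite
exercises: the meiosis model at 10,000 gametes; Mendelian transmission at
10,000 and 20,000 offspring; mapping-filter oracle equivalence on 1,000
random matrices; true-locus recovery on 100 seeded backcrosses of 47
genotyped animals; planted-window recovery on 200 seeded families of 6
targets and 3 nontargets; neighbor-joining consistency on 100 random
additive trees; Kruskal–Wallis type-I calibration and two-stage FDR control
on 1,000 replicates each; and GBE mode recovery on 200 reciprocal designs
of 50 animals per group. These sizes were chosen so each check has enough
resolution for its stated bound (3 standard errors, exact counts, or a 95%
recovery floor) while keeping a full run comfortably on one CPU.

# Known limitations

* The simulator's phenotype model is a two/three-state Beta mixture; real
  pyrosequencing data show locus-specific skew and CpG-position effects
  that are summarized (via the adjusted Fisher–Pearson skewness and
  Shapiro–Wilk flag) but not generated.
* The intersection filter assumes error-free genotyping of labelled
  individuals; a single phenotyping error can empty the candidate set,
  which is reported as an error rather than rescued — matching how the
  real experiment depends on a categorical phenotype.
* The progressive aligner is built for near-identical LTR families, not
  for deep divergence; guide-tree quality degrades with distance.
* Enrichment testing on trees treats the tree as fixed; phylogenetic
  uncertainty (no bootstrap) is out of scope.
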