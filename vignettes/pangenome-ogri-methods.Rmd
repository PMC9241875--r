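---
title: "Methods: pangenome openness, genome relatedness and genospecies delineation"
author: "panogri"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pangenome openness, genome relatedness and genospecies delineation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panogri)
```

# Scope

`panogri` implements the comparative-genomics inference chain used to
circumscribe bacterial genospecies within a genus: protein clustering into
gene families, pangenome partitioning and openness fitting, overall genome
relatedness indices (ANI, dDDH, 16S identity), threshold-based species and
genus calls, distance phylogenetics, and carotenoid gene-neighborhood
typing.  Genome assembly, gene calling, functional annotation and
maximum-likelihood phylogenetics are deliberately outside its scope: the
package consumes assemblies, protein sets, COG letters and alignments that
upstream tools produce.

Every stage can be exercised on synthetic data with known ground truth, so
the statistical behaviour of each estimator is testable without any genome
download.

# The synthetic generators and what they emulate

`gen_family_matrix()` draws gene content from a three-compartment model: a
core present in every genome, a shared accessory pool sampled independently
per genome with probability `p_accessory`, and per-genome unique families
drawn as Poisson counts from an infinite label space (uniqueness holds by
construction, with no collision bookkeeping).  This reproduces the
core/accessory/unique structure of real genus-level pangenomes and — because
the expected accumulation curve has the closed form
$E[\mathrm{pan}(x)] = \text{core} + \text{pool}\,(1-(1-p)^x) + u\,x$
(`expected_pan_curve()`) — gives an exact oracle for curve-fitting tests.
It does **not** emulate phylogenetic correlation of gene content, horizontal
transfer, or lineage-specific gene-family expansions; passing tests say the
estimators are correct under exchangeable sampling, not that any real genus
follows this model.

`gen_divergent_pair()` evolves a uniform-random ancestor by per-site
substitutions (uniform over the three alternative bases by default; a
transition/transversion weight `kappa` is available for K2P experiments) and
optional non-overlapping indels with geometric lengths.  Identity is defined
as matching sites over un-deleted ancestor sites and is recomputable from
the mutation log.  Substitution saturation is refused at
`sub_rate >= 0.75`, where the identity signal is no longer meaningful.
Codon structure, GC bias and rearrangements are not simulated.

`gen_protein_families()` gives each family an independent random ancestral
protein and mutates each genome's copy at a controlled per-residue
divergence.  Unrelated random proteins align at well under 50% identity, so
a 0.5 clustering threshold separates families cleanly up to ~0.2 divergence;
above 0.5 divergence the round-trip guarantee is lost and the generator
warns.

`gen_crt_annotation()` lays out a single-contig annotation with the
contiguous `crtB`–`log`–`crtI`(–`hyp`)–`crtY` cluster and the scattered
`crtE`, `crtG`+`DUF2141`, (`crtW`–)`crtZ` genes with filler genes between
them, one layout per arrangement type in the shipped rule table.

All generators take one explicit seed, use a private RNG stream, and are
byte-reproducible; the caller's RNG state is never touched.

# Ortholog clustering

`greedy_cluster()` is a deterministic re-statement of USEARCH-style greedy
centroid clustering at a global-identity threshold (default 0.5).  Two
design choices matter:

* **Identity denominator.** Identity is identical residue pairs over *all*
  alignment columns of a BLOSUM62 global alignment (gap open 10, extend 1) —
  symmetric and deterministic.  A `denominator = "shorter"` mode is provided
  for sensitivity checks, since greedy clustering tools differ silently on
  this point.
* **Processing order.** Sequences are processed longest-first with a
  lexicographic tie-break, which removes the input-order dependence of the
  original heuristic.  This is a deliberate divergence from USEARCH
  behaviour, traded for reproducibility.

A shared-5-mer prefilter skips centroids that cannot plausibly reach the
threshold.  Exact-k-mer screening is only sound when sequences are long
enough that a pair genuinely above the identity threshold is certain to
retain conserved 5-mers; the filter therefore fires only when both
sequences have at least `prefilter_min_len` (default 200) residues — at
that length and 0.2 divergence the expected conserved-5-mer count is about
a dozen, so the probability of wrongly skipping a true match is of order
1e-5 — and shorter sequences are always compared directly.  The filter can
be turned off (`prefilter = FALSE`), and the test suite verifies filtered
and unfiltered runs are identical over 100 random instances.  Paralogs stay in the counts
but collapse to presence for pangenome math, matching gene-family (not
gene) accounting.

# Pangenome partitioning and openness

`partition_families()` classifies families present in all genomes as core,
in exactly one as unique, and the remainder as accessory.
`accumulation_curves()` samples uniform random genome orders (default 500
iterations, sampled independently — two iterations may repeat a
permutation, which is how "n iterations" is conventionally meant) and
records union and intersection sizes.  The per-`x` medians — the centers of
the conventional boxplot presentation — are the fitting substrate; fitting
all iteration points instead is a one-line change but was not made the
default because a single `(a, b)` pair reported per dataset corresponds to
a single summary curve.  Whether the original pipeline fits medians or
means is not documentable from its outputs; medians were chosen and the
choice is visible in the API.

`fit_heaps()` fits $f(x) = a\,x^b$ and `fit_core_decay()` fits
$f_1(x) = c\,e^{dx}$ by Levenberg–Marquardt nonlinear least squares
(`minpack.lm`), initialized from log–log (resp. log-linear) regression and
iterated to a parameter tolerance of 1e-10.  Exact power-law or exponential
input is recovered to machine precision, which the tests assert.  The
openness rule is exactly: open iff $0 < b < 1$, closed iff $b < 0$; the
uncovered cases $b = 0$ and $b \ge 1$ are labelled *boundary* rather than
silently extrapolated.  `x = 1` is included in fits ($f(1) = a$ exactly).
Non-positive medians make the log-domain initialization impossible: the
Heaps fit refuses them, the decay fit falls back to the longest positive
prefix with a warning and requires at least three points.

# Overall genome relatedness indices

`fragment_ani()` implements the classical fragment recipe: 1020 bp
non-overlapping query fragments, k-mer seeding (k = 15) on both strands
with best-diagonal voting (ties to the leftmost reference position), gapped
end-to-end extension against the selected reference window (match 2,
mismatch −3, gap open 5, extend 2), and retention filters of 70% coverage
and 30% identity.  ANI is the mean identity of retained fragments.  All
five knobs are arguments.  When no fragment passes, ANI is *undefined* and
an error distinguishes "too divergent to estimate" from 0%.  On indel-free
simulated pairs the estimator tracks true identity to within 0.005 across
1–10% divergence (asserted at 200 kb).

`ddh_formula2()` forms HSPs with the same seeding but local alignments kept
above a raw score floor, and computes the formula-2 style distance
$d_2 = 1 - \sum \text{identities} / \sum \text{HSP lengths}$, which uses
only the aligned fraction of the genomes and is therefore robust to
incomplete assemblies.  The logistic map
$\mathrm{dDDH} = 100 / (1 + e^{\alpha + \beta d_2})$ converts distance to a
hybridization percentage.  The shipped defaults
($\alpha = -2.2469, \beta = 22.1127$) are anchored so the curve passes
through the conventional decision points of the genome-to-genome distance
framework (70% dDDH at $d_2 = 0.0633$, 79% at $d_2 = 0.0417$); they are
plain arguments, to be overridden wherever a differently calibrated model
is preferred.  Within-package comparisons are unaffected by the anchor
choice because the map is strictly monotone.

`identity_16s()` counts identical columns over non-double-gap columns,
aligning globally first when handed unaligned sequences.
`similarity_matrix()` assembles labeled symmetric matrices, symmetrizing
directional metrics (ANI, dDDH) as the mean of both directions and flagging
undefined pairs as missing rather than zero.

# Species and genus delineation

`delineate()` thresholds a dDDH or ANI matrix (defaults: 70% dDDH, 95% ANI,
configurable to 96) and takes connected components as genospecies.
Single-linkage was chosen over clique-finding because taxonomic practice
reasons pairwise; the price is possible chaining, which is why every
within-component pair below the threshold is reported as an explicit
conflict instead of being re-clustered away.  All comparisons are
inclusive, so a value exactly at a boundary passes.  `genus_screen()`
applies the 73.98% ANI and 94.5% 16S genus boundaries per strain and
reports the two screens independently; disagreements between metrics are
surfaced side by side, never resolved by rule.

# Distance phylogenetics

`k2p_distance()` is the closed-form Kimura two-parameter distance with
pairwise deletion of gap/N sites (complete deletion by flag).
`nj_tree()` is the canonical Saitou–Nei agglomeration with the Q-criterion;
ties in Q are broken by the lexicographically smallest label pair, and
negative branch lengths are clamped to zero with the clamped total recorded
in an attribute.  Additive matrices are recovered exactly — the property
tests draw random additive trees (up to 12 taxa) and compare path-length
matrices; topology is cross-checked against the independent `ape::nj`.
A two-taxon input yields two half-length edges through the connecting node,
preserving the path length.  `bootstrap_support()` resamples columns,
rebuilds K2P + NJ trees and counts bipartitions; a saturated replicate
distance falls back to the p-distance (logged), so replicates are never
discarded.  Supports are attached as internal node labels, and newick
output writes branch lengths with six decimals.

# Neighborhood typing

`detect_crt_cluster()` reports the maximal run of target genes with
intergenic gaps at or below `max_gap` (default 500 bp — the operational
meaning of "clustered" and "immediately adjacent"; it is an argument, not a
constant), canonicalized by majority strand so a reverse-complemented
contig produces the same signature.  Presence of the scattered carotenoid
genes, and of any cluster gene found outside the cluster, is recorded
genome-wide; the `crtW`→`crtZ` (upstream, strand-aware) and
`crtG`–`DUF2141` (orientation-free) adjacencies are tested under the same
gap rule.  `assign_arrangement_type()` applies an ordered, user-editable
YAML rule table; the shipped table distinguishes four types by `hyp`
presence and `crtW` presence-plus-adjacency, the two cues that separate the
published arrangement drawings, and is explicitly provisional: studies that
define types differently should ship their own table.  Unmatched
signatures return `"untyped"` with the failed predicates attached.

# Problem sizes and numerical choices

The test and acceptance workloads are sized for a laptop-class single CPU:
200 kb genome pairs for ANI accuracy, 40 kb pairs for the dDDH ladder,
30-genome content matrices with 500 rarefaction iterations for exponent
recovery, 20 clustering round-trip seeds, and additive trees of up to 12
taxa.  These sizes are where the asserted tolerances (ANI within 0.005 of
truth; Heaps exponent within 0.05 of the engineered value) hold with
comfortable margin; larger inputs only tighten them.

Degenerate inputs fail loudly by design: empty sequences, single-genome
partitions, saturated distances, all-gap column sets, fits with fewer than
three informative points and unknown arrangement labels are all errors with
named causes, not silent defaults.

# Known limitations

* The content model is exchangeable across genomes; it cannot emulate
  clade-structured gene content, so openness estimates on real genera
  should be read with that in mind.
* The ANI/dDDH machinery is a desk-scale reimplementation of the classical
  fragment and HSP recipes, not a wrapper of FastANI/GGDC; absolute values
  on real genomes will differ from those tools by implementation detail,
  while rankings and threshold calls are stable.
* dDDH percentages depend on the logistic anchor; only the distance
  $d_2$ is anchor-free.
* NJ/K2P covers the marker-gene trees; no model selection or
  maximum-likelihood inference is provided.
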