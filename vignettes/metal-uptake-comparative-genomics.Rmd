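---
title: "Methods: comparative genomics of trace-metal uptake inventories"
author: "MetalTraits authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative genomics of trace-metal uptake inventories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MetalTraits)
```

MetalTraits packages the analysis chain used to characterize trace-metal
(Mn, Fe, Co, Ni, Cu, Zn) uptake gene inventories across bacterial genome
collections — typified by the contrast between streamlined SAR11 and
versatile Roseobacter lineages — as a set of tested, seed-deterministic
modules. This vignette explains each method, its assumptions, the
tunable parameters, the numerical choices, and what the synthetic-data
generators do and do not emulate.

## Transporter inventory from domain hits

Inventories start from domain-model hit tables in the BLAST tabular
dialect ("outfmt 6" columns plus `hit_class` and `family_label`). Three
filters apply, in order:

1. **Significance**: e-value strictly below `evalueMax` (default 1e-5,
   the conventional ortholog-detection threshold for RPS-BLAST searches
   against conserved-domain models).
2. **Reciprocity**: "bidirectional reciprocal best hit" is ambiguous for
   a query-versus-model search, since the model database cannot be
   searched back against the proteome. We adopt the closest testable
   reading: a *mutual-best within genome* rule, keeping a hit iff it is
   its query's top-ranked model *and* its query has the highest bitscore
   among the genome's queries hitting that model. The rule is exercised
   against a brute-force enumeration oracle in the tests and can be
   disabled (`requireBidirectional = FALSE`).
3. **Specificity**: only `specific`-class hits assign a family; queries
   whose sole surviving assignment is at the superfamily level are kept
   and counted in separate `*_superfamily` columns, since
   superfamily-only substrate-binding proteins are themselves
   informative (e.g. *troA*-superfamily assignments).

Ties in bitscore rank by ascending e-value, then lexicographic model id
— fully deterministic. A multi-domain protein contributes once per
family by default (`countPerDomain = FALSE`); whether multi-domain
architecture should count per domain is genuinely open, so both modes
exist and the default is the conservative one.

The resulting `TraitTable` (genome × family integer counts with a
derived binary view) is the package's central object, the machine analog
of a per-genome metal-uptake abundance grid.

## Regulatory motif scanning

Fur-regulated iron uptake genes sit downstream of palindromic operator
motifs: classically a 19-bp inverted repeat (Fur box), with a 15-bp
7-1-7 variant in SAR11 and a related "iron-rhodo box" in Roseobacter.
Two scan modes are provided:

- **Reference scan** (`scanReferenceMotifs`): exhaustive
  Hamming-distance comparison of every window, both strands, against
  every reference sequence, reporting each window once with its best
  mismatch count. A BLASTN-style heuristic search is the instrument a
  large survey would use; at motif lengths of 15–19 bp an exhaustive
  scan is exact, deterministic and strictly more sensitive, so that is
  what we implement (via `Biostrings::matchPattern`, cross-checked in
  the tests against a hand-rolled all-window oracle). Default mismatch
  tolerance: 3 for 19-bp motifs, 2 for 15-bp. No published tolerance
  exists for "new" box discovery, so the parameter is exposed rather
  than defaulted to a faithfulness claim.
- **Structural scan** (`scanInvertedRepeats`): a window qualifies when
  at least `minPalindromicPairs` of its arm positions satisfy
  reverse-complement pairing across the spacer (default: all 7 of a
  7-1-7 geometry). Non-ACGT bases never pair. Because an inverted
  repeat is (near) self-complementary, hits are reported once on the
  forward strand.

Coordinates are 0-based half-open throughout; overlapping qualifying
windows are reported individually (no merging), since merging would
destroy the positional exactness the downstream gene-assignment step
relies on. Assignment (`assignHitsToGenes`) gives each hit the nearest
downstream gene start on the matching strand within `windowBp` (default
300 bp, a typical bacterial promoter span).

## Gene neighborhoods, enrichment, locus classes

Neighborhoods are ±`windowGenes` genes (default 10) around a focal gene
in contig gene order, truncated at contig ends. For enrichment, the
neighborhoods of a focal set are unioned before counting, so a gene
covered by two overlapping windows counts once — the paper-scale
alternative (counting occurrences) double-counts dense clusters.
Each family is tested with a one-sided (greater) Fisher's exact test —
computed as the hypergeometric upper tail, verified to machine precision
against an explicit tail-sum oracle on every 2×2 table with N ≤ 60 —
with Benjamini–Hochberg correction applied *jointly* across all
(focal set, family) pairs in a run, matching a global FDR reading of
"all multiple tests corrected". The gene universe is pooled across all
supplied genomes by default; a per-genome universe is a defensible
alternative and can be had by calling the test per genome.

Locus classification is a pure, first-match-wins rule list with an
explicit order: biosynthesis cluster (NRPS enterobactin-synthase
evidence) > heme (*hutB* and *hmuS* colocalized) > catecholate (*fatB*)
> hydroxamate (*fhuD*) > unknown-class siderophore
(siderophore-interacting protein or superfamily-level binding protein) >
`ambiguous`. Biosynthesis outranks uptake classes because synthase genes
are unambiguous whereas binding-protein families co-occur; the order is
fully overridable.

## Markov clustering

`mclCluster` implements MCL from scratch on dense column-stochastic
matrices: add self-loops, column-normalize, then iterate expansion
(matrix power, default 2), inflation (elementwise power then
renormalize, default 2.0 — the canonical setting; no published value
exists for the TBDT clustering this emulates), pruning (entries below
1e-5 zeroed, then renormalize) until the max absolute change falls below
1e-8 or 200 iterations. Self-loop weight defaults to each node's maximum
incident edge weight, the standard damping choice for weighted graphs.
Clusters are read from the attractor structure: nodes with positive
diagonal are attractors, attractors exchanging flow form systems, and
every node joins the system it flows to; a node flowing to two systems
joins the larger (tie: lexicographically smallest member). Labels are
`MCL1, MCL2, ...` by decreasing size; singletons are `MCLnull`. These
labels are size-ranked and not intended to match any published cluster
numbering nominally. Dense matrices are a deliberate scope choice: the
intended problem sizes are 10²–10³ proteins.

MCL carries no monotonicity theorem in the inflation parameter, so the
test suite asserts planted-partition recovery (adjusted Rand ≥ 0.9) and
component refinement, not inflation monotonicity.

## Phylogenetic signal: τ_D and D

**consenTRAIT trait depth.** A clade qualifies when ≥ 90 % of its tips
carry the trait (`positiveFraction = 0.90`, the algorithm's conventional
threshold; it is configurable but was not re-derived here). Maximal
qualifying clades (parent does not qualify) each contribute their mean
branch-length distance to their tips; positive tips outside every
qualifying clade contribute `singletonDepthFactor` (default 0.5) times
their terminal branch. τ_D is the mean of all contributions. Closed-form
consequences used as test anchors: the all-positive trait gives the mean
root-to-tip depth, and τ_D scales linearly with branch lengths.
Significance comes from permuting the tip-to-trait assignment
(`nPermutations = 1000`) with the add-one (Phipson–Smyth) estimator, so
p is never exactly zero. When a *set* of trees is supplied (bootstrap
replicates), the reported mean/SD aggregate per-tree depths across the
set — our reading of published per-trait Mean/SD columns, which do not
state their population; a single tree yields SD 0.

**Fritz–Purvis D.** Internal-node values are computed tips-to-root as
unweighted means of child values; the sister-difference sum Σd adds, at
each internal node, the absolute deviations of child values from their
mean (for a polytomy this generalizes the bifurcating |v₁ − v₂|). D
scales the observed sum between two null expectations,
D = (Σd_obs − mean Σd_B) / (mean Σd_R − mean Σd_B), with the random null
from tip permutations and the Brownian null from threshold simulations:
root value 0, increments Normal(0, branch length), thresholded at the
empirical quantile matching the observed prevalence (ties broken by tip
label order so the positive count is exact). By construction D ≈ 1 for
random and D ≈ 0 for Brownian-threshold traits; the calibration is
verified by parameter recovery (mean D within ±0.15 of each anchor over
200 replicates of 64-tip trees with 1000-draw nulls). Both null Σd
distributions are evaluated as single matrix passes per tree, which is
what makes the replicate grids cheap.

`welchT` implements the unequal-variance t from summary statistics with
Welch–Satterthwaite degrees of freedom. Published lineage comparisons of
trait depth say only "Student's t test" without stating pooling or n;
Welch is the safer default for unequal lineage sizes, and n is supplied
by the caller. `cohensD` uses the summary-statistics form
|m₁ − m₂| / √((s₁² + s₂²)/2) with the conventional small (< 0.5) and
large (> 1) bands.

## Multivariate layer

The source material names both "principal coordinates" and "principal
components" analysis for the same figure; we implement **PCA on the
count matrix** (which matches the plotted ordination) and provide
Bray–Curtis for the dispersion test or external embeddings. PCA is an
SVD of the centered (optionally unit-variance scaled; default
center-only) matrix with a deterministic sign convention — each loading
vector's largest-magnitude entry is positive — so runs are bytewise
reproducible. Whether the original analysis scaled features is unstated;
both modes are exposed and recorded in output provenance.

`envfitPerm` fits continuous variables by least squares on the first
k axes (default 2, the plotted plane) and factors by the
between-centroid R²; significance permutes the variable with the
add-one estimator (default 999 permutations). The test suite
cross-checks R² against `vegan::envfit` while the permutation machinery
remains our own.

`dispersionTest` measures each sample's distance to its group centroid
in the ordination space and computes a one-way F on those distances.
The permutation design permutes group labels **over the fixed
distances-to-own-centroid** rather than recomputing centroids per
permutation: when group centroids differ (the typical case — location
and dispersion effects co-occur), recomputing centroids under permuted
labels breaks exchangeability and the null p-values become
non-uniform; permuting the residual-like distances restores a
calibrated null, as verified by KS uniformity checks in the tests. The
exact test behind published dispersion-significance claims is not in
the main methods of the source material; this design is declared, not
claimed faithful.

Spearman screens use average ranks for ties with the t-approximation
two-sided p (ties make the exact distribution unavailable); constant
variables are flagged NA and excluded from BH. `bhAdjust` is the
standard step-up mapped back to input order (delegating to
`stats::p.adjust`), and `chiSquaredTest` is Pearson's statistic without
continuity correction by default.

## Synthetic data: what it emulates, and what it does not

The generators define the study conditions under which the package is
validated:

- `simTree`: pure-birth (Yule) trees conditioned on the tip count, with
  the birth rate set so the expected root-to-tip depth equals `scale`
  (default 1). Yule topologies are sufficient for every property the
  tests assert; no death process or rate heterogeneity is simulated.
- `simTraits`: `random` (i.i.d. Bernoulli, the no-signal null),
  `clumped` (the smallest clade containing the anchor tip that reaches
  the target count, trimmed by dropping tips patristically farthest
  from the anchor, ties by label order — note that when the enclosing
  clade is much larger than the target, trimming can leave a
  non-monophyletic positive set; tests that require a *literally*
  monophyletic trait construct it from a single clade directly), and
  `brownian_threshold` (the D statistic's own alternative model, with
  an exact realized prevalence).
- `simGenomes`: one contig per genome, fixed gene spacing, background
  families drawn from a weighted pool, locus templates planted as
  contiguous same-strand runs, 300-bp uniform-random upstream records,
  and verbatim motif planting with a stated number of random
  mismatches. Defaults for the count-matrix generator mirror the
  emulated two-lineage comparison: 42 dispersed vs 22 tight genomes
  over 20 transporter categories, with a covariate linearly related to
  the per-genome transporter total.
- `simSimilarityGraph`: planted partitions with within/between edge
  probabilities and mean weights (10 % relative jitter).

None of this emulates real sequence evolution, amino-acid composition,
indels, operon structure beyond contiguity, annotation error, or
incomplete genomes. Passing tests therefore demonstrate algorithmic
correctness and statistical calibration under controlled structure —
not robustness to the annotation noise and assembly artifacts of real
genome collections.

## Problem sizes, determinism, degenerate inputs

The validation grids use 64-tip trees, 200 replicates and 1000-draw
nulls for D; 500 simulations for p-value uniformity; 20-seed
planted-partition grids for MCL; and exhaustive 2×2 enumeration to
N = 60 for the enrichment oracle — sizes chosen so the full suite
completes in minutes while keeping Monte-Carlo error well inside the
asserted tolerances. Every stochastic function takes an explicit seed
and restores the caller's RNG state, so identical inputs give bitwise
identical outputs, including across the pipeline driver.

Degenerate inputs raise classed errors rather than producing silent
values: constant traits (D undefined), all-negative traits (τ_D
undefined), all-zero count rows (Bray–Curtis undefined), zero-variance
variables in scaled PCA and envfit, groups of size one in the
dispersion test, zero marginals in chi-squared, MCL columns pruned to
zero, and templates longer than genomes in the generators.

## Known limitations

- The mutual-best reading of bidirectional reciprocity is one of
  several defensible interpretations for model-database searches.
- MCL cluster labels are size-ranked; they cannot be matched nominally
  to any published cluster numbering.
- τ_D and D cannot distinguish lateral transfer from selective loss;
  they quantify distribution, not mechanism.
- The pipeline consumes trees as given (Newick); no inference,
  calibration or rooting checks beyond label validation are performed.
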