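---
title: "Methods and design of the mycoscan pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the mycoscan pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycoscan)
```

mycoscan re-implements, as a tested and fully seeded pipeline, the
analysis stack used in catalog-based gut mycobiome studies: a curated
fungal genome catalog, genome-size-normalized TPM profiles, and the
standard case/control statistics (diversity, differential abundance,
co-occurrence networks, classification). This vignette explains the
models and the design decisions; it states no empirical claim that the
test suite or `scripts/acceptance.R` does not itself compute.

## Genome catalog

Fungal assemblies are first screened for quality: a genome is removed
when its N50 is below 2,000 bp or it has more than 10,000 scaffolds.
Both inequalities are strict, so the boundary values (N50 exactly 2,000;
exactly 10,000 scaffolds) are retained — the thresholds are worded as
"below"/"more than" and we read them literally. N50 is the length of the
scaffold at which the descending cumulative length first reaches half of
the assembly.

Bacterial contamination is removed at the *scaffold* level, not the
genome level: a scaffold is dropped when at least half of its canonical
31-mers occur in the bacterial reference. Sub-genome removal matches how
mixed assemblies actually fail (individual contaminant scaffolds in an
otherwise fungal bin).

Species dereplication uses MinHash ANI. Each genome is reduced to the
2,000 smallest hashes of its canonical 21-mers; for two sketches the
Jaccard estimate `j` over the merged bottom sketch is mapped through the
Mash distance `d = -(1/k) ln(2j/(1+j))` and `ANI = 1 - d`. Because both
genomes pass through the identical sketch procedure the estimate is
exactly symmetric. Sketch-based ANI was chosen over alignment-based ANI
for speed and self-containment; at the scales that matter for a 95%
species boundary (within-species ≥ 0.98 versus between-species ≤ 0.90)
the estimator's bias (~0.3 points at ANI 0.95, 20–100 kb genomes) is
irrelevant, and the acceptance suite verifies perfect recovery of
planted species across seeds.

Clustering is greedy representative-linkage in the dRep style: genomes
sorted by (N50, total length, id), each joining the first cluster whose
*representative* it matches at ≥ 95% ANI, else founding a new cluster.
This is deterministic, O(n·clusters), and invariant to input order;
representative choice by assembly quality (N50) is our decision — the
source workflow names only the threshold. The "mixture of multiple
genomes" removal criterion sometimes applied to public assemblies is not
operationalizable from the stated rules and is deliberately not part of
`qc_filter`.

## Read QC

Pairs are filtered after polyG-tail trimming (a trailing run of ≥ 10 G,
the two-colour-chemistry artifact convention). The rules — length < 90
bp, mean Phred < 20, more than 30% of bases below Q20, complexity under
30% — are evaluated per mate, and a pair is dropped when either mate
fails; a removed pair is tallied once, under the first failing rule, so
the report's counts always sum to the input count.

Complexity is the fraction of distinct 3-mers among 3-mer positions.
This definition scores homopolymers at `1/(L-2)` ≈ 0.01 and dinucleotide
repeats at ≈ 0.25, both below the 30% cut, while random 100-mers score
≈ 0.5 (the ceiling for k = 3 is 64 distinct 3-mers over 98 positions,
so values near 1 are impossible; what matters operationally is the wide
margin between repetitive and random sequence). The popular
adjacent-mismatch definition was rejected because it rates dinucleotide
repeats as *high* complexity, contradicting the intent of the filter.

## Profiling and TPM normalization

Decontamination and assignment use canonical k-mers (k = 31). A pair is
a decoy hit when either mate has ≥ 50% of its 31-mers in the decoy index
(any FASTA set — host genome, prokaryote catalog, rRNA/tRNA database —
can serve as decoy). Remaining pairs are scored against every catalog
genome by the 31-mers shared across both mates jointly and assigned to
the unique top scorer; ties and zero scorers are discarded and counted,
the same conservative rule applied to external alignments
(`read_best_hits`), where equal top alignment scores also discard the
read. This k-mer pseudo-assignment replaces a gapped aligner only as the
self-contained default; real best-hit tables (SAM/TSV) drop in
unchanged.

Per sample, the count for genome *g* is divided by its genome length
and the quotients rescaled to sum to one million:

> TPM_g = 10^6 · (c_g / L_g) / Σ_h (c_h / L_h)

Genome-size division is what makes profiles comparable across species
with 10-fold different genome sizes; closure to 10^6 makes them
comparable across samples. Note this deliberately divides by genome
size only (no read-length term): it is an abundance, not a
transcript-abundance, normalization. Taxonomic roll-up is a column-sum
by lineage and therefore preserves row sums exactly.

## Community statistics

Alpha diversity (richness = taxa with abundance > 0; Shannon = −Σ p ln p,
natural log) is computed on untransformed fractions. The square-root
transform applies only where it is prescribed: Bray–Curtis distances are
computed on sqrt-transformed fraction profiles. PCoA uses Gower
double-centering `B = -J D² J / 2`; negative eigenvalues (Bray–Curtis is
non-Euclidean) are dropped from both the coordinates and the
explained-variance denominator, so axis percentages are fractions of the
positive spectrum. PERMANOVA is the one-factor decomposition of squared
distances with pseudo-F `(SS_B/(g-1))/(SS_W/(n-g))` and a label-
permutation p-value with the +1 correction, so p is never zero and its
floor is `1/(n_perm+1)`. The acceptance suite verifies the type-I error
at α = 0.05 over 500 null simulations and exact agreement of F and R²
with an independent implementation.

## Differential abundance

Per taxon: Wilcoxon rank-sum p (exact enumeration when n ≤ 12 and
tie-free, else normal approximation with tie correction and continuity
correction), BH adjustment across taxa, fold change
`(max+ε)/(min+ε)` with ε = 10⁻⁶ on the fraction scale (one TPM), and a
single-feature LDA effect size: 30 bootstrap rounds subsample each group
at 2/3 without replacement, the absolute group-mean gap on the TPM scale
is averaged, and the score is `log10(1 + mean gap)`. This deliberately
simplified, fully specified variant reproduces the conventional ">2 on
per-million data" operating point and is deterministic given its seed;
full multivariate LEfSe is out of scope. A taxon passes the screen when
FC > 1.2, LDA > 2, the larger group-mean fraction > 0.01 and q < 0.05
(all strict). The abundance filter is interpreted on the fraction scale
(0.01 = 1%); 0.01 TPM would exclude nothing. "Average relative
abundance" is read as the max of the two group means so that taxa
present in only one group remain detectable.

## Co-occurrence networks

Only taxa detected in strictly more than 10% of samples enter the
correlation matrix (Spearman by default — robust to the heavy tails and
zeros of compositional data). The correlation threshold is chosen by the
random-matrix-theory criterion: for a candidate threshold the masked
matrix's eigenvalues are unfolded through a monotone (Hyman) cubic
spline fitted to ⌈n/10⌉ knots of the empirical spectral CDF, and the
normalized nearest-neighbour spacings are tested against the Poisson law
`P(s) = e^{-s}` (Kolmogorov–Smirnov). The scan ascends from 0.30 in
steps of 0.01 and accepts the first threshold that is Poisson-compatible
(p ≥ 0.05) and remains so for two further steps — the stability check
guards against isolated flukes. GOE-like level repulsion (dense noise)
is reliably rejected and uncorrelated spectra accepted (both at ≥ 90%
rates in the acceptance suite). On clean simulated data the nulls are
already below 0.30, so the scan typically accepts near its starting
point; with real, structured correlation matrices the transition sits
higher.

Indirect edges are removed by network deconvolution: per connected
component, `S = G(I+G)^{-1}` expresses the direct part of an observed
association matrix under a path-sum model; S is rescaled to G's largest
off-diagonal magnitude (the diagonal is not an edge and would otherwise
dominate the rescale) and edges whose deconvolved strength falls below
the network threshold are dropped, after self-loops and "pathological"
near-unit edges (|w| ≥ 0.999). The output edge set is always a subset of
the input. This closed form replaces the published copula-based
indirect-edge procedure with an equivalent-intent, fully specifiable
step — a declared substitution, not a reproduction. A known limitation:
in a module generated by one latent factor *every* edge is partially
path-supported, so deconvolution prunes dense modules aggressively and
can fragment them; block-recovery guarantees are therefore stated for
the thresholded graph.

Topology metrics follow the Cytoscape conventions: average neighbours
2E/N, density 2E/(N(N−1)), characteristic path length averaged over
connected pairs only (unweighted BFS), heterogeneity sd(k)/mean(k) with
the population standard deviation, Freeman degree centralization
`(N/(N-2)) (k_max/(N-1) - density)`, and a top-10 hub list with kingdom
labels, ties broken by node id.

## Classification

Cross-validation is stratified (per-fold class counts within one sample
of proportionality) and repeated; folds are dealt round-robin over a
per-repeat shuffled order, all derived from one seed. Defaults follow
the conventional schemes: 10-fold × 5 repeats for the random forest,
5-fold × 5 for the LASSO. Models are fitted on training folds only; the
LASSO standardizes features on the training fold and picks its penalty
by inner 5-fold deviance CV, the forest uses a fixed tree count (500 by
default). The AUC is the Mann–Whitney rank statistic with midranks
(exactly the all-pairs count) on the pooled out-of-fold scores of each
repeat, averaged over repeats; its 95% CI is a stratified bootstrap of
the per-sample scores averaged across repeats. Importance is aggregated
across folds by mean Gini-decrease rank (forest) or mean absolute
standardized coefficient (LASSO) to avoid scale artifacts. Joint
fungal + bacterial models concatenate the kingdom tables over identical
samples with prefixed feature names.

## The synthetic-data module

The generators define the conditions under which the pipeline's
guarantees are tested:

* **Genomes** are i.i.d. base strings at a chosen GC content;
  `mutate_to_ani` applies point substitutions at rate `1 - ANI`, each to
  a uniformly chosen different base, so realized identity concentrates
  within ±0.2 points of the target.
* **Reads** take uniform fragment starts, a random strand per fragment
  (probability 0.5), per-base substitution errors at a chosen rate and a
  constant Q30 quality string (read-QC tests vary qualities explicitly).
  Contaminant pairs are drawn per pair with the requested probability.
* **Abundance studies** are log-normal: log abundance = log baseline +
  planted log fold change (enriched group only) + σ·ε, with block
  correlation induced by one shared latent factor per block
  (`ε = a f + sqrt(1-a²) e`, so the log-scale correlation between block
  members is a²; ranks survive exponentiation, hence Spearman sees the
  block). Rows are then closed to one million. The log-normal null is
  the standard model for relative-abundance microbiome data; defaults
  (σ = 0.5 on the natural log, planted fold changes 2–10) bracket the
  fold-change regimes the screen is designed to detect.

What the generator does *not* emulate: indels and chimeras, GC bias,
strain-level mixtures, and — importantly — the zero inflation of real
mycobiome profiles. Passing tests therefore demonstrate algorithmic
correctness under a clean generative model, not field performance.

Closure has a real consequence worth knowing: planting a strong fold
change on abundant taxa necessarily *depresses* every other taxon in
that group, so unplanted taxa acquire genuine opposite-direction fold
changes, and abundant correlated blocks acquire cross-block coupling.
The benchmark configurations therefore plant effects on taxa of modest
baseline abundance (network benchmarks use equal baselines), which
isolates the planted structure from closure artifacts; the remaining
coupling is discussed where it matters and is a property of
compositional data generally.

## Numerical choices and problem sizes

Degenerate inputs have defined behaviour throughout: empty composition,
all-zero samples (flagged, distance 0 with a warning), zero-variance
taxa (correlations set to 0 with a warning), all-tied rank-sum inputs
(p = 1), degenerate bootstrap rounds (skipped), singular deconvolution
(fall back to self-loop/pathological removal with a warning), and
sub-spectrum NNSD inputs (< 20 distinct eigenvalues: an error rather
than a silent answer).

The shipped experiments use problem sizes chosen to exercise every
statistical claim comfortably on a single CPU: 200-taxon, 150-sample
studies for the network benchmark; 100-taxon, 50 + 50 studies over 20
replicates for the differential screen; 500 null simulations at n = 30
with 199 permutations for PERMANOVA calibration; 30 genomes of 20 kb in
10 planted species over 10 seeds for the catalog; 20,000 error-free read
pairs for composition recovery; and 10-fold × 2-repeat forests of
100–200 trees for classifier calibration. All are re-run from scratch by
`scripts/acceptance.R` under any `--seed`.
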