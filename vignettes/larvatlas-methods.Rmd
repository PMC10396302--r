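---
title: "Methods: comparative single-cell atlas analysis with larvatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative single-cell atlas analysis with larvatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`larvatlas` packages the analysis stages used to build and compare
single-cell transcriptomic atlases of small marine invertebrate larvae
(for example a mollusc trochophore and a polyclad Müller's larva): QC and
normalization of droplet UMI counts, an iterative merging procedure that
reduces a deliberately over-clustered partition to transcriptionally
distinct clusters, cell-type-level phylostratigraphy (transcriptome age
index and phylostratum enrichment), cross-species cluster alignment
through an ortholog map, and neuropeptide-precursor discovery from a
proteome. Every stage can be exercised on seeded synthetic data with
planted ground truth; the test suite and the acceptance script are built
entirely on such data.

# Preprocessing

**Cell QC.** A cell is removed when it has strictly fewer than
`min_genes_per_cell` (default 200) detected genes, a mitochondrial count
fraction strictly above `max_mito_fraction` (default 0.20; flatworm-style
tissues are commonly run at 0.30), or a total UMI count strictly beyond
`umi_bound` (default 5000) on the side given by `umi_bound_side`. The
side is a parameter rather than a constant because an *upper* bound of
5000 UMIs is unusually strict for deeply sequenced libraries (mean depths
of tens of thousands of UMIs per cell are typical); the default follows
the literal convention of treating 5000 as an upper bound, and the knob
lets an analyst flip it without touching code. Cells exactly at a bound
are kept. Genes left without counts are dropped and reported.

**Normalization.** Counts are scaled per cell to `scale = 10^4` and
log-transformed: `value = ln(1 + 10^4 * count / total)`. This is the
standard library-size/log1p normalization of droplet pipelines; it makes
the values unitless and invariant to proportional per-cell depth changes.

**Variable genes.** The variance-stabilizing flavor of highly-variable
gene selection: per gene, the raw-count mean and variance are computed; a
loess curve (span 0.3, degree 2) of log10 variance on log10 mean gives a
trend-expected standard deviation; counts are standardized by it and
clipped at `sqrt(n_cells)`; genes are ranked by the variance of the
clipped standardized counts. The span and the clip ceiling are the
community defaults for this method. Ties are broken by gene id so the
selection is deterministic.

**PCA.** Selected genes are centered, unit-scaled, clipped at ±10, and
projected on the top `d` (default 70) principal axes. PCA is defined only
up to a sign per axis; we fix it by forcing each axis's
largest-magnitude gene loading to be positive, which makes embeddings
reproducible across platforms.

**Initial clustering.** A k-nearest-neighbor graph (k = 20, Euclidean,
ties broken by cell id) is converted to a shared-nearest-neighbor graph
with Jaccard weights `|shared| / (2k - |shared|)`, edges below 1/15
pruned, and partitioned by seeded multilevel modularity optimization
(Louvain) at resolution 10. The high default resolution *over-clusters
on purpose*: the merge stage below is the principled way the pipeline
decides how many clusters the data support. External labels can be
supplied instead, which also bypasses any stochasticity.

# Iterative cluster merging

The merge procedure treats "cluster" as a falsifiable hypothesis: two
clusters deserve to be separate only if enough genes distinguish them.

1. Compute each cluster's centroid (mean log-normalized expression).
2. Rank all cluster pairs by Pearson correlation of centroids, highest
   first (ties broken lexicographically).
3. Walking the ranked list, count differentially expressed genes between
   the pair's cells: per gene a two-sided Wilcoxon rank-sum test (normal
   approximation with average ranks, tie-corrected variance and 0.5
   continuity correction), Bonferroni-adjusted across genes; a gene is DE
   when adjusted p < 0.01 and |log2 fold change| of the group means
   (pseudocount 1e-9) is at least 0.25.
4. The first pair with fewer than `de_gene_threshold = 20` DE genes is
   merged into the lexicographically smaller id, the merge is logged, and
   the pass restarts from step 1.
5. Stop when a full pass makes no merge.

Bonferroni rather than a milder correction is intentional: it biases the
DE count down and the procedure toward merging, so surviving clusters are
conservatively distinct. The DE-count threshold of 20 operationalizes
"differing by less than 20 DE genes with fold change"; the fold-change
floor (0.25 on the log2 scale) and the per-pair significance level (0.01)
are the community defaults for this kind of filter. Pairs in which either
side has fewer than 3 cells are never merged — the test is undefined
there — and the audit property holds on termination: no remaining
testable pair is below the threshold. The tie-corrected mean and variance
used by the normal approximation equal the exact permutation-null moments
of the rank-sum statistic, which the test suite verifies by full
enumeration at small group sizes.

The per-gene rank-sum kernel is implemented in C++ (via Rcpp): merging
re-tests thousands of genes per candidate pair, and a vectorized kernel
keeps whole-pipeline runs interactive.

# Cell-type phylostratigraphy

Each gene carries a phylostratum rank (1 = oldest; larger = younger),
supplied as an input table. The transcriptome age index of a cluster is
the expression-weighted mean rank over the cluster's centroid:

TAI = Σ_g ps_g · e_g / Σ_g e_g

with `e_g` the log-normalized average expression and the sum over genes
with positive centroid expression *and* a known age; genes without an age
are excluded, never imputed, and their count is reported. As a weighted
mean, the TAI is bounded by the youngest and oldest rank present, and
moving weight from an older to a younger gene strictly increases it.
Whether to use all genes or expressed genes only is a genuine choice; we
restrict to positive centroid expression because a gene contributing zero
weight is undefined in the ratio and because "the transcriptome of a cell
type" is naturally the genes it expresses.

Marker genes are called one-vs-rest per cluster (same Wilcoxon kernel,
Benjamini–Hochberg within cluster, adjusted p < 0.05, log2FC ≥ 0.25,
in-cluster mean above out-cluster mean). Phylostratum enrichment of a
cluster's markers against the background of all expressed aged genes is
the upper hypergeometric tail P(X ≥ k) for k markers in a stratum versus
K background genes in it. The grid is reported raw (as such heatmaps
conventionally are, as −log10 p floored at 1e−300) with a BH-adjusted
column alongside; over-representation only, since depletion of a stratum
among markers is not the question these analyses ask.

# Cross-species cluster alignment

The module implements the alignment *score* over a fixed homology map; it
does not re-implement the iterative expression-driven reweighting of the
homology graph that dedicated tools perform, so scores here are a
transparent, reproducible summary rather than a clone of any tool.

1. **Ortholog collapse.** The (possibly many-to-many) ortholog map is
   treated as a bipartite graph; connected components become shared
   features. Within a component, each species' feature value is the
   weight-normalized average of its member genes' expression (a gene's
   weight is its total incident edge weight), so 1:1 pairs pass through
   unchanged and paralog fans average. One-sided components are dropped
   and counted.
2. **Joint embedding.** Features are standardized within species
   (removing species-level location/scale), the two cell blocks are
   concatenated, and PCA (d = 30, sign-fixed) is applied.
3. **Mutual nearest neighbors.** Cross-species pairs (x, y) such that
   each is among the other's k = 20 nearest cells of the other species
   (Euclidean, ties by cell id).
4. **Scores.** For clusters c, d: `s_c` = mean over cells of c of their
   mutual partners in d divided by k (the maximum possible); the reported
   score is the symmetric mean `(s_c + s_d)/2 ∈ [0, 1]`. Both directions
   are also emitted, since "the average over cells" does not by itself
   fix a direction; a pruned view zeroes scores below 0.1.

Two properties of mutual-kNN scores matter for interpretation. First,
aligning a dataset with itself through an identity map at k = 1 gives
exactly the identity matrix — the contract test of the implementation.
Second, score magnitudes depend on k relative to cluster sizes; clusters
should be comfortably larger than k for the "fraction of the maximum
possible neighbors" reading to be meaningful.

Shared markers of an aligned pair are the ortholog records whose two ends
are markers of the respective clusters; because the map may be
many-to-many, the two species' distinct-gene counts legitimately differ.

# Neuropeptide-precursor discovery

Secretion calls come from an external predictor table when available
(rows with a D-score below 0.34 are treated as non-secreted, mirroring a
sensitive secretome cutoff); otherwise a deliberately simple built-in
heuristic stands in: a length-8 window within the first 45 residues with
mean Kyte–Doolittle hydropathy ≥ 1.6 (a hydrophobic core) plus a basic
residue among the first five or an initiator M. The heuristic is a
documented stand-in, not a claim of predictor fidelity, and an external
table always wins.

Downstream of the signal peptide, cleavage sites are: dibasic —
left-to-right non-overlapping matches of `KR|RR|KK|RK`; monobasic — a
free-standing K/R preceded by another free-standing K/R exactly 2, 4 or 6
residues upstream. The context residue must not belong to a dibasic site:
otherwise the K of a `KR` separator would license cleavage *inside*
canonical `KR`-flanked peptide repeats (e.g. an internal R of an
FMRFamide-like peptide two residues after the separator), which is
exactly the repeat structure the scan is meant to preserve. The spacing
rule follows the convention of the precursor-discovery literature; it is
a documented grammar choice and is configurable.

Peptides are the segments strictly between signal end, site residues, and
sequence end; a terminal G before a downstream site flags amidation and
is trimmed; flanking K/R are trimmed; segments of 3–40 residues are kept.
Every post-signal residue is assigned to exactly one category (site,
trimmed basic, trimmed G, peptide, discarded segment), and
`audit_conservation()` verifies the partition reconstitutes the sequence
— the invariant that makes boundary arithmetic trustworthy. Candidates
are ranked by (peptide count, amidated count, maximum pairwise gap-free
identity), i.e. by how much they look like the repetitive, amidated
architecture of real precursors; ranking replaces the manual curation a
real study would apply and claims no fidelity to it.

# Synthetic data: what is planted and what is not modeled

All generators are pure functions of a `sim_spec()` (seed included), and
truth tables are returned alongside the data so tests never re-derive
truth from generator internals.

* `simulate_counts()`: per-gene log-normal baselines, disjoint marker
  blocks up-shifted by `marker_log2fc` (default 2), negative-binomial
  sampling (dispersion 0.5 — the standard count model for UMI data),
  per-cell depth uniform in 1500–3000, 240 cells, 2000 genes, 4 clusters
  by default; 20 `mt-` genes, with 5% of cells planted at 25–50%
  mitochondrial content so QC has something to remove.
* `simulate_gene_ages()`: 8 strata, uniform background; markers of the
  designated young cluster drawn from the youngest stratum with
  probability 0.8 — the cell-type-restricted young signature that a
  shell-gland-like innovation produces.
* `simulate_species_pair()`: a latent gene space (800 genes) instantiated
  in both species, 20% of latent genes with two paralogs on one side
  (making the map many-to-many); 3 shared types re-using the same latent
  marker blocks in both species plus 1 private type per species. Every
  type carries an additional unmapped species-specific "flavor" block, so
  marker mass is comparable across types; private types use a
  species-unique *mapped* block `private_program_scale = 4` times larger
  than a shared block. The scale matters: in the shared feature space a
  private type with no mapped program of its own is indistinguishable
  from "none of the shared types", and two such leftovers from the two
  species mutually attract (through mean-centering they share the
  complement signature of every shared block). A genuine lineage-specific
  innovation is an *outlier* in conserved-gene space; planting it far
  from the shared manifold (deviation y with y² ≳ 2x² relative to a
  shared block's x) makes each private cluster's cross-species neighbor
  lists land on shared-type cells, which never reciprocate, and its
  alignment scores collapse toward zero — the behavior the planted
  ground truth asserts.
* `simulate_precursors()`: 20 precursors (signal peptide, short leader,
  5 copies of a mutated base peptide separated by `KR`, 70% of copies
  amidated, polar tail) among 500 K/R-poor decoys, half of them with
  signal peptides; exact peptide intervals in the truth table. Peptide
  alphabets exclude K/R (no spurious sites inside planted peptides) and
  terminal G (no spurious amidation).

Not modeled: doublets, ambient RNA, batch/library effects, gene-length or
GC biases, within-cluster substructure, non-uniform stratum sizes, and
real signal-peptide sequence diversity. Passing the recovery tests
therefore demonstrates correctness of the *algorithms* under the stated
generative assumptions, not robustness to every artifact of real data.

# Numerical choices and degenerate inputs

* Fold changes use pseudocount 1e-9 on means of log-normalized values.
* Enrichment p-values are floored at 1e-300 before −log10.
* All orderings (pair ranking, gene selection, neighbor lists) break ties
  by identifier, making every output deterministic; the only seeded step
  is community detection, and `run_all()` re-running a config reproduces
  outputs byte-for-byte.
* Constant centroids get correlation 0 (with a warning) rather than NA.
* Zero-marker clusters get enrichment p = 1, flagged, rather than being
  dropped from the grid.
* A cluster with no aged genes is reported with a missing TAI, never 0.
* Wilcoxon p-values use the normal approximation throughout (group sizes
  in this context are tens of cells, where it is accurate; the exact
  null is used only as a test oracle).

# Problem sizes

Module tests run on matrices of roughly 40–240 cells × 150–2000 genes.
The acceptance checks use: 100 seeds × {2, 4, 6} planted types (60
cells/type, 2000 genes) for merge recovery; 100 seeds of the default
single-species spec for the young-cluster analyses; 100 seeds of the
default species pair for alignment recovery; 5 proteome seeds (520
proteins each) for precursor recovery; exhaustive enumeration up to
N = 30 for the hypergeometric oracle and 500 fixtures for the permutation
oracle. `scripts/acceptance.R` recomputes the same quantities at 30–50
seeds per item. These sizes were chosen so the planted effects are
comfortably detectable at desk scale while each suite stays fast.

# Known limitations

* The SNN/Louvain initial clustering is plumbing: resolutions are not
  calibrated across datasets, which is precisely why the merge stage, not
  the resolution, decides the final cluster count.
* The alignment module scores a *fixed* ortholog map; expression-informed
  homology reweighting, multi-way alignment and UMAP stitching are out of
  scope.
* The signal-peptide heuristic is a coarse stand-in; for real analyses an
  external predictor table should always be supplied.
* Gene ages are consumed, not computed; assigning phylostrata is a
  database-scale homology problem outside this package.
* Single-library path only: multi-library integration and batch
  correction are deliberately not implemented.
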