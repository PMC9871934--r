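---
title: "Cross-species cell-type correspondence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species cell-type correspondence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope

`orthocell` is a pipeline for comparative single-cell RNA-seq of two
species — the motivating setting is aortic aneurysm tissue profiled in
both human patients and angiotensin-II-infused mice. Its question is
whether the cell types (and disease-associated subtypes) found in one
species have transcriptional homologs in the other, and whether disease
shifts cellular composition the same way in both. The package covers
quality control, normalization, clustering, marker detection, gene-set
scoring and enrichment, and — the core step — cross-species cell-type
correspondence through ortholog marker intersection and hierarchical
clustering of pseudobulk profiles. A synthetic two-species generator with
planted ground truth backs every claim the test suite makes.

## The count model behind the generator

Counts are negative binomial with mean `mu` and dispersion `phi`
(`variance = mu + mu^2 / phi`), the standard overdispersed model for UMI
counts. Each gene has baseline mean `baseline_mean` (default 0.5, a
typical per-gene UMI rate in droplet data); the planted marker genes of a
cell type are elevated `marker_fold_change`-fold (default 4) in that type
only. Cell-type programs span `n_marker_genes_per_type = 40` ortholog
genes by default, disjoint between types: a distinct lineage differs by
dozens of genes in real tissue, and with far fewer planted markers the
between-type variance direction falls below the bulk of the noise
spectrum of the gene pool, which no clustering method can overcome — the
default is chosen to represent a *distinguishable* lineage, the regime
the source analysis operates in.

Two species share `n_shared_types = 5` homologous programs planted on the
same ortholog genes (species A symbol `GENEk` pairs with species B
`genek`, mirroring human/mouse symbol case conventions); each species
additionally carries one private type planted on ortholog genes the other
species' types do not use, so the correspondence step has true negatives.
Mitochondrial genes (`MT-`/`mt-` prefixes) are given means that put their
expected share of per-cell counts at `mito_mean_pct` (default 2.5%).
Condition composition multipliers (default: smooth-muscle 0.4x,
macrophage and T 1.5x in `aneurysm`) rescale cell numbers, not
expression — the phenomenon modeled is compositional. Doublets are
planted by adding a second random cell's counts to `round(rate * n)`
barcodes; the flag count is therefore exact by construction.

What the generator does *not* emulate: ambient RNA, batch effects between
samples, UMI saturation, cell-cycle structure, or a realistic spread of
per-gene baseline means (baseline genes share one mean so that count
moments are exactly checkable). Passing tests therefore demonstrate the
pipeline's correctness and recovery behavior under a clean NB world, not
robustness to those artifacts.

## Quality control

Filtering follows the published thresholds with literal boundary
semantics: genes detected in fewer than 3 cells are removed; cells are
retained when their detected-gene count lies in the closed interval
[100, 4000] and their mitochondrial percentage is at most 5.0. The stage
order is genes, then cells, then doublets; the order matters (removing
genes changes detected-gene counts) and is asserted stable in tests.
Thresholds are applied per sample.

Doublet scoring plants artificial doublets (25% of n) built by summing
the raw counts of two random distinct cells — the same generative process
a real doublet follows — then normalizes real and artificial cells
together, embeds them with PCA (10 components over up to 1,000 variable
genes), and scores each real cell by the artificial fraction among its
k = 20 nearest neighbors. The top `doublet_expected_rate` (default 5%)
of cells by score is flagged, exactly `round(rate * n)` cells. Summing
counts rather than averaging normalized profiles is deliberate: averaged
log-profiles sit systematically off the real doublet manifold and cost
detection power on the planted-doublet oracle.

## Normalization, variable genes, PCA

Log-normalization is `ln(1 + count * 1e4 / library_size)`; natural log
and scale factor 1e4 are the conventions of the pipeline family the
analysis used. The transform is scale-invariant per cell and keeps
sparsity.

Variable genes are ranked by binned standardized dispersion: genes are
placed in 20 equal-frequency bins of mean log-normalized expression and
scored by the within-bin z-score of `log(variance / mean)`; ties break
lexicographically so the selection is a pure function of the input. The
default selection size is 2,000. This dispersion variant was chosen over
a loess-based standardized variance because it is dependency-free and
deterministic with the same ranking intent; on matrices with fewer genes
than the selection size it degenerates gracefully to "all genes".

Scaling centers each gene, sets unit variance (zero-variance genes become
zero rows), and clips at ±10. PCA is an exact SVD of the scaled matrix
(30 components by default, the published setting); component signs are
fixed by the largest-magnitude loading, so results are deterministic
without a random solver. Rank-deficient inputs are zero-padded with a
warning. Multi-sample harmonization is a gene-intersection merge with a
sample covariate: anchor-based integration is a published external
algorithm and is intentionally not re-implemented; the correspondence
step operates on pseudobulk profiles, which are robust to this
substitution, and the generator produces no batch effect that would
require more.

## Clustering and composition

The cell graph is a shared-nearest-neighbor graph: union of directed
k = 20 nearest neighbors in PC space, edges weighted by the Jaccard
overlap of the endpoints' neighbor sets (self included). Communities are
found by Leiden modularity optimization at resolution 0.5 (the published
resolution; the algorithm itself was not named in the source, and Leiden
is the current default of the pipeline family), seeded, with labels
relabeled by decreasing size. One practical caveat documented by the
tests: on low-dimensional toy data a tight Gaussian blob's kNN graph is a
geometric graph with real fine-scale substructure, which modularity
optimization resolves into patches unless the neighborhood is comparable
to the group size; in the 30-dimensional embeddings the pipeline actually
uses, within-type graphs are expander-like and this does not occur.

t-SNE (perplexity `min(30, (n-1)/3)`, seeded) is provided for
visualization only; nothing downstream consumes its coordinates.
Composition tables are per-sample and per-condition cell-type fractions;
rows sum to one by construction. Clusters are mapped to named cell types
by the highest mean marker-set score (`annotate_clusters`); a YAML of
canonical aortic lineage markers ships in `inst/extdata/`.

## Marker detection

Markers are one-vs-rest Wilcoxon rank-sum tests on log-normalized
values, per cluster, for genes detected in at least 10% of the cluster.
The U statistic uses midranks; p-values are exact (null distribution of
U) when `n_x * n_y <= 400` and tie-free — forced-exact mode falls back to
full enumeration under ties — and otherwise use the normal approximation
with tie and continuity corrections. Fold change follows the
`log2((mean(expm1(x_in)) + 1) / (mean(expm1(x_out)) + 1))` convention of
the pipeline family, stated explicitly here because the source never
defines it. BH adjustment is applied within each cluster (markers are
reported per cluster; a global family would mix questions). Tables order
by decreasing fold change with gene-id tie-breaks, so "top n" is
deterministic; ranking by fold change rather than p follows the "arranged
by log2 fold change" presentation of the source.

## Cross-species correspondence

The homology procedure:

1. Resolve the ortholog map to one-to-one pairs (only genes occurring
   exactly once in the raw map survive; pairs absent from either dataset
   are dropped, with counts reported).
2. For each shared cell type, intersect the top 50 markers of species A
   with the ortholog-translated top 50 of species B; the union of
   per-type intersections is the shared gene set.
3. Average log-normalized expression per cluster (pseudobulk), stack both
   species' matrices over the shared genes, and z-score each gene column
   across the combined clusters. Scaling across the combined matrix (not
   within species) is a choice: it lets a gene's between-species level
   difference count against a pairing, which is the conservative reading
   of a shared scale bar.
4. Hierarchically cluster all rows with distance `1 - Pearson` and
   average linkage — the standard metric for expression-profile trees and
   robust under the z-scoring — and pair every A-cluster with its
   argmax-correlation B-cluster. Argmax pairing is used rather than a
   tree cut because the claim of interest ("every type clusters with its
   homolog") is a pairing claim and argmax is deterministic and testable;
   the dendrogram is still emitted (including Newick export) for
   inspection. Species-specific clusters are reported with their best
   match and (low) similarity, never suppressed.

Zero-variance gene columns are dropped with a warning before scaling.
Similarities live in [-1, 1]; on planted data homolog pairs sit near
+0.95 and private types below +0.2, and pairing similarity rises
monotonically with planted fold change.

## Gene-set scoring and enrichment

Module scores come in two flavors: the plain per-cell mean of the set's
log-normalized values (the definition the source states for immune-state
calls, and the default), and a control-adjusted score subtracting the
mean of `n_ctrl = 100` control genes drawn per set gene from the same
average-expression bin (24 equal-frequency bins), seeded — the
bin-matched construction that keeps random sets centered at zero on null
data. Group comparisons delegate to the same rank-sum test and report
medians.

Enrichment is the upper-tail hypergeometric test `P(X >= overlap)` over a
user-supplied GMT collection, BH-adjusted across sets. The universe
defaults to all genes surviving QC in the tested dataset; annotation
databases are out of scope by design (the published analysis used GO/KEGG
services, which are external resources). A small built-in T-cell state
collection (naive/resident/exhausted/cytotoxic/co-stimulatory) ships as
an editable convenience, not as the authors' exact sets.

## Orchestration and determinism

`run_pipeline()` drives simulate-or-read, QC, preprocessing, clustering,
markers, and correspondence from a single validated config (YAML-loadable,
unknown keys rejected). Stage s derives its seed as `seed + s`; every
stochastic step (generator, doublet scorer, Leiden, t-SNE, control-gene
sampling) is seeded from that derivation, so identical config plus seed
reproduces byte-identical artifacts, recorded with MD5 digests in a
manifest. A thin subcommand wrapper (`inst/scripts/orthocell.R`) exposes
simulate/qc/enrich/run for shell use; the R functions are the primary
interface.

## Problem sizes and numerical choices

The test suite and the reproduction script use datasets of five shared
types plus one private type per species at 200 cells per type (two
conditions of 100 before composition multipliers), 800 ortholog plus 100
private plus 10 mitochondrial genes — structure recovery is already
unambiguous at this size, and the suites stay fast enough to run
routinely. Other conventions: clip at ±10 in scaling; exact-p threshold
`n_x * n_y <= 400`; hypergeometric p of an empty overlap is exactly 1;
empty clusters and empty gene intersections are errors, not warnings;
zero-variance genes scale to zero rather than NaN.

## Known limitations

- One-to-one ortholog resolution discards paralog families entirely;
  expanded families (common for immune genes) contribute no signal.
- The correspondence operates on cluster pseudobulks: a type present in
  one species but absorbed into a neighbor cluster in the other will pair
  wrongly before it pairs weakly.
- The simplified doublet scorer is calibrated for heterotypic doublets;
  its AUROC on the generator is near-perfect partly because planted
  doublets are exact count sums — real doublets carry segmentation and
  ambient artifacts the generator omits.
- Per-sample QC thresholds are fixed, not adaptive; unusually deep or
  shallow libraries shift which cells the gene-count window retains.
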