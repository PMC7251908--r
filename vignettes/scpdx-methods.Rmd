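---
title: "Methods: mixed-species droplet analysis and expression-derived malignancy calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixed-species droplet analysis and expression-derived malignancy calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`scpdx` implements a complete analysis chain for droplet scRNA-seq of
patient-derived xenografts (PDX): a human tumor grown in a mouse, sequenced
as one mixed-species cell suspension. This vignette explains the models and
procedures, the parameters that matter, what the synthetic data generator
does and does not emulate, and the design choices made where the methods
left genuine freedom.

## Species demultiplexing and droplet QC

Each feature carries a genome tag (`GRCh38` / `mm10`). A barcode's candidate
species is its majority genome; if the minority genome contributes at least
`cross_species_fraction` (default 1%) of its UMIs the barcode is called a
**multiplet** (a human+mouse doublet, the only doublet class this rule can
see) and removed. The fraction is computed on UMI counts — the unit a
CellRanger matrix actually stores.

Cell-level filters then retain barcodes with 1,000–150,000 UMIs, 500–10,000
expressed genes (a gene is "expressed" at count ≥ 1), mitochondrial UMI
fraction ≤ 10% (gene-name prefix `MT-`/`mt-`, configurable regex), and mean
housekeeping expression ≥ 3. The housekeeping check uses beta-actin and
GAPDH on the log2(TPM-like + 1) scale: the threshold "3" is only meaningful
on a normalized log scale, and because the per-cell transform depends only
on that cell's own counts, the check is independent of which other cells
survive. Cells labeled mouse are checked against the mouse-cased symbols
(`Actb`, `Gapdh`) — the human genes are structurally absent from the mouse
genome, so a single symbol pair cannot serve both species. Tumor clusters
are additionally required to exceed 2,000 expressed genes (strict `>`),
reflecting that malignant cells carry systematically richer libraries.

The retained set is a conjunction of per-cell predicates, so filter order
cannot change it; the report attributes each removal to the *first* failing
rule in the fixed order multiplet, UMI, genes, mito, housekeeping.

An optional, explicitly logged cluster-purity filter
(`cluster_purity_filter()`) flags cells whose cluster label disagrees with
the majority label of their k = 20 nearest neighbours in PC space; it is
the package's concrete, reproducible stand-in for ad-hoc per-subtype
outlier removal, and it is off unless invoked.

## Normalization, clustering, differential expression

Counts are depth-normalized to a fixed per-cell total of 10^6 ("TPM-like";
no gene-length correction, appropriate for 3′ UMI chemistry) and
log2-transformed after adding one. Genes expressed in fewer than 1% of
cells are dropped first (inclusive boundary: 2 of 200 cells is kept).

Variable genes are selected by binned dispersion: genes are placed into 20
equal-frequency bins by mean expression, the dispersion (variance/mean) is
z-scored within each bin, and genes above a z cutoff of 1 are kept.
Constant genes can never be selected. PCA runs on per-gene z-scores capped
at ±10 (the cap stops a single extreme cell from dominating a component);
20 components feed a k = 20 nearest-neighbour graph clustered by Louvain
modularity at resolution 1. The component count is a fixed parameter rather
than a per-dataset significance test: the chain consumes a stated number of
components, and re-deriving it adds noise without changing the contract.
Clustering is deterministic for a fixed seed.

Clusters are annotated by marker programs: for each candidate type, the
cluster mean of the per-cell mean marker expression; the arg-max wins, ties
break alphabetically with a warning.

Differential expression is a per-gene two-sample t test on the
log-normalized values. The variance flavour is Welch (unequal variances):
the original description says only "Student's t test" via an old Seurat
default whose exact behaviour is not recoverable, and Welch is the safer
default under unequal group sizes and variances; fold-changes are log2
mean differences. Genes must be expressed in ≥ 10% of either group and have
|logFC| ≥ 0.25 to be tested; p-values are Bonferroni-adjusted over the
tested genes, and a reporting flag marks |logFC| > 0.8 with p < 0.001 (the
volcano-plot highlight rule).

## Expression-derived CNV inference and malignancy calling

The caller reconstructs broad copy-number dosage from smoothed,
position-ordered expression:

1. genes with mean log-normalized expression < 0.2 are discarded; genes
   without a position are dropped with a warning;
2. each gene is standardized (one centering + unit-variance pass; the
   separately stated "mean centering" and "z-score" steps collapse because
   centering is idempotent; zero-variance genes become all-zero);
3. values are clipped to ±3 *before* smoothing, so one extreme value cannot
   distort a whole window;
4. genes are ordered by (chromosome, start) in karyotype order
   (1–22, X, Y by default; unknown chromosomes sort last);
5. per chromosome, a 100-gene moving average (step 1, truncated at the
   ends, never spanning chromosomes) smooths each cell's profile, which is
   then re-centered to per-cell mean zero. Re-centering is per cell, not
   per gene: the quantity being adjusted is each cell's profile.

The **CNV score** is the mean of squared inferred values (a magnitude of
genomic distortion); the **CNV correlation** is each cell's Pearson r
against the reference profile, the per-gene mean over the top 5% of cells
by score, taken once from the pre-call ranking. Calls use two strict
cutoffs — score 0.02 and correlation 0.2: both above ⇒ tumor, both below ⇒
non-tumor, anything else (discordant values, exact boundary values,
undefined correlations) ⇒ undetermined. A single recalibration pass then
subtracts the non-tumor per-gene mean and recomputes scores, reference,
correlations and calls once; recalibration is not iterated because the
procedure is described as one final pass, and iterating would let call
flips feed back into their own baseline.

### Anchoring the baseline

Standardizing on *all* cells implicitly assumes normal cells dominate, so
that the per-gene mean approximates the diploid baseline. When the
malignant fraction approaches one half, the mean sits midway between the
two populations, both deviate symmetrically, and which one looks
"distorted" is decided by noise — on a 50/50 synthetic mixture the measured
score distributions of tumor and normal cells are identical and the
reference orientation flips between seeds. `prepare_expression()` and
`infer_cnv()` therefore accept `baseline_cells`: presumed-normal cells
(in practice, the marker-annotated non-tumor clusters, which the pipeline
has already computed by the time CNV runs) on which genes are centered and
scaled. This is the reference-cell convention of expression-CNV tools
generally, and it restores a stable zero point at the normal karyotype.
Without `baseline_cells` the all-cell behaviour is unchanged.

## Gene-set scores, cell cycle, subtype, composition

The enrichment score is a rank statistic: per cell, genes are ranked by
expression (average ranks on ties) and the score is the mean rank of
in-set genes minus the mean rank of out-set genes, divided by n/2 — the
largest attainable difference for any set size, making the score lie in
[−1, 1] with positive values meaning enrichment at high expression. Being
rank-based it is invariant to any monotone per-cell transform. It replaces
kernel-density GSVA scoring deliberately: the downstream classification
consumes only score *signs*, for which any monotone-equivalent scoring is
interchangeable, and numerical agreement with the GSVA package is a
non-goal.

Cell-cycle states use G1/S and G2/M panel scores: cycling if both are
strictly positive, non-cycling if both strictly negative, intermediate
otherwise. Exact zeros fall to intermediate — the strict inequalities of
the rule leave them unassigned, and intermediate is the only honest label.

Molecular subtypes of bulk profiles are assigned by Pearson correlation
against per-subtype signature centroids over the centroid's genes
(subtypes sharing < 3 genes with the sample are skipped): the call is the
arg-max r among subtypes with r > 0 and two-sided p < 0.05, else
"unclassified". Anti-correlation is never a call, however significant.
The bundled centroid table is synthetic (five subtypes × 40 genes,
generated once) and exists so the workflow is demonstrable and testable;
real analyses must supply their own signature centroids.

Composition shifts between two groups use the Pearson chi-squared test on
the 2 × k table of per-category counts (no continuity correction,
df = k − 1); categories with expected count zero are an error advising a
merge.

## Ligand–receptor networks

For every (ligand, receptor) pair and ordered (sender, receiver) type pair
— self-pairs included — the interaction count links every sender cell
expressing the ligand to every receiver cell expressing the receptor:
`count = n_senders_expressing × n_receivers_expressing`. "Expressing"
means normalized expression > 0 (configurable). Counts are unweighted by
expression level, matching the verbatim description of pair counting.
Node sizes are cell counts ÷ 20 and edge weights counts ÷ 4·10⁶ — fixed
drawing rescalings, not statistics. The 10% rule (sender
ligand-expressing fraction > 0.10) is a drawing flag only; it never
modifies counts. No permutation significance is attached to edges
(CellPhoneDB-style nulls are out of scope).

## The synthetic data generator

`simulate_mixed_pdx()` draws UMI counts per cell from a negative binomial
(size 2 by default — the standard droplet overdispersion model) around a
cell-type expression program, scaled by a lognormal per-cell depth (mean
5,000 UMIs, sdlog 0.3). Dosage acts multiplicatively on the NB mean
*without* renormalizing the program, so a planted dosage d multiplies the
expected count by exactly d — the simplest model consistent with
expression-derived CNV, and the property the recovery tests check.
Mitochondrial genes receive a configured fraction of depth (5% healthy,
15% dying); two housekeeping genes are pinned at ~1.5% of depth each;
marker programs boost 10 canonical genes per type 25-fold; cycle panels
(20 G1/S + 20 G2/M genes) are boosted 4-fold in cycling cells and damped
in non-cycling cells. Cycle genes get a fixed moderate base weight rather
than heavy-tailed random draws: canonical proliferation genes are
consistently expressed in real data, and a random draw occasionally left
half a panel near-silent, which no real cycling cell shows. Ambient
cross-species contamination adds a Poisson share (default 0.5%) of each
cell's depth on the other genome; a configurable fraction of barcodes
(default 2%) are human+mouse doublets. One integer seed drives every
sub-stream deterministically.

The default configuration — the study conditions for the whole test suite —
is ~2,000 cells in four types (500 human tumor, 500 human stromal, 500
mouse fibroblasts, 500 mouse macrophages), a 6,000-gene human genome over
10 chromosomes plus a 3,000-gene mouse genome, and one tumor subclone with
30% of human genes altered (genes 1–450 of chromosomes 1 and 3 at dosage
1.5, of chromosomes 2 and 4 at dosage 0.5). The genome size matters more
than it appears: with a 100-gene smoothing window, a g-gene genome has
roughly g/100 independent CNV windows, and a genome much below a few
thousand genes inflates the noise correlations of normal cells against the
reference — a regime no real post-filter droplet dataset occupies. Gene
positions are contiguous equal blocks per chromosome; only ordering
matters downstream. A planted ligand–receptor axis (human CD274 on tumor
cells → mouse Pdcd1 on macrophages) gives the network stage a known
ground-truth edge across the species boundary, mirroring how a
tumor-to-host checkpoint signal appears in PDX data.

What the generator does *not* emulate: read-level artifacts (it starts at
UMI counts), batch effects, within-species doublets, UMI collisions,
spliced/unspliced layers, and gene-length effects. Passing tests therefore
demonstrate correctness of the implemented procedures under a faithful
statistical cartoon of PDX droplet data — not robustness to every failure
mode of real libraries.

## Numerical choices and degenerate inputs

Zero-variance genes z-score to all-zero columns rather than NaN. Windows
truncate at chromosome ends; a matrix where every chromosome has fewer
genes than the window is an error. A constant reference profile makes the
correlation undefined: all calls become undetermined with a warning, and
recalibration without non-tumor cells returns the input flagged
uncalibrated. Exact cutoff equality is undetermined by construction.
Depth-zero cells are an error at normalization (QC should have removed
them). Ties in marker annotation and subtype correlation break
deterministically (alphabetical / centroid order) with warnings.
All randomness flows from single integer seeds; repeated runs are
byte-identical, which the pipeline tests assert on written CSVs.

## Problem sizes used by the test suite

The suite and the acceptance script run entirely on generated data: the
default ~2,000-cell, 9,000-gene configuration for end-to-end checks
(malignancy recovery, clustering ARI, cycle recovery, null calibrations),
and purpose-built toys of 3–120 cells for oracle equivalences
(moving-average naive loop, O(n²) pair enumeration, closed-form Welch t,
hand-computed chi-squared). These sizes were chosen so that every
stochastic recovery statement is backed by hundreds of cells per group
while any single check still runs in seconds.

## Known limitations

The multiplet rule only sees cross-species doublets; same-species doublets
pass. The malignancy caller needs either a sub-50% malignant fraction or a
baseline cell set; a sample that is almost entirely tumor with no
annotated normal cells will anchor poorly. Subtype calls are only as good
as the supplied centroids. The LR counts are descriptive; they carry no
significance model. The QC thresholds are the original study's and are not
auto-tuned per dataset.
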