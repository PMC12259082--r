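---
title: "Models and methods behind nichetrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nichetrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`nichetrace` quantifies how premalignant epithelial cell states and
their tissue microenvironment change together, from
single-cell-resolution spatial transcriptomics. This vignette explains
the models, the parameters that matter, the synthetic data the package
is validated on, and the design choices made where more than one
reasonable construction existed.

## The cell-state continuum: diffusion components

Premalignant epithelial phenotypes form a continuum between gastric-like
and progenitor-like states rather than discrete clusters. We model the
continuum with diffusion maps. From a latent representation (typically
PCA of normalized counts), a kNN graph (`k = 30`, Euclidean) carries an
adaptive Gaussian affinity

    a_ij = exp(-d_ij^2 / (sigma_i * sigma_j)),

with `sigma_i` the distance from cell *i* to its 10th nearest neighbour,
so the kernel adapts to local density. The kernel is symmetrized as
`(A + A')/2` (with unit self-affinities) and row-normalized into a
Markov operator `P`. Eigendecomposition runs on the symmetric conjugate
`D^{-1/2} W D^{-1/2}`, guaranteeing real eigenvalues; right eigenvectors
of `P` are recovered as `D^{-1/2} phi`. Diffusion components (DCs) are
the non-trivial eigenvectors; DC1 of a gastric/progenitor subset is the
gastric→progenitor axis used throughout. Reproducibility conventions:
components are unit-norm with the largest-|loading| cell positive, so
signs are stable across runs and LAPACK builds (biological orientation
still needs a marker, e.g. a progenitor signature).

Assumptions worth stating: the construction assumes the latent space
distances are meaningful at the `k`-neighbour scale, and applies no
density (alpha) normalization — niches and states are compared within
one dataset, where sampling density is roughly uniform; the option is
exposed but off by default. Imputation is operator exponentiation
(`P^t X`, default `t = 3`); larger `t` shares information over larger
manifold distances. Under a `condition` vector the operator is rebuilt
per condition on the shared latent space so no signal crosses
conditions. Diffusion distance uses
`d(i,j)^2 = sum_l lambda_l^{2t} (psi_l(i) - psi_l(j))^2` with `t = 1` by
default; the diffusion time there is exposed because no canonical choice
exists.

The number of components retained by the second-eigengap rule is the
count of top eigenvalues (including the trivial one) before the
second-largest drop of the post-trivial spectrum, with ties resolved
toward the earlier drop — so when the maximal drop repeats, its second
occurrence is the second gap. This convention reproduces
`1, .9, .89, .5, .49, .1 → 5`.

## Niches and their ordering

A niche is the set of cells within `r = 60` µm (inclusive) of an anchor
cell, computed per sample — niches never span samples. 60 µm captures a
glandular lesion and its immediate stroma; the radius is a first-class
parameter because other length scales highlight other structures. The
niche axis is the mean DC of gastric/progenitor members; at least 10
such members are required before a niche is placed on the axis
(averaging fewer cells is dominated by noise), and binned niches are
discretized into 100 uniform bins over the observed range (half-open
bins, last closed).

Composition is reported as counts always, and as fractions within a
compartment only where the niche holds at least 10 cells of that
compartment; cells labeled `mixed` (segmentation cross-contamination)
count toward totals but never fractions. The compartment-specific niche
expression tensor sums member counts per compartment, normalizes by the
compartment's total counts in the niche (the niche-level size factor),
scales by the median size factor, applies `log1p`, and z-scores each
(compartment, gene) across niches. Niches lacking a compartment are
masked, never zero-filled — a zero would be a strong (and wrong)
expression statement. z-scores use the population (n) SD everywhere in
the package; genes constant across niches get z = 0 rather than
infinities.

Gene trends average the z-scored tensor per axis bin. The "sign-change"
landmark used to order genes by how early they respond is located as
the best single-step split of the trend (the split maximizing the
difference of means before/after) rather than the literal first zero
crossing: in the flat part of a response the trend wiggles around zero
and the first crossing is dominated by bin noise, while the step fit
lands on the steepest part of the response. Ties in the resulting
ordering break by gene name.

Canonical niche sets: progenitor niches are those in bins where the
median progenitor fraction exceeds the median gastric fraction; the
gastric set takes the same number of occupied bins from the low end of
the axis. The resulting percentages are always computed from the data
(roughly half the binned niches per side in the synthetic tissues),
never assumed.

## Communication modules

Niche-level aggregation overcomes per-cell sparsity before estimating
gene–gene correlation. Communication genes of one compartment are
linked when Pearson r of their z-scored niche expression strictly
exceeds `rho = 0.2` (pairs sharing fewer than 10 unmasked niches get no
edge). Jaccard refinement computes, for every node pair, the similarity
of neighbour sets in the *original* graph (endpoints excluded from both
sets); edges below 0.05 are removed and non-edges above 0.95 added,
both applied simultaneously from the original graph. The simultaneous
convention makes refinement order-independent; the sequential variant
is not exposed because its result depends on edge enumeration order.

Module detection must allow overlapping gene sets (a ligand can serve
two programs). The detector is deterministic seed expansion: maximal
cliques of at least `min_module_size = 4` seed candidates; each absorbs
the neighbouring gene that most lowers the module conductance until no
addition helps; modules must end below conductance 0.5 (denser inside
than across the boundary — a set with no boundary at all, such as an
isolated component, has conductance 0); near-duplicates (Jaccard ≥ 0.9)
merge. This replaces an external overlapping-community binary with a
specified, dependency-free contract; the detector is pluggable behind
`detect_modules()`.

Modules with mean z strictly above 0.2 in the canonical progenitor
niches are progenitor-associated. Cognate channels require the ligand
in a flagged module of one compartment and *every* receptor subunit in
a flagged module of a different compartment; channels are ranked by the
Spearman correlation of ligand and receptor (subunit-mean) bin trends,
then by module scores. A small curated mouse ligand–receptor table
ships for tests (`builtin_lr_table()`); real analyses should supply a
full database as TSV.

## Copy-number inference from transcriptomes

Chromosome-scale dosage changes shift the expression of many adjacent
genes coherently. Reference means come from library-size-normalized
(never log) counts of diploid reference cells; genes with mean below
0.1, genes in user-supplied excluded groups (coordinately regulated
clusters that mimic CNVs), and mitochondrial/ribosomal genes are
dropped. Per gene, `log2((x + 0.1)/(mu + 0.1))` is clipped to [−3, 3]
and smoothed over 100-gene windows within chromosomes. "Trimming
chromosome ends" is implemented as fully interior windows only —
partial windows average fewer genes and would inflate variance exactly
where artifacts concentrate; windows are indexed by their centre gene
(left-of-centre for even sizes). Profiles are recentred by the per-cell
median *before* chromosome summaries are computed (the
recenter-then-summarize order). Chromosome means above 0.16 are gains,
below −0.16 losses; cells with fewer than 9 events are "quiet", 9 or
more "rearranged" (the bound is exclusive on the quiet side). The
iterative reference re-runs inference after restricting the reference
to cells at or below 0.17 on a recurrent chromosome, falling back (with
a warning) when fewer than 20 cells qualify.

## Morphometry from centroids

Lesions are connected components of the 20 µm epithelial
centroid graph (a cell-diameter scale: linked cells are plausibly
touching), with ids ordered by component (min x, min y) so labels are
reproducible. The tissue raster is 5 µm/px over the centroid bounding
box; centroid counts are smoothed with an isotropic Gaussian
(sigma = 3 px = 15 µm; the image is zero-padded before filtering so
density never wraps across edges) and thresholded at 0.01 into
foreground. Closed lumens: the epithelial bitmap is dilated with a
disk structuring element of radius 10 px, holes are filled, the mask is
eroded with the same element (boundaries return to scale), and empty
pixels inside are lumen. Open lumens propagate from epithelial pixels
over background in 20 µm steps to a fixed point (capped at 100
iterations; the cap has never bound in testing — propagation stalls at
foreground). Pixel-in-radius tests use pixel centres.

One genuine limitation surfaced during validation: the smoothed-density
foreground eats a rim of roughly one kernel sigma into any hole, so
lumens comparable to the 15 µm bandwidth are systematically
under-measured. The lumen tests therefore use lumens of 100–200 µm at
realistic centroid densities, where the rim is a small fraction of the
area; per-anchor lumen counting is additionally tested against
hand-built masks, isolating the counting from the density pipeline.
Absolute areas of small lumens should be read as lower bounds; trends
along the DC remain valid because the bias is monotone in lumen size.

## Differential-abundance annotation and calibration

Neighbourhoods (imported from an external differential-abundance tool,
or from the built-in sampler that takes random index cells with their
transcriptomic nearest neighbours) are annotated by dominant state.
Pure neighbourhoods get dominance ratio infinity and are never
excluded; among mixed ones the lowest 5% by ratio are flagged, not
dropped. The spatial score pools every member's spatial niche and takes
`ln(target fraction / dataset fraction)`. Per-anchor enrichment scores
floor zero niche fractions at half the minimum observed nonzero
fraction — the log of zero is otherwise undefined; a pseudo-count
alternative is exposed through the fraction inputs. The companion gate
(target score strictly > 2, competitor score < 0) follows the strict
inequality everywhere. The condition test is an exact 2×2 test
(inside/outside × condition) with BH correction and Haldane-corrected
log2 fold-changes; under permuted labels the q < 0.1 rate stays at or
below 0.1 (checked at 200 neighbourhoods), and the enrichment score
mean under uniform labels is below 0.05 in magnitude at 5,000 anchors —
the small negative Jensen bias of the log shrinks with niche size.

In silico dissection keeps epithelial cells plus everything within
200 µm, then removes connected components of lymph-node-state cells
(30 µm linkage) with strictly more than 250 cells.

## The synthetic tissue generator

`generate_tissue()` emulates the statistical structure the analysis
assumes: glandular lesions placed on a jittered grid inside a
rectangular field (continuous µm, origin bottom-left), epithelial cells
on annuli with an empty lumen disk (stromal cells are rejected from
lumens), a latent gastric→progenitor value per lesion (default: linear
in x) jittered per cell (SD 0.05), stromal cells scattered at
4,000/mm² (with the epithelium this yields niches of ~60–100 cells at
60 µm, matching imaging-based data), lymph nodes as dense lymphoid
blobs, and negative-binomial counts (shared dispersion, default
size 2) with mean `baseline × response(driver)`. The driver is the
cell's own latent value for epithelial genes and the local mean
epithelial latent within 60 µm for niche-coupled stromal genes; coupled
state frequencies follow a logistic in that local value (slope 6), which
produces the monotone compositional shifts the niche stage must
recover. Off-compartment expression leaks at 2% of baseline, standing
in for segmentation spill-over. The default panel (~210 genes, 6
chromosomes) carries gastric/progenitor markers, early/late sigmoid
responders, housekeeping constants, three fibroblast communication
modules driven by the latent axis and by two spatial fields orthogonal
to it, a myeloid receptor module, and flat negative controls excluded
from embeddings. The CNV cohort generator multiplies expected counts on
event chromosomes by 1.5 (gain) or 0.5 (loss) over a deep
(~16 counts/gene) thousand-gene panel mirroring droplet scRNA-seq.

What the generator does *not* emulate: transcript-level point patterns,
nuclear morphology, segmentation errors beyond uniform leakage, batch
effects, spatial autocorrelation of technical noise, and realistic
gene-gene correlation within a cell beyond the planted programs.
Passing tests therefore demonstrate that the implementations recover
the structures they model, under noise levels typical of the platform —
not that every biological confounder is handled.

Reproducibility: one seeded RNG stream per generate call with a fixed
generation order guarantees byte-identical output for identical
configurations. Stability under reordering of the gene panel is *not*
guaranteed (R lacks a cheap splittable RNG, and re-seeding per cell
would be slow and statistically fragile); reorder columns after
generation if needed.

## Problem sizes and numerical tolerances

The shipped tests run the framework at sizes a laptop handles in
minutes: tissues of four to nine thousand cells, 200-cell CNV cohorts
over 1,000 genes, 1,000-cell oracle comparisons, twenty-seed recovery
loops for the coupling property. Oracle equivalences are exact or at
1e-10; operator row sums hold at 1e-10; z-slice moments at 1e-6;
eigenvector orthogonality under the stationary inner product at 1e-6.
Degenerate inputs are errors, not silent results: empty tissues,
all-identical cells, single-bin histograms, zero-size references, and
unresolvable orientations all raise with messages naming the remedy.

## Known limitations

- Lumen areas near the smoothing bandwidth are lower bounds (above).
- The niche tensor aggregates away single-cell heterogeneity within a
  compartment; concerted state shifts appear as average expression
  changes, but bimodal within-compartment changes are diluted.
- The module detector's conductance contract is one of several
  reasonable overlapping-community definitions; modules near the 0.5
  conductance boundary are sensitive to the threshold.
- The condition test treats cells as independent; for replicated
  designs, aggregate to replicate-level scores (`group_score_test()`)
  instead.
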