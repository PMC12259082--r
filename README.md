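# nichetrace

Spatial niche analysis of premalignant tissue at single-cell resolution.

Imaging-based spatial transcriptomics (Xenium-style panels of a few
hundred genes, ~50–100 counts per cell) makes it possible to ask how the
transcriptional state of premalignant epithelial cells is coupled to the
remodelling of their microenvironment. `nichetrace` implements a complete
analysis framework for this question, aimed at computational biologists
working with single-cell-resolution spatial data of early tumorigenesis
(and the dissociated scRNA-seq cohorts that accompany it):

- **Diffusion-component continua.** A kNN diffusion operator with
  adaptive Gaussian kernel (`a_ij = exp(-d_ij² / σ_i σ_j)`, σ_i the
  distance to the 10th neighbour, kernel symmetrized and row-normalized)
  yields diffusion components (DCs) that order epithelial cells along a
  gastric→progenitor axis, diffusion distances between cell sets, and
  operator-power imputation (`P^t X`, t = 3).
- **Multicellular niches.** A niche is every cell within r = 60 µm of an
  anchor cell. Niches are ordered by the mean epithelial DC of their
  gastric/progenitor members (≥ 10 required), discretized into 100
  uniform bins, and characterized by composition, by compartment-specific
  niche expression tensors `X^{c×n×m}` (per-compartment size factors,
  median scaling, log1p, z-scoring across niches), and by gene trends
  along the axis.
- **Communication modules.** Genes are linked when the Pearson
  correlation of their niche expression exceeds ρ = 0.2, the graph is
  refined by neighbour-set Jaccard similarity (drop < 0.05, add > 0.95),
  and overlapping modules are found by deterministic conductance-guided
  seed expansion. Modules with mean z > 0.2 in canonical progenitor
  niches are flagged and cognate ligand–receptor channels between
  compartments are ranked by trend coordination.
- **Copy-number inference.** Per-gene log2 ratios against a diploid
  reference (pseudocount 0.1, clipped to [−3, 3]) are smoothed over
  100-gene windows, recentred per cell, summarized per chromosome, and
  thresholded at ±0.16 into gain/loss events; cells with fewer than 9
  events are genomically "quiet", the rest "rearranged". An iterative
  within-sample reference (cut 0.17 on a recurrent chromosome) mitigates
  batch effects.
- **Morphometry from centroids.** Lesions are connected components of a
  20 µm epithelial neighbour graph; a 5 µm/px density raster (Gaussian
  σ = 3 px, threshold 0.01) plus dilation/fill/erosion and iterative
  20 µm propagation recovers closed and open lumens; features are
  summarized along the DC in 11 bins.
- **Spatially annotated differential abundance.** Transcriptomic
  neighbourhoods are labeled by dominant state (the least-pure 5%
  excluded), scored by progenitor enrichment (log-ratio of niche
  fraction to dataset fraction, with the > 2 / < 0 gate), and tested for
  condition shifts with exact 2×2 tests and BH correction. In silico
  dissection keeps the 200 µm epithelial halo and removes lymph-node
  components (> 250 cells at 30 µm linkage).
- **Synthetic tissue with ground truth.** `generate_tissue()` emits
  glandular lesions with lumens on a latent gastric→progenitor gradient,
  niche-coupled stromal/myeloid states, lymph-node blobs,
  negative-binomial counts over a configurable panel, and the full
  ground truth; `generate_cnv_cohort()` plants chromosome-scale gains
  and losses. Every stage of the package is tested against this
  generator or against brute-force oracles.

## Worked example

```r
library(nichetrace)

sim <- generate_tissue(sim_config(seed = 1))
cells <- sim$cells[filter_cells(sim$counts, sim$genes), ]
counts <- sim$counts[cells$cell_id, ]

# epithelial diffusion component
epi <- cells$compartment == "epithelial"
norm <- normalize_counts(counts[epi, ], sim$genes)$normalized
pc <- prcomp(as.matrix(norm), rank. = 10)$x
dm <- build_diffusion_operator(pc, k = 30, bandwidth_neighbor = 10)
dc1 <- diffusion_components(dm, 1)[, 1]
cor(dc1, sim$truth$latent_dc[match(cells$cell_id[epi], sim$truth$cell_id)],
    method = "spearman")
#> [1] -0.938

# niches ordered along the axis, composition shift in the top decile
idx <- build_niche_index(cells, radius = 60)
dc <- rep(NA_real_, nrow(cells)); dc[which(epi)] <- dc1
bin <- order_niches(idx, dc,
                    cells$state %in% c("gastric-like", "progenitor-like"))
st <- niche_composition(idx, cells, level = "state")
```

The Spearman correlation of −0.94 (sign is arbitrary) says DC1 recovers
the planted gastric→progenitor axis almost perfectly; downstream,
`order_niches()` positions ~2,400 niches along that axis and the
`Itgax_mac` fraction among myeloid cells rises by ~0.81 from the bottom
to the top niche-DC decile — the planted microenvironment coupling.

See `vignettes/niche-analysis.Rmd` for the model, parameter and design
discussion.

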