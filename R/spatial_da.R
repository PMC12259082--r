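#' Per-anchor enrichment score for a target state
#'
#' For each niche: the fraction of target-state cells among
#' reference-compartment cells in the niche, log-ratioed against the
#' dataset-wide fraction. Niches with no reference-compartment member are
#' masked. Zero niche fractions are floored at half the minimum observed
#' nonzero niche fraction before the ratio, so the log is defined.
#'
#' @param index a `niche_index`.
#' @param is_target logical per cell: the state being scored (e.g.
#'   progenitor-like).
#' @param is_reference logical per cell: the compartment the fraction is
#'   taken within (e.g. epithelial). `is_target` must imply
#'   `is_reference`.
#' @return numeric per-anchor score (`NA` where masked), with attribute
#'   `dataset_fraction`.
#' @export
enrichment_score <- function(index, is_target, is_reference) {
  if (!any(is_target)) stop("target state absent from dataset")
  stopifnot(all(is_reference[is_target]))
  dataset_frac <- sum(is_target) / sum(is_reference)
  frac <- vapply(index$members, function(m) {
    nref <- sum(is_reference[m])
    if (nref == 0) NA_real_ else sum(is_target[m]) / nref
  }, numeric(1))
  nz <- frac[!is.na(frac) & frac > 0]
  floor_val <- if (length(nz)) min(nz) / 2 else NA_real_
  frac[!is.na(frac) & frac == 0] <- floor_val
  score <- log(frac / dataset_frac)
  attr(score, "dataset_fraction") <- dataset_frac
  score
}

#' Select anchors enriched for one state and depleted for another
#'
#' Gate used to nominate microenvironment cells tightly associated with a
#' state: strictly `target_score > target_cut` and
#' `other_score < other_cut`.
#'
#' @param target_score,other_score per-anchor scores from
#'   [enrichment_score()].
#' @param target_cut,other_cut thresholds (defaults 2 and 0).
#' @return logical per anchor (`FALSE` where either score is masked).
#' @export
select_enriched_anchors <- function(target_score, other_score,
                                    target_cut = 2, other_cut = 0) {
  out <- target_score > target_cut & other_score < other_cut
  out[is.na(out)] <- FALSE
  out
}

#' Built-in transcriptomic neighborhood sampler
#'
#' Plumbing that mimics differential-abundance neighbourhoods: index
#' cells are sampled at proportion `prop` and each neighbourhood is the
#' index cell plus its `k - 1` nearest transcriptomic neighbours.
#' External memberships (e.g. from a differential-abundance GLM run
#' elsewhere) can be imported with [read_neighborhood_tsv()] instead.
#'
#' @param latent cells x dims matrix (e.g. PC scores).
#' @param prop proportion of cells used as index cells (default 0.05).
#' @param k neighbourhood size (default 20).
#' @param seed RNG seed.
#' @return named list of integer cell-index vectors.
#' @export
sample_neighborhoods <- function(latent, prop = 0.05, k = 20, seed = 1) {
  latent <- as.matrix(latent)
  n <- nrow(latent)
  n_idx <- max(1L, round(prop * n))
  with_seed(seed, {
    idx <- sample.int(n, n_idx)
  })
  nn <- RANN::nn2(latent, latent[idx, , drop = FALSE], k = min(k, n))
  out <- lapply(seq_along(idx), function(i) as.integer(nn$nn.idx[i, ]))
  names(out) <- paste0("nbhd", seq_along(idx))
  out
}

#' Annotate neighborhoods by dominant state with spatial enrichment
#'
#' Labels each neighbourhood by its most frequent cell state. Pure
#' neighbourhoods (a single state) get dominance ratio `Inf` and are
#' never excluded; among mixed neighbourhoods the lowest
#' `purity_exclusion_quantile` by dominance ratio (most-frequent over
#' second-most-frequent state count) are flagged excluded, not dropped.
#' The spatial score is the log-ratio of the target-state fraction among
#' the union of the members' niche cells to the dataset fraction.
#'
#' @param neighborhoods named list of integer cell-index vectors.
#' @param states per-cell state labels.
#' @param index a `niche_index` whose anchors cover all cells (anchor i =
#'   cell i), used to pool each member's spatial niche.
#' @param is_target logical per cell for the spatial score's target state.
#' @param purity_exclusion_quantile fraction of mixed neighbourhoods to
#'   exclude (default 0.05).
#' @return data.frame with one row per neighbourhood: `label`,
#'   `dominance`, `excluded`, `spatial_score`, `n_cells`.
#' @export
annotate_neighborhoods <- function(neighborhoods, states, index = NULL,
                                   is_target = NULL,
                                   purity_exclusion_quantile = 0.05) {
  if (any(lengths(neighborhoods) == 0)) stop("empty neighborhood")
  ann <- lapply(neighborhoods, function(m) {
    tab <- sort(table(states[m]), decreasing = TRUE)
    dom <- if (length(tab) == 1) Inf else
      as.numeric(tab[1]) / as.numeric(tab[2])
    list(label = names(tab)[1], dominance = dom, n = length(m))
  })
  dominance <- vapply(ann, `[[`, numeric(1), "dominance")
  label <- vapply(ann, `[[`, character(1), "label")
  n_cells <- vapply(ann, `[[`, numeric(1), "n")
  excluded <- rep(FALSE, length(ann))
  mixed <- is.finite(dominance)
  if (any(mixed)) {
    cut <- stats::quantile(dominance[mixed], purity_exclusion_quantile,
                           names = FALSE)
    excluded <- mixed & dominance <= cut
  }
  spatial_score <- rep(NA_real_, length(ann))
  if (!is.null(index) && !is.null(is_target)) {
    dataset_frac <- mean(is_target)
    pool_of <- vector("list", length(index$cell_id))
    pool_of[index$anchors] <- index$members
    spatial_score <- vapply(neighborhoods, function(m) {
      pool <- unique(unlist(pool_of[m], use.names = FALSE))
      if (!length(pool)) return(NA_real_)
      frac <- mean(is_target[pool])
      log(frac / dataset_frac)
    }, numeric(1))
  }
  data.frame(neighborhood = names(neighborhoods) %||%
               seq_along(neighborhoods),
             label = label, dominance = dominance, excluded = excluded,
             spatial_score = spatial_score, n_cells = n_cells,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Condition-abundance test per neighborhood
#'
#' Two-sided Fisher exact test on the 2x2 table (inside vs outside the
#' neighbourhood x condition), Benjamini-Hochberg corrected across
#' neighbourhoods. The log2 fold-change compares the first condition's
#' proportion inside vs outside with Haldane (0.5) correction.
#'
#' @param neighborhoods named list of integer cell-index vectors.
#' @param condition per-cell condition labels; exactly two levels.
#' @return data.frame with `neighborhood`, `lfc`, `p`, `q`.
#' @export
neighborhood_condition_test <- function(neighborhoods, condition) {
  lev <- sort(unique(as.character(condition)))
  if (length(lev) < 2) stop("need at least 2 conditions")
  if (length(lev) > 2)
    stop("exactly two conditions supported; got ",
         paste(lev, collapse = ", "))
  is_a <- condition == lev[1]
  n <- length(condition)
  res <- t(vapply(neighborhoods, function(m) {
    inside <- rep(FALSE, n); inside[m] <- TRUE
    a <- sum(inside & is_a); b <- sum(inside & !is_a)
    c_ <- sum(!inside & is_a); d <- sum(!inside & !is_a)
    p <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))$p.value
    p_in <- (a + 0.5) / (a + b + 1)
    p_out <- (c_ + 0.5) / (c_ + d + 1)
    c(lfc = log2(p_in / p_out), p = p)
  }, numeric(2)))
  data.frame(neighborhood = names(neighborhoods) %||%
               seq_along(neighborhoods),
             lfc = res[, "lfc"], p = res[, "p"],
             q = stats::p.adjust(res[, "p"], "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Conditional density of one state fraction given another
#'
#' Both fraction vectors are log10-transformed with the minimum nonzero
#' value of each vector as its pseudocount, histogrammed jointly, and
#' each x-column normalized to sum one (empty columns stay `NA`) — a
#' visualization of how a microenvironment state's frequency responds to
#' the local density of a driver state, agnostic to the driver's marginal
#' distribution.
#'
#' @param x_fractions,y_fractions paired per-niche fractions.
#' @param n_bins_x,n_bins_y histogram resolution (defaults 20).
#' @return list with `density` (y-bins x x-bins column-normalized
#'   matrix), `x_edges`, `y_edges`, `pseudocounts`.
#' @export
conditional_density <- function(x_fractions, y_fractions, n_bins_x = 20,
                                n_bins_y = 20) {
  keep <- !is.na(x_fractions) & !is.na(y_fractions)
  x <- x_fractions[keep]; y <- y_fractions[keep]
  if (all(x == 0) || all(y == 0))
    stop("all-zero fraction vector: pseudocount undefined")
  px <- min(x[x > 0]); py <- min(y[y > 0])
  lx <- log10(x + px); ly <- log10(y + py)
  xe <- seq(min(lx), max(lx), length.out = n_bins_x + 1)
  ye <- seq(min(ly), max(ly), length.out = n_bins_y + 1)
  bx <- findInterval(lx, xe, rightmost.closed = TRUE)
  by <- findInterval(ly, ye, rightmost.closed = TRUE)
  dens <- matrix(0, n_bins_y, n_bins_x)
  for (i in seq_along(bx)) dens[by[i], bx[i]] <- dens[by[i], bx[i]] + 1
  csum <- colSums(dens)
  for (j in seq_len(n_bins_x)) {
    dens[, j] <- if (csum[j] > 0) dens[, j] / csum[j] else NA_real_
  }
  list(density = dens, x_edges = xe, y_edges = ye,
       pseudocounts = c(x = px, y = py))
}

#' Replicate-level niche signature scores with rank-sum test
#'
#' Per compartment: the score of a (group, replicate) is the mean
#' z-scored niche expression of the gene set over that replicate's niches
#' in the group; group differences are tested with a two-sided Wilcoxon
#' rank-sum test (exact for small n). Replicates with no niches in a
#' group are dropped with a warning.
#'
#' @param tensor a `niche_tensor`.
#' @param gene_set character vector of gene symbols.
#' @param niche_sets named list of two integer niche-index vectors (e.g.
#'   gastric and progenitor canonical sets).
#' @param replicate per-niche replicate labels (parallel to the tensor's
#'   niche rows).
#' @return list per compartment with `scores` (data.frame group,
#'   replicate, score) and `p`.
#' @export
group_score_test <- function(tensor, gene_set, niche_sets, replicate) {
  stopifnot(length(niche_sets) == 2, !is.null(names(niche_sets)))
  lapply(unclass(tensor), function(slice) {
    genes <- intersect(gene_set, colnames(slice$z))
    if (!length(genes)) stop("no gene-set genes in tensor")
    rows <- list()
    for (g in names(niche_sets)) {
      for (r in unique(replicate[niche_sets[[g]]])) {
        sel <- intersect(niche_sets[[g]], which(replicate == r))
        sel <- sel[slice$mask[sel]]
        if (!length(sel)) {
          warning("replicate ", r, " has no niches in group ", g,
                  "; dropped")
          next
        }
        rows[[length(rows) + 1]] <- data.frame(
          group = g, replicate = r,
          score = mean(slice$z[sel, genes, drop = FALSE], na.rm = TRUE),
          stringsAsFactors = FALSE)
      }
    }
    scores <- do.call(rbind, rows)
    gs <- split(scores$score, scores$group)
    p <- if (length(gs) == 2)
      stats::wilcox.test(gs[[1]], gs[[2]], exact = TRUE)$p.value
    else NA_real_
    list(scores = scores, p = p)
  })
}

#' In silico dissection of the parenchyma
#'
#' Keeps epithelial cells plus any cell within `epithelial_radius` of an
#' epithelial cell, then removes lymph nodes: connected components of
#' lymph-node-state cells linked at `ln_link` micrometres with more than
#' `ln_min_cells` members. All distances are within-sample.
#'
#' @param cells cell table.
#' @param epithelial_radius parenchyma inclusion radius, um (default 200).
#' @param ln_link lymph-node graph link distance, um (default 30).
#' @param ln_min_cells strict lower bound: components with more cells are
#'   removed (default 250).
#' @param ln_states states marking lymph-node-associated cells.
#' @return logical inclusion mask with attribute `retained_fraction` and
#'   `lymph_node_component` (integer id per cell, `NA` outside removed
#'   nodes).
#' @export
dissect_parenchyma <- function(cells, epithelial_radius = 200, ln_link = 30,
                               ln_min_cells = 250,
                               ln_states = c("B_cell", "CD4T", "CD8T")) {
  assert_cells(cells)
  epi <- cells$compartment == "epithelial"
  if (!any(epi)) stop("no epithelial cells")
  n <- nrow(cells)
  include <- logical(n)
  ln_comp <- rep(NA_integer_, n)
  for (s in unique(cells$sample)) {
    in_s <- which(cells$sample == s)
    epi_s <- in_s[epi[in_s]]
    if (length(epi_s)) {
      nn <- RANN::nn2(cbind(cells$x[epi_s], cells$y[epi_s]),
                      cbind(cells$x[in_s], cells$y[in_s]), k = 1)
      include[in_s] <- nn$nn.dists[, 1] <= epithelial_radius
    }
    ln_s <- in_s[cells$state[in_s] %in% ln_states]
    if (length(ln_s) > 1) {
      nb <- radius_neighbors(cbind(cells$x[ln_s], cells$y[ln_s]),
                             cbind(cells$x[ln_s], cells$y[ln_s]), ln_link)
      edges <- do.call(rbind, lapply(seq_along(ln_s), function(i)
        cbind(i, nb[[i]])))
      g <- igraph::graph_from_edgelist(edges[edges[, 1] < edges[, 2], ,
                                             drop = FALSE],
                                       directed = FALSE)
      g <- igraph::add_vertices(
        g, max(0, length(ln_s) - igraph::vcount(g)))
      comp <- igraph::components(g)
      big <- which(comp$csize > ln_min_cells)
      in_big <- comp$membership %in% big
      ln_comp[ln_s[in_big]] <- comp$membership[in_big]
      include[ln_s[in_big]] <- FALSE
    }
  }
  attr(include, "retained_fraction") <- mean(include)
  attr(include, "lymph_node_component") <- ln_comp
  include
}
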