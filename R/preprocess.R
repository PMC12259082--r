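#' Filter cells by total mRNA count
#'
#' Cells with fewer than `min_counts` total counts are dropped, matching
#' common practice for sparse imaging-based panels. Genes flagged
#' `excluded_from_embedding` in the annotation (negative controls and the
#' like) do not contribute to the totals.
#'
#' @param counts sparse cells x genes count matrix.
#' @param genes gene annotation aligned with `colnames(counts)`; only the
#'   optional `excluded_from_embedding` column is consulted.
#' @param min_counts minimum total counts per retained cell (default 25).
#' @return logical mask over cells (TRUE = keep), with attribute
#'   `fraction_removed`.
#' @export
filter_cells <- function(counts, genes = NULL, min_counts = 25) {
  stopifnot(min_counts >= 0)
  use <- rep(TRUE, ncol(counts))
  if (!is.null(genes) && "excluded_from_embedding" %in% names(genes))
    use <- !genes$excluded_from_embedding
  totals <- Matrix::rowSums(counts[, use, drop = FALSE])
  mask <- totals >= min_counts
  if (!any(mask)) stop("no cells pass filter")
  attr(mask, "fraction_removed") <- mean(!mask)
  mask
}

#' Median-of-size-factors normalization
#'
#' Size factors are per-cell totals over non-excluded genes; values become
#' `count / size_factor x median(size_factor)`. Linear (untransformed)
#' output is the default for sparse spatial panels; `log_transform = TRUE`
#' applies `log(value + pseudocount)`. Excluded genes stay in the matrix
#' but never contribute to size factors.
#'
#' @inheritParams filter_cells
#' @param log_transform apply a log transform after scaling.
#' @param pseudocount pseudocount for the log transform (default 1).
#' @return list with `normalized` (dgCMatrix, same shape as input) and
#'   `size_factors`.
#' @export
normalize_counts <- function(counts, genes = NULL, log_transform = FALSE,
                             pseudocount = 1) {
  use <- rep(TRUE, ncol(counts))
  if (!is.null(genes) && "excluded_from_embedding" %in% names(genes))
    use <- !genes$excluded_from_embedding
  sf <- Matrix::rowSums(counts[, use, drop = FALSE])
  if (any(sf <= 0))
    stop("cells with zero size factor present; filter cells first")
  scale <- stats::median(sf) / sf
  normalized <- Matrix::Diagonal(x = scale) %*% counts
  normalized <- methods::as(normalized, "CsparseMatrix")
  dimnames(normalized) <- dimnames(counts)
  if (log_transform) {
    normalized@x <- log(normalized@x + pseudocount) - log(pseudocount)
    # with the conventional pseudocount the zero pattern is preserved:
    # log((0 + p)/p) = 0; for other pseudocounts densify explicitly
    if (pseudocount != 1) {
      normalized <- Matrix::Matrix(
        log(as.matrix(Matrix::Diagonal(x = scale) %*% counts) + pseudocount),
        sparse = FALSE)
      dimnames(normalized) <- dimnames(counts)
    }
  }
  list(normalized = normalized, size_factors = sf)
}

#' Per-subpopulation gene detection rates
#'
#' Fraction of cells in each subpopulation with at least one count of each
#' gene — the statistic the compartment-aware censoring step thresholds.
#'
#' @param counts sparse cells x genes count matrix.
#' @param subpop character/factor of subpopulation labels per cell.
#' @return matrix subpopulations x genes with entries in `[0, 1]`.
#' @export
detection_rate <- function(counts, subpop) {
  stopifnot(length(subpop) == nrow(counts))
  pos <- counts
  pos@x <- rep(1, length(pos@x))
  groups <- sort(unique(as.character(subpop)))
  out <- t(vapply(groups, function(g)
    Matrix::colMeans(pos[subpop == g, , drop = FALSE]),
    numeric(ncol(counts))))
  rownames(out) <- groups
  colnames(out) <- colnames(counts)
  out
}

#' Triangle (Zack) threshold of a histogram
#'
#' Draws the line from the histogram peak to the farthest nonzero tail bin
#' and returns the bin-edge value at maximal perpendicular distance from
#' the histogram curve to that line. Ties break toward the smaller
#' threshold; for a symmetric histogram the longer-tail side is used (with
#' the lower side preferred on exact ties).
#'
#' @param counts bin counts.
#' @param edges bin edges, `length(counts) + 1`.
#' @return threshold value (a bin edge), with attribute `bin` (the chosen
#'   bin index).
#' @export
triangle_threshold <- function(counts, edges) {
  stopifnot(length(edges) == length(counts) + 1, length(counts) >= 3)
  nz <- which(counts > 0)
  if (length(nz) == 0) stop("histogram has no occupied bin")
  if (length(nz) == 1) stop("degenerate histogram")
  peak <- which.max(counts)
  # farthest occupied bin from the peak; tie -> lower side (smaller threshold)
  cand <- nz[nz != peak]
  dist_bins <- abs(cand - peak)
  far <- cand[dist_bins == max(dist_bins)]
  tail_bin <- min(far)
  lo <- min(peak, tail_bin); hi <- max(peak, tail_bin)
  idx <- lo:hi
  x1 <- peak; y1 <- counts[peak]
  x2 <- tail_bin; y2 <- counts[tail_bin]
  # perpendicular distance from (i, counts[i]) to the peak->tail line
  num <- abs((y2 - y1) * idx - (x2 - x1) * counts[idx] + x2 * y1 - y2 * x1)
  den <- sqrt((y2 - y1)^2 + (x2 - x1)^2)
  d <- num / den
  best <- idx[which.max(d)]  # which.max takes the first (smaller) on ties
  thr <- edges[best + 1]     # upper edge of the elbow bin
  attr(thr, "bin") <- best
  thr
}

#' Compartment-aware gene censoring
#'
#' A gene is kept for a compartment iff (a) it is detected in at least
#' `min_ref` of cells in at least one dissociated reference dataset, and
#' (b) its maximum subpopulation-level detection rate in the spatial data
#' reaches the triangle threshold computed on the flattened histogram of
#' spatial detection rates (`n_bins` bins). Both rules guard against
#' segmentation spill-over masquerading as expression.
#'
#' @param ref_detection list of reference detection-rate matrices
#'   (subpopulations x genes), all sharing the spatial gene set.
#' @param spatial_detection detection-rate matrix for the spatial data.
#' @param min_ref minimum reference detection fraction (default 0.01).
#' @param n_bins histogram bins for the triangle rule (default 25).
#' @return list with `pass` (logical per gene, named), `threshold` and
#'   `ref_pass`/`spatial_pass` component masks.
#' @export
censor_genes <- function(ref_detection, spatial_detection, min_ref = 0.01,
                         n_bins = 25) {
  genes <- colnames(spatial_detection)
  for (m in ref_detection)
    stopifnot(identical(colnames(m), genes))
  ref_pass <- Reduce(`|`, lapply(ref_detection, function(m)
    apply(m, 2, max) >= min_ref))
  edges <- seq(0, 1, length.out = n_bins + 1)
  h <- graphics::hist(as.vector(spatial_detection), breaks = edges,
                      plot = FALSE)
  thr <- tryCatch(as.numeric(triangle_threshold(h$counts, edges)),
                  error = function(e) {
                    warning("triangle threshold undefined; ",
                            "falling back to min_ref")
                    min_ref
                  })
  spatial_pass <- apply(spatial_detection, 2, max) >= thr
  pass <- ref_pass & spatial_pass
  names(pass) <- genes
  list(pass = pass, threshold = thr, ref_pass = ref_pass,
       spatial_pass = spatial_pass)
}

#' Signature scoring by averaged z-scores
#'
#' Each signature gene is z-scored across the reference cells (all cells
#' by default; population SD) and the per-cell score is the mean over the
#' gene set. Zero-variance genes in the reference are dropped with a
#' warning.
#'
#' @param normalized cells x genes matrix (dense or sparse), typically
#'   normalized expression.
#' @param gene_set character vector of gene symbols.
#' @param reference_cells optional logical mask of cells defining the
#'   z-scoring mean/SD (e.g. a control condition).
#' @return numeric per-cell score.
#' @export
score_signature <- function(normalized, gene_set, reference_cells = NULL) {
  found <- intersect(gene_set, colnames(normalized))
  if (!length(found)) {
    stop("no signature genes found in matrix; missing: ",
         paste(gene_set, collapse = ", "))
  }
  x <- as.matrix(normalized[, found, drop = FALSE])
  ref <- if (is.null(reference_cells)) rep(TRUE, nrow(x)) else reference_cells
  mu <- colMeans(x[ref, , drop = FALSE])
  n_ref <- sum(ref)
  sd_pop <- sqrt(colMeans(x[ref, , drop = FALSE]^2) - mu^2)
  keep <- sd_pop > 0
  if (!all(keep)) {
    warning("dropping zero-variance signature genes: ",
            paste(found[!keep], collapse = ", "))
    if (!any(keep)) stop("all signature genes have zero variance")
  }
  z <- sweep(sweep(x[, keep, drop = FALSE], 2, mu[keep]), 2, sd_pop[keep], "/")
  rowMeans(z)
}

#' Normalize signature scores for pseudocoloring
#'
#' Column-wise: subtract the minimum, divide by the given saturation
#' quantile of the shifted scores, clip to `[0, 1]`.
#'
#' @param S cells x signatures score matrix.
#' @param quantile saturation quantile in `(0, 1]` (0.95 for
#'   dissociated-style figures, 0.90 for spatial panels).
#' @return normalized matrix with entries in `[0, 1]`.
#' @export
normalize_signature_scores <- function(S, quantile = 0.95) {
  if (quantile <= 0 || quantile > 1) stop("quantile must be in (0, 1]")
  S <- as.matrix(S)
  apply(S, 2, function(col) {
    col <- col - min(col)
    q <- stats::quantile(col, quantile, names = FALSE)
    if (q <= 0) q <- 1
    pmin(pmax(col / q, 0), 1)
  })
}

#' Pseudocolor cells by multiple signatures
#'
#' RGB per cell is `clip(S %*% W, 0, 1)` where each signature carries an
#' RGB row in `W`. Scores are expected pre-normalized to `[0, 1]` (see
#' [normalize_signature_scores()]).
#'
#' @param S cells x signatures matrix of normalized scores.
#' @param W signatures x 3 RGB matrix, entries in `[0, 1]`.
#' @return cells x 3 RGB matrix, entries in `[0, 1]`.
#' @export
pseudocolor <- function(S, W) {
  S <- as.matrix(S); W <- as.matrix(W)
  stopifnot(ncol(S) == nrow(W), ncol(W) == 3)
  if (any(W < 0 | W > 1)) stop("W rows must be RGB in [0,1]")
  rgb <- S %*% W
  rgb[rgb > 1] <- 1
  rgb[rgb < 0] <- 0
  colnames(rgb) <- c("r", "g", "b")
  rgb
}
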