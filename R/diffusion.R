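#' Build an adaptive-bandwidth diffusion operator
#'
#' Constructs a kNN graph (Euclidean distance in the supplied latent
#' space), an adaptive Gaussian affinity
#' `a_ij = exp(-d_ij^2 / (sigma_i sigma_j))` with `sigma_i` the distance
#' from cell `i` to its `bandwidth_neighbor`-th nearest neighbour,
#' symmetrizes the kernel as `(A + t(A)) / 2` and row-normalizes it into a
#' Markov operator. Eigendecomposition is done on the symmetric conjugate
#' `D^{-1/2} W D^{-1/2}` so eigenvalues are real; right eigenvectors of
#' the operator are recovered as `D^{-1/2} phi`.
#'
#' @param latent cells x dims numeric matrix (e.g. PC scores).
#' @param k number of nearest neighbours (default 30).
#' @param bandwidth_neighbor neighbour index defining the adaptive kernel
#'   width (default 10).
#' @param n_eigs number of eigenpairs to retain (including the trivial
#'   leading one); defaults to `min(n, 50)`.
#' @return object of class `diffusion_model`: list with `operator`
#'   (row-stochastic dgCMatrix), `eigenvalues` (descending, leading = 1),
#'   `eigenvectors` (n x n_eigs right eigenvectors, first column
#'   constant), `bandwidths`, `stationary` (degree-proportional stationary
#'   distribution) and `k`.
#' @export
build_diffusion_operator <- function(latent, k = 30, bandwidth_neighbor = 10,
                                     n_eigs = NULL) {
  latent <- as.matrix(latent)
  n <- nrow(latent)
  stopifnot(n > k, k > bandwidth_neighbor, bandwidth_neighbor >= 1)
  n_eigs <- n_eigs %||% min(n, 50L)
  nn <- RANN::nn2(latent, latent, k = k + 1)
  idx <- nn$nn.idx[, -1, drop = FALSE]
  dst <- nn$nn.dists[, -1, drop = FALSE]
  sigma <- dst[, bandwidth_neighbor]
  if (any(sigma <= 0)) {
    if (!any(sigma > 0)) stop("all cells identical; no nontrivial geometry")
    warning("duplicate points give zero bandwidth; ",
            "substituting smallest positive bandwidth")
    sigma[sigma <= 0] <- min(sigma[sigma > 0])
  }
  i <- rep(seq_len(n), k)
  j <- as.vector(idx)
  a <- exp(-as.vector(dst)^2 / (sigma[i] * sigma[j]))
  A <- Matrix::sparseMatrix(i = i, j = j, x = a, dims = c(n, n))
  W <- (A + Matrix::t(A)) / 2
  Matrix::diag(W) <- 1  # self-affinity exp(0)
  model <- diffusion_from_affinity(W, n_eigs = n_eigs)
  model$bandwidths <- sigma
  model$k <- k
  model
}

#' Diffusion model from a symmetric affinity matrix
#'
#' Row-normalizes a (symmetrized) affinity kernel into a Markov operator
#' and eigendecomposes it through its symmetric conjugate. Used internally
#' by [build_diffusion_operator()]; exposed so operators can be built from
#' arbitrary kernels.
#'
#' @param W symmetric non-negative affinity matrix (self-affinities on the
#'   diagonal); asymmetric input is symmetrized as `(W + t(W)) / 2`.
#' @param n_eigs eigenpairs to retain (default all, capped at 50).
#' @return a `diffusion_model` (see [build_diffusion_operator()]).
#' @export
diffusion_from_affinity <- function(W, n_eigs = NULL) {
  W <- (W + Matrix::t(W)) / 2
  n <- nrow(W)
  n_eigs <- n_eigs %||% min(n, 50L)
  deg <- Matrix::rowSums(W)
  if (any(deg <= 0)) stop("affinity matrix has an all-zero row")
  P <- Matrix::Diagonal(x = 1 / deg) %*% W
  # symmetric conjugate S = D^-1/2 W D^-1/2 shares eigenvalues with P
  dh <- 1 / sqrt(deg)
  S <- Matrix::Diagonal(x = dh) %*% W %*% Matrix::Diagonal(x = dh)
  eig <- eigen(as.matrix(Matrix::forceSymmetric(S)), symmetric = TRUE)
  keep <- seq_len(min(n_eigs, n))
  vals <- eig$values[keep]
  vecs <- dh * eig$vectors[, keep, drop = FALSE]  # right eigenvectors of P
  structure(list(operator = methods::as(P, "CsparseMatrix"),
                 eigenvalues = vals, eigenvectors = vecs,
                 bandwidths = NULL, stationary = deg / sum(deg), k = NA),
            class = "diffusion_model")
}

#' Extract diffusion components
#'
#' Columns are the right eigenvectors 2..`n_comps + 1` of the diffusion
#' operator (the trivial constant component is dropped), scaled to unit
#' norm, sign fixed so the cell with the largest absolute loading is
#' positive.
#'
#' @param model a `diffusion_model`.
#' @param n_comps number of nontrivial components.
#' @return cells x `n_comps` matrix, columns named `DC1..`.
#' @export
diffusion_components <- function(model, n_comps) {
  avail <- ncol(model$eigenvectors) - 1L
  if (n_comps > avail)
    stop("requested ", n_comps, " components but only ", avail, " available")
  # degenerate geometry: all nontrivial eigenvalues numerically 1 means
  # disconnected identical points; guard the truly-degenerate case
  if (avail < 1L) stop("no nontrivial components")
  v <- model$eigenvectors[, 1 + seq_len(n_comps), drop = FALSE]
  v <- apply(v, 2, function(col) {
    col <- col / sqrt(sum(col^2))
    if (col[which.max(abs(col))] < 0) -col else col
  })
  colnames(v) <- paste0("DC", seq_len(n_comps))
  v
}

#' Choose the number of components by the second eigengap
#'
#' Gaps are the drops between consecutive eigenvalues after the trivial
#' leading eigenvalue. The returned value is the number of top
#' eigenvalues (including the trivial one) retained before the
#' second-largest drop; ties between equal drops break toward the earlier
#' one, so the second occurrence of a tied maximal drop counts as the
#' second gap.
#'
#' @param eigenvalues descending eigenvalue sequence starting at 1.
#' @return integer number of eigenvectors to retain.
#' @export
select_components_by_eigengap <- function(eigenvalues) {
  if (length(eigenvalues) < 4) stop("need at least 4 eigenvalues")
  lam <- eigenvalues[-1]  # drop trivial
  gaps <- -diff(lam)     # gaps[i]: drop after eigenvalue i + 1
  ord <- order(-gaps, seq_along(gaps), method = "radix")
  as.integer(ord[2] + 1L)
}

#' Diffusion distance between cell sets
#'
#' `d(i, j)^2 = sum_l lambda_l^(2t) (psi_l(i) - psi_l(j))^2` over the
#' nontrivial eigenpairs `l = 2..n_eigs + 1`. Returns, for every query
#' cell, the minimum distance to the target set.
#'
#' @param model a `diffusion_model`.
#' @param query_cells,target_cells integer or logical indices.
#' @param n_eigs number of nontrivial eigenvectors to use.
#' @param t diffusion time (default 1).
#' @return numeric vector, one minimum distance per query cell.
#' @export
diffusion_distance <- function(model, query_cells, target_cells, n_eigs,
                               t = 1) {
  if (is.logical(query_cells)) query_cells <- which(query_cells)
  if (is.logical(target_cells)) target_cells <- which(target_cells)
  if (!length(target_cells)) stop("empty target set")
  stopifnot(n_eigs + 1 <= ncol(model$eigenvectors))
  lam <- model$eigenvalues[1 + seq_len(n_eigs)]
  psi <- model$eigenvectors[, 1 + seq_len(n_eigs), drop = FALSE]
  w <- lam^(2 * t)
  q <- psi[query_cells, , drop = FALSE]
  g <- psi[target_cells, , drop = FALSE]
  # squared weighted distances query x target
  qn <- as.vector((q^2) %*% w)
  gn <- as.vector((g^2) %*% w)
  cross <- (q * rep(w, each = nrow(q))) %*% t(g)
  d2 <- outer(qn, gn, "+") - 2 * cross
  d2[d2 < 0] <- 0
  sqrt(apply(d2, 1, min))
}

#' Diffusion-operator imputation
#'
#' Smooths a count matrix by `t` steps of the Markov operator
#' (`imputed = P^t counts`), sharing signal along the phenotypic manifold.
#' With a `condition` vector, the operator is rebuilt per condition on the
#' shared latent space so information never crosses conditions.
#'
#' @param model a `diffusion_model` (ignored when `condition` given).
#' @param counts cells x genes matrix.
#' @param t non-negative integer diffusion time (default 3).
#' @param condition optional per-cell labels; requires `latent`.
#' @param latent latent space used to rebuild per-condition operators.
#' @param ... passed to [build_diffusion_operator()] for rebuilds.
#' @return imputed dense matrix, same dimensions as `counts`.
#' @export
impute_counts <- function(model, counts, t = 3, condition = NULL,
                          latent = NULL, ...) {
  if (t < 0) stop("t must be >= 0")
  if (!is.null(condition)) {
    stopifnot(!is.null(latent), length(condition) == nrow(counts))
    out <- as.matrix(counts)
    for (cond in unique(condition)) {
      m <- condition == cond
      sub <- build_diffusion_operator(latent[m, , drop = FALSE], ...)
      out[m, ] <- impute_counts(sub, counts[m, , drop = FALSE], t = t)
    }
    return(out)
  }
  x <- as.matrix(counts)
  if (t == 0) return(x)
  P <- model$operator
  for (i in seq_len(t)) x <- as.matrix(P %*% x)
  dimnames(x) <- dimnames(counts)
  x
}

#' Discretize a diffusion component into two states
#'
#' Histograms the component values, finds the density valley with the
#' triangle rule and labels cells above the threshold positive. The
#' positive side is oriented by `orient_scores` (the side holding the
#' maximum-score cell) or by an explicit `positive_side`.
#'
#' @param dc_values numeric per-cell component values.
#' @param n_bins histogram bins for the density (default 50).
#' @param orient_scores optional per-cell score (e.g. a progenitor
#'   signature) whose maximum marks the positive side.
#' @param positive_side `"high"` or `"low"`; overrides `orient_scores`.
#' @return list with `labels` (logical, TRUE = positive side) and
#'   `threshold`.
#' @export
discretize_component <- function(dc_values, n_bins = 50,
                                 orient_scores = NULL,
                                 positive_side = NULL) {
  if (length(unique(dc_values)) < 2) stop("need >= 2 distinct values")
  edges <- seq(min(dc_values), max(dc_values), length.out = n_bins + 1)
  h <- graphics::hist(dc_values, breaks = edges, plot = FALSE)
  thr <- as.numeric(triangle_threshold(h$counts, edges))
  if (is.null(positive_side)) {
    if (is.null(orient_scores))
      stop("orientation unresolvable: supply orient_scores or positive_side")
    positive_side <- if (dc_values[which.max(orient_scores)] > thr)
      "high" else "low"
  }
  labels <- if (positive_side == "high") dc_values > thr else dc_values <= thr
  list(labels = labels, threshold = thr, positive_side = positive_side)
}
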