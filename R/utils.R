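# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rolling mean over fully interior windows
#'
#' Mean over every run of `w` consecutive values; windows that would extend
#' past either end of the vector are dropped, so the result has
#' `length(x) - w + 1` entries. Used by the CNV smoothing step.
#'
#' @param x numeric vector.
#' @param w window size, `1 <= w <= length(x)`.
#' @return numeric vector of interior-window means.
#' @keywords internal
#' @noRd
rolling_mean <- function(x, w) {
  n <- length(x)
  stopifnot(w >= 1, w <= n)
  cs <- cumsum(c(0, x))
  (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
}

# radius search wrapper: returns list of integer vectors of indices in
# `data` within `radius` of each row of `query` (inclusive boundary).
radius_neighbors <- function(query, data, radius) {
  query <- as.matrix(query)
  data <- as.matrix(data)
  if (nrow(data) == 0L) {
    return(rep(list(integer(0)), nrow(query)))
  }
  # RANN treats searchtype = "radius" with strict squared-distance cutoff;
  # inflate minimally so cells at exactly `radius` are kept, then filter.
  k <- nrow(data)
  nn <- RANN::nn2(data, query, k = k, searchtype = "radius",
                  radius = radius * (1 + 1e-9))
  lapply(seq_len(nrow(query)), function(i) {
    idx <- nn$nn.idx[i, ]
    d <- nn$nn.dists[i, ]
    keep <- idx > 0L & d <= radius * (1 + 1e-9)
    idx[keep]
  })
}

# deterministic per-call seed handling: functions with randomness take a
# `seed` argument and restore the caller's RNG state on exit.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

assert_cells <- function(cells) {
  need <- c("cell_id", "x", "y", "sample", "condition", "compartment", "state")
  miss <- setdiff(need, names(cells))
  if (length(miss))
    stop("cell table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(paste(cells$sample, cells$cell_id)))
    stop("cell_id not unique within sample")
  if (!all(is.finite(cells$x)) || !all(is.finite(cells$y)))
    stop("non-finite coordinates in cell table")
  invisible(cells)
}

assert_genes <- function(genes) {
  need <- c("gene", "chromosome", "genomic_order")
  miss <- setdiff(need, names(genes))
  if (length(miss))
    stop("gene annotation missing columns: ", paste(miss, collapse = ", "))
  ok <- tapply(genes$genomic_order, genes$chromosome,
               function(o) all(diff(sort(o)) > 0))
  if (!all(unlist(ok)))
    stop("genomic_order not strictly increasing within every chromosome")
  invisible(genes)
}
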