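#' Build a radius-based niche index
#'
#' A niche is the set of cells within `radius` micrometres of an anchor
#' cell (inclusive boundary), computed per sample — niches never span
#' samples. Every anchor is a member of its own niche.
#'
#' @param cells cell table (see [read_cell_table()] for the columns).
#' @param radius niche radius in micrometres (default 60).
#' @param anchor_filter optional logical mask over cells restricting which
#'   cells act as anchors (all cells by default).
#' @return object of class `niche_index`: list with `radius`, `anchors`
#'   (integer row indices into `cells`), `members` (list of integer
#'   vectors, parallel to `anchors`), `n_members`, and `cell_id`.
#' @export
build_niche_index <- function(cells, radius = 60, anchor_filter = NULL) {
  if (radius <= 0) stop("radius must be positive")
  assert_cells(cells)
  n <- nrow(cells)
  anchor_filter <- anchor_filter %||% rep(TRUE, n)
  anchors <- which(anchor_filter)
  members <- vector("list", length(anchors))
  for (s in unique(cells$sample)) {
    in_s <- which(cells$sample == s)
    a_in_s <- which(cells$sample[anchors] == s)
    if (!length(a_in_s)) next
    nb <- radius_neighbors(cbind(cells$x[anchors[a_in_s]],
                                 cells$y[anchors[a_in_s]]),
                           cbind(cells$x[in_s], cells$y[in_s]), radius)
    members[a_in_s] <- lapply(nb, function(i) in_s[i])
  }
  structure(list(radius = radius, anchors = anchors, members = members,
                 n_members = lengths(members), cell_id = cells$cell_id),
            class = "niche_index")
}

#' Niche composition counts and fractions
#'
#' Counts member cells per category (cellular compartment, or fine state)
#' for every niche. Fractions at the compartment level are over all
#' non-mixed member cells; at the state level they are within the state's
#' own compartment, and are masked (`NA`) for niches with fewer than
#' `min_compartment_cells` cells of that compartment. Cells labeled
#' `mixed` contribute to counts but never to fractions.
#'
#' @param index a `niche_index`.
#' @param cells the cell table the index was built from.
#' @param level `"compartment"` or `"state"`.
#' @param min_compartment_cells gate for state-level fractions
#'   (default 10).
#' @return list with `counts` and `fractions` (niches x categories
#'   matrices; rows parallel to `index$anchors`).
#' @export
niche_composition <- function(index, cells, level = c("compartment", "state"),
                              min_compartment_cells = 10) {
  level <- match.arg(level)
  lab <- if (level == "compartment") cells$compartment else cells$state
  if (anyNA(lab)) stop("unknown labels for cells: ",
                       paste(cells$cell_id[is.na(lab)], collapse = ", "))
  cats <- sort(unique(lab))
  counts <- matrix(0L, length(index$anchors), length(cats),
                   dimnames = list(NULL, cats))
  cmp_cats <- sort(unique(cells$compartment))
  cmp_counts <- matrix(0L, length(index$anchors), length(cmp_cats),
                       dimnames = list(NULL, cmp_cats))
  for (i in seq_along(index$members)) {
    m <- index$members[[i]]
    t1 <- table(lab[m])
    counts[i, names(t1)] <- as.integer(t1)
    t2 <- table(cells$compartment[m])
    cmp_counts[i, names(t2)] <- as.integer(t2)
  }
  if (level == "compartment") {
    denom <- rowSums(counts[, setdiff(cats, "mixed"), drop = FALSE])
    fractions <- counts / ifelse(denom > 0, denom, NA)
    if ("mixed" %in% cats) fractions[, "mixed"] <- NA
  } else {
    # each state belongs to exactly one compartment
    map <- unique(cells[c("state", "compartment")])
    if (anyDuplicated(map$state))
      stop("states mapping to multiple compartments: ",
           paste(map$state[duplicated(map$state)], collapse = ", "))
    cmp_of <- stats::setNames(map$compartment, map$state)
    fractions <- counts * NA_real_
    for (s in cats) {
      cmp <- cmp_of[[s]]
      if (identical(cmp, "mixed")) next
      denom <- cmp_counts[, cmp]
      ok <- denom >= min_compartment_cells
      fractions[ok, s] <- counts[ok, s] / denom[ok]
    }
  }
  list(counts = counts, fractions = fractions)
}

#' Order niches along an epithelial diffusion component
#'
#' The niche-level axis value is the mean component value over qualifying
#' member cells (typically the gastric-like / progenitor-like classes).
#' Niches with fewer than `min_epithelial` qualifying members stay
#' unbinned; the rest are discretized into `n_bins` uniform bins spanning
#' the observed niche-axis range (half-open bins, last bin closed).
#'
#' @param index a `niche_index`.
#' @param dc numeric per-cell component values (length = number of cells;
#'   `NA` for cells without a value).
#' @param qualifying logical per-cell mask of the classes whose mean
#'   defines the niche axis.
#' @param min_epithelial minimum qualifying members (default 10).
#' @param n_bins number of uniform bins (default 100).
#' @return object of class `niche_binning`: list with `niche_dc`,
#'   `n_qualifying`, `bin` (integer 1..n_bins, `NA` where unbinned) and
#'   `edges`.
#' @export
order_niches <- function(index, dc, qualifying, min_epithelial = 10,
                         n_bins = 100) {
  stopifnot(length(dc) == length(qualifying))
  if (any(qualifying & is.na(dc)))
    stop("dc undefined for some qualifying cells")
  niche_dc <- rep(NA_real_, length(index$anchors))
  n_q <- integer(length(index$anchors))
  for (i in seq_along(index$members)) {
    m <- index$members[[i]]
    q <- m[qualifying[m]]
    n_q[i] <- length(q)
    if (length(q)) niche_dc[i] <- mean(dc[q])
  }
  binnable <- n_q >= min_epithelial
  if (!any(binnable)) stop("no niche qualifies for binning")
  rng <- range(niche_dc[binnable])
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- rep(NA_integer_, length(niche_dc))
  b <- findInterval(niche_dc[binnable], edges, rightmost.closed = TRUE,
                    all.inside = FALSE)
  b[b > n_bins] <- n_bins
  bin[binnable] <- b
  structure(list(niche_dc = niche_dc, n_qualifying = n_q, bin = bin,
                 edges = edges),
            class = "niche_binning")
}

#' Compartment-specific niche expression tensor
#'
#' For every (compartment, niche): member counts of that compartment are
#' summed per gene; the per-niche size factor is the compartment's total
#' counts in the niche; values are scaled by the median size factor over
#' unmasked niches, optionally `log1p`-transformed, and z-scored per
#' (compartment, gene) across unmasked niches (population SD; genes
#' constant across niches get z = 0). Niches where a compartment is
#' absent are masked, not zero.
#'
#' @param index a `niche_index`.
#' @param counts sparse cells x genes count matrix (rows parallel to the
#'   cell table the index was built from).
#' @param compartments per-cell compartment labels.
#' @param use_compartments compartments to tabulate (default: all except
#'   `mixed`).
#' @param log1p apply `log1p` before z-scoring (default TRUE).
#' @return object of class `niche_tensor`: named list per compartment,
#'   each with `z`, `normalized`, `size_factors` and `mask` (TRUE where
#'   the compartment is present); genes in columns, niches in rows.
#' @export
niche_expression <- function(index, counts, compartments,
                             use_compartments = NULL, log1p = TRUE) {
  stopifnot(nrow(counts) == length(compartments))
  use_compartments <- use_compartments %||%
    setdiff(sort(unique(compartments)), "mixed")
  n_niche <- length(index$anchors)
  # membership as sparse niche x cell matrix for fast aggregation
  G <- Matrix::sparseMatrix(
    i = rep(seq_len(n_niche), lengths(index$members)),
    j = unlist(index$members, use.names = FALSE),
    x = 1, dims = c(n_niche, length(compartments)))
  out <- list()
  for (cmp in use_compartments) {
    sel <- compartments == cmp
    agg <- as.matrix(G[, sel, drop = FALSE] %*% counts[sel, , drop = FALSE])
    sf <- rowSums(agg)
    mask <- sf > 0
    norm <- matrix(NA_real_, n_niche, ncol(counts),
                   dimnames = list(NULL, colnames(counts)))
    if (any(mask)) {
      med <- stats::median(sf[mask])
      norm[mask, ] <- agg[mask, , drop = FALSE] / sf[mask] * med
      if (log1p) norm[mask, ] <- log1p(norm[mask, , drop = FALSE])
    }
    z <- norm
    if (sum(mask) > 0) {
      mu <- colMeans(norm[mask, , drop = FALSE])
      sd_pop <- sqrt(pmax(colMeans(norm[mask, , drop = FALSE]^2) - mu^2, 0))
      sd_pop[sd_pop == 0] <- Inf  # constant gene -> z = 0
      z[mask, ] <- sweep(sweep(norm[mask, , drop = FALSE], 2, mu), 2,
                         sd_pop, "/")
    }
    out[[cmp]] <- list(z = z, normalized = norm, size_factors = sf,
                       mask = mask)
  }
  structure(out, class = "niche_tensor")
}

#' Gene trends along the niche axis
#'
#' Averages the z-scored niche expression over all niches in each bin,
#' per compartment and gene, and orders genes by how early their
#' expression changes along the axis (landmark bin: position of the
#' maximum, the minimum, or the first z-sign change). Empty bins are
#' masked; landmark ties break by gene name.
#'
#' @param tensor a `niche_tensor`.
#' @param binning a `niche_binning`.
#' @param landmark `"argmax"`, `"argmin"` or `"signchange"`.
#' @return list per compartment with `trend` (bins x genes mean-z matrix)
#'   and `ordering` (gene names sorted by landmark bin).
#' @export
gene_trends <- function(tensor, binning,
                        landmark = c("argmax", "argmin", "signchange")) {
  landmark <- match.arg(landmark)
  n_bins <- length(binning$edges) - 1L
  lapply(unclass(tensor), function(slice) {
    usable <- slice$mask & !is.na(binning$bin)
    trend <- matrix(NA_real_, n_bins, ncol(slice$z),
                    dimnames = list(NULL, colnames(slice$z)))
    for (b in sort(unique(binning$bin[usable]))) {
      rows <- usable & binning$bin == b
      trend[b, ] <- colMeans(slice$z[rows, , drop = FALSE])
    }
    occ <- which(rowSums(!is.na(trend)) > 0)
    lm_bin <- apply(trend[occ, , drop = FALSE], 2, function(v) {
      v <- v[!is.na(v)]
      switch(landmark,
        argmax = occ[which.max(v)],
        argmin = occ[which.min(v)],
        signchange = {
          # sign-change bin located robustly as the best single-step
          # split of the trend (a literal first zero-crossing is
          # dominated by bin noise in the flat part of the response)
          if (length(v) < 2) occ[1] else {
            deltas <- vapply(seq_len(length(v) - 1), function(k)
              abs(mean(v[(k + 1):length(v)]) - mean(v[seq_len(k)])),
              numeric(1))
            occ[which.max(deltas) + 1L]
          }
        })
    })
    ordering <- colnames(trend)[order(lm_bin, colnames(trend))]
    list(trend = trend, landmark_bin = lm_bin, ordering = ordering)
  })
}

#' Canonical gastric and progenitor niche sets
#'
#' The progenitor set is the union of niches in axis bins where the
#' median progenitor-state fraction exceeds the median gastric-state
#' fraction; the gastric set mirrors it with the same number of occupied
#' bins taken from the low end of the axis. The realized percentage of
#' niches in each set is reported, never assumed.
#'
#' @param fractions state-level fraction matrix from [niche_composition()]
#'   (niches x states, rows parallel to the index anchors).
#' @param binning a `niche_binning`.
#' @param progenitor_state,gastric_state column names in `fractions`.
#' @return list with `progenitor_niches`, `gastric_niches` (integer niche
#'   indices), the bin sets, and `pct_progenitor`/`pct_gastric` of binned
#'   niches.
#' @export
canonical_niche_sets <- function(fractions, binning,
                                 progenitor_state = "progenitor-like",
                                 gastric_state = "gastric-like") {
  binned <- which(!is.na(binning$bin))
  bins <- sort(unique(binning$bin[binned]))
  med <- t(vapply(bins, function(b) {
    rows <- binned[binning$bin[binned] == b]
    c(prog = stats::median(fractions[rows, progenitor_state], na.rm = TRUE),
      gast = stats::median(fractions[rows, gastric_state], na.rm = TRUE))
  }, numeric(2)))
  prog_bins <- bins[!is.na(med[, "prog"]) & !is.na(med[, "gast"]) &
                    med[, "prog"] > med[, "gast"]]
  if (!length(prog_bins)) {
    warning("no bin with progenitor majority; progenitor set empty")
    gast_bins <- integer(0)
  } else {
    gast_bins <- utils::head(bins, length(prog_bins))
  }
  prog_niches <- which(binning$bin %in% prog_bins)
  gast_niches <- which(binning$bin %in% gast_bins)
  n_binned <- length(binned)
  list(progenitor_niches = prog_niches, gastric_niches = gast_niches,
       progenitor_bins = prog_bins, gastric_bins = gast_bins,
       pct_progenitor = 100 * length(prog_niches) / n_binned,
       pct_gastric = 100 * length(gast_niches) / n_binned)
}
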