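#' Lesion connected components from epithelial centroids
#'
#' A lesion is a contiguous set of physically adjacent epithelial cells:
#' connected components of the spatial graph linking epithelial centroids
#' within `link_radius` micrometres (a cell-diameter scale), computed per
#' sample. Component ids are deterministic, ordered by the component's
#' (min x, min y).
#'
#' @param cells cell table; only rows with `compartment == "epithelial"`
#'   receive a lesion id.
#' @param link_radius link distance in micrometres (default 20).
#' @return list with `lesion_id` (integer per cell, `NA` for
#'   non-epithelial) and `sizes` (cell count per lesion id).
#' @export
lesion_components <- function(cells, link_radius = 20) {
  assert_cells(cells)
  epi <- which(cells$compartment == "epithelial")
  if (!length(epi)) stop("no epithelial cells")
  lesion_id <- rep(NA_integer_, nrow(cells))
  next_id <- 0L
  out_sizes <- integer(0)
  for (s in unique(cells$sample)) {
    e <- epi[cells$sample[epi] == s]
    if (!length(e)) next
    nb <- radius_neighbors(cbind(cells$x[e], cells$y[e]),
                           cbind(cells$x[e], cells$y[e]), link_radius)
    edges <- cbind(rep(seq_along(e), lengths(nb)),
                   unlist(nb, use.names = FALSE))
    g <- igraph::make_empty_graph(n = length(e), directed = FALSE)
    keep <- edges[, 1] < edges[, 2]
    if (any(keep))
      g <- igraph::add_edges(g, t(edges[keep, , drop = FALSE]))
    comp <- igraph::components(g)
    # deterministic ids by component (min x, min y)
    minx <- tapply(cells$x[e], comp$membership, min)
    miny <- tapply(cells$y[e], comp$membership, min)
    ord <- order(minx, miny)
    relabel <- integer(comp$no)
    relabel[ord] <- seq_len(comp$no)
    lesion_id[e] <- next_id + relabel[comp$membership]
    sizes <- tabulate(relabel[comp$membership], comp$no)
    out_sizes <- c(out_sizes, sizes)
    next_id <- next_id + comp$no
  }
  list(lesion_id = lesion_id, sizes = out_sizes)
}

#' Rasterize cell centroids into a tissue density image
#'
#' Builds a mesh grid at `resolution` micrometres per pixel covering all
#' centroids, counts centroids per pixel, denoises with an isotropic 2D
#' Gaussian (`sigma_px` pixels), and thresholds the smoothed density at
#' `density_thresh` into a foreground (tissue) mask. An epithelial bitmap
#' (pixels holding at least one epithelial centroid) is kept for the
#' lumen stage.
#'
#' @param cells cell table (one sample; rasterization is per tissue
#'   slice).
#' @param resolution micrometres per pixel (default 5).
#' @param sigma_px Gaussian bandwidth in pixels (default 3, i.e. 15 um at
#'   the default resolution).
#' @param density_thresh foreground threshold on the smoothed density
#'   (default 0.01).
#' @return object of class `tissue_raster`: list with `counts`,
#'   `smoothed`, `foreground`, `epi_bitmap` (nx x ny matrices), `origin`
#'   (um of the first pixel's lower-left corner), `resolution`, `dim`.
#' @export
rasterize_tissue <- function(cells, resolution = 5, sigma_px = 3,
                             density_thresh = 0.01) {
  assert_cells(cells)
  if (length(unique(cells$sample)) > 1)
    stop("rasterize one sample at a time")
  x0 <- min(cells$x); y0 <- min(cells$y)
  nx <- max(1L, ceiling((max(cells$x) - x0) / resolution + 1e-9))
  ny <- max(1L, ceiling((max(cells$y) - y0) / resolution + 1e-9))
  if (nx == 1L && ny == 1L)
    warning("degenerate extent: all cells at one point; 1-pixel raster")
  px <- pmin(pmax(floor((cells$x - x0) / resolution) + 1L, 1L), nx)
  py <- pmin(pmax(floor((cells$y - y0) / resolution) + 1L, 1L), ny)
  counts <- matrix(0, nx, ny)
  for (i in seq_along(px)) counts[px[i], py[i]] <- counts[px[i], py[i]] + 1
  epi <- cells$compartment == "epithelial"
  epi_bitmap <- matrix(0, nx, ny)
  epi_bitmap[cbind(px[epi], py[epi])] <- 1
  # zero-pad before smoothing so density never wraps across the image edge
  pad <- ceiling(4 * sigma_px)
  padded <- matrix(0, nx + 2 * pad, ny + 2 * pad)
  padded[pad + seq_len(nx), pad + seq_len(ny)] <- counts
  sm <- EBImage::gblur(padded, sigma = sigma_px)
  smoothed <- sm[pad + seq_len(nx), pad + seq_len(ny), drop = FALSE]
  structure(list(counts = counts, smoothed = smoothed,
                 foreground = smoothed >= density_thresh,
                 epi_bitmap = epi_bitmap,
                 origin = c(x0, y0), resolution = resolution,
                 dim = c(nx, ny)),
            class = "tissue_raster")
}

#' Lumen mask from a tissue raster
#'
#' Closed lumens: the epithelial bitmap is dilated with a disk kernel
#' (`dilate_px` radius), holes are filled, the mask is eroded back to its
#' original scale, and empty (background) pixels inside the filled mask
#' are lumen. Open lumens (disrupted epithelium): background pixels
#' reached by iterative propagation from epithelial pixels at steps of
#' `propagate_radius` micrometres, run to a fixed point (capped at
#' `max_iter`). The union is returned.
#'
#' @param raster a `tissue_raster`.
#' @param dilate_px disk radius in pixels for the morphological closing
#'   (default 10).
#' @param propagate_radius propagation step in micrometres (default 20).
#' @param max_iter propagation cap (default 100).
#' @return logical nx x ny lumen mask with attributes `closed` and
#'   `open` (the two components).
#' @export
lumen_mask <- function(raster, dilate_px = 10, propagate_radius = 20,
                       max_iter = 100) {
  background <- !raster$foreground
  brush <- EBImage::makeBrush(2 * dilate_px + 1, shape = "disc")
  dil <- EBImage::dilate(raster$epi_bitmap, brush)
  filled <- EBImage::fillHull(dil)
  ero <- EBImage::erode(filled, brush)
  closed <- (ero > 0) & background
  # open lumens: iterative propagation from epithelial pixels over background
  step_px <- max(1L, round(propagate_radius / raster$resolution))
  step_brush <- EBImage::makeBrush(2 * step_px + 1, shape = "disc")
  current <- matrix(0, raster$dim[1], raster$dim[2])
  seed <- raster$epi_bitmap
  for (i in seq_len(max_iter)) {
    grown <- EBImage::dilate(pmax(current, seed), step_brush)
    nxt <- (grown > 0) & background
    if (identical(nxt, current > 0)) break
    current <- nxt * 1
  }
  open <- current > 0
  out <- closed | open
  attr(out, "closed") <- closed
  attr(out, "open") <- open
  out
}

#' Lumen area within a radius of each anchor
#'
#' Counts lumen pixels whose centre lies within `radius` micrometres of
#' each anchor cell; multiply by `resolution^2` for an area in um^2.
#'
#' @param raster a `tissue_raster`.
#' @param lumen logical lumen mask from [lumen_mask()].
#' @param anchors data.frame or matrix of anchor coordinates (`x`, `y` in
#'   micrometres).
#' @param radius counting radius in micrometres (default 60).
#' @return integer lumen pixel count per anchor.
#' @export
niche_lumen_area <- function(raster, lumen, anchors, radius = 60) {
  anchors <- as.matrix(as.data.frame(anchors)[, c("x", "y")])
  idx <- which(lumen, arr.ind = TRUE)
  if (!nrow(idx)) return(rep(0L, nrow(anchors)))
  centers <- cbind(raster$origin[1] + (idx[, 1] - 0.5) * raster$resolution,
                   raster$origin[2] + (idx[, 2] - 0.5) * raster$resolution)
  nb <- radius_neighbors(anchors, centers, radius)
  lengths(nb)
}

#' Morphological features along a diffusion component
#'
#' Discretizes the component into `n_bins` equal-width bins over its
#' range and summarizes each feature per bin (median, first and third
#' quartiles, n). Empty bins are masked.
#'
#' @param features data.frame of per-cell features (e.g. lesion size,
#'   epithelial fraction, lumen pixel count).
#' @param dc per-cell component values, aligned with `features` rows.
#' @param n_bins number of equal-width bins (default 11).
#' @return list with `edges` and `summary` (data.frame: bin, feature,
#'   median, q25, q75, n).
#' @export
morphology_by_dc <- function(features, dc, n_bins = 11) {
  stopifnot(nrow(features) == length(dc))
  keep <- !is.na(dc)
  edges <- seq(min(dc[keep]), max(dc[keep]), length.out = n_bins + 1)
  bin <- findInterval(dc[keep], edges, rightmost.closed = TRUE)
  bin[bin > n_bins] <- n_bins
  rows <- list()
  for (f in names(features)) {
    v <- features[[f]][keep]
    for (b in sort(unique(bin))) {
      vb <- v[bin == b & !is.na(v)]
      if (!length(vb)) next
      q <- stats::quantile(vb, c(0.25, 0.5, 0.75), names = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        bin = b, feature = f, median = q[2], q25 = q[1], q75 = q[3],
        n = length(vb), stringsAsFactors = FALSE)
    }
  }
  list(edges = edges, summary = do.call(rbind, rows))
}
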