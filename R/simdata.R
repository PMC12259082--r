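#' Configuration for the synthetic-tissue generator
#'
#' Builds the parameter object consumed by [generate_tissue()]. Defaults
#' emulate an imaging-based spatial panel (a few hundred genes, 50-100
#' counts per cell) over a premalignant pancreas-like tissue: glandular
#' epithelial lesions with lumens placed in a rectangular field, a latent
#' gastric-to-progenitor axis in `[0, 1]` that varies across lesions,
#' stromal/myeloid cells whose states are coupled to the mean latent value
#' of nearby epithelial cells, and optional dense lymphoid blobs standing
#' in for lymph nodes.
#'
#' @param seed integer RNG seed; a fixed seed makes the generated tissue
#'   byte-identical across calls.
#' @param field numeric length-2, field of view in micrometres
#'   (width, height), origin bottom-left.
#' @param n_lesions number of glandular lesions.
#' @param cells_per_lesion integer length-2 range of epithelial cells per
#'   lesion (inclusive).
#' @param stroma_density non-epithelial cells per mm^2.
#' @param lesion_radius lesion outer radius, micrometres.
#' @param lumen_radius lumen (empty disk) radius, micrometres; 0 disables
#'   lumens.
#' @param gradient_field function `(cx, cy, field)` mapping a lesion centre
#'   to its latent axis value in `[0, 1]`; the default is a linear
#'   left-to-right gradient.
#' @param panel gene panel data.frame, see [default_panel()].
#' @param nb_dispersion negative-binomial size parameter shared by all
#'   genes; `Inf` gives Poisson counts.
#' @param lymph_nodes list of lists with fields `center` (length-2, um),
#'   `radius` (um) and `n_cells`.
#' @param conditions named numeric vector: condition label -> odds
#'   multiplier applied to the niche-coupled state probabilities. One
#'   tissue sample is generated per condition.
#' @param coupling_radius radius (um) over which the local mean epithelial
#'   latent value is computed for niche coupling.
#' @param coupling_slope slope of the logistic linking local latent value
#'   to coupled stromal/myeloid state probabilities.
#' @param latent_sd per-cell Gaussian jitter around the lesion latent value.
#' @param leak_fraction off-compartment expression as a fraction of a
#'   gene's baseline mean (segmentation spill-over stand-in).
#' @param lumen_vs_latent optional function mapping a lesion's latent
#'   value to its lumen radius (um), e.g. shrinking lumens along the
#'   progenitor axis; overrides `lumen_radius` per lesion.
#' @return an object of class `sim_config`.
#' @seealso [generate_tissue()], [generate_cnv_cohort()]
#' @export
sim_config <- function(seed = 1L,
                       field = c(2000, 1000),
                       n_lesions = 8L,
                       cells_per_lesion = c(80L, 150L),
                       stroma_density = 4000,
                       lesion_radius = 100,
                       lumen_radius = 30,
                       gradient_field = NULL,
                       panel = default_panel(),
                       nb_dispersion = 2,
                       lymph_nodes = list(),
                       conditions = c(ctrl = 1),
                       coupling_radius = 60,
                       coupling_slope = 6,
                       latent_sd = 0.05,
                       leak_fraction = 0.02,
                       lumen_vs_latent = NULL) {
  if (is.null(gradient_field)) {
    gradient_field <- function(cx, cy, field) cx / field[1]
  }
  stopifnot(length(field) == 2, all(field > 0),
            n_lesions >= 0, stroma_density >= 0,
            lesion_radius > 0, lumen_radius >= 0,
            lumen_radius < lesion_radius,
            nb_dispersion > 0, length(conditions) >= 1)
  if (any(panel$baseline < 0)) stop("panel baseline means must be >= 0")
  assert_genes(panel)
  structure(list(
    seed = as.integer(seed), field = as.numeric(field),
    n_lesions = as.integer(n_lesions),
    cells_per_lesion = as.integer(cells_per_lesion),
    stroma_density = stroma_density, lesion_radius = lesion_radius,
    lumen_radius = lumen_radius, gradient_field = gradient_field,
    panel = panel, nb_dispersion = nb_dispersion,
    lymph_nodes = lymph_nodes, conditions = conditions,
    coupling_radius = coupling_radius, coupling_slope = coupling_slope,
    latent_sd = latent_sd, leak_fraction = leak_fraction,
    lumen_vs_latent = lumen_vs_latent),
    class = "sim_config")
}

#' Default synthetic gene panel
#'
#' A deterministic panel of ~240 genes over 6 chromosomes covering the
#' compartments and response classes the downstream stages exercise:
#' epithelial gastric markers (decreasing along the latent axis),
#' progenitor markers (increasing), early/late sigmoid responders,
#' housekeeping constants, niche-coupled fibroblast and myeloid genes
#' (including three planted fibroblast communication modules driven by the
#' local epithelial latent value and by two independent smooth spatial
#' fields), and lymphoid/endothelial markers. Baseline means cycle through
#' a fixed ladder so the panel is reproducible without an RNG.
#'
#' @return data.frame with columns `gene`, `chromosome`, `genomic_order`,
#'   `baseline`, `compartment`, `response`, `coupling`, `is_communication`,
#'   `excluded_from_embedding`, `module`.
#' @export
default_panel <- function() {
  ladder <- c(0.4, 0.8, 1.4, 0.6, 1.0, 2.0, 0.5, 1.2, 0.9, 1.6)
  block <- function(prefix, n, compartment, response, coupling = 1,
                    comm = FALSE, module = NA_character_, scale = 1) {
    data.frame(
      gene = sprintf("%s%02d", prefix, seq_len(n)),
      baseline = rep_len(ladder, n) * scale,
      compartment = compartment, response = response, coupling = coupling,
      is_communication = comm, module = module, stringsAsFactors = FALSE)
  }
  panel <- rbind(
    block("GastA", 20, "epithelial", "decreasing"),
    block("ProgA", 20, "epithelial", "increasing"),
    block("EarlyE", 10, "epithelial", "early"),
    block("LateE", 10, "epithelial", "late"),
    block("HouseE", 20, "epithelial", "constant"),
    # fibroblast: three planted communication modules + constants
    block("FibLigA", 8, "fibroblast", "increasing", comm = TRUE,
          module = "fib_prog"),
    block("FibAuxB", 8, "fibroblast", "aux1", coupling = 0, comm = TRUE,
          module = "fib_aux1"),
    block("FibAuxC", 8, "fibroblast", "aux2", coupling = 0, comm = TRUE,
          module = "fib_aux2"),
    block("FibBase", 20, "fibroblast", "constant", comm = FALSE),
    block("FibDecR", 8, "fibroblast", "decreasing"),
    # myeloid: progenitor-niche receptor module + opposing markers
    block("MyeRecA", 8, "myeloid", "increasing", comm = TRUE,
          module = "mye_prog", scale = 3),
    block("MyeDecB", 8, "myeloid", "decreasing"),
    block("MyeBase", 16, "myeloid", "constant", scale = 1.6),
    block("LymBase", 20, "lymphoid", "constant", scale = 2.4),
    block("EndBase", 16, "endothelial", "constant", scale = 3.0),
    # negative-control style probes: flat, excluded from embeddings
    block("NegCtrl", 10, "none", "constant"))
  panel$excluded_from_embedding <- startsWith(panel$gene, "NegCtrl")
  n <- nrow(panel)
  n_chrom <- 6L
  panel$chromosome <- paste0("chr", rep_len(seq_len(n_chrom), n))
  ord <- stats::ave(seq_len(n), panel$chromosome, FUN = seq_along)
  panel$genomic_order <- as.integer(ord)
  panel[c("gene", "chromosome", "genomic_order", "baseline", "compartment",
          "response", "coupling", "is_communication",
          "excluded_from_embedding", "module")]
}

# response curve value for driver d in [0, 1]
response_value <- function(response, d, aux1, aux2) {
  switch(response,
    constant = rep(1, length(d)),
    increasing = 0.2 + 1.8 * d,
    decreasing = 2.0 - 1.8 * d,
    early = 0.2 + 1.8 * stats::plogis((d - 0.3) / 0.08),
    late = 0.2 + 1.8 * stats::plogis((d - 0.7) / 0.08),
    aux1 = 0.2 + 1.8 * aux1,
    aux2 = 0.2 + 1.8 * aux2,
    stop("unknown response curve: ", response))
}

draw_counts <- function(mu, size) {
  n <- length(mu)
  if (is.infinite(size)) stats::rpois(n, mu) else
    stats::rnbinom(n, size = size, mu = mu)
}

#' Generate a synthetic spatial tissue with ground truth
#'
#' Places epithelial cells on lesion annuli (the lumen is an empty inner
#' disk), scatters stromal cells at the configured density, couples
#' stromal/myeloid state frequencies to the local mean epithelial latent
#' value within `coupling_radius`, adds lymph-node blobs, and draws
#' negative-binomial counts per gene with mean
#' `baseline x response(driver)`. One sample is emitted per condition.
#'
#' @param config a [sim_config()] object.
#' @return list with elements `cells` (cell table), `counts` (sparse cells
#'   x genes), `genes` (panel annotation) and `truth` (per-cell latent
#'   values, lesion and lymph-node ids, planted module gene sets, coupled
#'   target states).
#' @export
generate_tissue <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_lesions == 0 && config$stroma_density == 0 &&
      length(config$lymph_nodes) == 0) stop("empty tissue")
  with_seed(config$seed, {
    samples <- lapply(seq_along(config$conditions), function(ci) {
      generate_one_sample(config,
                          condition = names(config$conditions)[ci],
                          odds_mult = config$conditions[[ci]],
                          sample_id = sprintf("S%d", ci))
    })
  })
  cells <- do.call(rbind, lapply(samples, `[[`, "cells"))
  counts <- do.call(rbind, lapply(samples, `[[`, "counts"))
  rownames(cells) <- NULL
  truth <- list(
    cell_id = cells$cell_id,
    latent_dc = unlist(lapply(samples, function(s) s$latent), use.names = FALSE),
    local_dc = unlist(lapply(samples, function(s) s$local_dc), use.names = FALSE),
    lesion_id = unlist(lapply(samples, function(s) s$lesion_id), use.names = FALSE),
    lymph_node_id = unlist(lapply(samples, function(s) s$ln_id), use.names = FALSE),
    lesion_centers = do.call(rbind, lapply(samples, `[[`, "lesion_centers")),
    modules = planted_modules(config$panel),
    coupling_targets = list(myeloid = "Itgax_mac", fibroblast = "Tnc_myCAF"))
  list(cells = cells, counts = counts, genes = config$panel, truth = truth)
}

planted_modules <- function(panel) {
  comm <- panel[panel$is_communication & !is.na(panel$module), ]
  out <- list()
  for (cmp in unique(comm$compartment)) {
    sub <- comm[comm$compartment == cmp, ]
    out[[cmp]] <- split(sub$gene, sub$module)
  }
  out
}

generate_one_sample <- function(config, condition, odds_mult, sample_id) {
  field <- config$field
  # lesion centres on a jittered grid so they always fit the field of view
  margin <- config$lesion_radius * 1.05
  centres <- NULL
  if (config$n_lesions > 0) {
    nx <- ceiling(sqrt(config$n_lesions * field[1] / field[2]))
    ny <- ceiling(config$n_lesions / nx)
    gx <- seq(margin, field[1] - margin, length.out = max(nx, 2))
    gy <- seq(margin, field[2] - margin, length.out = max(ny, 2))
    slots <- expand.grid(x = gx, y = gy)
    pick <- sample.int(nrow(slots), config$n_lesions)
    jit_x <- stats::runif(config$n_lesions, -margin / 4, margin / 4)
    jit_y <- stats::runif(config$n_lesions, -margin / 4, margin / 4)
    centres <- cbind(pmin(pmax(slots$x[pick] + jit_x, margin), field[1] - margin),
                     pmin(pmax(slots$y[pick] + jit_y, margin), field[2] - margin))
  }

  # epithelial cells on annuli
  epi <- list(x = numeric(0), y = numeric(0), latent = numeric(0),
              lesion = integer(0))
  lumen_radii <- numeric(config$n_lesions)
  if (config$n_lesions > 0) {
    for (li in seq_len(config$n_lesions)) {
      n <- if (config$cells_per_lesion[1] == config$cells_per_lesion[2])
        config$cells_per_lesion[1] else
        sample(config$cells_per_lesion[1]:config$cells_per_lesion[2], 1)
      lat0 <- config$gradient_field(centres[li, 1], centres[li, 2], field)
      lum <- if (is.null(config$lumen_vs_latent)) config$lumen_radius else
        min(config$lumen_vs_latent(lat0), 0.95 * config$lesion_radius)
      lumen_radii[li] <- lum
      frac2 <- (lum / config$lesion_radius)^2
      r <- config$lesion_radius * sqrt(stats::runif(n, frac2, 1))
      th <- stats::runif(n, 0, 2 * pi)
      lat <- pmin(pmax(lat0 + stats::rnorm(n, 0, config$latent_sd), 0), 1)
      epi$x <- c(epi$x, centres[li, 1] + r * cos(th))
      epi$y <- c(epi$y, centres[li, 2] + r * sin(th))
      epi$latent <- c(epi$latent, lat)
      epi$lesion <- c(epi$lesion, rep(li, n))
    }
  }
  n_epi <- length(epi$x)

  # stromal scatter; gland lumens are empty space, so stromal cells
  # falling inside a lesion's lumen disk are rejected
  area_mm2 <- prod(field) / 1e6
  n_str <- stats::rpois(1, config$stroma_density * area_mm2)
  str_x <- stats::runif(n_str, 0, field[1])
  str_y <- stats::runif(n_str, 0, field[2])
  if (config$n_lesions > 0 && n_str > 0) {
    in_lumen <- rep(FALSE, n_str)
    for (li in seq_len(config$n_lesions)) {
      if (lumen_radii[li] <= 0) next
      d2 <- (str_x - centres[li, 1])^2 + (str_y - centres[li, 2])^2
      in_lumen <- in_lumen | d2 < lumen_radii[li]^2
    }
    str_x <- str_x[!in_lumen]; str_y <- str_y[!in_lumen]
    n_str <- length(str_x)
  }
  str_cmp <- sample(c("fibroblast", "myeloid", "lymphoid", "endothelial"),
                    n_str, replace = TRUE, prob = c(.45, .30, .10, .15))

  # lymph nodes
  ln_x <- numeric(0); ln_y <- numeric(0); ln_id <- integer(0)
  ln_state <- character(0)
  if (length(config$lymph_nodes)) {
    for (k in seq_along(config$lymph_nodes)) {
      ln <- config$lymph_nodes[[k]]
      if (!is.null(centres)) {
        dd <- sqrt((centres[, 1] - ln$center[1])^2 +
                   (centres[, 2] - ln$center[2])^2)
        if (any(dd < ln$radius + config$lesion_radius))
          warning("lymph node ", k, " overlaps a lesion; emitting both")
      }
      r <- ln$radius * sqrt(stats::runif(ln$n_cells))
      th <- stats::runif(ln$n_cells, 0, 2 * pi)
      ln_x <- c(ln_x, ln$center[1] + r * cos(th))
      ln_y <- c(ln_y, ln$center[2] + r * sin(th))
      ln_id <- c(ln_id, rep(k, ln$n_cells))
      ln_state <- c(ln_state, sample(c("B_cell", "CD4T", "CD8T"), ln$n_cells,
                                     replace = TRUE, prob = c(.5, .25, .25)))
    }
  }

  x <- c(epi$x, str_x, ln_x)
  y <- c(epi$y, str_y, ln_y)
  n_cells <- length(x)
  compartment <- c(rep("epithelial", n_epi), str_cmp,
                   rep("lymphoid", length(ln_x)))

  # local mean epithelial latent value (niche coupling driver)
  local_dc <- rep(NA_real_, n_cells)
  if (n_epi > 0) {
    nb <- radius_neighbors(cbind(x, y), cbind(epi$x, epi$y),
                           config$coupling_radius)
    local_dc <- vapply(nb, function(i)
      if (length(i)) mean(epi$latent[i]) else NA_real_, numeric(1))
  }
  driver <- ifelse(is.na(local_dc), 0.5, local_dc)
  driver[seq_len(n_epi)] <- epi$latent

  # states
  state <- character(n_cells)
  state[seq_len(n_epi)] <- ifelse(epi$latent > 0.5,
                                  "progenitor-like", "gastric-like")
  p_coupled <- stats::plogis(config$coupling_slope * (driver - 0.5) +
                             log(odds_mult))
  is_str <- seq_len(n_cells) > n_epi & seq_len(n_cells) <= n_epi + n_str
  u <- stats::runif(n_cells)
  state[is_str & compartment == "myeloid"] <-
    ifelse(u[is_str & compartment == "myeloid"] <
             p_coupled[is_str & compartment == "myeloid"],
           "Itgax_mac", "Maf_mac")
  state[is_str & compartment == "fibroblast"] <-
    ifelse(u[is_str & compartment == "fibroblast"] <
             p_coupled[is_str & compartment == "fibroblast"],
           "Tnc_myCAF", "Tnxb_iCAF")
  state[is_str & compartment == "lymphoid"] <- "Tcell_parenchymal"
  state[is_str & compartment == "endothelial"] <- "vascular"
  if (length(ln_x)) state[(n_epi + n_str + 1):n_cells] <- ln_state

  # counts
  panel <- config$panel
  # auxiliary spatial fields driving the non-gradient communication
  # modules; both are constructed orthogonal to the left-right latent axis
  aux1 <- stats::plogis((y - field[2] / 2) / (field[2] / 8))
  aux2 <- stats::plogis(4 * sin(3 * pi * x / field[1]) *
                        sin(3 * pi * y / field[2]))
  counts <- matrix(0L, n_cells, nrow(panel))
  for (g in seq_len(nrow(panel))) {
    coup <- panel$coupling[g]
    d_eff <- coup * driver + (1 - coup) * 0.5
    resp <- response_value(panel$response[g], d_eff, aux1, aux2)
    mu <- ifelse(compartment == panel$compartment[g],
                 panel$baseline[g] * resp,
                 config$leak_fraction * panel$baseline[g])
    counts[, g] <- draw_counts(mu, config$nb_dispersion)
  }
  cell_id <- sprintf("%s_c%05d", sample_id, seq_len(n_cells))
  dimnames(counts) <- list(cell_id, panel$gene)
  cells <- data.frame(
    cell_id = cell_id, x = x, y = y, sample = sample_id,
    condition = condition, compartment = compartment, state = state,
    stringsAsFactors = FALSE)
  list(cells = cells,
       counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                            "CsparseMatrix"),
       latent = c(epi$latent, rep(NA_real_, n_cells - n_epi)),
       local_dc = local_dc,
       lesion_id = c(epi$lesion, rep(NA_integer_, n_cells - n_epi)),
       ln_id = c(rep(NA_integer_, n_epi + n_str), ln_id),
       lesion_centers = if (is.null(centres)) NULL else
         data.frame(sample = sample_id, lesion = seq_len(config$n_lesions),
                    cx = centres[, 1], cy = centres[, 2],
                    lumen_radius = lumen_radii,
                    stringsAsFactors = FALSE))
}

#' Default gene panel for the copy-number cohort generator
#'
#' Chromosome-scale copy-number calling smooths over 100-gene windows, so
#' the dissociated-cohort panel carries many genes per chromosome. All
#' genes are constant-response epithelial genes; baseline means cycle a
#' fixed ladder whose depth (~16 counts/gene, >10k counts per cell over
#' the thousand-gene panel) mirrors deeply sequenced droplet scRNA-seq
#' rather than a sparse imaging panel.
#'
#' @param n_chrom number of chromosomes.
#' @param genes_per_chrom genes on each chromosome.
#' @return gene panel data.frame (same columns as [default_panel()]).
#' @export
default_cnv_panel <- function(n_chrom = 5L, genes_per_chrom = 200L) {
  ladder <- 16 * c(0.3, 0.5, 0.9, 1.4, 0.6, 2.2, 0.4, 1.0, 0.7, 1.8)
  n <- n_chrom * genes_per_chrom
  data.frame(
    gene = sprintf("G%04d", seq_len(n)),
    chromosome = paste0("chr", rep(seq_len(n_chrom), each = genes_per_chrom)),
    genomic_order = rep(seq_len(genes_per_chrom), n_chrom),
    baseline = rep_len(ladder, n),
    compartment = "epithelial", response = "constant", coupling = 1,
    is_communication = FALSE, excluded_from_embedding = FALSE,
    module = NA_character_, stringsAsFactors = FALSE)
}

#' Generate a dissociated cohort with planted chromosome-scale CNVs
#'
#' Draws negative-binomial counts for every cell; for a cell carrying a
#' gain on chromosome `c`, the expected counts of all genes on `c` are
#' multiplied by `fold_gain` (losses by `fold_loss`). Cells whose event
#' row is all-neutral are clean diploid references.
#'
#' @param config a [sim_config()] whose `panel` has enough genes per
#'   chromosome for windowed smoothing (see [default_cnv_panel()]).
#' @param events character matrix cells x chromosomes with entries
#'   `"gain"`, `"loss"` or `"neutral"`; column names are chromosome labels.
#' @param fold_gain,fold_loss expected-count fold-changes for gains/losses.
#' @param window_size smoothing window the downstream caller intends to
#'   use; chromosomes with fewer genes are flagged in the returned truth.
#' @return list with `counts` (sparse cells x genes), `genes`, and `truth`
#'   (the planted `events` plus `short_chromosomes` warnings).
#' @export
generate_cnv_cohort <- function(config, events, fold_gain = 1.5,
                                fold_loss = 0.5, window_size = 100L) {
  stopifnot(inherits(config, "sim_config"), is.matrix(events))
  panel <- config$panel
  chroms <- colnames(events)
  if (is.null(chroms)) stop("events must have chromosome column names")
  per_chrom <- table(panel$chromosome)
  short <- chroms[per_chrom[chroms] < window_size]
  if (length(short))
    warning("chromosomes with fewer genes than the CNV window: ",
            paste(short, collapse = ", "))
  n_cells <- nrow(events)
  fold <- matrix(1, n_cells, length(chroms), dimnames = list(NULL, chroms))
  fold[events == "gain"] <- fold_gain
  fold[events == "loss"] <- fold_loss
  with_seed(config$seed, {
    counts <- matrix(0L, n_cells, nrow(panel))
    for (g in seq_len(nrow(panel))) {
      ch <- panel$chromosome[g]
      f <- if (ch %in% chroms) fold[, ch] else rep(1, n_cells)
      counts[, g] <- draw_counts(panel$baseline[g] * f, config$nb_dispersion)
    }
  })
  cell_id <- sprintf("cnv_c%05d", seq_len(n_cells))
  dimnames(counts) <- list(cell_id, panel$gene)
  list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                            "CsparseMatrix"),
       genes = panel,
       truth = list(events = events, short_chromosomes = short))
}
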