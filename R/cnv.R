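#' Configuration for transcriptome-based copy-number inference
#'
#' Defaults follow the modified inferCNV-style procedure for
#' chromosome-scale calling from sparse single-cell counts: genes below a
#' mean-expression floor are dropped, per-gene log2 ratios against a
#' diploid reference are clipped and smoothed over 100-gene windows, and
#' cells are classified genomically quiet or rearranged by counting
#' chromosome-level gain/loss events.
#'
#' @param min_threshold minimum reference mean (library-size-normalized
#'   counts) for a gene to be retained (default 0.1).
#' @param pseudocount pseudocount in both numerator and denominator of the
#'   log2 ratio (default 0.1).
#' @param clip two-sided clip interval for per-gene log2 ratios
#'   (default `c(-3, 3)`).
#' @param window_size sliding-window length in genes (default 100).
#' @param gain_cut,loss_cut chromosome-mean thresholds calling a gain
#'   (`> gain_cut`) or loss (`< loss_cut`); defaults 0.16 / -0.16.
#' @param quiet_max_events exclusive upper bound on events for a quiet
#'   genome: quiet iff `event_count < quiet_max_events` (default 9).
#' @param refine_chromosome optional chromosome whose recurrent gain
#'   drives iterative reference refinement.
#' @param refine_cut chromosome-mean cut separating carriers from the
#'   refined diploid reference (default 0.17).
#' @param refine_min_cells minimum refined-reference size before falling
#'   back to the initial reference (default 20).
#' @param excluded_gene_groups list of character vectors of gene symbols
#'   excluded from the reference regardless of expression (coordinately
#'   regulated clusters that mimic CNVs).
#' @return object of class `cnv_config`.
#' @export
cnv_config <- function(min_threshold = 0.1, pseudocount = 0.1,
                       clip = c(-3, 3), window_size = 100L,
                       gain_cut = 0.16, loss_cut = -0.16,
                       quiet_max_events = 9L,
                       refine_chromosome = NULL, refine_cut = 0.17,
                       refine_min_cells = 20L,
                       excluded_gene_groups = list()) {
  stopifnot(loss_cut < 0, gain_cut > 0, clip[1] < 0, clip[2] > 0,
            window_size >= 1, min_threshold >= 0, pseudocount > 0)
  structure(list(min_threshold = min_threshold, pseudocount = pseudocount,
                 clip = clip, window_size = as.integer(window_size),
                 gain_cut = gain_cut, loss_cut = loss_cut,
                 quiet_max_events = as.integer(quiet_max_events),
                 refine_chromosome = refine_chromosome,
                 refine_cut = refine_cut,
                 refine_min_cells = as.integer(refine_min_cells),
                 excluded_gene_groups = excluded_gene_groups),
            class = "cnv_config")
}

# library-size normalization (no log), the input contract for all CNV steps
libsize_normalize <- function(counts) {
  sf <- Matrix::rowSums(counts)
  if (any(sf <= 0)) stop("cells with zero counts; filter before CNV")
  out <- Matrix::Diagonal(x = stats::median(sf) / sf) %*% counts
  dimnames(out) <- dimnames(counts)
  methods::as(out, "CsparseMatrix")
}

#' Reference expression profile for CNV inference
#'
#' Means of library-size-normalized (never log-transformed) counts over
#' the reference cells. Genes are retained iff the mean reaches
#' `min_threshold`, the gene is in no excluded group, and it is not
#' mitochondrial/ribosomal (prefixes `mt-`, `Rps`, `Rpl`, case
#' insensitive). Retained genes are ordered by (chromosome,
#' genomic_order).
#'
#' @param ref_counts raw counts for reference cells (cells x genes);
#'   normalized internally.
#' @param genes gene annotation with `gene`, `chromosome`, `genomic_order`.
#' @param cfg a [cnv_config()].
#' @return list with `means` (named per retained gene) and `genes` (the
#'   retained, ordered annotation rows).
#' @export
reference_profile <- function(ref_counts, genes, cfg = cnv_config()) {
  if (nrow(ref_counts) == 0) stop("empty reference")
  assert_genes(genes)
  norm <- libsize_normalize(ref_counts)
  mu <- Matrix::colMeans(norm)
  excl <- unique(unlist(cfg$excluded_gene_groups))
  mito_ribo <- grepl("^(mt-|Rps|Rpl)", genes$gene, ignore.case = TRUE)
  keep <- mu >= cfg$min_threshold & !(genes$gene %in% excl) & !mito_ribo
  g <- genes[keep, , drop = FALSE]
  ord <- order(g$chromosome, g$genomic_order)
  g <- g[ord, , drop = FALSE]
  per_chrom <- table(g$chromosome)
  if (!any(per_chrom >= cfg$window_size)) stop("no analyzable chromosome")
  means <- mu[keep][ord]
  names(means) <- g$gene
  list(means = means, genes = g)
}

#' Smoothed per-window log2 expression ratios
#'
#' Per retained gene `g`, `r = log2((x_g + p) / (mu_g + p))` clipped to
#' the configured interval, then averaged over `window_size` consecutive
#' genes within each chromosome. Only fully interior windows are kept
#' (windows reaching past either chromosome end are trimmed); window
#' positions are indexed by their centre gene (left-of-centre for even
#' windows). Chromosomes with fewer retained genes than the window are
#' skipped with a warning.
#'
#' @param counts raw counts (cells x genes); library-size normalized
#'   internally to match the reference contract.
#' @param reference output of [reference_profile()].
#' @param cfg a [cnv_config()].
#' @return list with `smoothed` (cells x window-positions matrix),
#'   `windows` (data.frame `chromosome`, `center_gene`) — a partial
#'   karyotype profile completed by [recenter_profile()] and
#'   [classify_karyotype()].
#' @export
smoothed_log_ratio <- function(counts, reference, cfg = cnv_config()) {
  genes <- reference$genes
  norm <- libsize_normalize(counts)[, genes$gene, drop = FALSE]
  p <- cfg$pseudocount
  lr <- log2(sweep(as.matrix(norm) + p, 2, reference$means + p, "/"))
  lr[lr > cfg$clip[2]] <- cfg$clip[2]
  lr[lr < cfg$clip[1]] <- cfg$clip[1]
  w <- cfg$window_size
  chroms <- unique(genes$chromosome)
  sm_list <- list(); win_list <- list()
  for (ch in chroms) {
    cols <- which(genes$chromosome == ch)
    if (length(cols) < w) {
      warning("chromosome ", ch, " has fewer than window_size genes; skipped")
      next
    }
    block <- lr[, cols, drop = FALSE]
    sm <- t(apply(block, 1, rolling_mean, w = w))
    if (nrow(lr) == 1) sm <- matrix(sm, nrow = 1)
    centers <- cols[seq_len(ncol(sm)) + (w - 1L) %/% 2L]
    sm_list[[ch]] <- sm
    win_list[[ch]] <- data.frame(chromosome = ch,
                                 center_gene = genes$gene[centers],
                                 stringsAsFactors = FALSE)
  }
  if (!length(sm_list)) stop("no analyzable chromosome")
  smoothed <- do.call(cbind, sm_list)
  windows <- do.call(rbind, win_list)
  rownames(windows) <- NULL
  rownames(smoothed) <- rownames(counts)
  list(smoothed = smoothed, windows = windows)
}

#' Recenter karyotype profiles per cell
#'
#' Subtracts each cell's median smoothed value so the per-cell median
#' becomes exactly zero, removing global expression shifts that would
#' otherwise masquerade as whole-genome events.
#'
#' @param profile output of [smoothed_log_ratio()].
#' @return the profile with `smoothed` recentred.
#' @export
recenter_profile <- function(profile) {
  med <- apply(profile$smoothed, 1, stats::median)
  profile$smoothed <- profile$smoothed - med
  profile
}

#' Chromosome summaries and quiet/rearranged classification
#'
#' Chromosome summary = mean smoothed (recentred) value over the
#' chromosome's window positions. Per (cell, chromosome): gain if the
#' summary exceeds `gain_cut`, loss if below `loss_cut`, else neutral.
#' A cell is genomically quiet iff its event count is strictly below
#' `quiet_max_events`, rearranged otherwise.
#'
#' @param profile recentred profile from [recenter_profile()].
#' @param cfg a [cnv_config()].
#' @return list with `chrom_summary` (cells x chromosomes), `events`
#'   (character matrix, `"gain"/"loss"/"neutral"`), `event_count`, `class`
#'   (`"quiet"/"rearranged"`).
#' @export
classify_karyotype <- function(profile, cfg = cnv_config()) {
  chroms <- unique(profile$windows$chromosome)
  cs <- vapply(chroms, function(ch)
    rowMeans(profile$smoothed[, profile$windows$chromosome == ch,
                              drop = FALSE]),
    numeric(nrow(profile$smoothed)))
  if (nrow(profile$smoothed) == 1) cs <- matrix(cs, nrow = 1,
                                                dimnames = list(NULL, chroms))
  events <- matrix("neutral", nrow(cs), ncol(cs), dimnames = dimnames(cs))
  events[cs > cfg$gain_cut] <- "gain"
  events[cs < cfg$loss_cut] <- "loss"
  event_count <- rowSums(events != "neutral")
  cls <- ifelse(event_count < cfg$quiet_max_events, "quiet", "rearranged")
  list(chrom_summary = cs, events = events, event_count = event_count,
       class = cls)
}

#' End-to-end CNV inference
#'
#' Convenience wrapper: reference profile, smoothed log ratios, per-cell
#' recentring, and classification in one call.
#'
#' @param counts raw counts for the cells to profile.
#' @param genes gene annotation.
#' @param reference_mask logical mask over `counts` rows marking the
#'   diploid reference cells.
#' @param cfg a [cnv_config()].
#' @return list with `profile` (smoothed, recentred), `karyotype`
#'   (classification output) and `reference`.
#' @export
infer_cnv <- function(counts, genes, reference_mask, cfg = cnv_config()) {
  ref <- reference_profile(counts[reference_mask, , drop = FALSE], genes, cfg)
  prof <- recenter_profile(smoothed_log_ratio(counts, ref, cfg))
  list(profile = prof, karyotype = classify_karyotype(prof, cfg),
       reference = ref)
}

#' Iterative within-sample reference refinement
#'
#' Runs one full inference pass with the initial reference, then rebuilds
#' the reference from cells whose mean on the recurrent
#' `refine_chromosome` stays at or below `refine_cut` (non-carriers), and
#' runs a second pass. Falls back to the initial reference (with a
#' warning) when fewer than `refine_min_cells` cells qualify.
#'
#' @inheritParams infer_cnv
#' @param initial_reference_mask starting diploid reference mask.
#' @return list with `first` and `second` full inference results, plus
#'   `refined_mask`.
#' @export
refine_reference <- function(counts, genes, initial_reference_mask,
                             cfg = cnv_config()) {
  if (is.null(cfg$refine_chromosome))
    stop("cfg$refine_chromosome must be set for refinement")
  first <- infer_cnv(counts, genes, initial_reference_mask, cfg)
  ch <- cfg$refine_chromosome
  if (!ch %in% colnames(first$karyotype$chrom_summary))
    stop("refine chromosome ", ch, " not analyzable")
  carrier_score <- first$karyotype$chrom_summary[, ch]
  refined <- carrier_score <= cfg$refine_cut
  if (sum(refined) < cfg$refine_min_cells) {
    warning("refined reference smaller than minimum; keeping initial")
    refined <- initial_reference_mask
  }
  second <- infer_cnv(counts, genes, refined, cfg)
  list(first = first, second = second, refined_mask = refined)
}
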