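# tiny annotation helper: n genes split over chromosomes
cnv_genes <- function(per_chrom) {
  data.frame(
    gene = sprintf("g%03d", seq_len(sum(per_chrom))),
    chromosome = rep(paste0("chr", seq_along(per_chrom)), per_chrom),
    genomic_order = unlist(lapply(per_chrom, seq_len)),
    stringsAsFactors = FALSE)
}

test_that("reference profile applies expression and group exclusions", {
  genes <- cnv_genes(c(4, 4))
  # identical cells: equal library sizes, normalized means = raw values
  m <- t(matrix(rep(c(0.05, 2, 5, 3, 4, 1, 2, 3), 10), 8, 10))
  counts <- make_counts(m, genes$gene)
  cfg <- cnv_config(window_size = 2)
  ref <- reference_profile(counts, genes, cfg)
  expect_false("g001" %in% ref$genes$gene)  # mean below min_threshold
  expect_equal(nrow(ref$genes), 7)

  # excluded gene group beats high expression
  cfg2 <- cnv_config(window_size = 2,
                     excluded_gene_groups = list(c("g003", "g004")))
  ref2 <- reference_profile(counts, genes, cfg2)
  expect_false(any(c("g003", "g004") %in% ref2$genes$gene))

  # mitochondrial/ribosomal prefixes always excluded
  genes3 <- genes; genes3$gene[2] <- "mt-Nd1"; colnames(counts)[2] <- "mt-Nd1"
  ref3 <- reference_profile(counts, genes3, cfg)
  expect_false("mt-Nd1" %in% ref3$genes$gene)

  # all retained when everything passes
  genes4 <- cnv_genes(c(3))
  m4 <- matrix(5, 10, 3)
  ref4 <- reference_profile(make_counts(m4, genes4$gene), genes4,
                            cnv_config(window_size = 2))
  expect_equal(ref4$genes$gene, genes4$gene)

  # no chromosome with window_size genes -> error
  expect_error(reference_profile(make_counts(m4, genes4$gene), genes4,
                                 cnv_config(window_size = 10)),
               "no analyzable chromosome")
})

test_that("smoothed log ratios match clipping and windowing contracts", {
  # cell identical to reference -> all smoothed values 0
  genes <- cnv_genes(c(120))
  mu <- rep_len(c(1, 2, 4), 120)
  ref_m <- t(matrix(rep(mu, 20), 120, 20))
  counts <- make_counts(ref_m, genes$gene)
  cfg <- cnv_config(window_size = 100)
  ref <- reference_profile(counts, genes, cfg)
  prof <- smoothed_log_ratio(counts[1:2, ], ref, cfg)
  expect_equal(max(abs(prof$smoothed)), 0)
  # 120 genes, window 100 -> 21 fully interior positions
  expect_equal(ncol(prof$smoothed), 21)

  # rolling means equal the brute-force window oracle
  set.seed(8)
  v <- rnorm(120)
  brute <- vapply(seq_len(21), function(i) mean(v[i:(i + 99)]), numeric(1))
  expect_equal(nichetrace:::rolling_mean(v, 100), brute)

  # clipping: ratio log2(20.1/0.1) clipped to 3
  g2 <- cnv_genes(c(3))
  cfg2 <- cnv_config(window_size = 1)
  refc <- make_counts(matrix(c(0.2, 10, 10), 5, 3, byrow = TRUE), g2$gene)
  ref2 <- reference_profile(refc, g2, cfg2)
  hot <- make_counts(matrix(c(20, 10, 10.2), 1, 3), g2$gene)
  prof2 <- smoothed_log_ratio(hot, ref2, cfg2)
  # per-gene ratio for gene 1 before smoothing exceeds 3 -> clipped
  expect_equal(max(prof2$smoothed), 3, tolerance = 1e-9)

  # chromosome shorter than the window is skipped with a warning
  g3 <- cnv_genes(c(120, 3))
  m3 <- t(matrix(rep_len(c(1, 2, 4), 123 * 6), 123, 6))
  c3 <- make_counts(m3, g3$gene)
  ref3 <- reference_profile(c3, g3, cnv_config(window_size = 100))
  expect_warning(prof3 <- smoothed_log_ratio(c3[1:2, ], ref3,
                                             cnv_config(window_size = 100)),
                 "skipped")
  expect_true(all(prof3$windows$chromosome == "chr1"))
})

test_that("recentring zeroes the per-cell median", {
  set.seed(9)
  prof <- list(smoothed = matrix(rnorm(35), 5, 7),
               windows = data.frame(chromosome = "chr1",
                                    center_gene = sprintf("g%d", 1:7)))
  rec <- recenter_profile(prof)
  expect_equal(apply(rec$smoothed, 1, median), rep(0, 5))
  # brute-force oracle on the 5x7 toy
  expect_equal(rec$smoothed,
               prof$smoothed - apply(prof$smoothed, 1, median))
  # constant offset removed entirely
  prof2 <- list(smoothed = matrix(0.5, 3, 7), windows = prof$windows)
  expect_equal(max(abs(recenter_profile(prof2)$smoothed)), 0)
})

test_that("karyotype classification counts events with the stated cuts", {
  # 12 chromosomes, one window each; craft per-cell event counts
  windows <- data.frame(chromosome = paste0("chr", 1:12),
                        center_gene = sprintf("g%d", 1:12))
  sm <- rbind(c(rep(0.2, 8), rep(0, 4)),      # 8 gains -> quiet
              c(rep(0.2, 9), rep(0, 3)),      # 9 events -> rearranged
              c(rep(-0.2, 5), rep(0.2, 4), rep(0, 3)),  # mixed, 9 events
              rep(0.1, 12))                   # all inside the band
  prof <- list(smoothed = sm, windows = windows)
  k <- classify_karyotype(prof, cnv_config())
  expect_equal(k$event_count, c(8, 9, 9, 0), ignore_attr = TRUE)
  expect_equal(k$class, c("quiet", "rearranged", "rearranged", "quiet"),
               ignore_attr = TRUE)
  expect_equal(sum(k$events == "loss"), 5)
  # boundary: exactly 0.16 is neutral (strict inequality)
  prof2 <- list(smoothed = matrix(c(0.16, -0.16), 1, 2),
                windows = windows[1:2, ])
  expect_true(all(classify_karyotype(prof2, cnv_config())$events ==
                  "neutral"))
})

test_that("monotonicity: amplifying a chromosome raises its summary", {
  panel <- default_cnv_panel(n_chrom = 3, genes_per_chrom = 120)
  cfg <- sim_config(seed = 10, panel = panel, nb_dispersion = 4)
  events <- matrix("neutral", 60, 3,
                   dimnames = list(NULL, paste0("chr", 1:3)))
  coh <- generate_cnv_cohort(cfg, events)
  ccfg <- cnv_config()
  base <- infer_cnv(coh$counts, coh$genes, rep(TRUE, 60), ccfg)
  boosted <- coh$counts
  chr2 <- coh$genes$chromosome == "chr2"
  boosted[1, chr2] <- boosted[1, chr2] * 3
  ref <- reference_profile(coh$counts, coh$genes, ccfg)
  prof_b <- recenter_profile(smoothed_log_ratio(boosted[1, , drop = FALSE],
                                                ref, ccfg))
  k_b <- classify_karyotype(prof_b, ccfg)
  expect_gt(k_b$chrom_summary[1, "chr2"],
            base$karyotype$chrom_summary[1, "chr2"])
})

test_that("iterative reference refinement isolates non-carriers", {
  panel <- default_cnv_panel(n_chrom = 3, genes_per_chrom = 150)
  panel$baseline <- panel$baseline * 8  # deeper coverage: clean bimodality
  cfg <- sim_config(seed = 12, panel = panel, nb_dispersion = 20)
  events <- matrix("neutral", 120, 3,
                   dimnames = list(NULL, paste0("chr", 1:3)))
  events[1:60, "chr1"] <- "gain"   # recurrent gain in half the cohort
  coh <- generate_cnv_cohort(cfg, events, fold_gain = 2)
  ccfg <- cnv_config(refine_chromosome = "chr1")
  res <- refine_reference(coh$counts, coh$genes, rep(TRUE, 120), ccfg)
  # refined reference = the non-carrier mode, recovered exactly
  expect_identical(unname(which(res$refined_mask)), 61:120)
  # second pass tightens the within-reference spread on the refine chromosome
  sd1 <- sd(res$first$karyotype$chrom_summary[61:120, "chr1"])
  sd2 <- sd(res$second$karyotype$chrom_summary[61:120, "chr1"])
  expect_lt(sd2, sd1 + 0.01)
  # carriers stand out in the second pass
  expect_gt(mean(res$second$karyotype$chrom_summary[1:60, "chr1"]), 0.16)

  # no carriers: refined reference keeps everyone
  events0 <- matrix("neutral", 40, 3,
                    dimnames = list(NULL, paste0("chr", 1:3)))
  coh0 <- generate_cnv_cohort(sim_config(seed = 13, panel = panel,
                                         nb_dispersion = 20), events0)
  res0 <- refine_reference(coh0$counts, coh0$genes, rep(TRUE, 40), ccfg)
  expect_true(all(res0$refined_mask))

  # too-small refined reference falls back with a warning
  ccfg2 <- cnv_config(refine_chromosome = "chr1", refine_cut = -10,
                      refine_min_cells = 20)
  expect_warning(res2 <- refine_reference(coh0$counts, coh0$genes,
                                          rep(TRUE, 40), ccfg2),
                 "keeping initial")
  expect_true(all(res2$refined_mask))
})
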