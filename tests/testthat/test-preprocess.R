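test_that("cell filtering applies the count threshold exactly", {
  m <- matrix(0, 100, 2)
  m[, 1] <- seq_len(100)  # totals 1..100
  counts <- make_counts(m)
  mask <- filter_cells(counts, min_counts = 25)
  expect_equal(sum(mask), 76)            # totals 25..100 pass
  expect_false(mask[[24]])               # 24 counts -> removed
  expect_true(all(filter_cells(counts, min_counts = 0)))
  expect_equal(attr(mask, "fraction_removed"), 0.24)
  expect_error(filter_cells(counts, min_counts = 1000), "no cells pass")

  # excluded genes do not count toward the totals
  genes <- data.frame(gene = c("a", "b"), chromosome = "chr1",
                      genomic_order = 1:2,
                      excluded_from_embedding = c(FALSE, TRUE))
  m2 <- matrix(c(10, 40), 1, 2)
  expect_error(filter_cells(make_counts(m2), genes, min_counts = 25),
               "no cells pass")
})

test_that("normalization matches the median-size-factor formula", {
  # two cells, totals 10 and 30 -> median 20 -> scale x2 and x2/3
  m <- rbind(c(4, 6, 0), c(12, 18, 0))
  r <- normalize_counts(make_counts(m))
  expect_equal(r$size_factors, c(10, 30), ignore_attr = TRUE)
  expect_equal(as.matrix(r$normalized), rbind(c(8, 12, 0), c(8, 12, 0)),
               ignore_attr = TRUE)

  # equal totals: normalized equals raw in linear mode
  m2 <- rbind(c(5, 5), c(2, 8))
  r2 <- normalize_counts(make_counts(m2))
  expect_equal(as.matrix(r2$normalized), m2, ignore_attr = TRUE)

  # linear mode preserves the zero pattern
  sim <- small_tissue()
  rn <- normalize_counts(sim$counts, sim$genes)
  expect_identical(as.matrix(rn$normalized) == 0,
                   as.matrix(sim$counts) == 0)

  # log mode: zero count -> log(pseudocount) = 0 at pseudocount 1
  r3 <- normalize_counts(make_counts(m2), log_transform = TRUE)
  expect_equal(as.matrix(r3$normalized)[1, ], log(c(6, 6)),
               ignore_attr = TRUE)
  expect_equal(as.matrix(r3$normalized)[cbind(1, 1)],
               log(5 + 1), ignore_attr = TRUE)
  m4 <- rbind(c(0, 10), c(5, 5))
  r4 <- normalize_counts(make_counts(m4), log_transform = TRUE)
  expect_equal(as.matrix(r4$normalized)[1, 1], 0)
})

test_that("triangle threshold finds the valley of the histogram", {
  # two deltas with a flat gap between: threshold strictly inside the gap
  counts <- c(100, rep(0, 8), 20)
  edges <- seq(0, 1, length.out = 11)
  thr <- triangle_threshold(counts, edges)
  expect_gt(as.numeric(thr), 0.1)
  expect_lt(as.numeric(thr), 0.9)

  # symmetric histogram: tie-break takes the smaller threshold
  sym <- c(5, 20, 100, 20, 5)
  thr2 <- triangle_threshold(sym, seq(0, 1, length.out = 6))
  expect_lte(attr(thr2, "bin"), 3)

  # degenerate single occupied bin
  expect_error(triangle_threshold(c(0, 10, 0), seq(0, 1, length.out = 4)),
               "degenerate")

  # two-Gaussian mixture: misclassification within 5% of the Bayes rule
  set.seed(1)
  x <- c(rnorm(5000, 0.1, 0.05), rnorm(5000, 0.8, 0.05))
  lab <- rep(c(0, 1), each = 5000)
  h <- hist(x, breaks = seq(min(x), max(x), length.out = 26), plot = FALSE)
  thr3 <- as.numeric(triangle_threshold(h$counts, h$breaks))
  miscls <- mean((x > thr3) != lab)
  expect_lte(miscls, 0.05)
})

test_that("gene censoring combines reference and spatial evidence", {
  genes <- sprintf("g%02d", 1:20)
  # references: gene g01 never detected anywhere
  ref1 <- matrix(0.3, 2, 20, dimnames = list(NULL, genes))
  ref1[, 1] <- 0
  ref2 <- ref1
  # spatial detection: bimodal, modes near 0.02 and 0.60
  spatial <- rbind(c(rep(0.02, 10), rep(0.60, 10)),
                   c(rep(0.03, 10), rep(0.58, 10)))
  colnames(spatial) <- genes
  res <- censor_genes(list(ref1, ref2), spatial)
  expect_gt(res$threshold, 0.03)
  expect_lt(res$threshold, 0.58)
  expect_false(res$pass[["g01"]])          # absent from every reference
  expect_true(all(res$pass[genes[11:20]])) # high mode passes
  expect_false(any(res$pass[genes[1:10]]))

  # all genes detected everywhere -> all pass (flat histogram fallback)
  full <- matrix(1, 2, 20, dimnames = list(NULL, genes))
  expect_warning(res2 <- censor_genes(list(full), full), "falling back")
  expect_true(all(res2$pass))

  # monotonicity: raising min_ref never adds genes
  res3 <- censor_genes(list(ref1, ref2), spatial, min_ref = 0.1)
  expect_true(all(res$pass | !res3$pass))
})

test_that("signature scores are averaged reference z-scores", {
  # 4-cell x 3-gene toy: compare to hand-computed z-score means
  m <- rbind(c(1, 2, 3), c(3, 2, 1), c(5, 6, 1), c(7, 2, 3))
  counts <- make_counts(m, genes = c("gA", "gB", "gC"))
  z <- apply(m, 2, function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2)))
  expect_equal(score_signature(counts, c("gA", "gB", "gC")),
               rowMeans(z), ignore_attr = TRUE)

  # one gene, a cell at the reference mean scores 0
  s1 <- score_signature(counts, "gB")
  expect_equal(s1[[4]],
               (2 - mean(m[, 2])) / sqrt(mean((m[, 2] - mean(m[, 2]))^2)))

  # all genes 2 SD above the reference mean score exactly 2
  ref <- matrix(rnorm(600), 200, 3)
  mu <- colMeans(ref); sd_p <- sqrt(colMeans(ref^2) - mu^2)
  probe <- rbind(mu + 2 * sd_p)
  big <- make_counts(rbind(ref, probe), genes = c("gA", "gB", "gC"))
  s2 <- score_signature(big, c("gA", "gB", "gC"),
                        reference_cells = c(rep(TRUE, 200), FALSE))
  expect_equal(s2[[201]], 2)

  # invariance to adding a constant to one signature gene (all-cell ref)
  shifted <- m; shifted[, 2] <- shifted[, 2] + 100
  expect_equal(score_signature(make_counts(shifted, c("gA", "gB", "gC")),
                               c("gA", "gB", "gC")),
               score_signature(counts, c("gA", "gB", "gC")),
               ignore_attr = TRUE)

  # zero-variance gene dropped with warning; empty intersection errors
  mz <- cbind(m, 5)
  expect_warning(score_signature(make_counts(mz, c("gA", "gB", "gC", "gZ")),
                                 c("gA", "gZ")), "zero-variance")
  expect_error(score_signature(counts, c("nope1", "nope2")), "missing")
})

test_that("pseudocoloring is the clipped signature-color product", {
  W <- rbind(c(1, 0, 0), c(0.5, 0.5, 0))
  S <- rbind(c(0.8, 0.9))
  expect_equal(pseudocolor(S, W), cbind(r = 1, g = 0.45, b = 0),
               ignore_attr = TRUE)
  # single signature, score 1, pure red; two saturating signatures add
  expect_equal(as.numeric(pseudocolor(cbind(1), rbind(c(1, 0, 0)))),
               c(1, 0, 0))
  expect_equal(as.numeric(pseudocolor(cbind(1, 1),
                                      rbind(c(1, 0, 0), c(0, 0, 1)))),
               c(1, 0, 1))
  # output always within [0,1]^3; normalization contract
  set.seed(2)
  S2 <- normalize_signature_scores(matrix(rnorm(300), 100, 3), 0.95)
  expect_true(all(S2 >= 0 & S2 <= 1))
  rgb <- pseudocolor(S2, diag(3))
  expect_true(all(rgb >= 0 & rgb <= 1))
  expect_error(normalize_signature_scores(S2, 1.5), "quantile")
})
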