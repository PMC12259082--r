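test_that("niche index equals the brute-force distance oracle", {
  # boundary: inclusive at exactly the radius
  cells <- make_cells(c(0, 59), c(0, 0))
  idx <- build_niche_index(cells, radius = 60)
  expect_setequal(idx$members[[1]], c(1, 2))
  cells2 <- make_cells(c(0, 61), c(0, 0))
  idx2 <- build_niche_index(cells2, radius = 60)
  expect_identical(idx2$members[[1]], 1L)
  expect_identical(idx2$n_members, c(1L, 1L))

  # random tissue vs O(n^2) oracle, including a second sample
  set.seed(14)
  cells3 <- make_cells(runif(400, 0, 500), runif(400, 0, 500),
                       sample = rep(c("S1", "S2"), each = 200))
  idx3 <- build_niche_index(cells3, radius = 60)
  oracle <- oracle_niche_members(cells3, 60)
  for (i in seq_len(400)) expect_setequal(idx3$members[[i]], oracle[[i]])
  # every anchor is its own member
  expect_true(all(vapply(seq_len(400), function(i)
    i %in% idx3$members[[i]], logical(1))))

  # anchor filtering and errors
  idx4 <- build_niche_index(cells3, radius = 60,
                            anchor_filter = seq_len(400) <= 10)
  expect_length(idx4$members, 10)
  expect_error(build_niche_index(cells3, radius = 0), "radius")
})

test_that("niche composition gates state fractions by compartment size", {
  cells <- make_cells(rep(0, 10), seq(0, 45, 5),
                      compartment = rep(c("epithelial", "fibroblast"), 5),
                      state = rep(c("gastric-like", "Tnc_myCAF"), 5))
  idx <- build_niche_index(cells, radius = 60)
  comp <- niche_composition(idx, cells, level = "compartment")
  expect_equal(comp$counts[1, ], c(epithelial = 5, fibroblast = 5))
  expect_equal(comp$fractions[1, ],
               c(epithelial = 0.5, fibroblast = 0.5))
  # 5 fibroblasts < 10 -> state fractions masked
  st <- niche_composition(idx, cells, level = "state")
  expect_true(all(is.na(st$fractions[, "Tnc_myCAF"])))
  expect_equal(st$counts[1, "Tnc_myCAF"], 5, ignore_attr = TRUE)

  # single-cell niche: own fraction 1
  lone <- make_cells(0, 0, compartment = "epithelial",
                     state = "gastric-like")
  ic <- build_niche_index(lone, radius = 60)
  cc <- niche_composition(ic, lone, level = "compartment")
  expect_equal(cc$fractions[1, "epithelial"], c(epithelial = 1),
               ignore_attr = TRUE)

  # 30-cell random toy vs hand enumeration
  set.seed(15)
  cells3 <- make_cells(runif(30, 0, 100), runif(30, 0, 100),
                       compartment = sample(c("epithelial", "myeloid"), 30,
                                            replace = TRUE))
  idx3 <- build_niche_index(cells3, radius = 40)
  c3 <- niche_composition(idx3, cells3, level = "compartment")
  for (i in c(1, 10, 30)) {
    d <- sqrt((cells3$x - cells3$x[i])^2 + (cells3$y - cells3$y[i])^2)
    m <- d <= 40
    expect_equal(c3$counts[i, "epithelial"],
                 sum(cells3$compartment[m] == "epithelial"),
                 ignore_attr = TRUE)
  }

  # mixed cells count but never enter fractions
  cells4 <- make_cells(rep(0, 12), seq(0, 55, 5),
                       compartment = c(rep("epithelial", 10), "mixed",
                                       "mixed"),
                       state = c(rep("gastric-like", 10), "mixed", "mixed"))
  idx4 <- build_niche_index(cells4, radius = 100)
  c4 <- niche_composition(idx4, cells4, level = "compartment")
  expect_equal(c4$fractions[1, "epithelial"], c(epithelial = 1),
               ignore_attr = TRUE)
  expect_true(is.na(c4$fractions[1, "mixed"]))
})

test_that("niche ordering averages qualifying members and bins uniformly", {
  cells <- make_cells(rep(seq(0, 400, 100), each = 12),
                      rep(seq(0, 55, 5), 5))
  n <- nrow(cells)
  dc <- rep(c(0.2, 0.8), length.out = n)
  idx <- build_niche_index(cells, radius = 80)
  # all qualifying members share a value -> niche value equals it
  b <- order_niches(idx, rep(0.7, n), rep(TRUE, n), min_epithelial = 10,
                    n_bins = 10)
  expect_true(all(abs(b$niche_dc - 0.7) < 1e-12))
  # half at 0.2, half at 0.8 -> mean 0.5 in full niches
  b2 <- order_niches(idx, dc, rep(TRUE, n), min_epithelial = 12,
                     n_bins = 10)
  full <- b2$n_qualifying == 12
  expect_true(any(full))
  expect_true(all(abs(b2$niche_dc[full] - 0.5) < 1e-12))
  # below the gate -> unbinned; nothing qualifying -> error
  qual <- rep(c(TRUE, FALSE), length.out = n)
  b3 <- order_niches(idx, dc, qual, min_epithelial = 5, n_bins = 10)
  expect_true(all(is.na(b3$bin[b3$n_qualifying < 5])))
  expect_true(all(!is.na(b3$bin[b3$n_qualifying >= 5])))
  expect_error(order_niches(idx, dc, qual, min_epithelial = 10000),
               "no niche qualifies")
  # permutation invariance in cell order
  set.seed(16)
  perm <- sample(n)
  cellsP <- cells[perm, ]; cellsP$cell_id <- cells$cell_id
  idxP <- build_niche_index(cellsP, radius = 80)
  bP <- order_niches(idxP, dc[perm], rep(TRUE, n), min_epithelial = 10,
                     n_bins = 10)
  b4 <- order_niches(idx, dc, rep(TRUE, n), min_epithelial = 10,
                     n_bins = 10)
  expect_equal(sort(round(bP$niche_dc, 12)), sort(round(b4$niche_dc, 12)))
  expect_equal(bP$edges, b4$edges)
})

test_that("niche expression matches the sum/normalize/log/z oracle", {
  set.seed(17)
  n_cells <- 60
  cells <- make_cells(runif(n_cells, 0, 200), runif(n_cells, 0, 200),
                      compartment = sample(c("epithelial", "fibroblast"),
                                           n_cells, replace = TRUE))
  counts <- make_counts(matrix(rpois(n_cells * 8, 3), n_cells, 8))
  idx <- build_niche_index(cells, radius = 70)
  tensor <- niche_expression(idx, counts, cells$compartment, log1p = TRUE)

  # direct oracle for the fibroblast slice
  fib <- which(cells$compartment == "fibroblast")
  agg <- t(vapply(idx$members, function(m) {
    mm <- intersect(m, fib)
    if (length(mm)) Matrix::colSums(counts[mm, , drop = FALSE]) else
      rep(0, 8)
  }, numeric(8)))
  sf <- rowSums(agg)
  mask <- sf > 0
  med <- median(sf[mask])
  norm <- log1p(agg[mask, ] / sf[mask] * med)
  mu <- colMeans(norm)
  sdp <- sqrt(colMeans(norm^2) - mu^2)
  sdp[sdp == 0] <- Inf
  z_oracle <- sweep(sweep(norm, 2, mu), 2, sdp, "/")
  expect_equal(tensor$fibroblast$z[mask, ], z_oracle, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_identical(tensor$fibroblast$mask, mask)
  # z-slices: mean 0, population SD 1 over unmasked niches
  zz <- tensor$fibroblast$z[mask, ]
  expect_lt(max(abs(colMeans(zz))), 1e-8)
  sds <- sqrt(colMeans(zz^2))
  expect_true(all(abs(sds[sds > 0] - 1) < 1e-6))
  # masked where compartment absent, not zero
  expect_true(all(is.na(tensor$fibroblast$z[!mask, ])))
})

test_that("gene trends expose landmark ordering along the axis", {
  # synthetic tensor: 50 niches along a known axis, 3 genes
  nn <- 50
  axis <- seq(0, 1, length.out = nn)
  z <- cbind(flat = rep(0, nn),
             linear = as.numeric(scale(axis)),
             early = as.numeric(scale(pmin(axis * 4, 1))))
  tensor <- structure(list(epithelial = list(
    z = z, normalized = z, size_factors = rep(1, nn),
    mask = rep(TRUE, nn))), class = "niche_tensor")
  binning <- structure(list(
    niche_dc = axis, n_qualifying = rep(10L, nn),
    bin = findInterval(axis, seq(0, 1, length.out = 11),
                       rightmost.closed = TRUE),
    edges = seq(0, 1, length.out = 11)), class = "niche_binning")
  tr <- gene_trends(tensor, binning, landmark = "argmax")
  # constant gene flat at z 0
  expect_true(all(abs(tr$epithelial$trend[, "flat"]) < 1e-12))
  # linear gene: monotone trend, argmax in the last occupied bin
  lin <- tr$epithelial$trend[, "linear"]
  expect_true(all(diff(lin[!is.na(lin)]) > 0))
  expect_equal(unname(tr$epithelial$landmark_bin["linear"]), 10)
  # early responder saturates sooner than the linear gene
  trs <- gene_trends(tensor, binning, landmark = "signchange")
  expect_lt(trs$epithelial$landmark_bin["early"],
            trs$epithelial$landmark_bin["linear"])
})

test_that("canonical niche sets derive from median composition per bin", {
  # progenitor fraction dominates above axis position 0.8, exactly
  nn <- 200
  axis <- seq(0, 1, length.out = nn)
  frac <- cbind(`progenitor-like` = ifelse(axis > 0.8, 0.9, 0.1),
                `gastric-like` = ifelse(axis > 0.8, 0.1, 0.9))
  binning <- structure(list(
    niche_dc = axis, n_qualifying = rep(10L, nn),
    bin = findInterval(axis, seq(0, 1, length.out = 11),
                       rightmost.closed = TRUE),
    edges = seq(0, 1, length.out = 11)), class = "niche_binning")
  sets <- canonical_niche_sets(frac, binning)
  expect_true(all(axis[sets$progenitor_niches] > 0.8))
  expect_equal(length(sets$progenitor_bins), length(sets$gastric_bins))
  expect_true(all(axis[sets$gastric_niches] <= 0.2 + 1e-9))
  expect_gt(sets$pct_progenitor, 0)
  # all-gastric tissue: empty progenitor set with warning
  frac0 <- cbind(`progenitor-like` = rep(0.05, nn),
                 `gastric-like` = rep(0.9, nn))
  expect_warning(s0 <- canonical_niche_sets(frac0, binning), "empty")
  expect_length(s0$progenitor_niches, 0)
})

test_that("parenchyma dissection keeps the epithelial halo, drops nodes", {
  # boundary: stromal cell at 199 um retained, at 201 um excluded
  cells <- make_cells(c(0, 199, 201), c(0, 0, 0),
                      compartment = c("epithelial", "myeloid", "myeloid"),
                      state = c("gastric-like", "Maf_mac", "Maf_mac"))
  mask <- dissect_parenchyma(cells)
  expect_identical(as.logical(mask), c(TRUE, TRUE, FALSE))

  # lymph-node blob: components with > 250 cells removed, 250 kept
  blob <- function(n, cx) make_cells(cx + runif(n, 0, 10),
                                     runif(n, 0, 10),
                                     compartment = "lymphoid",
                                     state = "B_cell")
  set.seed(18)
  base <- make_cells(0, 0, compartment = "epithelial",
                     state = "gastric-like")
  keep250 <- rbind(base, blob(250, 50))
  keep250$cell_id <- sprintf("c%04d", seq_len(nrow(keep250)))
  m250 <- dissect_parenchyma(keep250)
  expect_true(all(m250))
  drop251 <- rbind(base, blob(251, 50))
  drop251$cell_id <- sprintf("c%04d", seq_len(nrow(drop251)))
  m251 <- dissect_parenchyma(drop251)
  expect_true(m251[1])
  expect_false(any(m251[-1]))
  expect_equal(attr(m251, "retained_fraction"), 1 / 252)

  # simdata planted lymph node recovered exactly
  cfg <- sim_config(seed = 19, n_lesions = 2, stroma_density = 300,
                    field = c(1500, 700),
                    lymph_nodes = list(list(center = c(1200, 350),
                                            radius = 90, n_cells = 400)))
  sim <- generate_tissue(cfg)
  dm <- dissect_parenchyma(sim$cells)
  in_ln <- !is.na(sim$truth$lymph_node_id)
  expect_false(any(dm[in_ln]))
  expect_error(dissect_parenchyma(
    make_cells(0, 0, compartment = "myeloid", state = "Maf_mac")),
    "no epithelial")
})
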