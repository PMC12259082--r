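# Shared in-code fixtures for the test suite.

# minimal valid cell table from coordinate vectors
make_cells <- function(x, y, compartment = "epithelial", state = NULL,
                       sample = "S1", condition = "ctrl") {
  n <- length(x)
  state <- state %||% ifelse(rep_len(compartment, n) == "epithelial",
                             "gastric-like", "stromal")
  data.frame(cell_id = sprintf("c%04d", seq_len(n)), x = x, y = y,
             sample = rep_len(sample, n), condition = rep_len(condition, n),
             compartment = rep_len(compartment, n),
             state = rep_len(state, n), stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sparse counts from a dense matrix with generic dimnames
make_counts <- function(m, genes = NULL) {
  genes <- genes %||% sprintf("g%03d", seq_len(ncol(m)))
  dimnames(m) <- list(sprintf("c%04d", seq_len(nrow(m))), genes)
  methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}

# small default tissue shared by several files (cached per session)
small_tissue <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 42, n_lesions = 4,
                        cells_per_lesion = c(60, 90),
                        stroma_density = 900, field = c(1200, 800))
      cache <<- generate_tissue(cfg)
    }
    cache
  }
})

# brute-force O(n^2) radius membership oracle (per sample)
oracle_niche_members <- function(cells, radius) {
  n <- nrow(cells)
  lapply(seq_len(n), function(i) {
    d <- sqrt((cells$x - cells$x[i])^2 + (cells$y - cells$y[i])^2)
    which(d <= radius & cells$sample == cells$sample[i])
  })
}
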