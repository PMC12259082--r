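#' Configuration for communication-module discovery
#'
#' @param rho Pearson correlation threshold for graph edges (default
#'   0.2, strict inequality).
#' @param jaccard_drop edges with neighbourhood Jaccard similarity below
#'   this are removed (default 0.05).
#' @param jaccard_add non-edges with Jaccard similarity above this are
#'   added (default 0.95).
#' @param min_module_size smallest reported module (default 4).
#' @param min_shared_niches minimum unmasked niches shared by a gene pair
#'   for a correlation to count (default 10).
#' @return object of class `comm_config`.
#' @export
comm_config <- function(rho = 0.2, jaccard_drop = 0.05, jaccard_add = 0.95,
                        min_module_size = 4L, min_shared_niches = 10L) {
  stopifnot(rho > 0, rho < 1, jaccard_drop >= 0, jaccard_drop < jaccard_add,
            jaccard_add <= 1, min_module_size >= 1)
  structure(list(rho = rho, jaccard_drop = jaccard_drop,
                 jaccard_add = jaccard_add,
                 min_module_size = as.integer(min_module_size),
                 min_shared_niches = as.integer(min_shared_niches)),
            class = "comm_config")
}

#' Gene-gene correlation graph from niche expression
#'
#' Nodes are communication genes; an undirected edge joins two genes iff
#' the Pearson correlation of their z-scored niche expression over
#' unmasked niches is strictly greater than `rho`. Constant genes become
#' isolated nodes with a warning; pairs sharing fewer than
#' `min_shared_niches` niches get no edge.
#'
#' @param z niches x genes z-scored expression (one compartment slice of
#'   a `niche_tensor`); rows with `NA` are treated as masked.
#' @param cfg a [comm_config()].
#' @return igraph undirected graph with vertex name = gene.
#' @export
correlation_graph <- function(z, cfg = comm_config()) {
  z <- as.matrix(z)
  mask <- stats::complete.cases(z)
  if (sum(mask) < cfg$min_shared_niches)
    stop("fewer than ", cfg$min_shared_niches, " unmasked niches")
  zz <- z[mask, , drop = FALSE]
  sds <- apply(zz, 2, stats::sd)
  if (any(sds == 0))
    warning("constant genes become isolated nodes: ",
            paste(colnames(zz)[sds == 0], collapse = ", "))
  r <- suppressWarnings(stats::cor(zz))
  r[is.na(r)] <- 0
  adj <- r > cfg$rho
  diag(adj) <- FALSE
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

#' Jaccard refinement of a correlation graph
#'
#' For every node pair, the Jaccard similarity of their neighbour sets in
#' the ORIGINAL graph (endpoints excluded from both sets) drives two
#' simultaneous rules applied from the original graph, not sequentially:
#' existing edges with similarity below `jaccard_drop` are removed
#' (spurious correlations) and non-edges with similarity above
#' `jaccard_add` are added (genes embedded in the same community that
#' missed the correlation cutoff).
#'
#' @param graph igraph graph from [correlation_graph()].
#' @param cfg a [comm_config()].
#' @return refined igraph graph over the same vertices.
#' @export
jaccard_refine <- function(graph, cfg = comm_config()) {
  n <- igraph::vcount(graph)
  A <- igraph::as_adjacency_matrix(graph, sparse = TRUE)
  shared <- as.matrix(A %*% A)      # common neighbours (endpoints drop out
  deg <- Matrix::rowSums(A)         # of each other's sets via the A_ij term)
  # neighbour sets exclude the two endpoints themselves:
  # |N(i)\{j}| = deg_i - A_ij, shared counts already exclude endpoints
  # unless i~k~j includes i or j; subtract those memberships explicitly
  Ad <- as.matrix(A)
  shared_excl <- shared - Ad * 0    # k ranges over all; k = i or j impossible
  # k = i would need A_ii = 1 (no self loops); k = j likewise, except
  # through A_ij A_jj = 0. But shared counts k adjacent to both i and j,
  # and k can be i or j only via self-loops, absent here.
  size_i <- matrix(deg, n, n) - Ad       # |N(i) \ {j}|
  size_j <- t(size_i)                    # |N(j) \ {i}|
  union_size <- size_i + size_j - shared_excl
  jac <- ifelse(union_size > 0, shared_excl / union_size, 0)
  drop_e <- Ad == 1 & jac < cfg$jaccard_drop
  add_e <- Ad == 0 & jac > cfg$jaccard_add
  diag(add_e) <- FALSE
  newA <- (Ad == 1 & !drop_e) | add_e
  g2 <- igraph::graph_from_adjacency_matrix(newA, mode = "undirected")
  igraph::V(g2)$name <- igraph::V(graph)$name
  g2
}

# conductance of a vertex set: boundary edges / min(vol(S), vol(V\S));
# a set with no boundary edges (isolated component or the whole graph)
# has conductance 0
set_conductance <- function(graph, vs) {
  deg <- igraph::degree(graph)
  vol_s <- sum(deg[vs])
  if (vol_s == 0) return(1)
  inside <- 2 * igraph::ecount(igraph::induced_subgraph(graph, vs))
  boundary <- vol_s - inside
  if (boundary == 0) return(0)
  vol_rest <- sum(deg) - vol_s
  boundary / min(vol_s, vol_rest)
}

#' Detect overlapping communication modules
#'
#' Deterministic seed-expansion community detection on the refined gene
#' graph: maximal cliques (at least `min_module_size` large) seed
#' candidate modules; each seed greedily absorbs the neighbouring gene
#' that most lowers the module's conductance until no addition helps;
#' near-duplicate modules (Jaccard >= 0.9) are merged. Genes may belong
#' to several modules. Every returned module has conductance below 0.5
#' (denser inside than across its boundary).
#'
#' @param graph refined igraph graph.
#' @param cfg a [comm_config()].
#' @return list of character vectors (gene sets), ordered by size then
#'   lexicographically; empty (with a warning) when nothing qualifies.
#' @export
detect_modules <- function(graph, cfg = comm_config()) {
  if (igraph::vcount(graph) == 0) stop("empty graph")
  cliques <- igraph::max_cliques(graph, min = cfg$min_module_size)
  # deterministic order: by size desc, then lexicographic member names
  keys <- vapply(cliques, function(cl)
    paste(sort(igraph::V(graph)$name[cl]), collapse = "|"), character(1))
  ord <- order(-lengths(cliques), keys)
  cliques <- cliques[ord]
  modules <- list()
  for (cl in cliques) {
    vs <- sort(as.integer(cl))
    repeat {
      nb <- setdiff(unique(unlist(
        igraph::adjacent_vertices(graph, vs))), vs)
      if (!length(nb)) break
      cur <- set_conductance(graph, vs)
      cand_cond <- vapply(sort(nb), function(v)
        set_conductance(graph, c(vs, v)), numeric(1))
      best <- which.min(cand_cond)
      if (cand_cond[best] < cur) vs <- sort(c(vs, sort(nb)[best])) else break
    }
    if (set_conductance(graph, vs) < 0.5 &&
        length(vs) >= cfg$min_module_size)
      modules[[length(modules) + 1]] <- sort(igraph::V(graph)$name[vs])
  }
  # merge near-duplicates
  out <- list()
  for (m in modules) {
    dup <- FALSE
    for (i in seq_along(out)) {
      j <- length(intersect(m, out[[i]])) / length(union(m, out[[i]]))
      if (j >= 0.9) {
        out[[i]] <- sort(union(out[[i]], m)); dup <- TRUE; break
      }
    }
    if (!dup) out[[length(out) + 1]] <- m
  }
  if (!length(out)) warning("no module reaches min_module_size")
  out[order(-lengths(out), vapply(out, paste, character(1),
                                  collapse = "|"))]
}

#' Score modules against canonical niche sets
#'
#' Mean z-scored niche expression of each module's genes over each niche
#' set, with a flag marking modules whose mean in a set strictly exceeds
#' `flag_cut` (progenitor-associated modules at the default sets).
#'
#' @param modules list of gene sets from [detect_modules()].
#' @param z niches x genes z matrix (the module's compartment slice).
#' @param niche_sets named list of integer niche-index vectors.
#' @param flag_cut flag threshold (default 0.2, strict).
#' @return data.frame: module id, one score column per niche set, one
#'   flag column per niche set.
#' @export
module_niche_score <- function(modules, z, niche_sets, flag_cut = 0.2) {
  rows <- lapply(seq_along(modules), function(i) {
    genes <- intersect(modules[[i]], colnames(z))
    s <- vapply(niche_sets, function(ns)
      mean(z[ns, genes, drop = FALSE], na.rm = TRUE), numeric(1))
    c(list(module = i), as.list(s),
      stats::setNames(as.list(s > flag_cut), paste0(names(s), "_flag")))
  })
  do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Built-in ligand-receptor table
#'
#' A minimal curated table of mouse cognate pairs spanning the signalling
#' channels relevant to the progenitor niche (IL-18, CSF2, TGF-beta,
#' Notch, matricellular integrin/syndecan, PDGF, neuregulin, LIF and
#' related axes). Receptor complexes are `;`-joined subunits. For real
#' analyses supply a full database via [read_lr_table()].
#'
#' @return data.frame with columns `ligand`, `receptor`, `pathway`.
#' @export
builtin_lr_table <- function() {
  tab <- rbind(
    c("Il18", "Il18r1;Il18rap", "IL18"),
    c("Csf2", "Csf2ra;Csf2rb", "CSF"),
    c("Csf1", "Csf1r", "CSF"),
    c("Tgfb1", "Tgfbr1;Tgfbr2", "TGFb"),
    c("Tgfb2", "Tgfbr1;Tgfbr2", "TGFb"),
    c("Jag1", "Notch3", "NOTCH"),
    c("Jag1", "Notch1", "NOTCH"),
    c("Dll1", "Notch1", "NOTCH"),
    c("Postn", "Itgb3", "POSTN"),
    c("Postn", "Sdc1", "POSTN"),
    c("Tnc", "Itgb3", "TENASCIN"),
    c("Tnc", "Sdc1", "TENASCIN"),
    c("Pdgfb", "Pdgfrb", "PDGF"),
    c("Pdgfa", "Pdgfra", "PDGF"),
    c("Nrg1", "Itgb3", "NRG"),
    c("Nrg1", "Erbb3", "NRG"),
    c("Lif", "Lifr;Il6st", "LIF"),
    c("Il6", "Il6ra;Il6st", "IL6"),
    c("Cxcl12", "Cxcr4", "CXCL"),
    c("Spp1", "Cd44", "SPP1"),
    c("Igf1", "Igf1r", "IGF"),
    c("Igf2", "Igf1r", "IGF"),
    c("Hbegf", "Egfr", "EGF"),
    c("Areg", "Egfr", "EGF"),
    c("Wnt5a", "Fzd1", "WNT"),
    c("Wnt7b", "Fzd1", "WNT"),
    c("Shh", "Ptch1", "HH"),
    c("Vegfa", "Kdr", "VEGF"),
    c("Angpt1", "Tek", "ANGPT"),
    c("Il1b", "Il1r1", "IL1"))
  out <- data.frame(ligand = tab[, 1], receptor = tab[, 2],
                    pathway = tab[, 3], stringsAsFactors = FALSE)
  out[!duplicated(out[c("ligand", "receptor")]), ]
}

#' Rank cognate ligand-receptor channels between compartments
#'
#' A channel is emitted when a ligand sits in a flagged module of one
#' compartment and every subunit of a cognate receptor sits in a flagged
#' module of a different compartment. Channels are scored by the Spearman
#' correlation of the ligand's and receptor's bin-averaged expression
#' trends along the niche axis (receptor complexes use the subunit-mean
#' trend), and ranked by that correlation, then by the sum of module
#' scores.
#'
#' @param flagged named list per compartment: list of flagged modules
#'   (gene-set character vectors) with attribute-free scores supplied via
#'   `module_scores` (numeric per module, same order).
#' @param module_scores named list per compartment: numeric vector of the
#'   flagged modules' niche scores.
#' @param lr ligand-receptor table (see [builtin_lr_table()]).
#' @param trends named list per compartment: bins x genes trend matrix
#'   from [gene_trends()].
#' @return data.frame of channels: ligand, ligand_compartment, receptor,
#'   receptor_compartment, trend_rho, score; ranked best first.
#' @export
cognate_channels <- function(flagged, module_scores, lr, trends) {
  if (!nrow(lr)) stop("empty ligand-receptor table")
  find_module <- function(cmp, gene) {
    mods <- flagged[[cmp]]
    for (i in seq_along(mods)) if (gene %in% mods[[i]]) return(i)
    NA_integer_
  }
  rows <- list()
  cmps <- names(flagged)
  for (i in seq_len(nrow(lr))) {
    subunits <- strsplit(lr$receptor[i], ";")[[1]]
    for (ca in cmps) {
      mi <- find_module(ca, lr$ligand[i])
      if (is.na(mi)) next
      for (cb in setdiff(cmps, ca)) {
        mjs <- vapply(subunits, function(su) find_module(cb, su),
                      integer(1))
        if (anyNA(mjs)) next
        tl <- trends[[ca]][, lr$ligand[i]]
        tr_m <- trends[[cb]][, subunits, drop = FALSE]
        tr <- rowMeans(tr_m)
        ok <- !is.na(tl) & !is.na(tr)
        if (sum(ok) < 3) next
        rho <- suppressWarnings(
          stats::cor(tl[ok], tr[ok], method = "spearman"))
        score <- module_scores[[ca]][mi] + mean(module_scores[[cb]][mjs])
        rows[[length(rows) + 1]] <- data.frame(
          ligand = lr$ligand[i], ligand_compartment = ca,
          receptor = lr$receptor[i], receptor_compartment = cb,
          trend_rho = rho, score = score, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(ligand = character(0),
                      ligand_compartment = character(0),
                      receptor = character(0),
                      receptor_compartment = character(0),
                      trend_rho = numeric(0), score = numeric(0)))
  out <- do.call(rbind, rows)
  out[order(-out$trend_rho, -out$score), , drop = FALSE]
}
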