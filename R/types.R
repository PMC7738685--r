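#' Construct a protein-protein interaction network
#'
#' A `ppi_network` is an undirected simple graph over gene symbols. Gene
#' identity is the raw symbol string, case-sensitive; no alias resolution is
#' attempted. Self-loops and duplicate edges are dropped at construction.
#'
#' @param edges two-column character matrix or data.frame of gene pairs.
#' @param confidence optional numeric vector of per-edge confidence scores in
#'   `[0, 1]`, aligned with the rows of `edges`.
#' @return An object of class `ppi_network` with elements `graph` (an
#'   [igraph::graph] object), `nodes` (sorted gene symbols) and `adj`
#'   (adjacency list, gene -> sorted neighbor genes).
#' @export
ppi_network <- function(edges, confidence = NULL) {
  if (is.data.frame(edges)) edges <- as.matrix(edges[, 1:2])
  storage.mode(edges) <- "character"
  if (!is.null(confidence)) {
    dw_assert(length(confidence) == nrow(edges),
              "confidence must align with edges")
  }
  keep <- edges[, 1] != edges[, 2]            # no self-loops
  edges <- edges[keep, , drop = FALSE]
  if (!is.null(confidence)) confidence <- confidence[keep]
  # canonical unordered orientation, then de-duplicate (first occurrence wins)
  flip <- edges[, 1] > edges[, 2]
  edges[flip, ] <- edges[flip, 2:1]
  key <- paste(edges[, 1], edges[, 2], sep = "\r")
  dup <- duplicated(key)
  edges <- edges[!dup, , drop = FALSE]
  if (!is.null(confidence)) confidence <- confidence[!dup]
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  adj <- lapply(igraph::adjacent_vertices(g, igraph::V(g)),
                function(v) as_set(names(v)))
  names(adj) <- igraph::V(g)$name
  conf <- NULL
  if (!is.null(confidence)) {
    conf <- as.numeric(confidence)
    names(conf) <- key[!dup]
  }
  structure(
    list(graph = g, nodes = as_set(igraph::V(g)$name), adj = adj,
         confidence = conf),
    class = "ppi_network"
  )
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d genes, %d interactions%s\n",
              length(x$nodes), igraph::ecount(x$graph),
              if (is.null(x$confidence)) "" else " (with confidence scores)"))
  invisible(x)
}

# Neighborhood N(M): union of neighbors of the given genes (may include the
# genes themselves when they are adjacent to one another).
network_neighborhood <- function(net, genes) {
  as_set(unlist(net$adj[intersect(genes, net$nodes)], use.names = FALSE))
}

# deg(g, M): degree of `gene` in the subgraph induced by M union {gene}.
degree_in <- function(net, gene, module_genes) {
  nb <- net$adj[[gene]]
  if (is.null(nb)) return(0L)
  sum(nb %in% setdiff(module_genes, gene))
}

# Connectivity of the induced subgraph G(M); vacuously TRUE for one gene.
induced_connected <- function(net, genes) {
  genes <- intersect(genes, net$nodes)
  if (length(genes) <= 1L) return(length(genes) == 1L)
  sub <- igraph::induced_subgraph(net$graph, genes)
  igraph::is_connected(sub)
}

#' Construct a somatic mutation profile
#'
#' A `mutation_profile` maps each gene to the set of cohort samples in which
#' it carries a somatic mutation, together with the sample universe (all
#' cohort sample identifiers).
#'
#' @param samples_by_gene named list, gene -> character vector of sample ids.
#' @param sample_universe character vector of all sample ids; defaults to the
#'   union of all per-gene sample sets.
#' @return An object of class `mutation_profile`.
#' @export
mutation_profile <- function(samples_by_gene, sample_universe = NULL) {
  samples_by_gene <- lapply(samples_by_gene, as_set)
  observed <- as_set(unlist(samples_by_gene, use.names = FALSE))
  if (is.null(sample_universe)) {
    sample_universe <- observed
  } else {
    sample_universe <- as_set(sample_universe)
    dw_assert(all(observed %in% sample_universe),
              "per-gene sample sets must be subsets of the sample universe",
              "dw_data_error")
  }
  structure(list(samples_by_gene = samples_by_gene,
                 sample_universe = sample_universe),
            class = "mutation_profile")
}

#' @export
print.mutation_profile <- function(x, ...) {
  cat(sprintf("<mutation_profile> %d genes, %d samples in universe\n",
              length(x$samples_by_gene), length(x$sample_universe)))
  invisible(x)
}

# Sample sets of the given genes; genes absent from the profile contribute
# empty sets (permits scoring arbitrary reference gene sets).
profile_sets <- function(profile, genes) {
  lapply(genes, function(g) {
    s <- profile$samples_by_gene[[g]]
    if (is.null(s)) character(0) else s
  })
}

#' Construct a module (a gene set anchored at an optional seed)
#'
#' @param genes character vector of gene symbols (non-empty, de-duplicated).
#' @param seed optional seed gene the module was grown from.
#' @return An object of class `dw_module`.
#' @export
dw_module <- function(genes, seed = NULL) {
  genes <- as_set(genes)
  dw_assert(length(genes) >= 1L, "a module must contain at least one gene",
            "dw_data_error")
  if (!is.null(seed)) {
    dw_assert(seed %in% genes, "the seed must be a module member",
              "dw_data_error")
  }
  structure(list(genes = genes, seed = seed), class = "dw_module")
}

#' Construct an ordered module set
#'
#' Order is rank order (construction order for discovered modules). Gene sets
#' must be pairwise distinct.
#'
#' @param modules list of [dw_module] objects (bare character vectors are
#'   promoted).
#' @return An object of class `dw_module_set`.
#' @export
dw_module_set <- function(modules = list()) {
  modules <- lapply(modules, function(m) {
    if (inherits(m, "dw_module")) m else dw_module(m)
  })
  if (length(modules) >= 2L) {
    keys <- vapply(modules, function(m) paste(m$genes, collapse = "\r"), "")
    dw_assert(!anyDuplicated(keys),
              "module sets must contain pairwise distinct gene sets",
              "dw_data_error")
  }
  structure(list(modules = modules), class = "dw_module_set")
}

#' @export
length.dw_module_set <- function(x) length(x$modules)

#' @export
print.dw_module_set <- function(x, ...) {
  sizes <- vapply(x$modules, function(m) length(m$genes), 0L)
  cat(sprintf("<dw_module_set> %d modules, %d genes in total (%d unique)\n",
              length(x$modules), sum(sizes),
              length(as_set(unlist(lapply(x$modules, `[[`, "genes"))))))
  invisible(x)
}

module_genes_list <- function(module_set) {
  lapply(module_set$modules, `[[`, "genes")
}

#' Discovery parameters
#'
#' Tuning knobs of the seed-and-extend heuristic. `t` throttles how much new
#' coverage an added gene must bring relative to the module's accumulated
#' mutation mass (larger `t`, smaller modules); `d` relaxes the connectivity
#' requirement for genes already placed in earlier modules (larger `d`, more
#' overlap between modules). `delta_m` is the minimum module size and
#' `delta_s` the target total (summed) size of the output set.
#'
#' @param t coverage-ratio threshold (default 1.0).
#' @param d connectivity laxness (default 3).
#' @param delta_m minimum module size (default 3).
#' @param delta_s target total size (sum of module sizes).
#' @param min_mut_fraction minimum fraction of the cohort a gene must be
#'   mutated in to be considered (default 0.01).
#' @param optimizer `"fixed"` to run at (`t`, `d`) as given, `"search"` to
#'   optimize them by maximizing the module-set score.
#' @param n_evaluations evaluation budget for the search (default 30).
#' @param t_range,d_range search ranges (defaults `[0.8, 1.2]` and `[2, 5]`).
#' @param search_strategy `"bayes"` (Gaussian-process expected improvement)
#'   or `"grid"` (deterministic lattice).
#' @param rng_seed integer seed controlling every stochastic choice.
#' @return An object of class `dw_params`.
#' @export
dw_params <- function(t = 1.0, d = 3, delta_m = 3L, delta_s = 30L,
                      min_mut_fraction = 0.01, optimizer = c("fixed", "search"),
                      n_evaluations = 30L, t_range = c(0.8, 1.2),
                      d_range = c(2, 5), search_strategy = c("bayes", "grid"),
                      rng_seed = 42L) {
  optimizer <- match.arg(optimizer)
  search_strategy <- match.arg(search_strategy)
  dw_assert(t > 0, "t must be positive")
  dw_assert(d > 0, "d must be positive")
  dw_assert(delta_m >= 1, "delta_m must be at least 1")
  dw_assert(delta_s >= delta_m, "delta_s must be at least delta_m")
  dw_assert(min_mut_fraction >= 0 && min_mut_fraction <= 1,
            "min_mut_fraction must lie in [0, 1]")
  dw_assert(length(t_range) == 2 && t_range[1] > 0 && t_range[1] <= t_range[2],
            "t_range must be an increasing positive interval")
  dw_assert(length(d_range) == 2 && d_range[1] > 0 && d_range[1] <= d_range[2],
            "d_range must be an increasing positive interval")
  structure(list(t = t, d = d, delta_m = as.integer(delta_m),
                 delta_s = as.integer(delta_s),
                 min_mut_fraction = min_mut_fraction, optimizer = optimizer,
                 n_evaluations = as.integer(n_evaluations),
                 t_range = as.numeric(t_range), d_range = as.numeric(d_range),
                 search_strategy = search_strategy,
                 rng_seed = as.integer(rng_seed)),
            class = "dw_params")
}
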