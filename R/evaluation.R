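as_gene_sets <- function(x) {
  if (inherits(x, "dw_module_set")) return(module_genes_list(x))
  if (inherits(x, "dw_discovery")) return(module_genes_list(x$modules))
  stopifnot(is.list(x))
  lapply(x, module_genes)
}

set_names_for <- function(sets, prefix) {
  nm <- names(sets)
  if (is.null(nm) || any(!nzchar(nm))) {
    nm <- paste0(prefix, seq_along(sets))
  }
  nm
}

#' Hypergeometric enrichment q-values of modules against pathways
#'
#' For every module/pathway pair, the upper-tail hypergeometric probability
#' of observing an intersection at least as large as the one seen, drawing
#' `|module|` genes from the universe in which `|pathway|` genes are the
#' successes. Pathways are intersected with the universe first; module genes
#' must already lie inside it. Benjamini-Hochberg FDR correction is applied
#' jointly over all module x pathway tests.
#'
#' @param modules a [dw_module_set] or list of gene sets.
#' @param pathways named list of reference gene sets (see [read_gmt()]).
#' @param universe character vector of background genes.
#' @return Matrix of q-values (modules x pathways), with the raw p-values
#'   attached as attribute `"p"`.
#' @export
hypergeom_qvalues <- function(modules, pathways, universe) {
  mods <- as_gene_sets(modules)
  universe <- as_set(universe)
  bad <- !vapply(mods, function(m) all(m %in% universe), logical(1))
  if (any(bad)) {
    dw_stop("module genes must be contained in the universe", "dw_data_error")
  }
  paths <- lapply(pathways, function(p) intersect(as_set(p), universe))
  N <- length(universe)
  p_mat <- matrix(NA_real_, nrow = length(mods), ncol = length(paths),
                  dimnames = list(set_names_for(mods, "M"),
                                  set_names_for(paths, "R")))
  for (i in seq_along(mods)) {
    n_i <- length(mods[[i]])
    for (j in seq_along(paths)) {
      K <- length(paths[[j]])
      k <- length(intersect(mods[[i]], paths[[j]]))
      p_mat[i, j] <- stats::phyper(k - 1L, K, N - K, n_i, lower.tail = FALSE)
    }
  }
  q_mat <- matrix(stats::p.adjust(p_mat, method = "BH"),
                  nrow = nrow(p_mat), dimnames = dimnames(p_mat))
  attr(q_mat, "p") <- p_mat
  q_mat
}

#' Module-to-pathway similarity matrix
#'
#' Complete (zero-including) similarity matrix between predicted modules and
#' reference pathways under one of three measures: `"overlap"` (the squared
#' intersection over the size product), `"qvalue"` (`-log10` of the BH
#' q-value, zeroed when q exceeds 0.05; q-values of exactly 0 are clamped to
#' the smallest positive double first), or `"go"` (Jaccard similarity of the
#' unions of level-standardized GO terms; two empty unions give 0).
#'
#' @param modules a [dw_module_set] or list of gene sets.
#' @param pathways named list of reference gene sets.
#' @param measure one of `"overlap"`, `"qvalue"`, `"go"`.
#' @param universe background gene set (required for `"qvalue"`).
#' @param go_map a standardized annotation map from [standardize_go()]
#'   (required for `"go"`).
#' @param q_cutoff significance cutoff for the q-value measure (default
#'   0.05; the boundary itself counts as significant).
#' @return Numeric matrix (modules x pathways) with attribute `"measure"`.
#' @export
similarity_matrix <- function(modules, pathways,
                              measure = c("overlap", "qvalue", "go"),
                              universe = NULL, go_map = NULL,
                              q_cutoff = 0.05) {
  measure <- match.arg(measure)
  mods <- as_gene_sets(modules)
  paths <- lapply(pathways, as_set)
  rn <- set_names_for(mods, "M"); cn <- set_names_for(paths, "R")
  if (measure == "overlap") {
    w <- outer(seq_along(mods), seq_along(paths),
               Vectorize(function(i, j) pairwise_overlap(mods[[i]], paths[[j]])))
  } else if (measure == "qvalue") {
    dw_assert(!is.null(universe), "the qvalue measure needs a universe")
    q <- hypergeom_qvalues(mods, paths, universe)
    q <- pmax(q, .Machine$double.xmin)
    w <- ifelse(q > q_cutoff, 0, -log10(q))
  } else {
    dw_assert(!is.null(go_map), "the go measure needs a standardized annotation map")
    term_union <- function(genes) {
      as_set(unlist(go_map$terms_by_gene[
        intersect(genes, names(go_map$terms_by_gene))], use.names = FALSE))
    }
    tm <- lapply(mods, term_union)
    tp <- lapply(paths, term_union)
    w <- outer(seq_along(mods), seq_along(paths),
               Vectorize(function(i, j) {
                 u <- union(tm[[i]], tp[[j]])
                 if (length(u) == 0L) return(0)
                 length(intersect(tm[[i]], tp[[j]])) / length(u)
               }))
  }
  w <- matrix(as.numeric(w), nrow = length(mods),
              dimnames = list(rn, cn))
  attr(w, "measure") <- measure
  w
}

#' Maximum-weight maximum-cardinality matching and its mean matched weight
#'
#' Builds the complete bipartite graph between modules (rows) and pathways
#' (columns), zero-weight edges included, finds a matching of maximum
#' cardinality `min(#modules, #pathways)` whose total weight is maximal, and
#' averages the matched edge weights. Keeping the zero edges is what stops a
#' single perfect module among k from inflating the score: the mean is over
#' all `min(m, n)` matched edges, so it is `(1 + 0 + ... + 0) / k`, not 1.
#'
#' @param sim complete similarity matrix (see [similarity_matrix()]), all
#'   values `>= 0`.
#' @return An object of class `dw_match`: list with `matching` (data.frame
#'   `module`, `pathway`, `weight`), `total_weight`, `cardinality` and `mmr`.
#' @export
mmr <- function(sim) {
  m <- nrow(sim); n <- ncol(sim)
  if (is.null(m) || m == 0L || n == 0L) {
    dw_stop("similarity matrix is empty", "dw_data_error")
  }
  dw_assert(all(sim >= 0), "similarity weights must be non-negative",
            "dw_data_error")
  if (is.null(rownames(sim))) rownames(sim) <- paste0("M", seq_len(m))
  if (is.null(colnames(sim))) colnames(sim) <- paste0("R", seq_len(n))
  types <- c(rep(FALSE, m), rep(TRUE, n))
  edges <- as.vector(t(cbind(rep(seq_len(m), each = n),
                             m + rep(seq_len(n), times = m))))
  g <- igraph::make_bipartite_graph(types, edges)
  w <- as.vector(t(sim))
  match <- igraph::max_bipartite_match(g, weights = w)
  mate <- match$matching[seq_len(m)]           # row i -> matched column vertex
  pairs <- data.frame(row = integer(0), col = integer(0))
  for (i in seq_len(m)) {
    if (!is.na(mate[i])) {
      pairs <- rbind(pairs, data.frame(row = i, col = as.integer(mate[i]) - m))
    }
  }
  # extend to maximum cardinality with (necessarily zero-gain) leftover pairs
  card <- min(m, n)
  free_r <- setdiff(seq_len(m), pairs$row)
  free_c <- setdiff(seq_len(n), pairs$col)
  extra <- min(length(free_r), length(free_c), card - nrow(pairs))
  if (extra > 0L) {
    pairs <- rbind(pairs, data.frame(row = free_r[seq_len(extra)],
                                     col = free_c[seq_len(extra)]))
  }
  pairs <- pairs[order(pairs$row), , drop = FALSE]
  weight <- sim[cbind(pairs$row, pairs$col)]
  rn <- rownames(sim); cn <- colnames(sim)
  structure(list(
    matching = data.frame(module = rn[pairs$row], pathway = cn[pairs$col],
                          weight = weight, stringsAsFactors = FALSE),
    total_weight = sum(weight),
    cardinality = nrow(pairs),
    mmr = sum(weight) / card
  ), class = "dw_match")
}

#' @export
print.dw_match <- function(x, ...) {
  cat(sprintf("<dw_match> cardinality %d, total weight %.4f, MMR %.4f\n",
              x$cardinality, x$total_weight, x$mmr))
  invisible(x)
}

#' Best-match precision/recall tables and their product F1
#'
#' Precision side: for each module, the best similarity over all pathways
#' (row maxima). Recall side: for each pathway, the best similarity over all
#' modules (column maxima). The aggregate F1 is the product of the two
#' averages (not a harmonic mean).
#'
#' @param sim complete similarity matrix.
#' @return List with `per_module` and `per_pathway` data.frames (name, best
#'   counterpart, score) and the scalar `f1`.
#' @export
best_match_tables <- function(sim) {
  if (is.null(nrow(sim)) || nrow(sim) == 0L || ncol(sim) == 0L) {
    dw_stop("similarity matrix is empty", "dw_data_error")
  }
  if (is.null(rownames(sim))) rownames(sim) <- paste0("M", seq_len(nrow(sim)))
  if (is.null(colnames(sim))) colnames(sim) <- paste0("R", seq_len(ncol(sim)))
  rbest <- apply(sim, 1, max)
  cbest <- apply(sim, 2, max)
  per_module <- data.frame(
    module = rownames(sim),
    best_pathway = colnames(sim)[apply(sim, 1, which.max)],
    score = unname(rbest), stringsAsFactors = FALSE)
  per_pathway <- data.frame(
    pathway = colnames(sim),
    best_module = rownames(sim)[apply(sim, 2, which.max)],
    score = unname(cbest), stringsAsFactors = FALSE)
  list(per_module = per_module, per_pathway = per_pathway,
       f1 = mean(rbest) * mean(cbest))
}

#' Gene-level ROC points from ranked modules
#'
#' Accumulates modules in rank order until the number of unique genes first
#' reaches each cutoff, then scores the accumulated gene set against a
#' reference driver list: TPR is the fraction of reference genes recovered,
#' FPR the fraction of non-reference background genes included.
#'
#' @param ranked_modules a [dw_module_set] (rank order = list order).
#' @param reference character vector of reference driver genes.
#' @param background character vector of background genes (superset of the
#'   module genes).
#' @param cutoffs ascending integer vector of unique-gene counts.
#' @return data.frame with columns `cutoff`, `n_unique`, `tpr`, `fpr`.
#' @export
roc_points <- function(ranked_modules, reference, background, cutoffs) {
  mods <- as_gene_sets(ranked_modules)
  dw_assert(!is.unsorted(cutoffs), "cutoffs must be ascending")
  background <- as_set(background)
  all_genes <- as_set(unlist(mods))
  dw_assert(all(all_genes %in% background),
            "background must contain every module gene", "dw_data_error")
  ref <- intersect(as_set(reference), background)
  nonref <- setdiff(background, ref)
  prefixes <- character(0)
  uniq_at <- integer(length(mods))
  acc <- character(0)
  sets_at <- vector("list", length(mods))
  for (i in seq_along(mods)) {
    acc <- union(acc, mods[[i]])
    uniq_at[i] <- length(acc)
    sets_at[[i]] <- acc
  }
  out <- lapply(cutoffs, function(ct) {
    hit <- which(uniq_at >= ct)
    if (length(hit) == 0L) {
      warning(sprintf(
        "cutoff %d exceeds the %d available unique genes; using all modules",
        ct, uniq_at[length(uniq_at)]))
      top <- sets_at[[length(sets_at)]]
    } else {
      top <- sets_at[[hit[1]]]
    }
    data.frame(cutoff = ct, n_unique = length(top),
               tpr = length(intersect(top, ref)) / length(ref),
               fpr = length(setdiff(top, ref)) / length(nonref))
  })
  do.call(rbind, out)
}
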