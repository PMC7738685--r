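# Internal scoring core. The coverage denominator |union of S_j over the
# gene universe V| is fixed once per analysis (V = network genes surviving
# the frequency filter) and passed around as a single integer.

union_size <- function(profile, genes) {
  length(unique(unlist(profile$samples_by_gene[
    intersect(genes, names(profile$samples_by_gene))], use.names = FALSE)))
}

sum_sizes <- function(profile, genes) {
  sum(lengths(profile$samples_by_gene[
    intersect(genes, names(profile$samples_by_gene))]))
}

coverage_denominator <- function(profile, universe_genes) {
  d <- union_size(profile, universe_genes)
  if (d == 0L) {
    dw_stop("coverage undefined: no gene in the universe is mutated",
            "dw_data_error")
  }
  d
}

# MS and its factors from precomputed counts; NA mex (all-empty module) is
# the caller's error to raise.
ms_from_counts <- function(n_union, n_sum, denom) {
  cov <- n_union / denom
  mex <- if (n_sum == 0L) NA_real_ else n_union / n_sum
  list(cov = cov, mex = mex, ms = cov * mex)
}

module_genes <- function(module) {
  if (inherits(module, "dw_module")) module$genes else as_set(module)
}

#' Coverage of a module
#'
#' The fraction of mutation-covered cohort samples that carry a mutation in
#' at least one module gene: `|union of S_i over module| / |union of S_j
#' over the gene universe|`. Genes missing from the profile contribute
#' empty sample sets.
#'
#' @param module a [dw_module] or character vector of genes.
#' @param profile a [mutation_profile].
#' @param universe_genes the gene universe V defining the denominator
#'   (typically the network genes that survived the frequency filter).
#' @return Coverage in `[0, 1]`.
#' @export
coverage <- function(module, profile, universe_genes) {
  genes <- module_genes(module)
  denom <- coverage_denominator(profile, universe_genes)
  union_size(profile, genes) / denom
}

#' Mutual exclusivity of a module
#'
#' The ratio `|union of S_i| / sum of |S_i|` over the module's genes: equal
#' to 1 exactly when the per-gene mutated-sample sets are pairwise disjoint,
#' and decreasing toward 0 as samples are hit by several module genes.
#'
#' @inheritParams coverage
#' @return Mutual exclusivity in `(0, 1]`.
#' @export
mutual_exclusivity <- function(module, profile) {
  genes <- module_genes(module)
  n_sum <- sum_sizes(profile, genes)
  if (n_sum == 0L) {
    dw_stop("mutual exclusivity undefined: no module gene is mutated",
            "dw_data_error")
  }
  union_size(profile, genes) / n_sum
}

#' Module score (coverage times mutual exclusivity)
#'
#' @inheritParams coverage
#' @return List with elements `cov`, `mex` and `ms = cov * mex`.
#' @export
module_score <- function(module, profile, universe_genes) {
  genes <- module_genes(module)
  denom <- coverage_denominator(profile, universe_genes)
  n_sum <- sum_sizes(profile, genes)
  if (n_sum == 0L) {
    dw_stop("module score undefined: no module gene is mutated",
            "dw_data_error")
  }
  ms_from_counts(union_size(profile, genes), n_sum, denom)
}

#' Module-set score: the sum of per-module scores
#'
#' The objective maximized by both the greedy discovery heuristic and the
#' exact solver. Additive over the list of modules; uniqueness of modules is
#' a solution constraint, not a property of the score.
#'
#' @param module_set a [dw_module_set] (or plain list of gene sets).
#' @inheritParams coverage
#' @return The summed module score (a non-negative real).
#' @export
odmss <- function(module_set, profile, universe_genes) {
  mods <- if (inherits(module_set, "dw_module_set")) {
    module_genes_list(module_set)
  } else {
    module_set
  }
  if (length(mods) == 0L) return(0)
  sum(vapply(mods, function(g) module_score(g, profile, universe_genes)$ms,
             numeric(1)))
}

#' Pairwise overlap score of two gene sets
#'
#' `|a intersect b|^2 / (|a| * |b|)`: 1 exactly for identical sets, 0 for
#' disjoint ones, symmetric.
#'
#' @param a,b non-empty character vectors of genes.
#' @return Overlap score in `[0, 1]`.
#' @export
pairwise_overlap <- function(a, b) {
  a <- module_genes(a); b <- module_genes(b)
  if (length(a) == 0L || length(b) == 0L) {
    dw_stop("pairwise overlap undefined for empty sets", "dw_data_error")
  }
  length(intersect(a, b))^2 / (length(a) * length(b))
}

#' Average pairwise overlap of a module set
#'
#' Mean of [pairwise_overlap()] over all unordered module pairs; quantifies
#' how strongly the modules of a set overlap one another.
#'
#' @param module_set a [dw_module_set] (or plain list of gene sets) with at
#'   least two modules.
#' @return Mean pairwise overlap in `[0, 1]`.
#' @export
average_pairwise_overlap <- function(module_set) {
  mods <- if (inherits(module_set, "dw_module_set")) {
    module_genes_list(module_set)
  } else {
    module_set
  }
  n <- length(mods)
  if (n < 2L) {
    dw_stop("average pairwise overlap needs at least two modules",
            "dw_data_error")
  }
  tot <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      tot <- tot + pairwise_overlap(mods[[i]], mods[[j]])
    }
  }
  tot / choose(n, 2)
}
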