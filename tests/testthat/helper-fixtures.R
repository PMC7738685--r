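# Shared fixtures and independent oracles, built in code at test time.

# triangle a-b-c with pairwise-disjoint singleton mutations: MS({a,b,c}) = 1
tri_network <- function() {
  ppi_network(cbind(c("a", "b", "a"), c("b", "c", "c")))
}

tri_profile <- function() {
  mutation_profile(list(a = "s1", b = "s2", c = "s3"))
}

# random small instance for exact-solver oracles
random_instance <- function(seed, n_range = 5:8, edge_p = 0.4,
                            n_samples = 12, max_muts = 5) {
  set.seed(seed)
  n <- sample(n_range, 1)
  g <- igraph::sample_gnp(n, edge_p)
  igraph::V(g)$name <- letters[seq_len(n)]
  el <- igraph::as_edgelist(g)
  if (nrow(el) == 0) return(NULL)
  net <- ppi_network(el)
  sets <- stats::setNames(lapply(seq_len(n), function(i) {
    sample(paste0("s", seq_len(n_samples)), sample(0:max_muts, 1))
  }), letters[seq_len(n)])
  sets <- sets[lengths(sets) > 0]
  if (length(sets) == 0 || length(intersect(net$nodes, names(sets))) == 0) {
    return(NULL)
  }
  list(network = net, profile = mutation_profile(sets))
}

# oracle: all connected vertex sets by testing every subset
brute_connected_sets <- function(net, min_s, max_s) {
  n <- length(net$nodes)
  out <- list()
  for (mask in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) < min_s || length(idx) > max_s) next
    gs <- net$nodes[idx]
    if (igraph::is_connected(igraph::induced_subgraph(net$graph, gs))) {
      out[[length(out) + 1]] <- sort(gs)
    }
  }
  out
}

safe_ms <- function(genes, profile, universe) {
  s <- tryCatch(module_score(genes, profile, universe)$ms,
                error = function(e) 0)
  if (is.na(s)) 0 else s
}

# oracle: best summed score over families of distinct catalog entries whose
# sizes sum exactly to `target`, by exhaustive recursion
brute_best_odmss <- function(cat_sets, scores, target) {
  sizes <- lengths(cat_sets)
  best <- -Inf
  rec <- function(i, left, acc) {
    if (left == 0) {
      best <<- max(best, acc)
      return()
    }
    if (i > length(cat_sets) || left < 0) return()
    rec(i + 1, left, acc)
    if (sizes[i] <= left) rec(i + 1, left - sizes[i], acc + scores[i])
  }
  rec(1, target, 0)
  best
}

# oracle: maximum total weight over all injections of rows into columns
# (or columns into rows when cols < rows)
brute_match_weight <- function(w) {
  if (ncol(w) < nrow(w)) w <- t(w)
  m <- nrow(w); n <- ncol(w)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- -Inf
  for (cols in utils::combn(n, m, simplify = FALSE)) {
    for (p in perms(cols)) {
      best <- max(best, sum(w[cbind(seq_len(m), p)]))
    }
  }
  best
}

# oracle: hypergeometric upper tail by enumerating every possible draw
brute_hyper_tail <- function(N, K, n, k_obs) {
  universe <- seq_len(N)
  successes <- seq_len(K)
  draws <- utils::combn(N, n, simplify = FALSE)
  mean(vapply(draws, function(d) length(intersect(d, successes)) >= k_obs,
              logical(1)))
}

# random mutation profile over a small cohort (for scoring properties)
random_profile <- function(seed, n_genes = 6, n_samples = 10,
                           max_muts = 4, allow_empty = TRUE) {
  set.seed(seed)
  sets <- stats::setNames(lapply(seq_len(n_genes), function(i) {
    sample(paste0("s", seq_len(n_samples)),
           sample((if (allow_empty) 0 else 1):max_muts, 1))
  }), paste0("g", seq_len(n_genes)))
  mutation_profile(sets, sample_universe = paste0("s", seq_len(n_samples)))
}
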