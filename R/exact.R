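#' Enumerate all connected induced subgraphs within a size window
#'
#' Recursive node-anchored extension: every connected vertex set is
#' generated exactly once from its lexicographically smallest member.
#' Intended for small instances (tens of nodes, window width a handful).
#'
#' @param network a [ppi_network].
#' @param min_size,max_size inclusive size window (`1 <= min_size <=
#'   max_size`).
#' @param cap abort with a resource error when more than this many entries
#'   would be produced (default `1e6`).
#' @return A list of character vectors (gene sets), each inducing a
#'   connected subgraph, sizes within the window, no duplicates.
#' @export
enumerate_connected_subgraphs <- function(network, min_size, max_size,
                                          cap = 1e6) {
  dw_assert(min_size >= 1 && min_size <= max_size,
            "need 1 <= min_size <= max_size")
  nodes <- network$nodes
  n <- length(nodes)
  idx <- seq_len(n)
  names(idx) <- nodes
  adj <- lapply(nodes, function(g) sort(unname(idx[network$adj[[g]]])))

  out <- vector("list", 1024L)
  count <- 0L
  emit <- function(sub) {
    count <<- count + 1L
    if (count > cap) {
      dw_stop(sprintf(
        "connected-subgraph catalog exceeds cap (%g); use a smaller instance",
        cap), "dw_resource_error")
    }
    if (count > length(out)) out[[2L * count]] <<- NULL  # grow
    out[[count]] <<- sub
  }
  # ext: extension candidates (> anchor, adjacent to sub, not yet chosen);
  # forb: sub plus its whole neighborhood above the anchor -- only vertices
  # outside it may enter ext, which makes each vertex set reachable exactly
  # once. Removing a tried vertex from ext before recursing keeps sibling
  # branches disjoint.
  extend <- function(sub, ext, forb) {
    if (length(sub) >= min_size) emit(sub)
    if (length(sub) == max_size || length(ext) == 0L) return()
    while (length(ext) > 0L) {
      v <- ext[1L]
      ext <- ext[-1L]
      fresh <- setdiff(adj[[v]][adj[[v]] > sub[1L]], forb)
      extend(c(sub, v), c(ext, fresh), c(forb, fresh))
    }
  }
  for (v in idx) {
    ext0 <- adj[[v]][adj[[v]] > v]
    extend(v, ext0, c(v, ext0))
  }
  lapply(out[seq_len(count)], function(s) nodes[sort(s)])
}

#' Exact solver for the overlapping driver module selection problem
#'
#' Enumerates every connected induced subgraph in the admissible size
#' window, scores each by MS, and selects a subset of distinct entries
#' whose sizes sum exactly to `delta_s` maximizing the summed score, by
#' dynamic programming over (entry, total size). With
#' `enforce_lemma_window = TRUE` (default) the window is
#' `[delta_m, 2 * delta_m)`, which provably still contains an optimum;
#' otherwise it is `[delta_m, delta_s]`. Pseudo-polynomial: practical for
#' networks of a few dozen nodes.
#'
#' @param network a [ppi_network].
#' @param profile a [mutation_profile].
#' @param delta_m minimum module size.
#' @param delta_s exact total size of the selected set.
#' @param enforce_lemma_window restrict module sizes to below `2 * delta_m`.
#' @param universe_genes coverage-denominator universe; defaults to the
#'   mutated network genes.
#' @param cap catalog size cap (see [enumerate_connected_subgraphs()]).
#' @return An object of class `dw_exact`: list with `feasible` (logical),
#'   and when feasible `modules` (a [dw_module_set]), `odmss`, plus the
#'   `catalog_size` used.
#' @export
solve_exact <- function(network, profile, delta_m, delta_s,
                        enforce_lemma_window = TRUE, universe_genes = NULL,
                        cap = 1e6) {
  delta_m <- as.integer(delta_m); delta_s <- as.integer(delta_s)
  if (delta_s < delta_m) {
    return(structure(list(feasible = FALSE, modules = NULL, odmss = NA_real_,
                          catalog_size = 0L),
                     class = "dw_exact"))
  }
  if (is.null(universe_genes)) {
    universe_genes <- intersect(network$nodes, names(profile$samples_by_gene))
  }
  denom <- coverage_denominator(profile, universe_genes)
  max_size <- if (enforce_lemma_window) {
    min(2L * delta_m - 1L, delta_s)
  } else {
    delta_s
  }
  catalog <- enumerate_connected_subgraphs(network, delta_m, max_size,
                                           cap = cap)
  p <- length(catalog)
  sizes <- lengths(catalog)
  score <- vapply(catalog, function(g) {
    ms_from_counts(union_size(profile, g), sum_sizes(profile, g), denom)$ms
  }, numeric(1))
  score[is.na(score)] <- 0   # modules with no mutated gene contribute nothing

  # c[i+1, j+1]: best total score using entries 1..i at exact total size j
  c_tab <- matrix(-Inf, nrow = p + 1L, ncol = delta_s + 1L)
  c_tab[1L, 1L] <- 0
  for (i in seq_len(p)) {
    prev <- c_tab[i, ]
    cur <- prev
    s <- sizes[i]
    if (s <= delta_s) {
      src <- seq_len(delta_s + 1L - s)
      take <- prev[src] + score[i]
      dst <- src + s
      upd <- take > cur[dst]
      cur[dst][upd] <- take[upd]
    }
    c_tab[i + 1L, ] <- cur
  }
  best <- c_tab[p + 1L, delta_s + 1L]
  if (!is.finite(best)) {
    return(structure(list(feasible = FALSE, modules = NULL, odmss = NA_real_,
                          catalog_size = p),
                     class = "dw_exact"))
  }
  # reconstruct: prefer "not used" when both branches attain the value
  chosen <- integer(0)
  j <- delta_s + 1L
  for (i in rev(seq_len(p))) {
    if (c_tab[i, j] == c_tab[i + 1L, j]) next
    chosen <- c(chosen, i)
    j <- j - sizes[i]
  }
  mods <- dw_module_set(catalog[rev(chosen)])
  structure(list(feasible = TRUE, modules = mods, odmss = best,
                 catalog_size = p),
            class = "dw_exact")
}

#' @export
print.dw_exact <- function(x, ...) {
  if (!x$feasible) {
    cat("<dw_exact> infeasible total size\n")
  } else {
    cat(sprintf("<dw_exact> %d modules, ODMSS %.6f (catalog of %d subgraphs)\n",
                length(x$modules), x$odmss, x$catalog_size))
  }
  invisible(x)
}

#' Check that the restricted size window loses no optimality
#'
#' Solves the same instance twice -- once with module sizes restricted to
#' `[delta_m, 2 * delta_m)` and once with the unrestricted window
#' `[delta_m, delta_s]` -- and reports both optima. They are expected to be
#' equal: any module of size at least `2 * delta_m` can be split into
#' connected parts without lowering the summed score.
#'
#' @inheritParams solve_exact
#' @return List with `windowed`, `unwindowed` (both `dw_exact`), `feasible`
#'   and `equal` (optima equal within `1e-9`, or both infeasible).
#' @export
verify_lemma_window <- function(network, profile, delta_m, delta_s,
                                universe_genes = NULL, cap = 1e6) {
  w <- solve_exact(network, profile, delta_m, delta_s,
                   enforce_lemma_window = TRUE,
                   universe_genes = universe_genes, cap = cap)
  u <- solve_exact(network, profile, delta_m, delta_s,
                   enforce_lemma_window = FALSE,
                   universe_genes = universe_genes, cap = cap)
  feas <- w$feasible && u$feasible
  equal <- if (!w$feasible && !u$feasible) {
    TRUE
  } else if (xor(w$feasible, u$feasible)) {
    FALSE
  } else {
    abs(w$odmss - u$odmss) <= 1e-9
  }
  list(windowed = w, unwindowed = u, feasible = feas, equal = equal)
}
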