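# Greedy seed-and-extend discovery of possibly overlapping driver modules.
#
# Strict-improvement tolerance for the add/remove compete step: two MS values
# closer than this are treated as equal, so floating noise can neither stall
# nor loop the growth.
MS_TOL <- 1e-12

#' Rank seed genes by the module score of their extended neighborhood
#'
#' Each surviving network gene g is scored by `MS(N_e(g))`, the module score
#' of g together with its direct neighbors -- a measure of how fit the gene
#' is for immediate growth. Genes are sorted nonincreasingly by this score;
#' ties are broken by descending mutated-sample count, then by gene symbol.
#'
#' @param network a [ppi_network].
#' @param profile a frequency-filtered [mutation_profile] (see
#'   [filter_low_frequency_genes()]).
#' @param universe_genes optional gene universe for the coverage denominator;
#'   defaults to the mutated network genes.
#' @return A data.frame with columns `gene` and `score`, ordered by rank.
#' @export
rank_seeds <- function(network, profile, universe_genes = NULL) {
  mutated <- names(profile$samples_by_gene)[
    lengths(profile$samples_by_gene) > 0L]
  seeds <- intersect(network$nodes, mutated)
  if (length(seeds) == 0L) {
    dw_stop("no mutated gene appears in the network", "dw_data_error")
  }
  if (is.null(universe_genes)) universe_genes <- seeds
  denom <- coverage_denominator(profile, universe_genes)
  score <- vapply(seeds, function(g) {
    ext <- union(network$adj[[g]], g)
    ms_from_counts(union_size(profile, ext), sum_sizes(profile, ext), denom)$ms
  }, numeric(1))
  n_mut <- lengths(profile$samples_by_gene[seeds])
  ord <- order(-score, -n_mut, seeds)
  data.frame(gene = seeds[ord], score = score[ord],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Candidate genes for extending a module
#'
#' A neighbor g of the current module M is a candidate when (1) the sample
#' union of M plus g, relative to M's summed per-gene sample counts, exceeds
#' the threshold `t` (it must bring enough fresh coverage relative to the
#' module's mutation mass), and (2) g is at least `1/d` times as connected
#' to M as it is, on average, to the earlier modules it already belongs to.
#' A gene that belongs to no earlier module passes condition (2) vacuously,
#' as does one whose average prior-module degree is zero. Membership in
#' earlier modules does not exclude a gene -- this is what permits overlaps.
#'
#' @param current character vector: the genes of the module being grown.
#' @param prior_modules list of gene sets of the already constructed modules.
#' @param network a [ppi_network].
#' @param profile a [mutation_profile].
#' @param t,d the coverage-ratio and connectivity-laxness parameters.
#' @return Character vector of candidate genes (possibly empty).
#' @export
candidate_set <- function(current, prior_modules, network, profile, t, d) {
  n_sum <- sum_sizes(profile, current)
  dw_assert(n_sum > 0, "current module has no mutated gene", "dw_data_error")
  cand <- setdiff(network_neighborhood(network, current), current)
  if (length(cand) == 0L) return(character(0))
  cur_samples <- unique(unlist(profile$samples_by_gene[
    intersect(current, names(profile$samples_by_gene))], use.names = FALSE))
  ok <- vapply(cand, function(g) {
    s <- profile$samples_by_gene[[g]]
    u <- length(cur_samples) + length(setdiff(s, cur_samples))
    if (!(u / n_sum > t)) return(FALSE)
    in_prior <- vapply(prior_modules, function(m) g %in% m, logical(1))
    if (!any(in_prior)) return(TRUE)
    mean_deg <- mean(vapply(prior_modules[in_prior],
                            function(m) degree_in(network, g, m), numeric(1)))
    if (mean_deg == 0) return(TRUE)
    degree_in(network, g, current) / mean_deg > 1 / d
  }, logical(1))
  cand[ok]
}

# One grown module from a seed. At each step the best single-gene addition
# from the candidate set (all tied maximizers added together) competes with
# the best legal removal (non-seed genes whose individual removal keeps the
# module connected; tied maximizers removed together, falling back to the
# first alone if the joint removal would disconnect). The larger strict MS
# improvement is committed; addition wins ties. MS is asserted to increase
# strictly across accepted steps, which bounds the iteration count.
grow_module_impl <- function(seed, prior_modules, network, profile, params,
                             denom) {
  current <- seed
  ms_cur <- ms_from_counts(union_size(profile, current),
                           sum_sizes(profile, current), denom)$ms
  trace <- ms_cur
  repeat {
    if (length(trace) > 10000L) {
      dw_stop("module growth failed to terminate", "dw_internal_error")
    }
    ms_of <- function(genes) {
      ms_from_counts(union_size(profile, genes),
                     sum_sizes(profile, genes), denom)$ms
    }
    # best addition
    cs <- sort(candidate_set(current, prior_modules, network, profile,
                             params$t, params$d))
    add_module <- NULL; ms_add <- -Inf
    if (length(cs) > 0L) {
      gains <- vapply(cs, function(g) ms_of(c(current, g)), numeric(1))
      best <- max(gains)
      tied <- cs[gains >= best - MS_TOL]
      add_module <- as_set(c(current, tied))
      ms_add <- ms_of(add_module)
    }
    # best removal
    rem_module <- NULL; ms_rem <- -Inf
    removable <- setdiff(current, seed)
    if (length(removable) > 0L) {
      removable <- removable[vapply(removable, function(g) {
        induced_connected(network, setdiff(current, g))
      }, logical(1))]
    }
    if (length(removable) > 0L) {
      removable <- sort(removable)
      losses <- vapply(removable, function(g) ms_of(setdiff(current, g)),
                       numeric(1))
      best <- max(losses)
      tied <- removable[losses >= best - MS_TOL]
      rem_module <- setdiff(current, tied)
      if (length(tied) > 1L && !induced_connected(network, rem_module)) {
        rem_module <- setdiff(current, tied[1])   # joint removal disconnects
      }
      ms_rem <- ms_of(rem_module)
    }
    gain_add <- ms_add - ms_cur
    gain_rem <- ms_rem - ms_cur
    if (max(gain_add, gain_rem) <= MS_TOL) break
    if (gain_add >= gain_rem) {                   # addition wins ties
      current <- add_module
      ms_cur <- ms_add
    } else {
      current <- rem_module
      ms_cur <- ms_rem
    }
    stopifnot(ms_cur > trace[length(trace)])      # strict MS monotonicity
    trace <- c(trace, ms_cur)
  }
  list(genes = current, trace = trace)
}

#' Grow a single module from a seed gene
#'
#' @param seed the seed gene; must not belong to any module in
#'   `prior_modules`.
#' @param prior_modules list of gene sets of already constructed modules (or
#'   a [dw_module_set]).
#' @param network a [ppi_network].
#' @param profile a frequency-filtered [mutation_profile].
#' @param params a [dw_params] (`t`, `d` are used).
#' @param universe_genes optional coverage-denominator universe; defaults to
#'   the mutated network genes.
#' @return A [dw_module], with attribute `trace` holding the accepted MS
#'   values (strictly increasing).
#' @export
grow_module <- function(seed, prior_modules, network, profile, params,
                        universe_genes = NULL) {
  if (inherits(prior_modules, "dw_module_set")) {
    prior_modules <- module_genes_list(prior_modules)
  }
  dw_assert(!any(vapply(prior_modules, function(m) seed %in% m, logical(1))),
            "the seed must not belong to an existing module", "dw_data_error")
  if (is.null(universe_genes)) {
    universe_genes <- intersect(network$nodes, names(profile$samples_by_gene))
  }
  denom <- coverage_denominator(profile, universe_genes)
  res <- grow_module_impl(seed, prior_modules, network, profile, params, denom)
  out <- dw_module(res$genes, seed = seed)
  attr(out, "trace") <- res$trace
  out
}

#' Build the set of overlapping driver modules
#'
#' Runs the full greedy pipeline: frequency-filter the mutation profile,
#' rank the seeds, and repeatedly grow a module from the highest-ranking
#' seed that is not yet inside an existing module. Grown modules smaller
#' than `delta_m`, or duplicating an earlier module, are discarded (their
#' seed is consumed). Construction stops once the summed module size reaches
#' `delta_s`; the last module is kept whole, so the total may overshoot by
#' at most that module's size minus one. If the seeds run out first, the
#' partial set is returned with a warning.
#'
#' @param network a [ppi_network].
#' @param profile a [mutation_profile] (filtered internally using
#'   `params$min_mut_fraction`).
#' @param params a [dw_params].
#' @return An object of class `dw_discovery`: a list with `modules` (a
#'   [dw_module_set]), `scores` (data.frame `cov`/`mex`/`ms` per module),
#'   `odmss`, `total_size`, `universe_genes`, `seed_ranking`, `traces` and
#'   `params`.
#' @export
build_module_set <- function(network, profile, params = dw_params()) {
  profile <- filter_low_frequency_genes(profile, params$min_mut_fraction)
  universe <- intersect(network$nodes, names(profile$samples_by_gene)[
    lengths(profile$samples_by_gene) > 0L])
  ranking <- rank_seeds(network, profile, universe_genes = universe)
  denom <- coverage_denominator(profile, universe)

  modules <- list()
  keys <- character(0)
  traces <- list()
  total <- 0L
  for (seed in ranking$gene) {
    if (total >= params$delta_s) break
    if (any(vapply(modules, function(m) seed %in% m$genes, logical(1)))) next
    res <- grow_module_impl(seed, lapply(modules, `[[`, "genes"),
                            network, profile, params, denom)
    if (length(res$genes) < params$delta_m) next          # too small
    key <- paste(res$genes, collapse = "\r")
    if (key %in% keys) next                               # duplicate
    m <- dw_module(res$genes, seed = seed)
    modules <- c(modules, list(m))
    keys <- c(keys, key)
    traces <- c(traces, list(res$trace))
    total <- total + length(res$genes)
  }
  if (total < params$delta_s) {
    warning(sprintf(
      "seeds exhausted at total size %d before reaching delta_s = %d; returning partial set",
      total, params$delta_s))
  }
  mset <- dw_module_set(modules)
  scores <- do.call(rbind, lapply(modules, function(m) {
    s <- ms_from_counts(union_size(profile, m$genes),
                        sum_sizes(profile, m$genes), denom)
    data.frame(cov = s$cov, mex = s$mex, ms = s$ms)
  }))
  if (is.null(scores)) {
    scores <- data.frame(cov = numeric(0), mex = numeric(0), ms = numeric(0))
  }
  structure(list(modules = mset, scores = scores, odmss = sum(scores$ms),
                 total_size = total, universe_genes = universe,
                 seed_ranking = ranking, traces = traces, params = params),
            class = "dw_discovery")
}

#' @export
print.dw_discovery <- function(x, ...) {
  cat(sprintf("<dw_discovery> %d modules, total size %d, ODMSS %.4f (t = %g, d = %g)\n",
              length(x$modules), x$total_size, x$odmss,
              x$params$t, x$params$d))
  invisible(x)
}

#' Choose t and d by maximizing the module-set score
#'
#' Evaluates [build_module_set()] at up to `params$n_evaluations` points of
#' the `(t, d)` box and returns the evaluated point with the largest summed
#' module score, together with its module set. Two strategies share this
#' interface: `"bayes"` (Gaussian-process surrogate with expected-improvement
#' acquisition) and `"grid"` (a deterministic lattice). Both are fully
#' deterministic given `params$rng_seed`. A point whose evaluation fails
#' scores `-Inf` and is skipped, not fatal.
#'
#' @param network a [ppi_network].
#' @param profile a [mutation_profile].
#' @param params a [dw_params] with `optimizer = "search"`.
#' @return A list with `params` (the input params at the best `(t, d)`,
#'   `optimizer` reset to `"fixed"`), `result` (the winning `dw_discovery`)
#'   and `history` (data.frame of evaluated `t`, `d`, `odmss`).
#' @export
optimize_params <- function(network, profile, params) {
  dw_assert(params$optimizer == "search",
            "optimize_params requires optimizer = \"search\"")
  evaluate <- function(x) {
    p <- params
    p$t <- x[1]; p$d <- x[2]
    tryCatch(suppressWarnings(build_module_set(network, profile, p)),
             error = function(e) NULL)
  }
  cache <- new.env(parent = emptyenv())
  objective <- function(x) {
    key <- paste(format(x, digits = 15), collapse = ",")
    res <- evaluate(x)
    assign(key, res, envir = cache)
    if (is.null(res)) -Inf else res$odmss
  }
  lower <- c(params$t_range[1], params$d_range[1])
  upper <- c(params$t_range[2], params$d_range[2])
  if (params$search_strategy == "grid") {
    nt <- max(1L, ceiling(sqrt(params$n_evaluations)))
    nd <- max(1L, ceiling(params$n_evaluations / nt))
    grid_pts <- function(lo, hi, k) if (k == 1L) (lo + hi) / 2 else seq(lo, hi, length.out = k)
    pts <- expand.grid(t = grid_pts(lower[1], upper[1], nt),
                       d = grid_pts(lower[2], upper[2], nd))
    pts <- as.matrix(pts[seq_len(min(nrow(pts), params$n_evaluations)), ,
                         drop = FALSE])
    ys <- apply(pts, 1, objective)
    history <- data.frame(t = pts[, 1], d = pts[, 2], odmss = ys)
  } else {
    bo <- dw_bayes_opt(objective, lower, upper,
                       n_calls = params$n_evaluations,
                       seed = params$rng_seed)
    history <- data.frame(t = bo$X[, 1], d = bo$X[, 2], odmss = bo$y)
  }
  if (!any(is.finite(history$odmss))) {
    dw_stop("every parameter evaluation failed", "dw_data_error")
  }
  best <- which.max(history$odmss)   # first maximum: deterministic tie-break
  key <- paste(format(c(history$t[best], history$d[best]), digits = 15),
               collapse = ",")
  out_params <- params
  out_params$t <- history$t[best]
  out_params$d <- history$d[best]
  out_params$optimizer <- "fixed"
  list(params = out_params, result = get(key, envir = cache),
       history = history)
}
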