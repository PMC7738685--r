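test_that("seeds are ranked by extended-neighborhood module score, ties broken deterministically", {
  # star: hub with 4 leaves, disjoint singleton mutations, 5 covered samples
  net <- ppi_network(cbind("h", paste0("l", 1:4)))
  prof <- mutation_profile(stats::setNames(
    as.list(paste0("s", 1:5)), c("h", paste0("l", 1:4))))
  rk <- rank_seeds(net, prof)
  expect_equal(rk$gene[1], "h")
  expect_equal(rk$score[1], 1.0)
  # every leaf: N_e = {leaf, hub} covering 2 of 5 samples, fully exclusive
  expect_equal(rk$score[rk$gene == "l1"], 0.4)
  expect_equal(nrow(rk), 5)

  # a gene whose only neighbor is unmutated: MS(N_e) = own coverage
  net2 <- ppi_network(rbind(c("iso", "pad"), c("w", "pad")))
  prof2 <- mutation_profile(list(iso = "s6", w = paste0("s", 7:10),
                                 big = paste0("s", 1:5)))
  rk2 <- rank_seeds(net2, prof2, universe_genes = c("iso", "w", "big"))
  expect_equal(rk2$score[rk2$gene == "iso"], 0.1)

  # equal scores and equal mutation counts: lexicographic order, stable
  net3 <- ppi_network(rbind(c("b", "x"), c("a", "y")))
  prof3 <- mutation_profile(list(a = "s1", b = "s2"))
  rk3 <- rank_seeds(net3, prof3)
  expect_equal(rk3$gene, c("a", "b"))
  expect_identical(rk3, rank_seeds(net3, prof3))

  expect_error(rank_seeds(net3, mutation_profile(list(zzz = "s1"))),
               class = "dw_data_error")
})

test_that("candidate set implements the coverage and connectivity inequalities", {
  net <- ppi_network(rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  prof <- mutation_profile(list(a = "s1", b = "s2", c = "s3"))
  # fresh coverage: union(M+c)/sum(M) = 3/2 > 1
  expect_equal(candidate_set(c("a", "b"), list(), net, prof, t = 1, d = 3),
               "c")
  # no fresh coverage: 2/2 = 1 is not strictly above t = 1
  prof2 <- mutation_profile(list(a = "s1", b = "s2", c = "s1"))
  expect_length(candidate_set(c("a", "b"), list(), net, prof2, t = 1, d = 3),
                0)
  # membership in an earlier module does not exclude a gene, but throttles it:
  # deg(c, M)/mean_deg(c) = 1/2, admitted only when 1/d < 1/2
  net2 <- ppi_network(rbind(c("a", "c"), c("c", "d"), c("c", "e"),
                            c("d", "e"), c("a", "b")))
  prof3 <- mutation_profile(list(a = "s1", b = "s2", c = "s3", d = "s4",
                                 e = "s5"))
  prior <- list(c("c", "d", "e"))
  expect_true("c" %in% candidate_set(c("a", "b"), prior, net2, prof3,
                                     t = 1, d = 3))
  expect_false("c" %in% candidate_set(c("a", "b"), prior, net2, prof3,
                                      t = 1, d = 1.5))
})

test_that("module growth on the triangle reaches the global optimum and stops", {
  net <- tri_network(); prof <- tri_profile()
  m <- grow_module("a", list(), net, prof, dw_params(t = 1, d = 3))
  expect_equal(m$genes, c("a", "b", "c"))
  tr <- attr(m, "trace")
  expect_true(all(diff(tr) > 0))
  expect_equal(tr[length(tr)], 1.0)
  # exhaustive check: 1.0 is the maximum over every connected vertex set
  best <- max(vapply(brute_connected_sets(net, 1, 3),
                     safe_ms, numeric(1), prof, c("a", "b", "c")))
  expect_equal(tr[length(tr)], best)
})

test_that("a neighbor adding no fresh coverage is never added", {
  net <- ppi_network(cbind("a", "b"))
  prof <- mutation_profile(list(a = "s1", b = "s1"))
  m <- grow_module("a", list(), net, prof, dw_params(t = 1, d = 3))
  expect_equal(m$genes, "a")
})

test_that("the remove step can win the compete and falls back on disconnecting joint removals", {
  # square a-b-c-d-a; b and d carry the same single sample, c a fresh one.
  # The tied additions {b,d} enter together; after c arrives, removing either
  # b or d is the best single change (tied), their joint removal would
  # disconnect, and the fallback removal lifts MS to its optimum.
  net <- ppi_network(rbind(c("a", "b"), c("b", "c"), c("c", "d"),
                           c("d", "a")))
  prof <- mutation_profile(list(a = "s1", b = "s2", c = "s3", d = "s2"))
  m <- grow_module("a", list(), net, prof, dw_params(t = 0.1, d = 3))
  expect_equal(m$genes, c("a", "c", "d"))
  tr <- attr(m, "trace")
  expect_true(all(diff(tr) > 0))
  expect_equal(tr[length(tr)], 1.0)
})

test_that("module-set construction satisfies the solution constraints on synthetic data", {
  for (k in 1:10) {
    spec <- synthetic_spec(rng_seed = k)
    sim <- generate_synthetic(spec)
    ds <- sum(lengths(sim$truth$modules))
    p <- dw_params(t = 1, d = 3, delta_m = 3, delta_s = ds)
    res <- suppressWarnings(build_module_set(sim$network, sim$profile, p))
    genes_list <- lapply(res$modules$modules, `[[`, "genes")
    expect_gt(length(genes_list), 0)
    # connectivity, minimum size, seed membership, uniqueness
    for (m in res$modules$modules) {
      expect_true(igraph::is_connected(
        igraph::induced_subgraph(sim$network$graph, m$genes)))
      expect_gte(length(m$genes), p$delta_m)
      expect_true(m$seed %in% m$genes)
    }
    keys <- vapply(genes_list, paste, "", collapse = ",")
    expect_false(anyDuplicated(keys) > 0)
    # total size within the allowed overshoot window (unless seeds ran out)
    last <- length(genes_list[[length(genes_list)]])
    expect_lte(res$total_size, ds + last - 1)
    # accepted growth steps strictly increase MS
    for (tr in res$traces) expect_true(all(diff(tr) > 0))
    expect_equal(res$odmss, sum(res$scores$ms))
  }
})

test_that("construction stops once the total size reaches its target", {
  net <- tri_network(); prof <- tri_profile()
  res <- build_module_set(net, prof,
                          dw_params(t = 1, d = 3, delta_m = 3, delta_s = 3,
                                    min_mut_fraction = 0))
  expect_length(res$modules$modules, 1)
  expect_equal(res$total_size, 3)
  expect_warning(
    build_module_set(net, prof,
                     dw_params(t = 1, d = 3, delta_m = 3, delta_s = 50,
                               min_mut_fraction = 0)),
    "exhausted")
})

test_that("noiseless planted cliques are recovered exactly and match the exact optimum", {
  spec <- synthetic_spec(n_genes = 6, n_samples = 60, n_modules = 2,
                         module_size_range = c(3, 3), overlap_genes = 0,
                         p_in = 1, p_bg = 0, passenger_rate = 0, rng_seed = 3)
  sim <- generate_synthetic(spec)
  p <- dw_params(t = 1, d = 3, delta_m = 3, delta_s = 6, min_mut_fraction = 0)
  res <- build_module_set(sim$network, sim$profile, p)
  found <- lapply(res$modules$modules, `[[`, "genes")
  expect_setequal(vapply(found, paste, "", collapse = ","),
                  vapply(sim$truth$modules, paste, "", collapse = ","))
  ex <- solve_exact(sim$network, sim$profile, 3, 6)
  expect_equal(res$odmss, ex$odmss, tolerance = 1e-12)
})

test_that("a shared planted gene lands in two output modules when d is lax", {
  spec <- synthetic_spec(overlap_genes = 1, passenger_rate = 0, p_bg = 0,
                         rng_seed = 1)
  sim <- generate_synthetic(spec)
  sizes <- lengths(sim$truth$modules)
  p <- dw_params(t = 1, d = 5, delta_m = min(sizes), delta_s = sum(sizes))
  res <- suppressWarnings(build_module_set(sim$network, sim$profile, p))
  counts <- table(unlist(lapply(res$modules$modules, `[[`, "genes")))
  shared <- unlist(lapply(seq_len(length(sim$truth$modules) - 1), function(i) {
    intersect(sim$truth$modules[[i]], sim$truth$modules[[i + 1]])
  }))
  expect_gte(sum(counts[shared] >= 2, na.rm = TRUE), 1)
})

test_that("parameter search returns the best evaluated point, deterministically", {
  spec <- synthetic_spec(n_genes = 30, n_samples = 120, n_modules = 3,
                         module_size_range = c(3, 4), rng_seed = 11)
  sim <- generate_synthetic(spec)
  base <- dw_params(optimizer = "search", n_evaluations = 8, delta_m = 3,
                    delta_s = 10, rng_seed = 5)

  # degenerate 1-point grid equals the fixed run at the range midpoint
  p1 <- base
  p1$n_evaluations <- 1L
  p1$search_strategy <- "grid"
  p1$t_range <- c(1, 1); p1$d_range <- c(3, 3)
  ans1 <- suppressWarnings(optimize_params(sim$network, sim$profile, p1))
  fixed <- suppressWarnings(build_module_set(
    sim$network, sim$profile, dw_params(t = 1, d = 3, delta_m = 3,
                                        delta_s = 10)))
  expect_equal(ans1$result$odmss, fixed$odmss)
  expect_equal(nrow(ans1$history), 1)

  # argmax property and evaluation budget
  ans <- suppressWarnings(optimize_params(sim$network, sim$profile, base))
  expect_lte(nrow(ans$history), base$n_evaluations)
  expect_equal(ans$result$odmss, max(ans$history$odmss))
  expect_equal(ans$params$optimizer, "fixed")

  # identical seeds give identical searches and identical modules
  ans2 <- suppressWarnings(optimize_params(sim$network, sim$profile, base))
  expect_identical(ans$history, ans2$history)
  expect_identical(lapply(ans$result$modules$modules, `[[`, "genes"),
                   lapply(ans2$result$modules$modules, `[[`, "genes"))
})
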