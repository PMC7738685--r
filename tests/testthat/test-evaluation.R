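test_that("hypergeometric enrichment matches exact draw enumeration", {
  # 10-gene universe, 5-gene pathway, 5-gene module, full intersection:
  # only 1 of the C(10,5) draws achieves it
  uni <- paste0("g", 1:10)
  q <- hypergeom_qvalues(list(uni[1:5]), list(pw = uni[1:5]), uni)
  p <- attr(q, "p")
  expect_equal(p[1, 1], 1 / choose(10, 5), tolerance = 1e-12)
  # single test: q = p
  expect_equal(q[1, 1], p[1, 1])

  # oracle: enumerate every draw for random small configurations
  for (seed in 1:15) {
    set.seed(seed)
    N <- sample(6:12, 1)
    uni <- paste0("g", seq_len(N))
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    pw <- uni[seq_len(K)]
    mod <- sample(uni, n)
    p <- attr(hypergeom_qvalues(list(mod), list(pw = pw), uni), "p")[1, 1]
    k_obs <- length(intersect(mod, pw))
    expect_equal(p, brute_hyper_tail(N, K, n, k_obs), tolerance = 1e-10)
  }

  expect_error(hypergeom_qvalues(list(c("g1", "zzz")), list(pw = "g1"),
                                 paste0("g", 1:5)),
               class = "dw_data_error")
})

test_that("BH adjustment is monotone and never below the raw p-value", {
  set.seed(42)
  uni <- paste0("g", 1:30)
  mods <- lapply(1:4, function(i) sample(uni, sample(3:8, 1)))
  paths <- stats::setNames(lapply(1:5, function(i) sample(uni, sample(3:10, 1))),
                           paste0("pw", 1:5))
  q <- hypergeom_qvalues(mods, paths, uni)
  p <- attr(q, "p")
  expect_true(all(q >= p - 1e-15))
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-15))
})

test_that("similarity matrices implement the three measures with their boundary rules", {
  mods <- list(M1 = c("a", "b", "c"))
  paths <- list(R1 = c("a", "b", "c"), R2 = c("x", "y", "z"))
  w <- similarity_matrix(mods, paths, "overlap")
  expect_equal(unname(w[1, ]), c(1, 0))

  # q exactly at the cutoff keeps its -log10 weight; only q > 0.05 is zeroed
  with_mocked_bindings(
    hypergeom_qvalues = function(...) {
      matrix(c(0.05, 0.050000001), 1, 2,
             dimnames = list("M1", c("R1", "R2")))
    },
    expect_equal(
      unname(similarity_matrix(mods, paths, "qvalue",
                               universe = letters)[1, ]),
      c(-log10(0.05), 0))
  )

  # GO consistency: Jaccard of standardized term unions; empty unions give 0
  go_map <- structure(list(terms_by_gene = list(a = c("t1", "t2"),
                                                b = "t2", x = c("t1", "t2"),
                                                y = "t3"),
                           level = 5L), class = "dw_go_map")
  w3 <- similarity_matrix(list(M1 = c("a", "b"), M2 = "q"),
                          list(R1 = c("x"), R2 = c("y"), R3 = "q"),
                          "go", go_map = go_map)
  expect_equal(w3["M1", "R1"], 1)          # identical unions {t1,t2}
  expect_equal(w3["M1", "R2"], 0)          # disjoint
  expect_equal(w3["M2", "R3"], 0)          # both unions empty
})

test_that("GO annotations standardize to a fixed depth of the hierarchy", {
  obo <- withr::local_tempfile(fileext = ".obo")
  # linear chain root -> a -> b -> c -> d -> e (depths 0..5), plus a diamond:
  # deep (depth 7) reaches two distinct depth-5 ancestors e and e2
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:root", "name: root", "namespace: bp", "",
    "[Term]", "id: GO:a", "is_a: GO:root ! root", "",
    "[Term]", "id: GO:b", "is_a: GO:a", "",
    "[Term]", "id: GO:c", "is_a: GO:b", "",
    "[Term]", "id: GO:d", "is_a: GO:c", "",
    "[Term]", "id: GO:e", "is_a: GO:d", "",
    "[Term]", "id: GO:e2", "is_a: GO:d", "",
    "[Term]", "id: GO:f", "is_a: GO:e", "",
    "[Term]", "id: GO:deep", "is_a: GO:f", "is_a: GO:e2", "",
    "[Term]", "id: GO:old", "is_a: GO:e", "is_obsolete: true"
  ), obo)
  dag <- read_obo(obo)
  expect_equal(unname(dag$depth[c("GO:root", "GO:e", "GO:deep")]),
               c(0L, 5L, 6L))

  ann <- list(g1 = "GO:e",      # exactly at level 5: kept
              g2 = "GO:c",      # above the level: dropped
              g3 = "GO:deep",   # below: replaced by both level-5 ancestors
              g4 = "GO:old")    # obsolete: dropped
  std <- standardize_go(dag, ann, level = 5)
  expect_equal(std$terms_by_gene$g1, "GO:e")
  expect_equal(std$terms_by_gene$g2, character(0))
  expect_setequal(std$terms_by_gene$g3, c("GO:e", "GO:e2"))
  expect_equal(std$terms_by_gene$g4, character(0))

  # idempotent at a fixed level
  std2 <- standardize_go(dag, std$terms_by_gene, level = 5)
  expect_equal(std2$terms_by_gene, std$terms_by_gene)

  expect_warning(standardize_go(dag, list(g = "GO:unknown"), 5), "absent")
})

test_that("the matching score equals the brute-force optimum and averages zero edges", {
  expect_equal(mmr(matrix(0.7, 1, 1, dimnames = list("M1", "R1")))$mmr, 0.7)

  # forced matching: the zero edge is counted in the mean
  w <- matrix(c(1, 0, 0, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("M1", "M2"), c("R1", "R2")))
  res <- mmr(w)
  expect_equal(res$cardinality, 2)
  expect_equal(res$mmr, 0.5)

  # oracle equivalence on random rectangular matrices
  for (seed in 1:20) {
    set.seed(seed)
    m <- sample(2:6, 1); n <- sample(2:7, 1)
    w <- matrix(round(stats::runif(m * n), 3), m, n)
    w[stats::runif(m * n) < 0.3] <- 0
    dimnames(w) <- list(paste0("M", 1:m), paste0("R", 1:n))
    res <- mmr(w)
    expect_equal(res$total_weight, brute_match_weight(w), tolerance = 1e-9)
    expect_equal(res$cardinality, min(m, n))
    expect_equal(res$mmr, res$total_weight / min(m, n))
    # dropping zero edges and averaging matched positives only can only
    # inflate the score
    pos <- res$matching$weight[res$matching$weight > 0]
    if (length(pos) > 0) expect_gte(mean(pos), res$mmr - 1e-12)
  }

  expect_error(mmr(matrix(numeric(0), 0, 0)), class = "dw_data_error")
})

test_that("best-match tables take row/column maxima and multiply the averages", {
  w <- matrix(c(1, 0, 0, 1), 2, 2,
              dimnames = list(c("M1", "M2"), c("R1", "R2")))
  expect_equal(best_match_tables(w)$f1, 1)
  expect_equal(best_match_tables(matrix(0, 2, 3))$f1, 0)
  w2 <- matrix(c(0.5, 0.2, 0.1, 0.3), 2, 2, byrow = TRUE,
               dimnames = list(c("M1", "M2"), c("R1", "R2")))
  bm <- best_match_tables(w2)
  expect_equal(bm$per_module$score, c(0.5, 0.3))
  expect_equal(bm$per_pathway$score, c(0.5, 0.3))
  expect_equal(bm$f1, 0.4 * 0.4)
})

test_that("ROC points accumulate ranked modules to each unique-gene cutoff", {
  mods <- dw_module_set(list(c("r1", "r2"), c("r3", "r4"), c("x1", "x2")))
  ref <- paste0("r", 1:4)
  bg <- c(paste0("r", 1:4), paste0("x", 1:6))
  pts <- roc_points(mods, ref, bg, cutoffs = c(4, 6))
  expect_equal(pts$tpr, c(1, 1))
  expect_equal(pts$fpr, c(0, 2 / 6))

  # reference disjoint from the modules
  pts2 <- roc_points(dw_module_set(list(c("x1", "x2"))), ref, bg, 2)
  expect_equal(pts2$tpr, 0)

  # 10-gene background, 4-gene reference, top = {2 ref, 3 non-ref}
  mods3 <- dw_module_set(list(c("r1", "r2", "x1", "x2", "x3")))
  pts3 <- roc_points(mods3, ref, bg, 5)
  expect_equal(pts3$tpr, 0.5)
  expect_equal(pts3$fpr, 0.5)

  # cutoff beyond the available genes: warn, emit at the achievable maximum
  expect_warning(pts4 <- roc_points(mods3, ref, bg, c(5, 50)), "exceeds")
  expect_equal(pts4$n_unique, c(5, 5))
})
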