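test_that("undirected projection applies the declared edge rule", {
  cn <- toy_connectome(n = 3, p = 1)
  cn$status["A", "B"] <- 1L; cn$status["B", "A"] <- 0L
  adj_m <- undirected_projection(cn, "mutual")
  adj_a <- undirected_projection(cn, "any")
  expect_false(adj_m["A", "B"])
  expect_true(adj_a["A", "B"])
  expect_true(adj_m["B", "C"] && adj_a["B", "C"])  # reciprocal pair
  cn$status["A", "C"] <- NA_integer_
  expect_error(undirected_projection(cn, "mutual"), "edge-complete")
})

test_that("maximal_cliques handles the textbook cases", {
  tri <- matrix(TRUE, 3, 3); diag(tri) <- FALSE
  dimnames(tri) <- list(letters[1:3], letters[1:3])
  expect_equal(clique_key(maximal_cliques(tri)), "a|b|c")
  k4 <- matrix(TRUE, 4, 4); diag(k4) <- FALSE
  dimnames(k4) <- list(letters[1:4], letters[1:4])
  k4["a", "b"] <- k4["b", "a"] <- FALSE        # K4 minus one edge
  expect_equal(clique_key(maximal_cliques(k4)), c("a|c|d", "b|c|d"))
})

test_that("maximal_cliques equals exhaustive enumeration on random graphs", {
  set.seed(30)
  for (r in 1:15) {
    adj <- random_undirected(10, 0.5)
    expect_equal(clique_key(maximal_cliques(adj)),
                 clique_key(oracle_cliques(adj)))
  }
})

test_that("core_from_cliques keeps all largest cliques", {
  cl <- list(c("a", "b", "c"), c("c", "d", "e"), c("f", "g"))
  part <- core_from_cliques(cl, letters[1:8])
  expect_equal(part$max_clique_size, 3)
  expect_length(part$cliques, 2)
  expect_setequal(part$core, c("a", "b", "c", "d", "e"))
  expect_setequal(part$periphery, c("f", "g", "h"))
  single <- core_from_cliques(list(c("a", "b")), letters[1:3])
  expect_setequal(single$core, c("a", "b"))
  expect_error(core_from_cliques(list(), letters[1:3]), "no cliques")
})

test_that("planted reciprocal cliques are recovered in the core", {
  hits <- 0
  for (s in 1:50) {
    cn <- toy_connectome(n = 60, p = 0.15, seed = 500 + s)
    cn <- plant_core(cn, 8, seed = 600 + s)
    planted <- attr(cn, "planted_core")
    adj <- undirected_projection(cn, "mutual")
    part <- core_from_cliques(maximal_cliques(adj), rownames(adj))
    hits <- hits + all(planted %in% part$core)
  }
  expect_gte(hits, 48)   # >= 95% of 50 seeds
})

test_that("degree-matched surrogates preserve degrees, never loops/dups", {
  cn <- toy_connectome(n = 20, p = 0.3, seed = 31)
  s <- cn$status; diag(s) <- 0L
  edges <- corticonn:::directed_edges(cn$status)
  set.seed(32)
  for (r in 1:10) {
    e2 <- corticonn:::cpp_edge_swap(edges, 20, 10 * nrow(edges),
                                    100 * nrow(edges))
    expect_equal(nrow(e2), nrow(edges))                    # edge count
    expect_equal(tabulate(e2[, 1] + 1, 20), tabulate(edges[, 1] + 1, 20))
    expect_equal(tabulate(e2[, 2] + 1, 20), tabulate(edges[, 2] + 1, 20))
    expect_true(all(e2[, 1] != e2[, 2]))                   # no self-loops
    expect_false(anyDuplicated(e2[, 1] * 20 + e2[, 2]) > 0)
  }
})

test_that("core significance uses the add-one rule", {
  expect_equal(core_significance(9, rep(7, 1000)), 1 / 1001)
  expect_equal(core_significance(5, rep(5, 200)), 1)
  cn <- toy_connectome(n = 40, p = 0.15, seed = 33)
  cn <- plant_core(cn, 7, seed = 34)
  part <- detect_core(edge_complete_subgraph(cn), n_null = 100, seed = 35)
  expect_equal(part$p_value, 1 / 101)
  expect_true(all(attr(cn, "planted_core") %in% part$core))
})

test_that("core/periphery attribute comparison behaves at the extremes", {
  cl <- list(letters[1:4])
  part <- core_from_cliques(cl, letters[1:10])
  vals <- setNames(rep(2, 10), letters[1:10])
  r <- compare_core_periphery_attribute(part, vals, "energy",
                                        n_perm = 200, seed = 1)
  expect_gte(r$p_value, 0.5)
  r2 <- compare_core_periphery_attribute(part, vals, "ks",
                                         n_perm = 200, seed = 1)
  expect_equal(r2$statistic, 0)
  vals2 <- setNames(c(rep(1, 4), rep(5, 6)) + runif(10, 0, 0.01),
                    letters[1:10])
  r3 <- compare_core_periphery_attribute(part, vals2, "energy",
                                         n_perm = 200, seed = 2)
  expect_lt(r3$p_value, 0.05)
  part0 <- part; part0$periphery <- character(0)
  expect_error(compare_core_periphery_attribute(part0, vals), "nonempty")
})

test_that("core planted among low-cyto areas shows a significant contrast", {
  hits <- 0
  for (s in 1:10) {
    set.seed(700 + s)
    cn <- toy_connectome(n = 50, p = 0.12, seed = 700 + s,
                         cyto = sample(1:5, 50, replace = TRUE))
    low <- order(cn$areas$cyto)[1:7]   # plant the clique on low types
    ids <- cn$areas$id[low]
    block <- matrix(1L, 7, 7); diag(block) <- NA_integer_
    cn$status[ids, ids] <- block
    part <- core_from_cliques(maximal_cliques(
      undirected_projection(cn, "mutual")), cn$areas$id)
    vals <- setNames(cn$areas$cyto + runif(50, 0, 0.01), cn$areas$id)
    r <- compare_core_periphery_attribute(part, vals, "energy",
                                          n_perm = 200, seed = s)
    hits <- hits + (r$p_value < 0.05)
  }
  expect_gte(hits, 9)
})

test_that("core cytoarchitecture contrast is robust to reassignment", {
  set.seed(36)
  cyto <- c(rep(1:2, length.out = 10), rep(4:5, length.out = 30))
  cn <- toy_connectome(n = 40, p = 0.1, seed = 36, cyto = cyto)
  ids <- cn$areas$id[1:10]
  block <- matrix(1L, 10, 10); diag(block) <- NA_integer_
  cn$status[ids, ids] <- block
  part <- core_from_cliques(maximal_cliques(
    undirected_projection(cn, "mutual")), cn$areas$id)
  rob <- core_cyto_robustness(cn, part, fractions = c(0, 0.8), n_rep = 20,
                              seed = 37)
  f0 <- rob$table$energy[rob$table$fraction == 0]
  expect_true(all(f0 == rob$baseline))
  mean08 <- mean(rob$table$energy[rob$table$fraction == 0.8])
  expect_gt(mean08, quantile(rob$null_stats, 0.95))
})
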