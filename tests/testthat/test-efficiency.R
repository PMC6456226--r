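cycle3 <- matrix(c(0, 1, 0,
                   0, 0, 1,
                   1, 0, 0), 3, 3, byrow = TRUE,
                 dimnames = list(letters[1:3], letters[1:3]))

test_that("shortest paths match hand counts and Floyd-Warshall", {
  D <- shortest_path_lengths(cycle3)
  expect_equal(D["a", "b"], 1); expect_equal(D["a", "c"], 2)
  expect_equal(D["b", "a"], 2)
  # disconnected pair is infinite
  s <- matrix(0L, 2, 2); s[1, 2] <- 1L
  D2 <- shortest_path_lengths(s)
  expect_equal(D2[2, 1], Inf)
  set.seed(40)
  for (r in 1:25) {
    g <- random_digraph(sample(5:15, 1), runif(1, 0.1, 0.5))
    expect_equal(unname(shortest_path_lengths(g)), oracle_floyd(g))
  }
})

test_that("node efficiency follows the 1/D convention", {
  eff <- node_efficiency(cycle3)
  expect_equal(eff$eff_out_sp, rep((1 + 1 / 2) / 2, 3))
  expect_equal(eff$eff_in_sp, rep(0.75, 3))
  K <- matrix(1L, 5, 5); diag(K) <- 0L
  effK <- node_efficiency(K)
  expect_true(all(effK$eff_out_sp == 1 & effK$eff_in_sp == 1))
  # isolated sink: no outgoing paths
  s <- rbind(cbind(K[1:4, 1:4], 1L), 0L)
  effS <- node_efficiency(s)
  expect_equal(effS$eff_out_sp[5], 0)
})

test_that("MFPT matches closed forms and the simulation oracle", {
  # two mutually connected nodes: forced alternation
  two <- matrix(c(0, 1, 1, 0), 2, 2)
  H2 <- mean_first_passage_times(two)$H
  expect_equal(H2[1, 2], 1); expect_equal(H2[2, 1], 1)
  # deterministic directed cycle
  mf <- mean_first_passage_times(cycle3)
  expect_equal(unname(mf$H), matrix(c(0, 1, 2, 2, 0, 1, 1, 2, 0), 3, 3,
                                    byrow = TRUE))
  expect_equal(unname(mf$pi), rep(1 / 3, 3))
  # Monte-Carlo oracle on random strongly connected graphs
  set.seed(41)
  for (r in 1:4) {
    g <- random_strong_digraph(8, 0.3)
    H <- mean_first_passage_times(g)$H
    for (k in 1:3) {
      ij <- sample(8, 2)
      mc <- oracle_mfpt_mc(g, ij[1], ij[2], n_walks = 3000)
      expect_lt(abs(H[ij[1], ij[2]] - mc$mean), 3 * mc$se + 1e-9)
    }
  }
})

test_that("stationary distribution matches long-run visit frequencies", {
  set.seed(42)
  g <- random_strong_digraph(6, 0.4)
  pi_v <- mean_first_passage_times(g)$pi
  nbr <- lapply(1:6, function(v) which(g[v, ] == 1))
  cur <- 1L; visits <- numeric(6); n_steps <- 200000
  for (t in seq_len(n_steps)) {
    cur <- nbr[[cur]][sample.int(length(nbr[[cur]]), 1)]
    visits[cur] <- visits[cur] + 1
  }
  expect_lt(max(abs(visits / n_steps - unname(pi_v))), 0.02)
  expect_equal(sum(pi_v), 1)
  expect_true(all(pi_v > 0))
})

test_that("diffusion efficiency: closed forms, H >= D, hub dominance", {
  de <- diffusion_efficiency(cycle3)
  expect_equal(de$eff_out_diff, rep(0.75, 3))
  Kn <- matrix(1L, 5, 5); diag(Kn) <- 0L
  deK <- diffusion_efficiency(Kn)
  expect_equal(deK$eff_in_diff, deK$eff_out_diff, tolerance = 1e-10)
  expect_lt(diff(range(deK$eff_in_diff)), 1e-10)  # vertex-transitive
  set.seed(43)
  for (r in 1:5) {
    g <- random_strong_digraph(7, 0.35)
    H <- mean_first_passage_times(g)$H
    D <- shortest_path_lengths(g)
    off <- row(H) != col(H)
    expect_true(all(H[off] >= D[off] - 1e-9))
  }
  # hub-and-spoke: hub reached faster than spokes
  n <- 6
  hub <- matrix(0L, n, n)
  hub[1, 2:n] <- 1L; hub[2:n, 1] <- 1L
  deH <- diffusion_efficiency(hub)
  expect_true(all(deH$eff_in_diff[1] > deH$eff_in_diff[2:n]))
})

test_that("non-strongly-connected graphs are refused with component info", {
  s <- matrix(0L, 4, 4); s[1, 2] <- s[2, 1] <- s[3, 4] <- s[4, 3] <- 1L
  expect_error(mean_first_passage_times(s), "not strongly connected")
  expect_error(diffusion_efficiency(s), "components")
})

test_that("core vs periphery efficiency comparison is sound", {
  # identical values: no contrast detectable
  part <- core_from_cliques(list(letters[1:3]), letters[1:8])
  pa <- data.frame(area = letters[1:8], eff_out_sp = 1, eff_in_sp = 1,
                   eff_out_diff = 0.4, eff_in_diff = 0.4)
  prof <- structure(list(per_area = pa, D = NULL, H = NULL, pi = NULL),
                    class = "efficiency_profile")
  res <- compare_core_periphery_efficiency(part, prof, n_perm = 200,
                                           seed = 1)
  expect_named(res, c("eff_in_sp", "eff_out_sp", "eff_in_diff",
                      "eff_out_diff"))
  for (t in res) expect_gte(t$p_value, 0.5)
  res2 <- compare_core_periphery_efficiency(part, prof, n_perm = 200,
                                            seed = 1)
  expect_equal(vapply(res, `[[`, 0, "p_value"),
               vapply(res2, `[[`, 0, "p_value"))
})

test_that("a planted dense core has higher incoming efficiency", {
  hits_sp <- 0; hits_diff <- 0
  n_seeds <- 15
  for (s in 1:n_seeds) {
    cn <- toy_connectome(n = 40, p = 0.12, seed = 800 + s)
    cn <- plant_core(cn, 8, seed = 900 + s)
    ids <- attr(cn, "planted_core")
    part <- core_from_cliques(list(ids), cn$areas$id)
    g <- cn$status
    diag(g) <- 0L
    for (k in 1:40) g[k, k %% 40 + 1] <- 1L   # guarantee strong connectivity
    prof <- efficiency_profile(g)
    res <- compare_core_periphery_efficiency(part, prof, n_perm = 200,
                                             seed = s)
    better_in <- res$eff_in_sp$median_core > res$eff_in_sp$median_periphery
    hits_sp <- hits_sp + (res$eff_in_sp$p_value < 0.05 && better_in)
    hits_diff <- hits_diff +
      (res$eff_in_diff$p_value < 0.05 &&
         res$eff_in_diff$median_core > res$eff_in_diff$median_periphery)
  }
  expect_gte(hits_sp, 0.9 * n_seeds)
  expect_gte(hits_diff, 0.9 * n_seeds)
})
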