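make_pairs <- function(n = 200, bd = -3, bc = -2, b0 = 0, seed = 1) {
  set.seed(seed)
  d <- runif(n); cc <- runif(n)
  y <- rbinom(n, 1, plogis(b0 + bd * d + bc * cc))
  structure(data.frame(source = "s", target = "t", d01 = d, c01 = cc,
                       status = factor(ifelse(y == 1, "present", "absent"),
                                       levels = c("absent", "present")),
                       species = "sim"),
            class = c("pair_table", "data.frame"))
}

test_that("fit_logistic attains the ML optimum (generic-optimizer oracle)", {
  set.seed(10)
  for (r in 1:20) {
    pairs <- make_pairs(n = 120, bd = runif(1, -4, 0), bc = runif(1, -4, 2),
                        seed = 100 + r)
    if (length(unique(pairs$status)) < 2) next
    fit <- fit_logistic(pairs)
    oracle <- oracle_logistic_loglik(cbind(pairs$d01, pairs$c01),
                                     as.integer(pairs$status == "present"))
    expect_lt(abs(fit$log_likelihood - oracle), 1e-6)
    expect_lte(fit$log_likelihood, 0)
    expect_equal(fit$n_obs, nrow(pairs))
  }
})

test_that("perfect separation is flagged, not silently returned", {
  pairs <- make_pairs(n = 50, seed = 3)
  pairs$status <- factor(ifelse(pairs$d01 < 0.5, "present", "absent"),
                         levels = c("absent", "present"))
  expect_warning(fit <- fit_logistic(pairs), "separation|unreliable")
  expect_false(fit$converged)
  pairs$status <- factor(rep("present", 50),
                         levels = c("absent", "present"))
  expect_warning(expect_error(fit_logistic(pairs), NA))
})

test_that("species interaction model and LR test behave structurally", {
  set.seed(11)
  pa <- make_pairs(400, bc = -1, seed = 21); pa$species <- "a"
  pb <- make_pairs(400, bc = -4, seed = 22); pb$species <- "b"
  res <- fit_species_interaction(pa, pb)
  expect_named(res$fit$coefficients,
               c("(Intercept)", "d01", "c01", "species", "c01:species"))
  expect_gte(res$lr$lr_statistic, 0)
  expect_equal(res$lr$p_value,
               pchisq(res$lr$lr_statistic, 1, lower.tail = FALSE))
  # invariance to which species is coded as reference (relabel swap)
  pa2 <- pa; pa2$species <- "z"
  res2 <- fit_species_interaction(pa2, pb)
  expect_equal(res2$lr$lr_statistic, res$lr$lr_statistic, tolerance = 1e-8)
  # interaction sign flips with the dummy direction
  expect_equal(unname(res2$fit$coefficients[["c01:species"]]),
               -unname(res$fit$coefficients[["c01:species"]]),
               tolerance = 1e-6)
})

test_that("interaction is detected when generative beta_c differs", {
  hits <- 0
  for (s in 1:10) {
    spec_a <- synthetic_spec(n_areas = 60, beta_c = -1, seed = 300 + s)
    spec_b <- synthetic_spec(n_areas = 60, beta_c = -4, seed = 400 + s)
    ca <- generate_connectome(generate_areas(spec_a), spec_a)
    cb <- generate_connectome(generate_areas(spec_b), spec_b)
    ca$species <- "a"; cb$species <- "b"
    res <- fit_species_interaction(build_pair_table(ca),
                                   build_pair_table(cb))
    hits <- hits + (res$lr$p_value < 0.05)
  }
  expect_gte(hits, 9)
})

test_that("probability_curve evaluates the inverse link on the grid", {
  pairs <- make_pairs(200, seed = 5)
  fit <- fit_logistic(pairs)
  d0 <- c(0.1, 0.5); cg <- seq(0, 1, 0.25)
  p <- probability_curve(fit, d0, cg)
  expect_equal(dim(p), c(2, 5))
  b <- fit$coefficients
  for (i in 1:2) for (j in 1:5)
    expect_equal(p[i, j],
                 plogis(b[["(Intercept)"]] + b[["d01"]] * d0[i] +
                          b[["c01"]] * cg[j]), tolerance = 1e-12)
  if (b[["c01"]] < 0) expect_true(all(diff(p[1, ]) < 0))
  # null model: flat 0.5
  fit0 <- fit
  fit0$coefficients[] <- 0
  expect_true(all(probability_curve(fit0, d0, cg) == 0.5))
})

test_that("present/absent comparison reports medians and floors p", {
  pairs <- make_pairs(300, bd = -4, bc = -3, seed = 6)
  r <- compare_present_absent(pairs, "c01", n_perm = 200, seed = 1)
  expect_lt(r$median_present, r$median_absent)
  # maximal separation attains the add-one floor
  pairs2 <- make_pairs(100, seed = 7)
  pairs2$c01 <- ifelse(pairs2$status == "present", 0, 1)
  pairs2$c01 <- pairs2$c01 + runif(100, 0, 1e-3)   # break exact ties
  r2 <- compare_present_absent(pairs2, "c01", n_perm = 200, seed = 2)
  expect_equal(r2$p_value, 1 / 201)
})

test_that("type reassignment respects the scale and the no-op case", {
  cyto <- as.numeric(rep(1:5, each = 6))
  set.seed(8)
  for (r in 1:50) {
    idx <- sample(30, 10)
    out <- corticonn:::reassign_types(cyto, idx, "clamped", 1, 5)
    expect_true(all(out %in% 1:5))
    expect_identical(out[-idx], cyto[-idx])
    out2 <- corticonn:::reassign_types(cyto, idx, "stretched", 1, 5)
    expect_true(all(out2 >= 1 & out2 <= 6))
  }
  spec <- synthetic_spec(n_areas = 40, cyto_scale = "ordinal", seed = 9)
  cn <- generate_connectome(generate_areas(spec), spec)
  rob <- type_reassignment_robustness(cn, fractions = c(0, 0.5),
                                      n_rep = 5, seed = 3)
  f0 <- rob$table$coef_c01[rob$table$fraction == 0]
  expect_true(all(f0 == rob$baseline))
  # continuous scale refuses reassignment
  spec2 <- synthetic_spec(n_areas = 40, seed = 9)
  cn2 <- generate_connectome(generate_areas(spec2), spec2)
  expect_error(type_reassignment_robustness(cn2), "ordinal")
})

test_that("strong cytoarchitecture effect survives 80% reassignment", {
  spec <- synthetic_spec(n_areas = 60, beta_c = -4, cyto_scale = "ordinal",
                         seed = 12)
  cn <- generate_connectome(generate_areas(spec), spec)
  rob <- type_reassignment_robustness(cn, fractions = 0.8, n_rep = 20,
                                      seed = 4)
  mean_coef <- mean(abs(rob$table$coef_c01))
  null_q95 <- quantile(abs(rob$null_coefs), 0.95)
  expect_gt(mean_coef, null_q95)
})
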