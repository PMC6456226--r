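#' Compare present vs absent connections on one predictor
#'
#' Energy permutation test between the predictor values (`d01` or `c01`)
#' of pairs with a present connection and pairs without one, plus the two
#' group medians.  Present connections are expected to span shorter
#' rescaled distances and more similar cytoarchitecture.
#'
#' @param pairs a `pair_table` from [build_pair_table()].
#' @param feature `"d01"` or `"c01"`.
#' @param n_perm permutations for the energy test.
#' @param seed integer seed.
#' @return a `corticonn_test` with extra fields `median_present`,
#'   `median_absent`, `feature`.
#' @export
compare_present_absent <- function(pairs, feature = c("c01", "d01"),
                                   n_perm = 1000, seed = NULL) {
  feature <- match.arg(feature)
  stopifnot(inherits(pairs, "data.frame"))
  v <- pairs[[feature]]
  pres <- v[pairs$status == "present"]
  abs_ <- v[pairs$status == "absent"]
  if (length(pres) < 2 || length(abs_) < 2)
    stop("both present and absent pairs are required")
  out <- energy_test(pres, abs_, n_perm = n_perm, seed = seed)
  out$median_present <- median(pres)
  out$median_absent <- median(abs_)
  out$feature <- feature
  out
}

# internal: maximum-likelihood logistic fit through glm (IRLS), wrapped so
# perfect separation / non-convergence is surfaced as a flag + warning
# rather than an opaque glm warning.
logistic_ml <- function(formula, data) {
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(formula, data = data, family = binomial(),
        control = list(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  # single-class responses and boundary fits escape glm's own warning
  fv <- fitted(fit)
  if (length(unique(fit$y)) < 2 || any(fv > 1 - 1e-10) || any(fv < 1e-10))
    sep_warn <- TRUE
  converged <- fit$converged && !sep_warn
  if (!converged)
    warning("logistic fit flagged: perfect separation or non-convergence; ",
            "coefficients are unreliable")
  list(fit = fit, converged = converged)
}

logistic_fit_result <- function(fit, converged, n_obs) {
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  structure(list(
    coefficients = est,
    standard_error = se,
    wald_p = 2 * pnorm(-abs(est / se)),
    log_likelihood = as.numeric(logLik(fit)),
    n_obs = n_obs, converged = converged, glm = fit),
    class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic fit> n = %d, logLik = %.3f%s\n", x$n_obs,
              x$log_likelihood,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(data.frame(coef = x$coefficients, se = x$standard_error,
                   p = x$wald_p))
  invisible(x)
}

#' Logistic regression of connection existence
#'
#' Binary logistic regression of connection presence on the rescaled
#' predictors, fitted by iteratively reweighted least squares
#' (log-likelihood tolerance 1e-8, at most 100 iterations).  Wald
#' standard errors come from the observed information; perfect separation
#' or non-convergence is flagged with a warning while coefficients are
#' still reported.
#'
#' @param pairs a `pair_table`.
#' @param regressors character vector of predictor columns, default
#'   `c("d01", "c01")`.
#' @return object of class `logistic_fit` with `coefficients`,
#'   `standard_error`, `wald_p`, `log_likelihood`, `n_obs`, `converged`.
#' @export
fit_logistic <- function(pairs, regressors = c("d01", "c01")) {
  stopifnot(inherits(pairs, "data.frame"), nrow(pairs) >= 20,
            all(regressors %in% names(pairs)))
  df <- data.frame(y = as.integer(pairs$status == "present"),
                   pairs[, regressors, drop = FALSE])
  f <- stats::as.formula(paste("y ~", paste(regressors, collapse = " + ")))
  m <- logistic_ml(f, df)
  logistic_fit_result(m$fit, m$converged, nrow(df))
}

#' Cross-species logistic model with cytoarchitecture interaction
#'
#' Pools two per-species pair tables (each already rescaled within its
#' own species), adds a 0/1 species dummy (alphabetically first species
#' = reference level 0) and its interaction with cytoarchitectonic
#' dissimilarity, and compares the full model against the model without
#' the interaction with a likelihood-ratio test (df = 1).  No
#' species-by-distance interaction is included.
#'
#' @param pairs_a,pairs_b per-species `pair_table`s.
#' @return list with elements `fit` (full-model `logistic_fit`; regressor
#'   names `d01`, `c01`, `species`, `c01:species`) and `lr` (list
#'   `lr_statistic`, `df`, `p_value`).
#' @export
fit_species_interaction <- function(pairs_a, pairs_b) {
  stopifnot(nrow(pairs_a) > 0, nrow(pairs_b) > 0)
  pooled <- rbind(as.data.frame(pairs_a), as.data.frame(pairs_b))
  lv <- sort(unique(pooled$species))
  if (length(lv) != 2)
    stop("exactly two species are required")
  df <- data.frame(
    y = as.integer(pooled$status == "present"),
    d01 = pooled$d01, c01 = pooled$c01,
    species = as.numeric(pooled$species == lv[2]))
  full <- logistic_ml(y ~ d01 + c01 + species + c01:species, df)
  red <- logistic_ml(y ~ d01 + c01 + species, df)
  lr <- 2 * (as.numeric(logLik(full$fit)) - as.numeric(logLik(red$fit)))
  lr <- max(lr, 0)
  list(
    fit = logistic_fit_result(full$fit, full$converged, nrow(df)),
    lr = list(lr_statistic = lr, df = 1L,
              p_value = pchisq(lr, df = 1, lower.tail = FALSE)),
    species_levels = lv)
}

#' Predicted connection probability over a predictor grid
#'
#' Evaluates the fitted inverse-logit on a grid of cytoarchitectonic
#' dissimilarity values for each supplied distance, visualizing how the
#' probability of a connection decays with dissimilarity at fixed
#' distance.
#'
#' @param fit a `logistic_fit`.
#' @param d01_values distances (rows of the result).
#' @param c01_grid dissimilarity grid (columns).
#' @param species_level value of the species dummy (0 = reference); only
#'   used when the fit contains species terms.
#' @return matrix of probabilities in (0, 1), rows = `d01_values`.
#' @export
probability_curve <- function(fit, d01_values, c01_grid,
                              species_level = 0) {
  stopifnot(inherits(fit, "logistic_fit"))
  b <- fit$coefficients
  get <- function(nm) if (nm %in% names(b)) b[[nm]] else 0
  eta <- outer(d01_values * get("d01"),
               c01_grid * (get("c01") + get("c01:species") * species_level),
               "+") +
    b[["(Intercept)"]] + get("species") * species_level
  p <- plogis(eta)
  dimnames(p) <- list(d01 = signif(d01_values, 4),
                      c01 = signif(c01_grid, 4))
  p
}

# one random reassignment of ordinal cortical types: move each selected
# area one level up or down; clamped reflects at the scale ends,
# stretched allows exceeding them.
reassign_types <- function(cyto, idx, mode, lo, hi) {
  step <- sample(c(-1, 1), length(idx), replace = TRUE)
  newv <- cyto[idx] + step
  if (mode == "clamped") {
    newv[newv < lo] <- lo + 1
    newv[newv > hi] <- hi - 1
  } else {                      # stretched: only reflect at the bottom
    newv[newv < lo] <- lo + 1
  }
  cyto[idx] <- newv
  cyto
}

#' Robustness of the cytoarchitecture effect to type reassignment
#'
#' Randomly reassigns the ordinal cortical type of a fraction of areas
#' one level up or down (`clamped`: reflected at the scale ends;
#' `stretched`: the top level may be exceeded), rebuilds the pair table,
#' refits the logistic model, and records the dissimilarity coefficient.
#' A label-permutation null (cortical types shuffled across areas) is
#' refitted `n_rep` times for comparison.
#'
#' @param x a [connectome] with ordinal (`type`) cytoarchitecture.
#' @param fractions fractions of areas to reassign, each in \[0, 1\].
#' @param n_rep reassignments per fraction.
#' @param mode `"clamped"` or `"stretched"`.
#' @param seed integer seed.
#' @return list with `table` (data.frame `fraction`, `rep`, `coef_c01`),
#'   `null_coefs` (length `n_rep`), `baseline` (the unperturbed
#'   coefficient).
#' @export
type_reassignment_robustness <- function(x, fractions = c(0, 0.2, 0.4, 0.6, 0.8),
                                         n_rep = 100,
                                         mode = c("clamped", "stretched"),
                                         seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "connectome"))
  if (x$cyto_kind != "type" || any(x$areas$cyto != round(x$areas$cyto)))
    stop("type reassignment requires an ordinal cortical-type scale")
  stopifnot(all(fractions >= 0 & fractions <= 1))
  cyto0 <- x$areas$cyto
  lo <- min(cyto0); hi <- max(cyto0)
  n <- length(cyto0)
  refit_with <- function(cyto) {
    xx <- x
    xx$areas$cyto <- cyto
    fit <- suppressWarnings(fit_logistic(build_pair_table(xx)))
    unname(fit$coefficients[["c01"]])
  }
  baseline <- refit_with(cyto0)
  with_seed(seed, {
    rows <- lapply(fractions, function(f) {
      k <- ceiling(f * n)
      coefs <- vapply(seq_len(n_rep), function(r) {
        if (k == 0) return(baseline)
        idx <- sample.int(n, k)
        refit_with(reassign_types(cyto0, idx, mode, lo, hi))
      }, numeric(1))
      data.frame(fraction = f, rep = seq_len(n_rep), coef_c01 = coefs)
    })
    null_coefs <- vapply(seq_len(n_rep), function(r)
      refit_with(sample(cyto0)), numeric(1))
    list(table = do.call(rbind, rows), null_coefs = null_coefs,
         baseline = baseline, mode = mode)
  })
}
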