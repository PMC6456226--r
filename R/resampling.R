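#' Two-sample energy statistic (logarithmic potential)
#'
#' Aslan-Zech minimum-energy statistic with potential `R(r) = -ln r`:
#' \deqn{\Phi = -\frac{1}{n^2}\sum_{i<j}\ln|x_i-x_j|
#'             -\frac{1}{m^2}\sum_{i<j}\ln|y_i-y_j|
#'             +\frac{1}{nm}\sum_{i,j}\ln|x_i-y_j|}
#' Larger values indicate more separated samples.  Distances below `eps`
#' are clipped to `eps` so ties do not produce infinities.
#'
#' @param x,y numeric samples (length >= 2 each).
#' @param eps regularizer for coincident points.
#' @return the energy statistic (real; symmetric in `x`, `y`).
#' @export
energy_statistic <- function(x, y, eps = 1e-8) {
  stopifnot(length(x) >= 2, length(y) >= 2,
            all(is.finite(x)), all(is.finite(y)))
  L <- cpp_log_potential(c(x, y), eps)
  cpp_energy_from_L(L, seq_along(x) - 1L,
                    length(x) + seq_along(y) - 1L)
}

# Shared permutation-test builder: stat_fun computes the observed value,
# null_fun(n_perm) the permutation null after pooling.  The add-one rule
# (b + 1)/(m + 1) keeps p in (0, 1].
perm_test_result <- function(statistic, null_values, n_perm, seed) {
  structure(list(
    statistic = statistic,
    p_value = (sum(null_values >= statistic) + 1) / (n_perm + 1),
    null_values = null_values, n_perm = n_perm, seed = seed),
    class = "corticonn_test")
}

#' @export
print.corticonn_test <- function(x, ...) {
  cat(sprintf("<permutation test> statistic = %.4g, p = %.4g (%d permutations)\n",
              x$statistic, x$p_value, x$n_perm))
  invisible(x)
}

#' Energy permutation test
#'
#' Two-sample test based on [energy_statistic()]; the null is built by
#' pooling both samples and re-splitting the labels `n_perm` times.
#' Significance uses the add-one rule `p = (b + 1)/(n_perm + 1)`.
#'
#' @inheritParams energy_statistic
#' @param n_perm number of label permutations (>= 100).
#' @param seed integer seed (`NULL` = use current RNG state).
#' @return list of class `corticonn_test` with `statistic`, `p_value`,
#'   `null_values`, `n_perm`, `seed`.
#' @export
energy_test <- function(x, y, n_perm = 1000, seed = NULL, eps = 1e-8) {
  stopifnot(n_perm >= 100)
  obs <- energy_statistic(x, y, eps)
  L <- cpp_log_potential(c(x, y), eps)
  null_vals <- with_seed(seed,
                         cpp_energy_perm(L, length(x), length(y), n_perm))
  perm_test_result(obs, null_vals, n_perm, seed)
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' `sup |ECDF_x - ECDF_y|`, with ties handled exactly.
#'
#' @param x,y numeric samples.
#' @return statistic in \[0, 1\].
#' @export
ks_statistic <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  cpp_ks_stat(as.numeric(x), as.numeric(y))
}

#' Kolmogorov-Smirnov permutation test
#'
#' Same permutation scheme and p-value rule as [energy_test()] but with
#' the KS statistic, matching the distribution comparisons used for core
#' versus periphery efficiency values.
#'
#' @inheritParams energy_test
#' @return list of class `corticonn_test`.
#' @export
ks_perm_test <- function(x, y, n_perm = 1000, seed = NULL) {
  stopifnot(n_perm >= 100)
  obs <- ks_statistic(x, y)
  null_vals <- with_seed(seed,
                         cpp_ks_perm(c(x, y), length(x), length(y), n_perm))
  perm_test_result(obs, null_vals, n_perm, seed)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties averaged).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0)
    stop("Spearman correlation undefined for a constant vector")
  cor(rank(x), rank(y))
}

#' Partial Spearman rank correlation
#'
#' First-order partial correlation computed on Spearman correlations:
#' `(r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`.  Used to
#' estimate the unique association of NSG% with one predictor while
#' controlling for the other.
#'
#' @param x,y,z numeric vectors of equal length >= 4.
#' @return partial rho.
#' @export
partial_spearman <- function(x, y, z) {
  stopifnot(length(x) == length(y), length(y) == length(z), length(x) >= 4)
  rxy <- spearman_rho(x, y)
  rxz <- spearman_rho(x, z)
  ryz <- spearman_rho(y, z)
  if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12)
    stop("partial Spearman degenerate: a control correlation is +-1")
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: `U / (n_pos * n_neg)` with ties counted 0.5,
#' i.e. the probability that a random positive outscores a random
#' negative.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (logical, 0/1, or two-level factor; the
#'   second factor level / larger value is the positive class).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(as.logical(labels) | labels == 1)
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("roc_auc needs both classes present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
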