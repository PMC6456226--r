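#' Fraction of supragranular labeled neurons (NSG%)
#'
#' `100 * n_supra / (n_supra + n_infra)`: the percentage of retrogradely
#' labeled projection neurons located in supragranular layers.  Values
#' near 0 indicate a predominantly infragranular ("feedback"-like)
#' origin, values near 100 a predominantly supragranular
#' ("feedforward"-like) origin.
#'
#' @param n_supra,n_infra neuron counts in supra- and infragranular
#'   layers (nonnegative, total >= 1).
#' @return NSG% in \[0, 100\].
#' @examples
#' compute_nsg(20, 80)  # 20: predominantly infragranular
#' @export
compute_nsg <- function(n_supra, n_infra) {
  stopifnot(all(n_supra >= 0), all(n_infra >= 0))
  total <- n_supra + n_infra
  if (any(total < 1))
    stop("at least one labeled neuron is required")
  100 * n_supra / total
}

#' Signed rostrocaudal offset of a projection
#'
#' Offset of origin relative to termination along the normalized
#' rostrocaudal axis (1 = most rostral): positive values denote
#' rostral-to-caudal projections, negative caudal-to-rostral.
#' Antisymmetric under swapping origin and termination.
#'
#' @param origin,termination single-row area slices (with a
#'   `rostrocaudal` column) or plain normalized coordinates.
#' @return signed offset in \[-1, 1\].
#' @export
rostrocaudal_offset <- function(origin, termination) {
  get_rc <- function(z) if (is.data.frame(z)) z$rostrocaudal else z
  ro <- get_rc(origin); rt <- get_rc(termination)
  if (any(!is.finite(c(ro, rt))) || any(c(ro, rt) < 0) || any(c(ro, rt) > 1))
    stop("rostrocaudal coordinates must be normalized to [0, 1]")
  ro - rt
}

#' Assemble a laminar table from per-projection records
#'
#' Joins projection records onto an area table to compute the signed
#' cytoarchitectonic difference (origin minus termination) and the
#' signed rostrocaudal offset.  Provide either `nsg` directly, counts
#' (`n_supra`, `n_infra`), or a binary `class` label
#' (feedforward/feedback).
#'
#' @param records data.frame with `origin`, `termination` and one of
#'   `nsg` / (`n_supra`,`n_infra`) / `class`.
#' @param areas area table with `id`, `cyto`, `rostrocaudal`.
#' @return data.frame of class `laminar_table`.
#' @export
laminar_table <- function(records, areas) {
  stopifnot(all(c("origin", "termination") %in% names(records)))
  unknown <- setdiff(unique(c(records$origin, records$termination)),
                     areas$id)
  if (length(unknown))
    stop("areas missing from table: ", paste(unknown, collapse = ", "))
  cyto <- setNames(areas$cyto, areas$id)
  rc <- setNames(areas$rostrocaudal, areas$id)
  out <- data.frame(origin = as.character(records$origin),
                    termination = as.character(records$termination),
                    stringsAsFactors = FALSE)
  if ("nsg" %in% names(records)) {
    out$nsg <- records$nsg
  } else if (all(c("n_supra", "n_infra") %in% names(records))) {
    out$nsg <- compute_nsg(records$n_supra, records$n_infra)
  }
  if ("class" %in% names(records)) out$class <- records$class
  if (!is.null(out$nsg) && any(out$nsg < 0 | out$nsg > 100))
    stop("nsg must lie in [0, 100]")
  if (any(out$origin == out$termination))
    stop("self-projections are not allowed")
  out$cyto_diff <- as.numeric(cyto[out$origin] - cyto[out$termination])
  out$rc_diff <- as.numeric(rostrocaudal_offset(rc[out$origin],
                                                rc[out$termination]))
  class(out) <- c("laminar_table", "data.frame")
  out
}

# predictor matrix for a laminar model
laminar_X <- function(table, predictor_set) {
  stopifnot(all(predictor_set %in% c("cyto_diff", "rc_diff")))
  as.matrix(table[, predictor_set, drop = FALSE])
}

#' Train a laminar-origin model on a full table
#'
#' Linear epsilon-SVR (C = 1 by default) of NSG% on the chosen
#' predictors, trained on all supplied records.  Used for in-sample
#' inspection and for cross-species extrapolation.
#'
#' @param table a `laminar_table` with quantitative `nsg`.
#' @param predictor_set subset of `c("cyto_diff", "rc_diff")`.
#' @param svr_C regularization constant.
#' @return list of class `laminar_model`.
#' @export
train_laminar_model <- function(table, predictor_set = "cyto_diff",
                                svr_C = 1) {
  X <- laminar_X(table, predictor_set)
  fit <- svr_fit(X, table$nsg, C = svr_C)
  structure(list(fit = fit, predictor_set = predictor_set, svr_C = svr_C),
            class = "laminar_model")
}

#' Repeated out-of-sample evaluation of NSG% predictions
#'
#' For each repetition a fresh random split assigns `train_fraction` of
#' the records (drawn without replacement) to training; a linear SVR is
#' fitted and the Spearman correlation between held-out actual and
#' predicted NSG% is recorded.  Repetitions whose training split has a
#' constant predictor or constant NSG% are excluded and counted.
#'
#' @param table `laminar_table` with quantitative `nsg` (>= 20 records).
#' @param predictor_set subset of `c("cyto_diff", "rc_diff")`.
#' @param n_rep number of random splits.
#' @param train_fraction fraction of records used for training.
#' @param svr_C regularization constant.
#' @param seed integer seed.
#' @return list of class `prediction_eval`: `rho_per_rep`, `n_excluded`,
#'   `n_rep`, `train_fraction`, `predictor_set`, `seed`.
#' @export
evaluate_out_of_sample <- function(table, predictor_set = "cyto_diff",
                                   n_rep = 1000, train_fraction = 0.7,
                                   svr_C = 1, seed = NULL) {
  stopifnot(nrow(table) >= 20, !is.null(table$nsg))
  X <- laminar_X(table, predictor_set)
  y <- table$nsg
  n <- length(y)
  n_train <- round(train_fraction * n)
  stopifnot(n_train >= 2, n_train < n)
  with_seed(seed, {
    rho <- vapply(seq_len(n_rep), function(r) {
      idx <- sample.int(n, n_train)
      ytr <- y[idx]; yte <- y[-idx]
      Xtr <- X[idx, , drop = FALSE]
      if (sd(ytr) == 0 || all(apply(Xtr, 2, sd) == 0) || sd(yte) == 0)
        return(NA_real_)
      fit <- svr_fit(Xtr, ytr, C = svr_C)
      pred <- predict(fit, X[-idx, , drop = FALSE])
      if (sd(pred) == 0) return(NA_real_)
      spearman_rho(yte, pred)
    }, numeric(1))
    structure(list(rho_per_rep = rho[!is.na(rho)],
                   n_excluded = sum(is.na(rho)),
                   n_rep = n_rep, train_fraction = train_fraction,
                   predictor_set = predictor_set, svr_C = svr_C,
                   seed = seed),
              class = "prediction_eval")
  })
}

#' @export
print.prediction_eval <- function(x, ...) {
  cat(sprintf(
    "<out-of-sample eval> predictors {%s}: median rho = %.3f over %d reps (%d excluded)\n",
    paste(x$predictor_set, collapse = ", "), median(x$rho_per_rep),
    x$n_rep, x$n_excluded))
  invisible(x)
}

#' Permutation null for out-of-sample NSG% predictions
#'
#' Shuffles NSG% across records `n_shuffles` times and reruns the
#' out-of-sample evaluation on each shuffled table (with a reduced
#' number of internal repetitions for tractability), recording the mean
#' held-out rho per shuffle.
#'
#' @inheritParams evaluate_out_of_sample
#' @param n_shuffles number of label shuffles.
#' @param n_rep_inner internal repetitions per shuffle (default 50;
#'   deliberately smaller than the observed evaluation).
#' @return numeric vector of null mean rho values, length `n_shuffles`.
#' @export
permutation_null <- function(table, predictor_set = "cyto_diff",
                             n_shuffles = 100, n_rep_inner = 50,
                             train_fraction = 0.7, svr_C = 1,
                             seed = NULL) {
  with_seed(seed, {
    vapply(seq_len(n_shuffles), function(s) {
      tab <- table
      tab$nsg <- sample(tab$nsg)
      ev <- evaluate_out_of_sample(tab, predictor_set,
                                   n_rep = n_rep_inner,
                                   train_fraction = train_fraction,
                                   svr_C = svr_C, seed = NULL)
      mean(ev$rho_per_rep)
    }, numeric(1))
  })
}

#' Paired comparison of two predictor sets
#'
#' Sign-flip permutation test on the per-repetition difference of
#' held-out Spearman rho between two evaluations run with the same seed
#' stream (paired splits).  Tests whether predictor set A outperforms
#' predictor set B.
#'
#' @param eval_a,eval_b `prediction_eval` objects with equal `n_rep`.
#' @param n_perm sign-flip permutations.
#' @param seed integer seed.
#' @return a `corticonn_test`; `statistic` is the mean rho difference
#'   (A minus B), one-sided p favouring A.
#' @export
compare_predictor_sets <- function(eval_a, eval_b, n_perm = 1000,
                                   seed = NULL) {
  stopifnot(inherits(eval_a, "prediction_eval"),
            inherits(eval_b, "prediction_eval"))
  if (eval_a$n_rep != eval_b$n_rep ||
      length(eval_a$rho_per_rep) != length(eval_b$rho_per_rep))
    stop("evaluations must have matching repetitions")
  d <- eval_a$rho_per_rep - eval_b$rho_per_rep
  obs <- mean(d)
  null_vals <- with_seed(seed, vapply(seq_len(n_perm), function(p)
    mean(d * sample(c(-1, 1), length(d), replace = TRUE)), numeric(1)))
  perm_test_result(obs, null_vals, n_perm, seed)
}

#' Out-of-sample feedforward/feedback classification
#'
#' Same resampling protocol as [evaluate_out_of_sample()] for tables
#' carrying a binary feedforward/feedback label: the SVR is trained on
#' the labels coded 0/100 and its held-out scores are assessed with the
#' ROC AUC.  Splits missing one class are excluded and counted.
#'
#' @param table `laminar_table` with a two-level `class` column
#'   (the alphabetically later level, e.g. "feedforward", is positive).
#' @inheritParams evaluate_out_of_sample
#' @return list of class `classification_eval`: `auc_per_rep`,
#'   `n_excluded`, settings.
#' @export
classify_ff_fb <- function(table, predictor_set = "cyto_diff",
                           n_rep = 1000, train_fraction = 0.7,
                           svr_C = 1, seed = NULL) {
  stopifnot(!is.null(table$class))
  lv <- sort(unique(as.character(table$class)))
  if (length(lv) != 2) stop("class must have exactly two levels")
  y <- as.integer(as.character(table$class) == lv[2])
  X <- laminar_X(table, predictor_set)
  n <- length(y)
  n_train <- round(train_fraction * n)
  with_seed(seed, {
    auc <- vapply(seq_len(n_rep), function(r) {
      idx <- sample.int(n, n_train)
      ytr <- y[idx]; yte <- y[-idx]
      if (length(unique(ytr)) < 2 || length(unique(yte)) < 2)
        return(NA_real_)
      fit <- svr_fit(X[idx, , drop = FALSE], 100 * ytr, C = svr_C)
      roc_auc(predict(fit, X[-idx, , drop = FALSE]), yte)
    }, numeric(1))
    structure(list(auc_per_rep = auc[!is.na(auc)],
                   n_excluded = sum(is.na(auc)), n_rep = n_rep,
                   train_fraction = train_fraction,
                   predictor_set = predictor_set, positive = lv[2],
                   seed = seed),
              class = "classification_eval")
  })
}

#' Extrapolate laminar-origin predictions to a target cortex
#'
#' Applies a cytoarchitecture-based laminar model trained on a source
#' species to every ordered pair of target areas, irrespective of
#' whether a connection exists.  Cytoarchitectonic values are min-max
#' normalized within each species before differencing, since source and
#' target densities live on different measurement scales.  Predictions
#' are clipped to \[0, 100\].
#'
#' @param model a `laminar_model` trained with `predictor_set =
#'   "cyto_diff"` on within-species normalized cyto values.
#' @param target_areas area table for the target cortex (e.g. human
#'   regions with von Economo-Koskinas cell densities).
#' @param normalization only `"minmax_within_species"` is implemented.
#' @return square matrix of predicted NSG%, rows = projection origin,
#'   columns = termination; generally asymmetric.
#' @export
extrapolate_to_target <- function(model, target_areas,
                                  normalization = "minmax_within_species") {
  stopifnot(inherits(model, "laminar_model"),
            identical(model$predictor_set, "cyto_diff"),
            normalization == "minmax_within_species")
  if (is.null(target_areas$cyto) || anyNA(target_areas$cyto))
    stop("target areas lack cytoarchitectonic values")
  cy <- rescale01(target_areas$cyto)
  diff_mat <- outer(cy, cy, "-")    # origin minus termination
  pred <- matrix(predict(model$fit, matrix(as.numeric(diff_mat), ncol = 1)),
                 nrow = nrow(target_areas),
                 dimnames = list(target_areas$id, target_areas$id))
  pred[] <- pmin(100, pmax(0, pred))
  pred
}

#' Aggregate cytoarchitectonic areas into target regions
#'
#' Collapses a correspondence table (atlas region to one or more
#' cytoarchitectonic areas with cell densities) into one area per
#' region, with cyto equal to the arithmetic mean of the assigned
#' densities.  Used to carry von Economo-Koskinas densities onto
#' Desikan-Killiany-style regions before extrapolation.
#'
#' @param correspondence data.frame with columns `region`, `area`,
#'   `density`.
#' @return area data.frame (`id`, `name`, `cyto`), one row per region.
#' @export
map_human_regions <- function(correspondence) {
  stopifnot(all(c("region", "density") %in% names(correspondence)))
  bad <- is.na(correspondence$density)
  if (any(bad))
    stop("regions with no usable density assignment: ",
         paste(unique(correspondence$region[bad]), collapse = ", "))
  agg <- tapply(correspondence$density, correspondence$region, mean)
  regions <- unique(as.character(correspondence$region))
  data.frame(id = regions, name = regions,
             cyto = as.numeric(agg[regions]),
             stringsAsFactors = FALSE)
}
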