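#' Project a directed connectome onto an undirected graph
#'
#' The clique analysis is defined on undirected edges, so the directed
#' status matrix must be projected: under `mutual` an undirected edge
#' requires both directions present (reciprocal connection), under `any`
#' a single direction suffices.  The connectome must be edge-complete
#' (apply [edge_complete_subgraph()] first); unknown statuses are an
#' error, never silently treated as absent.
#'
#' @param x a [connectome].
#' @param edge_rule `"mutual"` (default) or `"any"`.
#' @return symmetric logical adjacency matrix with zero diagonal.
#' @export
undirected_projection <- function(x, edge_rule = c("mutual", "any")) {
  edge_rule <- match.arg(edge_rule)
  stopifnot(inherits(x, "connectome"))
  ids <- intersect(rownames(x$status), colnames(x$status))
  s <- x$status[ids, ids, drop = FALSE]
  s <- offdiag_mask(s)
  diag(s) <- 0L
  if (anyNA(s))
    stop("unknown statuses present; restrict to the edge-complete block first")
  adj <- if (edge_rule == "mutual") (s == 1) & (t(s) == 1)
         else (s == 1) | (t(s) == 1)
  diag(adj) <- FALSE
  dimnames(adj) <- list(ids, ids)
  adj
}

#' Enumerate all maximal cliques
#'
#' Bron-Kerbosch algorithm with pivoting, outer loop in degeneracy
#' order.  Every maximal clique of the simple undirected graph is
#' reported exactly once.
#'
#' @param adj symmetric logical adjacency matrix.
#' @return list of character vectors of vertex names (or indices when
#'   unnamed).
#' @export
maximal_cliques <- function(adj) {
  adj <- adj | FALSE          # coerce to logical
  stopifnot(isSymmetric(unname(adj)))
  n <- nrow(adj)
  diag(adj) <- FALSE
  nbrs <- lapply(seq_len(n), function(i) which(adj[i, ]))
  # degeneracy ordering: repeatedly remove a minimum-degree vertex
  deg <- vapply(nbrs, length, integer(1))
  alive <- rep(TRUE, n)
  ord <- integer(n)
  for (k in seq_len(n)) {
    v <- which(alive)[which.min(deg[alive])]
    ord[k] <- v
    alive[v] <- FALSE
    deg[nbrs[[v]]] <- deg[nbrs[[v]]] - 1L
  }
  cliques <- list()
  bk <- function(R, P, X) {
    if (length(P) == 0L && length(X) == 0L) {
      cliques[[length(cliques) + 1L]] <<- R
      return(invisible())
    }
    # pivot: vertex of P union X with most neighbours in P
    PX <- c(P, X)
    u <- PX[which.max(vapply(PX, function(v) sum(P %in% nbrs[[v]]),
                             integer(1)))]
    for (v in setdiff(P, nbrs[[u]])) {
      nv <- nbrs[[v]]
      bk(c(R, v), intersect(P, nv), intersect(X, nv))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
  }
  later <- rep(TRUE, n)
  for (v in ord) {
    later[v] <- FALSE
    nv <- nbrs[[v]]
    bk(v, nv[later[nv]], nv[!later[nv]])
  }
  nm <- rownames(adj)
  if (is.null(nm)) cliques else lapply(cliques, function(cl) nm[sort(cl)])
}

#' Build the core partition from cliques
#'
#' Keeps the maximum-size cliques only; the core is the union of their
#' members (all ties kept), the periphery the remaining analyzed areas.
#'
#' @param cliques list of cliques (from [maximal_cliques()]).
#' @param all_areas character vector of all analyzed area ids.
#' @return list of class `core_partition`: `cliques` (largest only),
#'   `max_clique_size`, `core`, `periphery`, `edge_rule` (NA here).
#' @export
core_from_cliques <- function(cliques, all_areas) {
  if (length(cliques) == 0L) stop("no cliques supplied")
  sizes <- lengths(cliques)
  top <- cliques[sizes == max(sizes)]
  core <- sort(unique(unlist(top)))
  structure(list(
    cliques = top, max_clique_size = max(sizes),
    core = core, periphery = setdiff(all_areas, core),
    null_max_sizes = NULL, p_value = NA_real_, edge_rule = NA_character_),
    class = "core_partition")
}

#' @export
print.core_partition <- function(x, ...) {
  cat(sprintf(
    "<core partition> %d clique(s) of size %d; core %d areas, periphery %d%s\n",
    length(x$cliques), x$max_clique_size, length(x$core),
    length(x$periphery),
    if (is.na(x$p_value)) "" else sprintf(", p = %.4g", x$p_value)))
  invisible(x)
}

# status matrix -> 0-based directed edge list
directed_edges <- function(s) {
  e <- which(offdiag_mask(s) == 1, arr.ind = TRUE)
  cbind(e[, 1], e[, 2]) - 1L
}

#' Maximum clique sizes of degree-matched surrogate networks
#'
#' Generates surrogate directed networks by Maslov-Sneppen double-edge
#' swaps (10 |E| accepted swaps per surrogate; self-loops and duplicate
#' edges rejected), preserving every node's in- and out-degree exactly,
#' then projects each surrogate with the chosen edge rule and records
#' its maximum clique size.
#'
#' @param x an edge-complete [connectome].
#' @param edge_rule `"mutual"` or `"any"`.
#' @param n_null number of surrogates.
#' @param seed integer seed.
#' @param swaps_per_edge accepted swaps per edge (default 10).
#' @return integer vector of length `n_null`.
#' @export
degree_matched_null_sizes <- function(x, edge_rule = c("mutual", "any"),
                                      n_null = 1000, seed = NULL,
                                      swaps_per_edge = 10) {
  edge_rule <- match.arg(edge_rule)
  stopifnot(inherits(x, "connectome"))
  ids <- intersect(rownames(x$status), colnames(x$status))
  s <- x$status[ids, ids, drop = FALSE]
  if (anyNA(s[row(s) != col(s)]))
    stop("surrogates require an edge-complete connectome")
  edges <- directed_edges(s)
  n <- length(ids)
  n_swap <- swaps_per_edge * nrow(edges)
  with_seed(seed, {
    vapply(seq_len(n_null), function(i) {
      e2 <- cpp_edge_swap(edges, n, n_swap, 100L * nrow(edges))
      s2 <- matrix(0L, n, n, dimnames = list(ids, ids))
      s2[e2 + 1L] <- 1L
      adj <- if (edge_rule == "mutual") (s2 == 1) & (t(s2) == 1)
             else (s2 == 1) | (t(s2) == 1)
      diag(adj) <- FALSE
      max(lengths(maximal_cliques(adj)))
    }, numeric(1))
  })
}

#' Significance of the observed core
#'
#' One-sided permutation-style p-value by the add-one rule: the fraction
#' of surrogates whose maximum clique size reaches the observed one.
#'
#' @param observed_size observed maximum clique size.
#' @param null_sizes surrogate maximum clique sizes.
#' @return p-value in (0, 1\].
#' @export
core_significance <- function(observed_size, null_sizes) {
  stopifnot(length(null_sizes) > 0)
  (sum(null_sizes >= observed_size) + 1) / (length(null_sizes) + 1)
}

#' Detect the structural network core
#'
#' End-to-end core-periphery detection: undirected projection, maximal
#' cliques, core = union of the largest cliques, and significance
#' against degree-matched surrogates.
#'
#' @inheritParams degree_matched_null_sizes
#' @return a `core_partition` with `null_max_sizes` and `p_value` filled
#'   in.
#' @export
detect_core <- function(x, edge_rule = c("mutual", "any"), n_null = 1000,
                        seed = NULL) {
  edge_rule <- match.arg(edge_rule)
  adj <- undirected_projection(x, edge_rule)
  part <- core_from_cliques(maximal_cliques(adj), rownames(adj))
  part$edge_rule <- edge_rule
  part$null_max_sizes <- degree_matched_null_sizes(x, edge_rule,
                                                   n_null = n_null,
                                                   seed = seed)
  part$p_value <- core_significance(part$max_clique_size,
                                    part$null_max_sizes)
  part
}

#' Compare an area attribute between core and periphery
#'
#' Two-sample test (energy or KS) between the attribute values of core
#' and periphery areas; significance by permuting the core/periphery
#' labels.
#'
#' @param partition a `core_partition`.
#' @param values named numeric vector of the attribute (names = area
#'   ids), defined for every analyzed area.
#' @param test `"energy"` or `"ks"`.
#' @param n_perm label permutations.
#' @param seed integer seed.
#' @return a `corticonn_test`.
#' @export
compare_core_periphery_attribute <- function(partition, values,
                                             test = c("energy", "ks"),
                                             n_perm = 1000, seed = NULL) {
  test <- match.arg(test)
  stopifnot(inherits(partition, "core_partition"))
  if (length(partition$core) == 0L || length(partition$periphery) == 0L)
    stop("core and periphery must both be nonempty")
  missing_ids <- setdiff(c(partition$core, partition$periphery),
                         names(values))
  if (length(missing_ids))
    stop("attribute missing for areas: ",
         paste(missing_ids, collapse = ", "))
  vc <- values[partition$core]
  vp <- values[partition$periphery]
  if (test == "energy") energy_test(vc, vp, n_perm = n_perm, seed = seed)
  else ks_perm_test(vc, vp, n_perm = n_perm, seed = seed)
}

#' Robustness of the core-periphery cytoarchitecture contrast
#'
#' Reuses the ordinal type-reassignment scheme of
#' [type_reassignment_robustness()] with the partition held fixed: per
#' fraction and repetition the core-vs-periphery energy statistic is
#' recomputed on the reassigned types; the null shuffles core/periphery
#' labels.
#'
#' @param x a [connectome] with ordinal cytoarchitecture.
#' @param partition a fixed `core_partition`.
#' @param fractions fractions of areas reassigned.
#' @param n_rep repetitions per fraction.
#' @param mode `"clamped"` or `"stretched"`.
#' @param seed integer seed.
#' @return list with `table` (`fraction`, `rep`, `energy`), `null_stats`
#'   (label-permutation energies, length `n_rep`), `baseline`.
#' @export
core_cyto_robustness <- function(x, partition,
                                 fractions = c(0, 0.2, 0.4, 0.6, 0.8),
                                 n_rep = 100,
                                 mode = c("clamped", "stretched"),
                                 seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "connectome"), inherits(partition, "core_partition"))
  if (x$cyto_kind != "type" || any(x$areas$cyto != round(x$areas$cyto)))
    stop("type reassignment requires an ordinal cortical-type scale")
  analyzed <- c(partition$core, partition$periphery)
  cyto0 <- setNames(x$areas$cyto, x$areas$id)[analyzed]
  lo <- min(cyto0); hi <- max(cyto0)
  n <- length(cyto0)
  is_core <- analyzed %in% partition$core
  stat_with <- function(cyto, grp = is_core)
    energy_statistic(cyto[grp], cyto[!grp])
  baseline <- stat_with(cyto0)
  with_seed(seed, {
    rows <- lapply(fractions, function(f) {
      k <- ceiling(f * n)
      st <- vapply(seq_len(n_rep), function(r) {
        if (k == 0) return(baseline)
        idx <- sample.int(n, k)
        stat_with(reassign_types(cyto0, idx, mode, lo, hi))
      }, numeric(1))
      data.frame(fraction = f, rep = seq_len(n_rep), energy = st)
    })
    null_stats <- vapply(seq_len(n_rep), function(r)
      stat_with(cyto0, sample(is_core)), numeric(1))
    list(table = do.call(rbind, rows), null_stats = null_stats,
         baseline = baseline, mode = mode)
  })
}
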