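# directed adjacency from a connectome (edge-complete block), or pass a
# 0/1 matrix straight through
as_directed_adj <- function(x) {
  if (inherits(x, "connectome")) {
    ids <- intersect(rownames(x$status), colnames(x$status))
    s <- x$status[ids, ids, drop = FALSE]
    if (anyNA(s[row(s) != col(s)]))
      stop("unknown statuses present; restrict to the edge-complete block first")
    diag(s) <- 0L
    s
  } else {
    s <- as.matrix(x)
    stopifnot(nrow(s) == ncol(s))
    diag(s) <- 0
    s
  }
}

#' Directed shortest-path length matrix
#'
#' Minimum hop counts between all ordered pairs of a binary directed
#' graph, by breadth-first search from every node; unreachable pairs are
#' `Inf`.
#'
#' @param graph binary directed adjacency matrix (or an edge-complete
#'   [connectome]).
#' @return matrix `D` with zero diagonal.
#' @export
shortest_path_lengths <- function(graph) {
  s <- as_directed_adj(graph)
  n <- nrow(s)
  nbrs <- lapply(seq_len(n), function(i) which(s[i, ] == 1))
  D <- matrix(Inf, n, n, dimnames = dimnames(s))
  for (i in seq_len(n)) {
    dist_i <- rep(Inf, n)
    dist_i[i] <- 0
    frontier <- i
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- unique(unlist(nbrs[frontier]))
      nxt <- nxt[dist_i[nxt] == Inf]
      dist_i[nxt] <- d
      frontier <- nxt
    }
    D[i, ] <- dist_i
  }
  D
}

#' Shortest-path node efficiency
#'
#' Out-efficiency of node i is the mean over all other nodes j of
#' `1/D(i,j)`; in-efficiency uses `1/D(j,i)`; `1/Inf = 0`.  Values lie
#' in \[0, 1\], with 1 attained on a complete directed graph.
#'
#' @inheritParams shortest_path_lengths
#' @return data.frame with `area`, `eff_out_sp`, `eff_in_sp`.
#' @export
node_efficiency <- function(graph) {
  D <- shortest_path_lengths(graph)
  n <- nrow(D)
  inv <- 1 / D
  diag(inv) <- 0
  data.frame(area = rownames(D) %||% as.character(seq_len(n)),
             eff_out_sp = rowSums(inv) / (n - 1),
             eff_in_sp = colSums(inv) / (n - 1),
             row.names = NULL, stringsAsFactors = FALSE)
}

# strongly connected components (Kosaraju), for error reporting
scc_membership <- function(s) {
  n <- nrow(s)
  reach <- function(adj, start) {
    seen <- rep(FALSE, n)
    seen[start] <- TRUE
    frontier <- start
    while (length(frontier)) {
      nxt <- unique(unlist(lapply(frontier, function(i) which(adj[i, ] == 1))))
      nxt <- nxt[!seen[nxt]]
      seen[nxt] <- TRUE
      frontier <- nxt
    }
    seen
  }
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (v in seq_len(n)) {
    if (!is.na(comp[v])) next
    k <- k + 1L
    members <- which(reach(s, v) & reach(t(s), v) & is.na(comp))
    comp[members] <- k
  }
  comp
}

#' Mean first-passage times of the random walk on a directed graph
#'
#' The walk moves from a node uniformly at random along its out-edges
#' (transition matrix P = row-normalized adjacency).  For an irreducible
#' chain the stationary distribution pi is the left eigenvector of P,
#' and MFPTs come from the fundamental matrix
#' `Z = (I - P + 1 pi')^{-1}` via `H(i,j) = (Z(j,j) - Z(i,j)) / pi(j)`,
#' with `H(i,i) = 0` by convention.
#'
#' @inheritParams shortest_path_lengths
#' @return list with `H` (MFPT matrix) and `pi` (stationary
#'   distribution).
#' @export
mean_first_passage_times <- function(graph) {
  s <- as_directed_adj(graph)
  n <- nrow(s)
  comp <- scc_membership(s)
  if (length(unique(comp)) > 1L) {
    sizes <- table(comp)
    stop("graph is not strongly connected: ", length(sizes),
         " components of sizes ", paste(sizes, collapse = ", "))
  }
  P <- s / rowSums(s)
  # pi: left eigenvector for eigenvalue 1
  e <- eigen(t(P))
  i1 <- which.min(abs(e$values - 1))
  pi_v <- Re(e$vectors[, i1])
  pi_v <- pi_v / sum(pi_v)
  if (any(pi_v <= 0))
    stop("stationary distribution has nonpositive entries; chain degenerate")
  Z <- solve(diag(n) - P + matrix(1, n, 1) %*% t(pi_v))
  H <- (matrix(diag(Z), n, n, byrow = TRUE) - Z) /
    matrix(pi_v, n, n, byrow = TRUE)
  diag(H) <- 0
  dimnames(H) <- dimnames(s)
  list(H = H, pi = setNames(pi_v, rownames(s)))
}

#' Random-walk (diffusion) node efficiency
#'
#' Pairwise diffusion efficiency is the reciprocal mean first-passage
#' time `1/H(i,j)`; out- and in-efficiency average it over targets and
#' sources respectively.
#'
#' @inheritParams shortest_path_lengths
#' @return data.frame with `area`, `eff_out_diff`, `eff_in_diff`.
#' @export
diffusion_efficiency <- function(graph) {
  mf <- mean_first_passage_times(graph)
  H <- mf$H
  n <- nrow(H)
  inv <- 1 / H
  diag(inv) <- 0
  data.frame(area = rownames(H) %||% as.character(seq_len(n)),
             eff_out_diff = rowSums(inv) / (n - 1),
             eff_in_diff = colSums(inv) / (n - 1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Full communication-efficiency profile
#'
#' Per-area shortest-path and diffusion efficiencies plus the internal
#' matrices (shortest-path lengths, MFPTs, stationary distribution).
#'
#' @inheritParams shortest_path_lengths
#' @return list of class `efficiency_profile`: `per_area` data.frame and
#'   internals `D`, `H`, `pi`.
#' @export
efficiency_profile <- function(graph) {
  sp <- node_efficiency(graph)
  mf <- mean_first_passage_times(graph)
  H <- mf$H
  inv <- 1 / H
  diag(inv) <- 0
  n <- nrow(H)
  per_area <- cbind(sp,
                    eff_out_diff = rowSums(inv) / (n - 1),
                    eff_in_diff = colSums(inv) / (n - 1))
  structure(list(per_area = per_area,
                 D = shortest_path_lengths(graph), H = H, pi = mf$pi),
            class = "efficiency_profile")
}

#' Compare core and periphery communication efficiency
#'
#' Kolmogorov-Smirnov permutation tests between core and periphery
#' values of each of the four efficiency measures (in/out crossed with
#' shortest-path/diffusion), with core/periphery label shuffles as the
#' null.
#'
#' @param partition a `core_partition`.
#' @param profile an `efficiency_profile` on the same analyzed areas.
#' @param n_perm label permutations per measure.
#' @param seed integer seed.
#' @return named list of four `corticonn_test`s (`eff_in_sp`,
#'   `eff_out_sp`, `eff_in_diff`, `eff_out_diff`), each with extra
#'   fields `median_core`, `median_periphery`.
#' @export
compare_core_periphery_efficiency <- function(partition, profile,
                                              n_perm = 1000, seed = NULL) {
  stopifnot(inherits(partition, "core_partition"),
            inherits(profile, "efficiency_profile"))
  pa <- profile$per_area
  if (!setequal(pa$area, c(partition$core, partition$periphery)))
    stop("profile and partition cover different area sets")
  if (length(partition$core) == 0L || length(partition$periphery) == 0L)
    stop("core and periphery must both be nonempty")
  measures <- c("eff_in_sp", "eff_out_sp", "eff_in_diff", "eff_out_diff")
  seeds <- if (is.null(seed)) vector("list", 4) else as.list(seed + 0:3)
  out <- lapply(seq_along(measures), function(k) {
    v <- setNames(pa[[measures[k]]], pa$area)
    r <- ks_perm_test(v[partition$core], v[partition$periphery],
                      n_perm = n_perm, seed = seeds[[k]])
    r$median_core <- median(v[partition$core])
    r$median_periphery <- median(v[partition$periphery])
    r
  })
  setNames(out, measures)
}
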