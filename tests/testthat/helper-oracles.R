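# Independent oracles: deliberately naive implementations used only to
# check the package's optimized paths on tiny inputs.

# energy statistic by direct double loops over the printed formula
oracle_energy <- function(x, y, eps = 1e-8) {
  n <- length(x); m <- length(y)
  lp <- function(a, b) log(pmax(abs(a - b), eps))
  sxx <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) sxx <- sxx + lp(x[i], x[j])
  syy <- 0
  for (i in seq_len(m - 1)) for (j in (i + 1):m) syy <- syy + lp(y[i], y[j])
  sxy <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) sxy <- sxy + lp(x[i], y[j])
  -sxx / n^2 - syy / m^2 + sxy / (n * m)
}

# KS statistic by brute-force ECDF sup over all breakpoints
oracle_ks <- function(x, y) {
  br <- sort(unique(c(x, y)))
  max(vapply(br, function(b) abs(mean(x <= b) - mean(y <= b)), numeric(1)))
}

# Spearman rho: rank (ties averaged) then textbook Pearson
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# AUC by trapezoidal integration of the ROC curve
oracle_auc <- function(scores, labels) {
  th <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(th, function(t) mean(scores[labels == 1] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(scores[labels == 0] >= t), numeric(1))
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# maximal cliques by exhaustive subset enumeration (n <= 15): a subset is
# a maximal clique iff all pairs are adjacent and no outside vertex is
# adjacent to every member
oracle_cliques <- function(adj) {
  n <- nrow(adj)
  maximal <- list()
  for (m in seq_len(2^n - 1)) {
    v <- which(bitwAnd(m, 2^(0:(n - 1))) > 0)
    if (length(v) > 1 && !all(adj[v, v][upper.tri(matrix(0, length(v), length(v)))]))
      next
    out <- setdiff(seq_len(n), v)
    if (length(out) && any(colSums(adj[v, out, drop = FALSE]) == length(v)))
      next
    maximal[[length(maximal) + 1L]] <- v
  }
  nm <- rownames(adj)
  lapply(maximal, function(v) if (is.null(nm)) v else nm[v])
}

# all-pairs shortest paths by Floyd-Warshall
oracle_floyd <- function(s) {
  n <- nrow(s)
  D <- unname(ifelse(s == 1, 1, Inf))
  diag(D) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# Monte-Carlo mean first-passage time i -> j (vectorized over walks)
oracle_mfpt_mc <- function(s, i, j, n_walks = 2000, max_steps = 5000) {
  nbr <- lapply(seq_len(nrow(s)), function(v) which(s[v, ] == 1))
  deg <- lengths(nbr)
  nbr_mat <- matrix(0L, nrow(s), max(deg))
  for (v in seq_len(nrow(s))) nbr_mat[v, seq_len(deg[v])] <- nbr[[v]]
  cur <- rep.int(i, n_walks)
  steps <- rep.int(NA_integer_, n_walks)
  active <- rep(TRUE, n_walks)
  for (t in seq_len(max_steps)) {
    idx <- which(active)
    if (!length(idx)) break
    pick <- ceiling(runif(length(idx)) * deg[cur[idx]])
    cur[idx] <- nbr_mat[cbind(cur[idx], pick)]
    hit <- idx[cur[idx] == j]
    steps[hit] <- t
    active[hit] <- FALSE
  }
  steps <- steps[!is.na(steps)]
  list(mean = mean(steps), se = sd(steps) / sqrt(length(steps)),
       n = length(steps))
}

# logistic log-likelihood maximized by a generic optimizer
oracle_logistic_loglik <- function(X, y) {
  nll <- function(b) {
    eta <- as.numeric(cbind(1, X) %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  fit <- optim(rep(0, ncol(X) + 1), nll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-12))
  -fit$value
}

# canonical string form of a clique list, for set equality
clique_key <- function(cliques)
  sort(vapply(cliques, function(v) paste(sort(as.character(v)), collapse = "|"),
              character(1)))
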