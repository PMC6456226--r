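# Small connectomes and graphs built in code; no stored fixtures.

# fully specified toy connectome: n areas on a line, all statuses known,
# Bernoulli(p) edges
toy_connectome <- function(n = 6, p = 0.6, cyto = NULL, seed = 1,
                           cyto_kind = "type") {
  set.seed(seed)
  ids <- if (n <= 26) LETTERS[seq_len(n)] else sprintf("A%02d", seq_len(n))
  areas <- data.frame(id = ids, name = ids,
                      cyto = cyto %||% sample(1:5, n, replace = TRUE),
                      x = seq_len(n), y = 0, z = 0)
  status <- matrix(rbinom(n * n, 1, p), n, n, dimnames = list(ids, ids))
  diag(status) <- NA_integer_
  connectome(areas, status, species = "toy", cyto_kind = cyto_kind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random directed simple graph as 0/1 matrix
random_digraph <- function(n, p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- matrix(rbinom(n * n, 1, p), n, n)
  diag(s) <- 0L
  dimnames(s) <- list(paste0("v", 1:n), paste0("v", 1:n))
  s
}

# random strongly connected digraph: overlay a directed Hamiltonian cycle
random_strong_digraph <- function(n, p, seed = NULL) {
  s <- random_digraph(n, p, seed)
  ord <- sample(n)
  for (k in seq_len(n)) s[ord[k], ord[k %% n + 1]] <- 1L
  s
}

# random undirected adjacency (logical, symmetric)
random_undirected <- function(n, p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- matrix(FALSE, n, n)
  a[upper.tri(a)] <- runif(n * (n - 1) / 2) < p
  a <- a | t(a)
  dimnames(a) <- list(paste0("v", 1:n), paste0("v", 1:n))
  a
}

# synthetic laminar table with a strong cytoarchitectonic signal
strong_laminar <- function(n_areas = 60, seed = 11, nsg_slope = 30,
                           nsg_noise_sd = 5) {
  spec <- synthetic_spec(n_areas = n_areas, nsg_slope = nsg_slope,
                         nsg_noise_sd = nsg_noise_sd, seed = seed)
  generate_cortex(spec)$laminar
}
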