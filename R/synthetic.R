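#' Specify a synthetic cortex
#'
#' The generator emulates the structure the downstream analyses assume:
#' spatially embedded areas, a smooth cytoarchitectonic gradient radiating
#' from an origin point, connection probabilities that decay logistically
#' with rescaled distance and cytoarchitectonic dissimilarity, NSG%
#' (percentage of supragranular projection neurons) generated as a noisy
#' monotone function of the signed cytoarchitectonic difference, and an
#' optionally planted reciprocal clique acting as a structural core.
#'
#' Defaults describe a mid-sized mammalian cortex: 100 areas scattered on
#' a 10 mm square sheet, distance coefficient -3 and dissimilarity
#' coefficient -2 on the unit-rescaled predictors (connections strongly
#' favour nearby, cytoarchitectonically similar areas), NSG% slope 30
#' with residual SD 5 on the 0-100 scale.
#'
#' @param n_areas number of cortical areas (>= 4).
#' @param layout `"uniform2d"` (areas uniform on a square sheet),
#'   `"grid2d"` (regular grid) or `"line"`.
#' @param gradient_origin point in layout space from which the
#'   cytoarchitectonic gradient radiates (defaults to the sheet corner).
#' @param gradient_noise_sd SD of Gaussian noise added to the gradient
#'   (on the 1-5 cortical-type scale).
#' @param cyto_scale `"continuous"` or `"ordinal"`; ordinal values are
#'   binned into `cyto_levels` equal-frequency levels.
#' @param cyto_levels number of ordinal cortical types.
#' @param beta0,beta_d,beta_c intercept and logistic coefficients on the
#'   rescaled distance and dissimilarity.
#' @param nsg_slope NSG% change per SD of signed cytoarchitectonic
#'   difference (origin minus termination).
#' @param nsg_noise_sd SD of NSG% noise (percentage points).
#' @param planted_core_size size of the planted reciprocal clique (0 =
#'   none).
#' @param seed integer seed driving all randomness of the generator.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_areas = 100,
                           layout = c("uniform2d", "grid2d", "line"),
                           gradient_origin = c(0, 0),
                           gradient_noise_sd = 0.25,
                           cyto_scale = c("continuous", "ordinal"),
                           cyto_levels = 5,
                           beta0 = 0, beta_d = -3, beta_c = -2,
                           nsg_slope = 30, nsg_noise_sd = 5,
                           planted_core_size = 0,
                           seed = 1) {
  layout <- match.arg(layout)
  cyto_scale <- match.arg(cyto_scale)
  stopifnot(n_areas >= 4, gradient_noise_sd >= 0, nsg_noise_sd >= 0,
            planted_core_size >= 0, planted_core_size <= n_areas,
            cyto_levels >= 2)
  structure(list(
    n_areas = as.integer(n_areas), layout = layout,
    gradient_origin = gradient_origin,
    gradient_noise_sd = gradient_noise_sd, cyto_scale = cyto_scale,
    cyto_levels = as.integer(cyto_levels),
    beta0 = beta0, beta_d = beta_d, beta_c = beta_c,
    nsg_slope = nsg_slope, nsg_noise_sd = nsg_noise_sd,
    planted_core_size = as.integer(planted_core_size),
    seed = as.integer(seed)), class = "synthetic_spec")
}

# side length of the square sheet, in mm
.sheet_mm <- 10

#' Generate synthetic cortical areas
#'
#' Places areas according to the layout and assigns each a cytoarchitectonic
#' value increasing with distance from the gradient origin (mapped onto the
#' 1-5 cortical-type range) plus Gaussian noise.  For an ordinal scale the
#' values are binned into equal-frequency levels so every level is
#' populated.  The rostrocaudal coordinate is the normalized first spatial
#' coordinate (1 = most rostral).
#'
#' @param spec a [synthetic_spec()].
#' @return area data.frame (`id`, `name`, `cyto`, `x`, `y`, `z`,
#'   `rostrocaudal`).
#' @export
generate_areas <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n_areas
    xy <- switch(spec$layout,
      uniform2d = cbind(runif(n), runif(n)) * .sheet_mm,
      grid2d = {
        k <- ceiling(sqrt(n))
        g <- expand.grid(seq(0, 1, length.out = k),
                         seq(0, 1, length.out = k))[seq_len(n), ]
        as.matrix(g) * .sheet_mm
      },
      line = cbind(seq(0, 1, length.out = n), 0) * .sheet_mm)
    origin <- spec$gradient_origin
    if (length(origin) < 2) origin <- c(origin, 0)
    gdist <- sqrt((xy[, 1] - origin[1])^2 + (xy[, 2] - origin[2])^2)
    base <- 1 + 4 * rescale01(gdist)          # map onto cortical types 1-5
    cyto <- base + rnorm(n, sd = spec$gradient_noise_sd)
    cyto <- pmax(cyto, 0.1)                   # cyto must stay positive
    if (spec$cyto_scale == "ordinal") {
      qs <- quantile(cyto, probs = seq(0, 1, length.out = spec$cyto_levels + 1))
      cyto <- as.numeric(cut(cyto, breaks = unique(qs), include.lowest = TRUE,
                             labels = FALSE))
    }
    data.frame(
      id = sprintf("A%03d", seq_len(n)),
      name = sprintf("synthetic area %d", seq_len(n)),
      cyto = cyto, x = xy[, 1], y = xy[, 2], z = 0,
      rostrocaudal = rescale01(xy[, 1]),
      stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic connectome from areas
#'
#' For every ordered pair the connection probability is
#' `plogis(beta0 + beta_d * d01 + beta_c * c01)` with `d01` (Euclidean
#' distance) and `c01` (absolute cytoarchitectonic difference) rescaled to
#' \[0, 1\] over all ordered pairs; statuses are sampled independently.
#' The realized probability matrix is attached as attribute `truth`.
#'
#' @param areas area table from [generate_areas()].
#' @param spec a [synthetic_spec()].
#' @return a [connectome] with a `truth` attribute (probability matrix).
#' @export
generate_connectome <- function(areas, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- nrow(areas)
  D <- as.matrix(dist(as.matrix(areas[, c("x", "y", "z")])))
  dimnames(D) <- list(areas$id, areas$id)
  off <- row(D) != col(D)
  C <- abs(outer(areas$cyto, areas$cyto, "-"))
  d01 <- matrix(0, n, n); c01 <- matrix(0, n, n)
  d01[off] <- rescale01(D[off])
  c01[off] <- rescale01(C[off])
  prob <- plogis(spec$beta0 + spec$beta_d * d01 + spec$beta_c * c01)
  status <- matrix(NA_integer_, n, n, dimnames = dimnames(D))
  with_seed(spec$seed + 1L,
            status[off] <- rbinom(sum(off), 1, prob[off]))
  cyto_kind <- if (spec$cyto_scale == "ordinal") "type" else "density"
  conn <- connectome(areas, status, D, species = "synthetic",
                     distance_kind = "euclidean", cyto_kind = cyto_kind)
  dimnames(prob) <- dimnames(D)
  attr(conn, "truth") <- prob
  conn
}

#' Generate synthetic laminar-origin data
#'
#' For every present edge, NSG% is 50 plus `nsg_slope` times the
#' standardized signed cytoarchitectonic difference (origin minus
#' termination) plus Gaussian noise, clipped to \[0, 100\].  Equal
#' cytoarchitecture therefore yields "lateral-type" connections centred
#' on 50.
#'
#' @param areas area table.
#' @param conn connectome over `areas`.
#' @param spec a [synthetic_spec()].
#' @return data.frame of class `laminar_table` with `origin`,
#'   `termination`, `nsg`, `cyto_diff`, `rc_diff`.
#' @export
generate_laminar <- function(areas, conn, spec) {
  stopifnot(inherits(conn, "connectome"), inherits(spec, "synthetic_spec"))
  status <- offdiag_mask(conn$status)
  e <- which(status == 1, arr.ind = TRUE)
  if (nrow(e) == 0L) stop("connectome has no present edges")
  origin <- rownames(status)[e[, 1]]
  termination <- colnames(status)[e[, 2]]
  cyto <- setNames(areas$cyto, areas$id)
  rc <- setNames(areas$rostrocaudal, areas$id)
  s <- cyto[origin] - cyto[termination]
  # scale by the SD only: the signed difference is symmetric around zero
  # by construction, and not re-centering keeps equal-cyto pairs at 50
  z <- if (sd(s) > 0) s / sd(s) else s * 0
  nsg <- with_seed(spec$seed + 2L,
                   50 + spec$nsg_slope * z + rnorm(length(z),
                                                   sd = spec$nsg_noise_sd))
  out <- data.frame(
    origin = origin, termination = termination,
    nsg = pmin(100, pmax(0, nsg)),
    cyto_diff = as.numeric(s),
    rc_diff = as.numeric(rc[origin] - rc[termination]),
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("laminar_table", "data.frame")
  out
}

#' Plant a reciprocal clique in a connectome
#'
#' Chooses `k` areas at random and sets every ordered pair among them to
#' present (a fully reciprocal clique); all other statuses are untouched.
#' Used as a ground-truth structural core for recovery tests.
#'
#' @param conn a [connectome].
#' @param k clique size (>= 2).
#' @param seed integer seed for the choice of areas.
#' @return the modified connectome, with attribute `planted_core` holding
#'   the chosen area ids.
#' @export
plant_core <- function(conn, k, seed = 1) {
  stopifnot(inherits(conn, "connectome"))
  ids <- intersect(rownames(conn$status), colnames(conn$status))
  if (k < 2) stop("planted core must have k >= 2")
  if (k > length(ids)) stop("k exceeds the number of areas")
  members <- with_seed(seed, sample(ids, k))
  block <- matrix(1L, k, k); diag(block) <- NA_integer_
  conn$status[members, members] <- block
  attr(conn, "planted_core") <- members
  conn
}

#' Generate a full synthetic cortex
#'
#' Convenience wrapper: areas, connectome (with optional planted core)
#' and laminar table from one spec, with the full ground truth retained.
#'
#' @param spec a [synthetic_spec()].
#' @return list of class `synthetic_cortex` with elements `connectome`,
#'   `laminar`, `truth` (spec + probability matrix + planted core ids).
#' @export
generate_cortex <- function(spec) {
  areas <- generate_areas(spec)
  conn <- generate_connectome(areas, spec)
  planted <- NULL
  if (spec$planted_core_size >= 2) {
    conn <- plant_core(conn, spec$planted_core_size, seed = spec$seed + 3L)
    planted <- attr(conn, "planted_core")
  }
  laminar <- generate_laminar(areas, conn, spec)
  structure(list(
    connectome = conn, laminar = laminar,
    truth = list(spec = spec, prob = attr(conn, "truth"),
                 planted_core = planted)),
    class = "synthetic_cortex")
}
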