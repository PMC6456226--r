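#' Construct a connectome object
#'
#' A connectome bundles a directed tri-state adjacency ("status") matrix,
#' an interareal distance matrix, and a per-area attribute table.  Status
#' entries are `1` (connection present), `0` (absent) or `NA` (unknown:
#' the pair was never tested).  Unknown is an explicit third state and is
#' never coerced to absent.  The status matrix may be rectangular
#' (rows = injected source areas, columns = all areas), as produced by
#' retrograde tract-tracing compilations.
#'
#' @param areas data.frame with columns `id`, `name`, `cyto` (ordinal
#'   cortical type or neuronal density per mm^3), `x`, `y`, `z` (atlas
#'   native coordinates; `x` is the rostrocaudal axis, larger = more
#'   rostral) and optionally `rostrocaudal` (pre-normalized to \[0, 1\],
#'   1 = most rostral; computed from `x` when absent).
#' @param status integer/numeric matrix in \{1, 0, NA\} with area ids as
#'   dimnames; row ids must be a subset of column ids.
#' @param distance nonnegative distance matrix over all areas (geodesic
#'   mm, Euclidean mm, or ordinal border counts); symmetric where both
#'   entries are known.  Computed as Euclidean distance from coordinates
#'   when `NULL`.
#' @param species species label.
#' @param distance_kind one of `"geodesic"`, `"euclidean"`, `"border"`.
#' @param cyto_kind `"type"` for the ordinal cortical-type scale,
#'   `"density"` for neurons per mm^3.
#' @return An object of class `connectome`.
#' @export
connectome <- function(areas, status, distance = NULL, species = "unknown",
                       distance_kind = c("euclidean", "geodesic", "border"),
                       cyto_kind = c("type", "density")) {
  distance_kind <- match.arg(distance_kind)
  cyto_kind <- match.arg(cyto_kind)
  stopifnot(is.data.frame(areas))
  required <- c("id", "cyto")
  missing_cols <- setdiff(required, names(areas))
  if (length(missing_cols))
    stop("areas table lacks columns: ", paste(missing_cols, collapse = ", "))
  areas$id <- as.character(areas$id)
  if (anyDuplicated(areas$id))
    stop("duplicated area ids: ",
         paste(unique(areas$id[duplicated(areas$id)]), collapse = ", "))
  if (!all(is.finite(areas$cyto)) || any(areas$cyto <= 0))
    stop("cyto must be finite and positive for every area")
  if (is.null(areas$name)) areas$name <- areas$id
  if (is.null(areas$rostrocaudal)) {
    areas$rostrocaudal <- if (!is.null(areas$x) &&
                              length(unique(areas$x)) > 1L)
      rescale01(areas$x) else rep(NA_real_, nrow(areas))
  }
  rc <- areas$rostrocaudal
  if (any(!is.na(rc) & (rc < 0 | rc > 1)))
    stop("rostrocaudal coordinates must lie in [0, 1] after normalization")

  status <- as.matrix(status)
  if (is.null(rownames(status)) || is.null(colnames(status)))
    stop("status matrix must carry area ids as dimnames")
  bad <- !(status %in% c(0, 1) | is.na(status))
  if (any(bad))
    stop("status entries must be 1, 0 or NA")
  extra <- setdiff(c(rownames(status), colnames(status)), areas$id)
  if (length(extra))
    stop("status matrix ids missing from areas table: ",
         paste(unique(extra), collapse = ", "))
  if (!all(rownames(status) %in% colnames(status)))
    stop("status row ids must be a subset of column ids")

  if (is.null(distance)) {
    xyz <- as.matrix(areas[, intersect(c("x", "y", "z"), names(areas)),
                           drop = FALSE])
    if (ncol(xyz) == 0L)
      stop("no coordinates available to derive a distance matrix")
    distance <- as.matrix(dist(xyz))
    dimnames(distance) <- list(areas$id, areas$id)
  }
  distance <- as.matrix(distance)
  if (any(distance < 0, na.rm = TRUE))
    stop("distances must be nonnegative")

  structure(
    list(areas = areas, status = status, distance = distance,
         species = species, distance_kind = distance_kind,
         cyto_kind = cyto_kind),
    class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  known <- sum(!is.na(offdiag_mask(x$status)))
  cat(sprintf(
    "<connectome> %s: %d x %d status matrix, %d areas, %d known pairs (%s cyto, %s distance)\n",
    x$species, nrow(x$status), ncol(x$status), nrow(x$areas), known,
    x$cyto_kind, x$distance_kind))
  invisible(x)
}

# status entries with the diagonal (self-connections) masked out
offdiag_mask <- function(status) {
  diag_pairs <- outer(rownames(status), colnames(status), "==")
  status[diag_pairs] <- NA
  status
}

#' Read a connectome from CSV files
#'
#' The adjacency CSV has area ids in the first column and header row;
#' cells are `1`, `0` or `NA` ("NA" is the sole unknown token).  The
#' areas CSV provides `id,name,cyto,x,y,z` (and optionally
#' `rostrocaudal`).  An optional distance CSV mirrors the adjacency
#' layout with nonnegative reals.
#'
#' @param adjacency_path path to the adjacency CSV.
#' @param areas_path path to the area-attributes CSV.
#' @param species species label stored on the object.
#' @param distance_path optional distance-matrix CSV; when absent,
#'   Euclidean distances are derived from the area coordinates.
#' @inheritParams connectome
#' @return A [connectome] object.
#' @export
load_connectome <- function(adjacency_path, areas_path, species,
                            distance_path = NULL,
                            distance_kind = if (is.null(distance_path))
                              "euclidean" else "geodesic",
                            cyto_kind = c("type", "density")) {
  adj_raw <- read.csv(adjacency_path, row.names = 1, check.names = FALSE)
  status <- as.matrix(adj_raw)
  bad <- which(!(status %in% c(0, 1) | is.na(status)), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-{1,0,NA} adjacency cell at row '%s', column '%s'",
                 rownames(status)[bad[1, 1]], colnames(status)[bad[1, 2]]))
  storage.mode(status) <- "integer"

  areas <- read.csv(areas_path, stringsAsFactors = FALSE)
  areas$id <- as.character(areas$id)
  adj_ids <- unique(c(rownames(status), colnames(status)))
  missing_areas <- setdiff(adj_ids, areas$id)
  if (length(missing_areas))
    stop("adjacency ids absent from areas file: ",
         paste(missing_areas, collapse = ", "))
  extra_areas <- setdiff(areas$id, adj_ids)
  if (length(extra_areas))
    stop("areas file ids absent from adjacency: ",
         paste(extra_areas, collapse = ", "))
  # order areas by adjacency columns so matrices and table align
  areas <- areas[match(colnames(status), areas$id), , drop = FALSE]
  rownames(areas) <- NULL

  distance <- NULL
  if (!is.null(distance_path)) {
    distance <- as.matrix(read.csv(distance_path, row.names = 1,
                                   check.names = FALSE))
    distance <- distance[colnames(status), colnames(status)]
  }
  connectome(areas, status, distance, species = species,
             distance_kind = match.arg(distance_kind,
                                       c("euclidean", "geodesic", "border")),
             cyto_kind = match.arg(cyto_kind))
}

#' Write a connectome to CSV files
#'
#' Emits the same dialect [load_connectome()] reads (comma-separated,
#' "NA" for unknown), so write/load round-trips are the identity on
#' status, distance and attributes.
#'
#' @param x a [connectome].
#' @param adjacency_path,areas_path,distance_path output paths
#'   (`distance_path = NULL` skips the distance matrix).
#' @return `x`, invisibly.
#' @export
write_connectome <- function(x, adjacency_path, areas_path,
                             distance_path = NULL) {
  stopifnot(inherits(x, "connectome"))
  write.csv(as.data.frame(x$status), adjacency_path)
  write.csv(x$areas, areas_path, row.names = FALSE)
  if (!is.null(distance_path))
    write.csv(as.data.frame(x$distance), distance_path)
  invisible(x)
}

#' Linearly rescale values to the unit interval
#'
#' Affine map sending the minimum to 0 and the maximum to 1; order is
#' preserved.  Applied to each predictor separately within each species
#' before any cross-species pooling.
#'
#' @param values numeric vector with at least two distinct finite values.
#' @return numeric vector in \[0, 1\].
#' @export
rescale01 <- function(values) {
  stopifnot(is.numeric(values))
  r <- range(values, na.rm = TRUE)
  if (!all(is.finite(r)))
    stop("rescale01 needs finite values")
  if (r[1] == r[2])
    stop("rescale01 is degenerate on a constant vector")
  (values - r[1]) / (r[2] - r[1])
}

#' Cytoarchitectonic dissimilarity of two areas
#'
#' Absolute difference of the cortical type or neuronal density of a pair
#' of areas.  Symmetric; zero for identical cytoarchitecture.  Both areas
#' must be measured on the same scale (ordinal type vs density).
#'
#' @param a,b single-row slices of an area table (or plain numeric cyto
#'   values).
#' @param kind_a,kind_b optional scale labels (`"type"`/`"density"`)
#'   checked for agreement when both given.
#' @return nonnegative real.
#' @export
cyto_dissimilarity <- function(a, b, kind_a = NULL, kind_b = NULL) {
  get_cyto <- function(z) if (is.data.frame(z)) z$cyto else z
  if (!is.null(kind_a) && !is.null(kind_b) && !identical(kind_a, kind_b))
    stop("cannot mix cytoarchitectonic scales ('", kind_a, "' vs '",
         kind_b, "')")
  ca <- get_cyto(a); cb <- get_cyto(b)
  stopifnot(is.numeric(ca), is.numeric(cb))
  abs(ca - cb)
}

#' Build the ordered area-pair table
#'
#' One record per ordered (source, target) pair whose connection status
#' is known; unknown pairs are excluded, never imputed.  Distance and
#' cytoarchitectonic dissimilarity are rescaled to \[0, 1\] over exactly
#' the included pairs of this species, so pooled cross-species models see
#' per-species normalized predictors.
#'
#' @param x a [connectome].
#' @return data.frame of class `pair_table` with columns `source`,
#'   `target`, `d01`, `c01`, `status` (factor present/absent), `species`.
#' @export
build_pair_table <- function(x) {
  stopifnot(inherits(x, "connectome"))
  status <- offdiag_mask(x$status)
  known <- which(!is.na(status), arr.ind = TRUE)
  if (nrow(known) == 0L)
    stop("no pairs with known connection status")
  src <- rownames(status)[known[, 1]]
  tgt <- colnames(status)[known[, 2]]
  cyto <- setNames(x$areas$cyto, x$areas$id)
  d <- x$distance[cbind(match(src, rownames(x$distance)),
                        match(tgt, colnames(x$distance)))]
  cdis <- abs(cyto[src] - cyto[tgt])
  out <- data.frame(
    source = src, target = tgt,
    d01 = rescale01(d), c01 = rescale01(cdis),
    status = factor(ifelse(status[known] == 1, "present", "absent"),
                    levels = c("absent", "present")),
    species = x$species,
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("pair_table", "data.frame")
  out
}

#' Restrict a connectome to its edge-complete block
#'
#' Keeps the areas whose connection status is known for every ordered
#' pair among them.  For injection-based rectangular matrices this is the
#' square block of injected areas; areas lacking data are dropped from
#' core-periphery and efficiency analyses.
#'
#' @param x a [connectome].
#' @return A square, fully known [connectome].
#' @export
edge_complete_subgraph <- function(x) {
  stopifnot(inherits(x, "connectome"))
  # only injected (row) areas can belong to a fully known block
  keep <- intersect(rownames(x$status), colnames(x$status))
  # greedily drop the area with the most unknown pairs until the block is
  # edge-complete (exact for the usual injected-square-block case)
  repeat {
    if (length(keep) < 3L) break
    sub <- offdiag_mask(x$status[keep, keep, drop = FALSE])
    diag(sub) <- 0L
    n_unknown <- rowSums(is.na(sub)) + colSums(is.na(sub))
    if (all(n_unknown == 0L)) break
    keep <- keep[-which.max(n_unknown)]
  }
  if (length(keep) < 3L)
    stop("edge-complete subgraph has fewer than 3 areas")
  connectome(
    areas = x$areas[match(keep, x$areas$id), , drop = FALSE],
    status = x$status[keep, keep, drop = FALSE],
    distance = x$distance[keep, keep, drop = FALSE],
    species = x$species, distance_kind = x$distance_kind,
    cyto_kind = x$cyto_kind)
}
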