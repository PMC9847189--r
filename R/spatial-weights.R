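#' Spatial contiguity weights
#'
#' Constructs a symmetric first-order contiguity structure over a set of areal
#' units. Neighbor sets never contain the unit itself; self-inclusion (needed by
#' the Gi* statistic) is carried as a flag and applied at computation time.
#'
#' @param ids character vector of unit identifiers (unique).
#' @param neighbors named list mapping each id to a character vector of
#'   neighboring ids. Must be symmetric: `j %in% neighbors[[i]]` iff
#'   `i %in% neighbors[[j]]`. Units with no neighbors get `character(0)`.
#' @param include_self logical; whether statistics over these weights treat each
#'   unit as its own neighbor with weight 1 (the Gi* convention).
#' @param scheme weighting scheme, `"binary"` (0/1 weights) or
#'   `"row_standardized"` (each row of weights sums to 1).
#'
#' @return an object of class `spatial_weights`.
#' @export
spatial_weights <- function(ids, neighbors, include_self = TRUE,
                            scheme = c("binary", "row_standardized")) {
  scheme <- match.arg(scheme)
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate unit ids in spatial weights")
  if (!all(ids %in% names(neighbors))) {
    neighbors <- c(neighbors,
                   stats::setNames(rep(list(character(0)),
                                       sum(!ids %in% names(neighbors))),
                                   setdiff(ids, names(neighbors))))
  }
  neighbors <- lapply(neighbors[ids], as.character)
  for (i in ids) {
    nb <- neighbors[[i]]
    if (i %in% nb) stop("unit ", i, " listed as its own neighbor")
    bad <- setdiff(nb, ids)
    if (length(bad)) stop("unknown neighbor id(s): ", paste(bad, collapse = ", "))
    for (j in nb) {
      if (!i %in% neighbors[[j]]) {
        stop("asymmetric adjacency: ", i, " -> ", j, " has no reverse edge")
      }
    }
  }
  structure(list(ids = ids, neighbors = neighbors,
                 include_self = include_self, scheme = scheme),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  deg <- lengths(x$neighbors)
  cat("Spatial weights:", length(x$ids), "units,",
      sum(deg) / 2, "undirected edges\n")
  cat("  scheme:", x$scheme,
      "| self-inclusive:", x$include_self,
      "| avg neighbors:", round(mean(deg), 2), "\n")
  invisible(x)
}

#' First-order rook contiguity on a rectangular lattice
#'
#' Units are laid out row-major on an `nrow` x `ncol` grid; rook neighbors share
#' a full cell edge (no diagonals). With `torus = TRUE` edges wrap around, so
#' every unit has exactly four neighbors (useful for exact symmetry checks).
#'
#' @param nrow,ncol lattice dimensions (>= 1).
#' @param ids optional unit ids, row-major order; defaults to `"N001"`, ...
#' @param torus logical; wrap the lattice into a torus.
#' @inheritParams spatial_weights
#' @return a [spatial_weights] object.
#' @export
lattice_rook_weights <- function(nrow, ncol, ids = NULL, torus = FALSE,
                                 include_self = TRUE) {
  n <- nrow * ncol
  if (is.null(ids)) ids <- sprintf("N%03d", seq_len(n))
  stopifnot(length(ids) == n)
  idx <- function(r, c) (r - 1L) * ncol + c
  nb <- vector("list", n)
  for (r in seq_len(nrow)) {
    for (c in seq_len(ncol)) {
      cur <- integer(0)
      if (torus) {
        if (nrow > 1L) cur <- c(cur, idx(1L + (r %% nrow), c),
                                idx(1L + ((r - 2L) %% nrow), c))
        if (ncol > 1L) cur <- c(cur, idx(r, 1L + (c %% ncol)),
                                idx(r, 1L + ((c - 2L) %% ncol)))
      } else {
        if (r > 1L) cur <- c(cur, idx(r - 1L, c))
        if (r < nrow) cur <- c(cur, idx(r + 1L, c))
        if (c > 1L) cur <- c(cur, idx(r, c - 1L))
        if (c < ncol) cur <- c(cur, idx(r, c + 1L))
      }
      nb[[idx(r, c)]] <- ids[sort(unique(cur))]
    }
  }
  names(nb) <- ids
  spatial_weights(ids, nb, include_self = include_self)
}

#' Rook contiguity from an adjacency edge list
#'
#' @param edges data frame with columns `src` and `dst`; each undirected edge
#'   must appear in both directions (the reader refuses asymmetric lists rather
#'   than silently symmetrizing).
#' @param ids optional full set of unit ids (isolated units allowed).
#' @inheritParams spatial_weights
#' @return a [spatial_weights] object.
#' @export
weights_from_edges <- function(edges, ids = NULL, include_self = TRUE) {
  if (!all(c("src", "dst") %in% names(edges))) {
    stop("edge list must have columns 'src' and 'dst'")
  }
  src <- as.character(edges$src)
  dst <- as.character(edges$dst)
  if (is.null(ids)) ids <- sort(unique(c(src, dst)))
  nb <- split(dst, factor(src, levels = ids))
  nb <- lapply(nb, function(v) sort(unique(v)))
  spatial_weights(ids, nb, include_self = include_self)
}

#' Rook contiguity from GeoJSON polygons
#'
#' Derives first-order rook neighbors from a planar partition of polygons: two
#' units are neighbors when they share a boundary segment of positive length.
#' Corner-only contact (a single shared vertex) is excluded, which is what
#' distinguishes rook from queen contiguity. Polygons must form a planar
#' partition with coincident vertices along shared boundaries (true of
#' lattice-style and properly noded administrative polygons); boundaries that
#' overlap without sharing vertices are not detected.
#'
#' @param geojson path to a GeoJSON `FeatureCollection` of Polygon /
#'   MultiPolygon features, or an already-parsed list in GeoJSON structure.
#' @param id_property name of the feature property holding the unit id.
#' @inheritParams spatial_weights
#' @return a [spatial_weights] object.
#' @export
rook_from_polygons <- function(geojson, id_property = "neighborhood_id",
                               include_self = TRUE) {
  if (is.character(geojson)) {
    geojson <- jsonlite::fromJSON(geojson, simplifyVector = FALSE)
  }
  feats <- geojson$features
  if (is.null(feats)) stop("expected a GeoJSON FeatureCollection")
  ids <- vapply(feats, function(f) as.character(f$properties[[id_property]]),
                character(1))
  if (anyDuplicated(ids)) stop("duplicate feature ids")
  # canonical key for an undirected segment between two vertices
  seg_key <- function(a, b) {
    pa <- sprintf("%.9g,%.9g", a[[1]], a[[2]])
    pb <- sprintf("%.9g,%.9g", b[[1]], b[[2]])
    if (pa <= pb) paste(pa, pb, sep = "|") else paste(pb, pa, sep = "|")
  }
  ring_segs <- function(ring) {
    m <- length(ring)
    if (m < 2L) return(character(0))
    out <- character(m - 1L)
    for (k in seq_len(m - 1L)) out[k] <- seg_key(ring[[k]], ring[[k + 1L]])
    out[!duplicated(out)]
  }
  feat_segs <- function(f) {
    g <- f$geometry
    rings <- switch(g$type,
                    Polygon = g$coordinates,
                    MultiPolygon = do.call(c, g$coordinates),
                    stop("unsupported geometry type: ", g$type))
    unique(unlist(lapply(rings, ring_segs)))
  }
  segs <- lapply(feats, feat_segs)
  owner <- data.frame(seg = unlist(segs),
                      unit = rep(ids, lengths(segs)),
                      stringsAsFactors = FALSE)
  shared <- split(owner$unit, owner$seg)
  shared <- shared[lengths(shared) >= 2L]
  nb <- stats::setNames(rep(list(character(0)), length(ids)), ids)
  for (units in shared) {
    for (u in units) nb[[u]] <- union(nb[[u]], setdiff(units, u))
  }
  nb <- lapply(nb, sort)
  spatial_weights(ids, nb, include_self = include_self)
}

#' Edge list representation of spatial weights
#'
#' @param w a [spatial_weights] object.
#' @return data frame with columns `src`, `dst`; both directions of each edge.
#' @export
weights_to_edges <- function(w) {
  stopifnot(inherits(w, "spatial_weights"))
  src <- rep(w$ids, lengths(w$neighbors))
  dst <- unlist(w$neighbors, use.names = FALSE)
  if (is.null(dst)) dst <- character(0)
  data.frame(src = src, dst = dst, stringsAsFactors = FALSE)
}
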