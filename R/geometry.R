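#' Queen-contiguity adjacency from polygons
#'
#' Two areas are neighbours when their boundaries share at least one point
#' (queen contiguity: a shared border segment or a single shared corner both
#' count). Contact is detected by exact segment-segment intersection tests on
#' the polygon boundaries, within a small absolute tolerance, so vertices of
#' the two polygons do not need to coincide.
#'
#' @param polygons named list; each element is one area's geometry, given as
#'   a list of rings, each ring a two-column coordinate matrix (closed or
#'   open; the closing edge is implied). A single matrix is accepted as a
#'   one-ring polygon. Multipolygon parts are simply additional rings.
#' @param tol absolute coordinate tolerance for contact (default 1e-9).
#' @return an [area_graph] ordered by sorted labels.
#' @export
adjacency_from_polygons <- function(polygons, tol = 1e-9) {
  stop_if_not(length(polygons) >= 1, "empty polygon collection",
              class = "mortmap_invalid_input")
  stop_if_not(!is.null(names(polygons)) && all(nzchar(names(polygons))),
              "polygons must be labeled", class = "mortmap_invalid_input")
  stop_if_not(!anyDuplicated(names(polygons)), "duplicate polygon labels",
              class = "mortmap_invalid_input")
  ids <- sort(names(polygons))
  polys <- lapply(polygons[ids], normalize_rings)
  segs <- lapply(polys, rings_to_segments)
  bbox <- lapply(segs, function(s)
    c(min(s[, 1], s[, 3]), max(s[, 1], s[, 3]),
      min(s[, 2], s[, 4]), max(s[, 2], s[, 4])))
  n <- length(ids)
  edges <- list()
  for (a in seq_len(n - 1L)) for (b in seq.int(a + 1L, n)) {
    ba <- bbox[[a]]; bb <- bbox[[b]]
    if (ba[1] > bb[2] + tol || bb[1] > ba[2] + tol ||
        ba[3] > bb[4] + tol || bb[3] > ba[4] + tol) next
    if (boundaries_touch(segs[[a]], segs[[b]], tol))
      edges[[length(edges) + 1L]] <- c(a, b)
  }
  area_graph(ids, if (length(edges)) do.call(rbind, edges) else NULL)
}

normalize_rings <- function(p) {
  if (is.matrix(p)) p <- list(p)
  lapply(p, function(r) {
    r <- as.matrix(r)
    stop_if_not(ncol(r) == 2L && nrow(r) >= 3L,
                "ring must be an n x 2 matrix with n >= 3",
                class = "mortmap_invalid_input")
    r
  })
}

# each boundary as a matrix of segments (x1, y1, x2, y2), closing edge included
rings_to_segments <- function(rings) {
  do.call(rbind, lapply(rings, function(r) {
    nxt <- rbind(r[-1L, , drop = FALSE], r[1L, , drop = FALSE])
    cbind(r, nxt)
  }))
}

# any contact between two segment sets (vectorized over the second set)
boundaries_touch <- function(s1, s2, tol) {
  for (k in seq_len(nrow(s1))) {
    if (any(segment_intersects(s1[k, 1], s1[k, 2], s1[k, 3], s1[k, 4],
                               s2[, 1], s2[, 2], s2[, 3], s2[, 4], tol)))
      return(TRUE)
  }
  FALSE
}

# does segment (p1,p2) touch segments (q1,q2)? standard orientation test with
# collinear/endpoint handling; q-arguments vectorized
segment_intersects <- function(p1x, p1y, p2x, p2y, q1x, q1y, q2x, q2y, tol) {
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  d1 <- cross(q1x, q1y, q2x, q2y, p1x, p1y)
  d2 <- cross(q1x, q1y, q2x, q2y, p2x, p2y)
  d3 <- cross(p1x, p1y, p2x, p2y, q1x, q1y)
  d4 <- cross(p1x, p1y, p2x, p2y, q2x, q2y)
  proper <- (sign_tol(d1, tol) * sign_tol(d2, tol) < 0) &
            (sign_tol(d3, tol) * sign_tol(d4, tol) < 0)
  # touching: an endpoint of one lies on the other (covers collinear overlap)
  on1 <- point_on_segment(p1x, p1y, q1x, q1y, q2x, q2y, tol) |
         point_on_segment(p2x, p2y, q1x, q1y, q2x, q2y, tol)
  on2 <- point_on_segment(q1x, q1y, p1x, p1y, p2x, p2y, tol) |
         point_on_segment(q2x, q2y, p1x, p1y, p2x, p2y, tol)
  proper | on1 | on2
}

sign_tol <- function(x, tol) ifelse(abs(x) <= tol, 0, sign(x))

# is point (px,py) on segment (ax,ay)-(bx,by)? vectorized over segments
point_on_segment <- function(px, py, ax, ay, bx, by, tol) {
  crs <- (bx - ax) * (py - ay) - (by - ay) * (px - ax)
  len2 <- (bx - ax)^2 + (by - ay)^2
  dot <- (px - ax) * (bx - ax) + (py - ay) * (by - ay)
  near_line <- abs(crs) <= tol * pmax(1, sqrt(len2))
  within <- dot >= -tol & dot <= len2 + tol
  near_line & within
}

#' Adjacency from a GeoJSON FeatureCollection
#'
#' Parses polygon features and applies [adjacency_from_polygons()]. The area
#' label is taken from the given property of each feature.
#'
#' @param path GeoJSON file.
#' @param id_property name of the feature property holding the area label.
#' @param tol contact tolerance passed on.
#' @return an [area_graph].
#' @export
graph_from_geojson <- function(path, id_property = "id", tol = 1e-9) {
  stop_if_not(file.exists(path), "GeoJSON file not found",
              class = "mortmap_invalid_input")
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  stop_if_not(identical(gj$type, "FeatureCollection"),
              "expected a GeoJSON FeatureCollection",
              class = "mortmap_invalid_input")
  polys <- list()
  for (f in gj$features) {
    lab <- f$properties[[id_property]]
    stop_if_not(!is.null(lab), sprintf("feature lacks property '%s'", id_property),
                class = "mortmap_invalid_input")
    g <- f$geometry
    rings <- switch(g$type,
      Polygon = lapply(g$coordinates, coords_to_matrix),
      MultiPolygon = unlist(lapply(g$coordinates, function(pp)
        lapply(pp, coords_to_matrix)), recursive = FALSE),
      stop_if_not(FALSE, sprintf("unsupported geometry type '%s'", g$type),
                  class = "mortmap_invalid_input"))
    polys[[as.character(lab)]] <- rings
  }
  adjacency_from_polygons(polys, tol = tol)
}

coords_to_matrix <- function(ring) {
  m <- do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
  # GeoJSON rings repeat the first vertex; drop the duplicate
  if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  m
}
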