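#' Area adjacency graphs
#'
#' An `area_graph` stores the neighbourhood structure of a set of small areas
#' (census tracts): the binary adjacency matrix `W`, the diagonal of
#' neighbour counts `D`, the edge list, and the partition into connected
#' components. All matrices are ordered by `area_ids`, which is the
#' lexicographic order of the labels unless an explicit order is given.
#'
#' @param area_ids character vector of unique area labels.
#' @param edges two-column matrix (or data.frame) of area labels or indices,
#'   one unordered adjacency per row. May have zero rows.
#' @return an object of class `area_graph` with fields `area_ids`, `edges`
#'   (integer index pairs, `i < j`), `n_areas`, `W` (sparse symmetric 0/1),
#'   `degree` (neighbour counts, the diagonal of D), `components` (integer
#'   component membership).
#' @export
area_graph <- function(area_ids, edges) {
  stop_if_not(length(area_ids) >= 1, "at least one area is required")
  area_ids <- as.character(area_ids)
  stop_if_not(!anyDuplicated(area_ids), "duplicate area labels",
              class = "mortmap_invalid_input")
  n <- length(area_ids)
  if (is.null(edges) || NROW(edges) == 0L) {
    em <- matrix(integer(0), ncol = 2L)
  } else {
    edges <- as.matrix(edges)
    stop_if_not(ncol(edges) == 2L, "edges must have two columns")
    if (is.character(edges)) {
      i <- match(edges[, 1L], area_ids)
      j <- match(edges[, 2L], area_ids)
      stop_if_not(!anyNA(c(i, j)), "edge refers to unknown area label",
                  class = "mortmap_invalid_input")
    } else {
      i <- as.integer(edges[, 1L]); j <- as.integer(edges[, 2L])
      stop_if_not(all(i >= 1 & i <= n & j >= 1 & j <= n),
                  "edge index out of range", class = "mortmap_invalid_input")
    }
    keep <- i != j                       # drop self-loops
    i <- i[keep]; j <- j[keep]
    em <- cbind(pmin(i, j), pmax(i, j))
    em <- unique(em)
    em <- em[order(em[, 1L], em[, 2L]), , drop = FALSE]
  }
  W <- Matrix::sparseMatrix(i = c(em[, 1L], em[, 2L]),
                            j = c(em[, 2L], em[, 1L]),
                            x = 1, dims = c(n, n),
                            dimnames = list(area_ids, area_ids))
  degree <- Matrix::rowSums(W)
  g <- structure(list(area_ids = area_ids, edges = em, n_areas = n,
                      W = W, degree = degree,
                      components = graph_components(n, em)),
                 class = "area_graph")
  g
}

# connected components by repeated flood fill over the edge list
graph_components <- function(n, edges) {
  comp <- integer(n)
  nbr <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1L]; j <- edges[r, 2L]
    nbr[[i]] <- c(nbr[[i]], j); nbr[[j]] <- c(nbr[[j]], i)
  }
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      if (comp[v] != 0L) next
      comp[v] <- cur
      stack <- c(stack, nbr[[v]][comp[nbr[[v]]] == 0L])
    }
  }
  comp
}

#' @export
print.area_graph <- function(x, ...) {
  cat("area_graph:", x$n_areas, "areas,", nrow(x$edges), "edges,",
      max(x$components), "connected component(s)\n")
  iso <- sum(x$degree == 0)
  if (iso) cat("  islands (no neighbours):", iso, "\n")
  invisible(x)
}

#' Rook-contiguity lattice graph
#'
#' Builds the regular `rows` x `cols` grid used by the synthetic-city
#' generator, with areas adjacent when they share a grid edge. Area labels
#' are `"r<row>c<col>"` in row-major order (and the graph preserves this
#' order rather than re-sorting lexicographically, so that `A[r,c]` is area
#' `(r-1)*cols + c`).
#'
#' @param rows,cols positive integers.
#' @return an [area_graph].
#' @export
build_lattice_graph <- function(rows, cols) {
  stop_if_not(is_count(rows) && is_count(cols),
              "rows and cols must be positive integers")
  idx <- function(r, c) (r - 1L) * cols + c
  e <- list()
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    if (c < cols) e[[length(e) + 1L]] <- c(idx(r, c), idx(r, c + 1L))
    if (r < rows) e[[length(e) + 1L]] <- c(idx(r, c), idx(r + 1L, c))
  }
  ids <- as.vector(t(outer(seq_len(rows), seq_len(cols),
                           function(r, c) sprintf("r%02dc%02d", r, c))))
  edges <- if (length(e)) do.call(rbind, e) else NULL
  area_graph(ids, edges)
}

#' Adjacency from an edge list file
#'
#' Reads a two-column whitespace- or comma-separated file of
#' `area_id neighbor_id` pairs; symmetric closure is applied. Areas are
#' ordered lexicographically.
#'
#' @param path file path.
#' @param area_ids optional full label set (so isolated areas can be kept).
#' @return an [area_graph].
#' @export
graph_from_edgelist <- function(path, area_ids = NULL) {
  stop_if_not(file.exists(path), "edge-list file not found",
              class = "mortmap_invalid_input")
  txt <- readLines(path, warn = FALSE)
  txt <- trimws(txt)
  txt <- txt[nzchar(txt) & !startsWith(txt, "#")]
  parts <- strsplit(txt, "[,[:space:]]+")
  stop_if_not(all(lengths(parts) == 2L), "each line must hold two labels",
              class = "mortmap_invalid_input")
  em <- do.call(rbind, parts)
  ids <- sort(unique(c(em[, 1L], em[, 2L], as.character(area_ids))))
  area_graph(ids, em)
}
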