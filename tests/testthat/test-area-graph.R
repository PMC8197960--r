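test_that("lattice graphs have the rook-contiguity structure", {
  g1 <- build_lattice_graph(1, 1)
  expect_equal(g1$n_areas, 1)
  expect_equal(nrow(g1$edges), 0)

  g2 <- build_lattice_graph(2, 2)
  expect_equal(g2$n_areas, 4)
  expect_equal(nrow(g2$edges), 4)

  # brute-force enumeration of horizontal/vertical adjacencies on 3x3
  g3 <- build_lattice_graph(3, 3)
  cells <- expand.grid(r = 1:3, c = 1:3)
  brute <- 0
  for (a in 1:9) for (b in 1:9) {
    if (a < b && abs(cells$r[a] - cells$r[b]) + abs(cells$c[a] - cells$c[b]) == 1)
      brute <- brute + 1
  }
  expect_equal(brute, 12)
  expect_equal(nrow(g3$edges), brute)
  expect_equal(g3$n_areas, 9)
  # generic edge-count formula
  for (rc in list(c(2, 5), c(4, 4), c(1, 7))) {
    g <- build_lattice_graph(rc[1], rc[2])
    expect_equal(nrow(g$edges), rc[1] * (rc[2] - 1) + rc[2] * (rc[1] - 1))
  }
  expect_error(build_lattice_graph(0, 3), class = "mortmap_invalid_argument")
})

test_that("area_graph invariants hold: symmetry, degrees, components", {
  set.seed(11)
  for (rep in 1:10) {
    g <- random_graph(sample(2:8, 1))
    W <- as.matrix(g$W)
    expect_identical(W, t(W))
    expect_true(all(diag(W) == 0))
    expect_true(all(W %in% c(0, 1)))
    expect_equal(unname(g$degree), unname(rowSums(W)))
    expect_equal(sort(unique(g$components)), seq_len(max(g$components)))
    # edges and W encode the same relation
    expect_equal(nrow(g$edges), sum(W) / 2)
    for (r in seq_len(nrow(g$edges)))
      expect_equal(W[g$edges[r, 1], g$edges[r, 2]], 1)
  }
})

test_that("area_graph rejects duplicate labels and keeps area order stable", {
  expect_error(area_graph(c("a", "a"), NULL), class = "mortmap_invalid_input")
  g <- area_graph(c("b", "a", "c"), rbind(c("a", "b")))
  expect_identical(g$area_ids, c("b", "a", "c"))  # caller order preserved
  expect_equal(g$degree[["c"]], 0)                 # island allowed
})

test_that("queen contiguity from polygons detects edge and corner contact", {
  sq <- function(x, y) cbind(c(x, x + 1, x + 1, x), c(y, y, y + 1, y + 1))
  # two unit squares sharing an edge
  g <- adjacency_from_polygons(list(A = sq(0, 0), B = sq(1, 0)))
  expect_equal(nrow(g$edges), 1)
  # disjoint squares
  g2 <- adjacency_from_polygons(list(A = sq(0, 0), B = sq(5, 5)))
  expect_equal(nrow(g2$edges), 0)
  expect_equal(max(g2$components), 2)
  # 2x2 checkerboard: 4 rook + 2 corner contacts = 6 edges
  polys <- list(A = sq(0, 0), B = sq(1, 0), C = sq(0, 1), D = sq(1, 1))
  g3 <- adjacency_from_polygons(polys)
  expect_equal(nrow(g3$edges), 6)
  # brute-force oracle: count label pairs sharing any vertex
  labs <- names(polys)
  brute <- 0
  for (a in 1:3) for (b in (a + 1):4) {
    va <- polys[[labs[a]]]; vb <- polys[[labs[b]]]
    shared <- FALSE
    for (i in seq_len(nrow(va))) for (j in seq_len(nrow(vb)))
      if (all(va[i, ] == vb[j, ])) shared <- TRUE
    brute <- brute + shared
  }
  expect_equal(nrow(g3$edges), brute)
  # contact without any shared vertex (non-conforming boundaries)
  g4 <- adjacency_from_polygons(list(
    A = sq(0, 0), B = cbind(c(1, 2, 2, 1), c(0.25, 0.25, 0.75, 0.75))))
  expect_equal(nrow(g4$edges), 1)
  expect_error(adjacency_from_polygons(list()), class = "mortmap_invalid_input")
  expect_error(adjacency_from_polygons(setNames(list(sq(0, 0), sq(1, 0)),
                                                c("A", "A"))),
               class = "mortmap_invalid_input")
})

test_that("polygon adjacency is invariant under input reordering", {
  sq <- function(x, y) cbind(c(x, x + 1, x + 1, x), c(y, y, y + 1, y + 1))
  polys <- list(A = sq(0, 0), B = sq(1, 0), C = sq(0, 1), D = sq(1, 1))
  g1 <- adjacency_from_polygons(polys)
  g2 <- adjacency_from_polygons(rev(polys))
  expect_identical(g1$area_ids, g2$area_ids)
  expect_identical(g1$edges, g2$edges)
})

test_that("GeoJSON and edge-list readers reproduce the polygon graph", {
  ring <- function(x, y) list(list(list(x, y), list(x + 1, y),
                                   list(x + 1, y + 1), list(x, y + 1),
                                   list(x, y)))
  gj <- list(type = "FeatureCollection", features = list(
    list(type = "Feature", properties = list(tract = "T1"),
         geometry = list(type = "Polygon", coordinates = ring(0, 0))),
    list(type = "Feature", properties = list(tract = "T2"),
         geometry = list(type = "Polygon", coordinates = ring(1, 0))),
    list(type = "Feature", properties = list(tract = "T3"),
         geometry = list(type = "Polygon", coordinates = ring(1, 1)))))
  path <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  g <- graph_from_geojson(path, id_property = "tract")
  expect_equal(g$n_areas, 3)
  expect_equal(nrow(g$edges), 3)   # T1-T2 edge, T2-T3 edge, T1-T3 corner

  ep <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("T1 T2", "T2 T1", "T2 T3"), ep)   # symmetric closure applied
  ge <- graph_from_edgelist(ep)
  expect_equal(nrow(ge$edges), 2)
  expect_identical(ge$area_ids, c("T1", "T2", "T3"))
})
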