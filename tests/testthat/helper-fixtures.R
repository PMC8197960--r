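# shared builders for small in-code fixtures

# random sparse graph on n nodes (always valid, possibly disconnected)
random_graph <- function(n, p = 0.3) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p
  area_graph(sprintf("a%02d", seq_len(n)),
             if (any(keep)) pairs[keep, , drop = FALSE] else NULL)
}

# dense entry-wise Leroux precision, independent of the package implementation
leroux_dense_oracle <- function(graph, lam, scale = 1) {
  n <- graph$n_areas
  W <- matrix(0, n, n)
  for (r in seq_len(nrow(graph$edges))) {
    i <- graph$edges[r, 1]; j <- graph$edges[r, 2]
    W[i, j] <- W[j, i] <- 1
  }
  Q <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d_ij <- if (i == j) sum(W[i, ]) else 0
    Q[i, j] <- scale * (lam * (d_ij - W[i, j]) + (1 - lam) * (i == j))
  }
  Q
}

# small observed/expected pair with matching lattice graph
toy_city <- function(rows = 3, cols = 3, J = 2, seed = 99, lam = 0.6, s = 0.4) {
  cfg <- synthetic_config(n_cities = 1, rows = rows, cols = cols, causes = J,
                          lam = lam, sigma = s, seed = seed)
  city <- generate_city(cfg, 1)
  list(oe = expected_counts(city$data), graph = city$graph, city = city)
}

# independent draw-by-draw Poisson log-likelihood (library pmf oracle)
loglik_oracle <- function(O, E, theta) {
  tot <- 0
  for (i in seq_len(nrow(O))) for (j in seq_len(ncol(O))) {
    if (E[i, j] > 0)
      tot <- tot + stats::dpois(O[i, j], E[i, j] * theta[i, j], log = TRUE)
  }
  tot
}

random_orthogonal <- function(k) {
  qr.Q(qr(matrix(rnorm(k * k), k)))
}
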