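#' Leroux precision matrix
#'
#' The Leroux conditional autoregressive prior for a zero-mean spatial field
#' has precision `Q = scale * (lam * (D - W) + (1 - lam) * I)`, interpolating
#' between spatial independence (`lam = 0`) and the intrinsic CAR
#' (`lam = 1`). `Q` is strictly positive definite for `lam < 1`; at
#' `lam = 1` it is the ICAR precision, singular with one null vector per
#' connected component.
#'
#' @param graph an [area_graph].
#' @param lam spatial mixing parameter in `[0, 1]`.
#' @param scale precision multiplier, `> 0`.
#' @return sparse symmetric `n x n` [Matrix::Matrix].
#' @export
leroux_precision <- function(graph, lam, scale = 1) {
  stop_if_not(inherits(graph, "area_graph"), "`graph` must be an area_graph")
  stop_if_not(is.numeric(lam) && length(lam) == 1 && lam >= 0 && lam <= 1,
              "`lam` must lie in [0, 1]")
  stop_if_not(is.numeric(scale) && length(scale) == 1 && scale > 0,
              "`scale` must be positive")
  n <- graph$n_areas
  I <- Matrix::Diagonal(n)
  Dm <- Matrix::Diagonal(n, graph$degree)
  Q <- scale * (lam * (Dm - graph$W) + (1 - lam) * I)
  methods::as(Matrix::symmpart(Q), "CsparseMatrix")
}

#' Log-density of a Leroux field
#'
#' Evaluates `log N(phi; 0, Q^{-1})` with `Q = scale*(lam*(D-W)+(1-lam)*I)`,
#' using the eigenvalues `gamma` of `D - W` so that
#' `log|Q| = n*log(scale) + sum(log(lam*gamma + 1 - lam))`.
#'
#' @param phi numeric vector of length `n_areas`.
#' @param graph an [area_graph].
#' @param lam,scale Leroux parameters, `lam < 1`.
#' @param gamma optional precomputed eigenvalues of `D - W`.
#' @return scalar log-density.
#' @export
dleroux <- function(phi, graph, lam, scale = 1, gamma = NULL) {
  stop_if_not(lam >= 0 && lam < 1, "`lam` must lie in [0, 1) for a proper density")
  if (is.null(gamma)) gamma <- structural_eigenvalues(graph)
  n <- graph$n_areas
  quad <- scale * (lam * quad_struct(graph, phi) + (1 - lam) * sum(phi^2))
  ld <- n * log(scale) + sum(log(lam * gamma + 1 - lam))
  0.5 * ld - 0.5 * n * log(2 * pi) - 0.5 * quad
}

# phi' (D - W) phi, via the edge-difference identity sum over edges (phi_i-phi_j)^2
quad_struct <- function(graph, phi) {
  e <- graph$edges
  if (!nrow(e)) return(0)
  sum((phi[e[, 1L]] - phi[e[, 2L]])^2)
}

structural_eigenvalues <- function(graph) {
  L <- as.matrix(Matrix::Diagonal(graph$n_areas, graph$degree) - graph$W)
  eigen(L, symmetric = TRUE, only.values = TRUE)$values
}

#' Sample zero-mean Leroux fields
#'
#' Exact Gaussian draws from the field with precision [leroux_precision()],
#' by backsolving the (dense) Cholesky factor of `Q`. Requires a proper
#' prior: `lam < 1`, or `lam = 1` with `constrain = TRUE`, in which case
#' draws from the ICAR are produced by sum-to-zero-constrained sampling per
#' connected component (islands are rejected).
#'
#' @param graph an [area_graph].
#' @param lam,scale Leroux parameters.
#' @param n_draws number of fields to draw.
#' @param seed optional integer seed for reproducibility.
#' @param constrain apply the per-component sum-to-zero constraint needed
#'   when `lam = 1`.
#' @return `n_draws x n_areas` matrix; one field per row.
#' @export
sample_leroux_field <- function(graph, lam, scale = 1, n_draws = 1,
                                seed = NULL, constrain = FALSE) {
  stop_if_not(is_count(n_draws), "`n_draws` must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  n <- graph$n_areas
  if (lam >= 1 && !constrain) {
    stop_if_not(FALSE, "lam = 1 gives an improper (singular) prior; use constrain = TRUE",
                class = "mortmap_degenerate_prior")
  }
  if (lam < 1) {
    Q <- as.matrix(leroux_precision(graph, lam, scale))
    R <- chol(Q)                        # Q = R'R, R upper triangular
    z <- matrix(rnorm(n_draws * n), nrow = n)
    x <- backsolve(R, z)                # cov(x) = Q^{-1}
    return(t(x))
  }
  stop_if_not(all(graph$degree > 0),
              "ICAR (lam = 1) is undefined on graphs with islands",
              class = "mortmap_degenerate_prior")
  # ICAR: eigen-decompose D - W, drop null eigenvectors, constrain components
  L <- as.matrix(Matrix::Diagonal(n, graph$degree) - graph$W) * scale
  eg <- eigen(L, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  z <- matrix(rnorm(n_draws * sum(pos)), ncol = sum(pos))
  t(eg$vectors[, pos, drop = FALSE] %*% (t(z) / sqrt(eg$values[pos])))
}
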