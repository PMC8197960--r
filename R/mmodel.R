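#' M-model run configuration
#'
#' Settings for [mmodel()]. Defaults mirror a conventional disease-mapping
#' MCMC setup: 3 chains, 5,000 burn-in and 5,000 sampling iterations thinned
#' by 5. `prior_sd_M` is the upper bound of the uniform prior on the
#' per-cause loading scale `sigma_j` (standard-deviation scale).
#'
#' @param n_latent number of latent spatial fields; default (`NULL`) means
#'   one per cause (square loading matrix).
#' @param n_chains number of independent chains (>= 2).
#' @param n_burnin,n_iter,thin burn-in length, retained-phase length, and
#'   thinning interval; `n_iter` must be a multiple of `thin`.
#' @param seed master seed; per-chain seeds are derived by a fixed rule.
#' @param prior_sd_M upper bound of the uniform prior on each `sigma_j`.
#' @param adapt_window batch size for proposal-scale adaptation (burn-in only).
#' @param sigma_fixed optional fixed per-cause loading scales (disables the
#'   `sigma` update; used for prior checks and the univariate collapse).
#' @param lam_fixed optional fixed per-latent Leroux mixing parameters.
#' @param likelihood set `FALSE` to sample from the prior only.
#' @return object of class `mmodel_config`.
#' @export
mmodel_config <- function(n_latent = NULL, n_chains = 3, n_burnin = 5000,
                          n_iter = 5000, thin = 5, seed = 1,
                          prior_sd_M = 5, adapt_window = 50,
                          sigma_fixed = NULL, lam_fixed = NULL,
                          likelihood = TRUE) {
  stop_if_not(n_chains >= 2, "`n_chains` must be at least 2")
  stop_if_not(is_count(n_iter) && is_count(thin) && n_iter %% thin == 0,
              "`n_iter` must be a positive multiple of `thin`")
  stop_if_not(is.numeric(n_burnin) && n_burnin >= 0, "`n_burnin` must be >= 0")
  stop_if_not(is.null(n_latent) || is_count(n_latent), "invalid `n_latent`")
  stop_if_not(prior_sd_M > 0, "`prior_sd_M` must be positive")
  structure(list(n_latent = n_latent, n_chains = as.integer(n_chains),
                 n_burnin = as.integer(n_burnin), n_iter = as.integer(n_iter),
                 thin = as.integer(thin), seed = as.integer(seed),
                 prior_sd_M = prior_sd_M, adapt_window = as.integer(adapt_window),
                 sigma_fixed = sigma_fixed, lam_fixed = lam_fixed,
                 likelihood = isTRUE(likelihood)),
            class = "mmodel_config")
}

#' Poisson log-likelihood of observed counts
#'
#' `sum over cells with E > 0 of log Poisson(O; E * theta)`. Cells with zero
#' expected deaths are excluded (the log link is undefined there); such
#' cells must carry zero observed deaths.
#'
#' @param O,E,theta `area x cause` matrices of observed counts, expected
#'   counts and relative risks.
#' @return scalar log-likelihood.
#' @export
poisson_loglik <- function(O, E, theta) {
  stop_if_not(all(O >= 0) && all(O == floor(O)),
              "`O` must hold non-negative integers", class = "mortmap_invalid_input")
  stop_if_not(all(E >= 0), "`E` must be non-negative", class = "mortmap_invalid_input")
  inc <- E > 0
  stop_if_not(all(theta[inc] > 0), "`theta` must be positive on modeled cells",
              class = "mortmap_invalid_input")
  stop_if_not(all(O[!inc] == 0), "observed deaths in cells with zero expected deaths",
              class = "mortmap_invalid_input")
  sum(dpois(O[inc], E[inc] * theta[inc], log = TRUE))
}

#' Between-cause covariance from the loading matrix
#'
#' The M-model induces covariance `Sigma = M'M` between the log-risk
#' surfaces of the causes.
#'
#' @param M `latent x cause` loading matrix.
#' @return `cause x cause` symmetric positive semi-definite matrix.
#' @export
derive_sigma <- function(M) crossprod(as.matrix(M))

#' Model state container
#'
#' @param Phi `area x latent` matrix of spatial fields.
#' @param M `latent x cause` loading matrix.
#' @param lam per-latent Leroux mixing parameters in `[0, 1)`.
#' @param sigma per-cause loading scales (> 0).
#' @return object of class `mmodel_state`.
#' @export
mmodel_state <- function(Phi, M, lam, sigma) {
  Phi <- as.matrix(Phi); M <- as.matrix(M)
  stop_if_not(ncol(Phi) == nrow(M), "Phi and M dimensions disagree")
  stop_if_not(length(lam) == ncol(Phi) && all(lam >= 0 & lam < 1),
              "`lam` entries must lie in [0, 1)")
  stop_if_not(length(sigma) == ncol(M) && all(sigma > 0),
              "`sigma` entries must be positive")
  stop_if_not(all(is.finite(Phi %*% M)), "log-risk matrix is not finite")
  structure(list(Phi = Phi, M = M, lam = lam, sigma = sigma),
            class = "mmodel_state")
}

#' Joint log-posterior density of an M-model state
#'
#' Poisson likelihood with `log theta = Phi M`, plus unit-scale Leroux
#' log-densities for the columns of `Phi`, `Normal(0, sigma_j^2)`
#' log-densities for the loadings, and the uniform priors on `lam` (on
#' `[0,1]`) and `sigma` (on `[0, prior_sd_M]`).
#'
#' @param state an [mmodel_state].
#' @param data a [mortality_matrices].
#' @param graph an [area_graph].
#' @param config an [mmodel_config] (only the prior settings are used).
#' @return scalar log-posterior (up to the normalizing constant of the data).
#' @export
log_posterior <- function(state, data, graph, config = mmodel_config()) {
  stop_if_not(inherits(state, "mmodel_state"), "`state` must be an mmodel_state")
  theta <- exp(state$Phi %*% state$M)
  ll <- if (config$likelihood) poisson_loglik(data$O, data$E, theta) else 0
  gamma <- structural_eigenvalues(graph)
  lp_phi <- sum(vapply(seq_along(state$lam), function(k)
    dleroux(state$Phi[, k], graph, state$lam[k], scale = 1, gamma = gamma), 0))
  lp_M <- sum(stats::dnorm(state$M, 0,
                           rep(state$sigma, each = nrow(state$M)), log = TRUE))
  lp_sigma <- sum(stats::dunif(state$sigma, 0, config$prior_sd_M, log = TRUE))
  lp_lam <- sum(stats::dunif(state$lam, 0, 1, log = TRUE))
  out <- ll + lp_phi + lp_M + lp_sigma + lp_lam
  if (!is.finite(out)) {
    parts <- c(likelihood = ll, leroux = lp_phi, loadings = lp_M,
               sigma_prior = lp_sigma, lam_prior = lp_lam)
    stop_if_not(FALSE, paste0("non-finite log-posterior (",
                              paste(names(parts)[!is.finite(parts)], collapse = ", "),
                              ")"), class = "mortmap_numerical_overflow")
  }
  out
}

# greedy proper coloring: sites of one color are non-adjacent, hence
# conditionally independent given the rest and updatable simultaneously
graph_coloring <- function(graph) {
  n <- graph$n_areas
  nbr <- vector("list", n)
  e <- graph$edges
  for (r in seq_len(nrow(e))) {
    nbr[[e[r, 1L]]] <- c(nbr[[e[r, 1L]]], e[r, 2L])
    nbr[[e[r, 2L]]] <- c(nbr[[e[r, 2L]]], e[r, 1L])
  }
  col <- integer(n)
  for (v in order(graph$degree, decreasing = TRUE)) {
    used <- col[nbr[[v]]]
    col[v] <- min(setdiff(seq_len(n), used[used > 0L]))
  }
  lapply(seq_len(max(col)), function(cc) which(col == cc))
}

#' Fit the multivariate spatial M-model by MCMC
#'
#' Fits the joint disease-mapping model `O_ij ~ Poisson(theta_ij * E_ij)`,
#' `log theta = Phi M`, where the columns of `Phi` follow independent
#' unit-scale Leroux spatial priors with mixing parameters `lam_k ~ U(0,1)`
#' and the loadings follow `M[k,j] ~ Normal(0, sigma_j^2)` with
#' `sigma_j ~ U(0, prior_sd_M)`. Sampling is Metropolis-within-Gibbs:
#' `Phi` is updated site-wise (simultaneously over the color classes of the
#' adjacency graph), `M` and `sigma` by random-walk Metropolis, `lam` by
#' random walk on the logit scale. Proposal scales adapt toward 20-40%
#' acceptance during burn-in only. `Phi` and `M` are not individually
#' identifiable (any rotation leaves the likelihood unchanged), so only the
#' identifiable quantities `theta`, `Sigma = M'M`, `lam` and `sigma` are
#' retained and monitored.
#'
#' @param data a [mortality_matrices] (or [stratified_mortality], which is
#'   standardized first).
#' @param graph an [area_graph] sharing the area list with `data`.
#' @param config an [mmodel_config].
#' @return object of class `mmodel`: per-chain draw matrices of `theta`
#'   (`SMR/100` scale), `Sigma`, `lam`, `sigma` and `M`, plus acceptance
#'   rates, seeds and inputs.
#' @export
mmodel <- function(data, graph, config = mmodel_config()) {
  if (inherits(data, "stratified_mortality")) data <- expected_counts(data)
  stop_if_not(inherits(data, "mortality_matrices"),
              "`data` must be a mortality_matrices")
  stop_if_not(inherits(graph, "area_graph"), "`graph` must be an area_graph")
  stop_if_not(graph$n_areas >= 2, "at least 2 areas are required")
  stop_if_not(identical(as.character(data$area_ids), graph$area_ids),
              "data and graph disagree on the area list",
              class = "mortmap_invalid_input")
  O <- data$O; E <- data$E
  n <- nrow(O); J <- ncol(O)
  stop_if_not(all(O[E == 0] == 0),
              "observed deaths in cells with zero expected deaths",
              class = "mortmap_invalid_input")
  if (any(colSums(O) == 0))
    warning("cause(s) with zero observed deaths retained: ",
            paste(colnames(O)[colSums(O) == 0], collapse = ", "))
  K <- if (is.null(config$n_latent)) J else config$n_latent
  stop_if_not(K >= 1 && K <= J, "`n_latent` must lie in 1..n_causes")

  colors <- graph_coloring(graph)
  A <- methods::as(Matrix::Diagonal(n, graph$degree) - graph$W, "CsparseMatrix")
  eg <- eigen(as.matrix(A), symmetric = TRUE)
  gamma <- eg$values
  V <- eg$vectors
  deg <- graph$degree
  chain_seeds <- derive_seeds(config$seed, config$n_chains)
  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    chains[[ch]] <- run_chain(O, E, A, deg, gamma, V, colors, K, config,
                              chain_seeds[ch])
  }
  structure(list(chains = chains, config = config, graph = graph, data = data,
                 n_latent = K, chain_seeds = chain_seeds,
                 modeled = E > 0,
                 acceptance = lapply(chains, attr, "acceptance")),
            class = "mmodel")
}

run_chain <- function(O, E, A, deg, gamma, V, colors, K, config, chain_seed) {
  set.seed(chain_seed)
  n <- nrow(O); J <- ncol(O)
  use_lik <- config$likelihood
  # overdispersed random starts
  Phi <- matrix(rnorm(n * K, 0, 0.5), n, K)
  M <- matrix(rnorm(K * J, 0, 0.5), K, J)
  sigma <- if (!is.null(config$sigma_fixed)) rep(config$sigma_fixed, length.out = J)
           else runif(J, 0.2, min(2, config$prior_sd_M))
  lam <- if (!is.null(config$lam_fixed)) rep(config$lam_fixed, length.out = K)
         else runif(K, 0.1, 0.9)
  fix_sigma <- !is.null(config$sigma_fixed)
  fix_lam <- !is.null(config$lam_fixed)
  eta <- Phi %*% M

  ls_phi <- rep(log(0.5), K)
  ls_M <- matrix(log(0.3), K, J)
  ls_sig <- rep(log(0.3), J)
  ls_lam <- rep(log(1.0), K)
  ls_lamj <- rep(log(1.0), K)
  zero_acc <- function() list(phi = numeric(K), M = matrix(0, K, J),
                              sigma = numeric(J), lam = numeric(K),
                              lamj = numeric(K))
  acc <- zero_acc()
  try_n <- zero_acc()
  batch <- 0L

  n_keep <- config$n_iter %/% config$thin
  theta_d <- matrix(NA_real_, n_keep, n * J)
  Sigma_d <- matrix(NA_real_, n_keep, J * J)
  lam_d <- matrix(NA_real_, n_keep, K)
  sigma_d <- matrix(NA_real_, n_keep, J)
  M_d <- matrix(NA_real_, n_keep, K * J)
  kept <- 0L
  total <- config$n_burnin + config$n_iter

  for (it in seq_len(total)) {
    in_burn <- it <= config$n_burnin
    ## --- Phi: site-wise Metropolis, simultaneous within color classes ---
    for (k in seq_len(K)) {
      step <- exp(ls_phi[k])
      mk <- M[k, ]
      for (idx in colors) {
        Aphi <- as.vector(A %*% Phi[, k])
        qphi <- lam[k] * Aphi[idx] + (1 - lam[k]) * Phi[idx, k]
        qii <- lam[k] * deg[idx] + (1 - lam[k])
        delta <- rnorm(length(idx)) * step
        dtot <- -delta * qphi - 0.5 * delta^2 * qii
        if (use_lik) {
          etaI <- eta[idx, , drop = FALSE]
          netaI <- etaI + tcrossprod(delta, mk)
          dtot <- dtot + rowSums(O[idx, , drop = FALSE] * (netaI - etaI) -
                                 E[idx, , drop = FALSE] * (exp(netaI) - exp(etaI)))
        }
        ok <- is.finite(dtot) & (log(runif(length(idx))) < dtot)
        if (any(ok)) {
          Phi[idx[ok], k] <- Phi[idx[ok], k] + delta[ok]
          if (use_lik) eta[idx[ok], ] <- netaI[ok, , drop = FALSE]
        }
        acc$phi[k] <- acc$phi[k] + sum(ok)
        try_n$phi[k] <- try_n$phi[k] + length(idx)
      }
    }
    if (!use_lik) eta <- Phi %*% M
    ## --- M: entry-wise random-walk Metropolis ---
    for (k in seq_len(K)) for (j in seq_len(J)) {
      delta <- rnorm(1) * exp(ls_M[k, j])
      m0 <- M[k, j]
      dtot <- (m0^2 - (m0 + delta)^2) / (2 * sigma[j]^2)
      if (use_lik) {
        ne <- eta[, j] + delta * Phi[, k]
        dtot <- dtot + sum(O[, j] * (ne - eta[, j]) -
                           E[, j] * (exp(ne) - exp(eta[, j])))
      }
      if (is.finite(dtot) && log(runif(1)) < dtot) {
        M[k, j] <- m0 + delta
        if (use_lik) eta[, j] <- ne
        acc$M[k, j] <- acc$M[k, j] + 1
      }
      try_n$M[k, j] <- try_n$M[k, j] + 1
    }
    if (!use_lik) eta <- Phi %*% M
    ## --- sigma: random walk on log scale (Jacobian included) ---
    if (!fix_sigma) {
      for (j in seq_len(J)) {
        s0 <- sigma[j]; s1 <- s0 * exp(rnorm(1) * exp(ls_sig[j]))
        if (s1 < config$prior_sd_M) {
          S <- sum(M[, j]^2)
          dtot <- -(K - 1) * (log(s1) - log(s0)) - S / 2 * (1 / s1^2 - 1 / s0^2)
          if (is.finite(dtot) && log(runif(1)) < dtot) {
            sigma[j] <- s1
            acc$sigma[j] <- acc$sigma[j] + 1
          }
        }
        try_n$sigma[j] <- try_n$sigma[j] + 1
      }
    }
    ## --- lam: random walk on logit scale (Jacobian included) ---
    if (!fix_lam) {
      for (k in seq_len(K)) {
        qs <- leroux_quad_parts(A, Phi[, k])
        tgt <- function(l) 0.5 * sum(log(l * gamma + 1 - l)) -
          0.5 * (l * qs$struct + (1 - l) * qs$ss) + log(l) + log1p(-l)
        l0 <- lam[k]
        el0 <- stats::qlogis(min(max(l0, 1e-12), 1 - 1e-12))
        l1 <- stats::plogis(el0 + rnorm(1) * exp(ls_lam[k]))
        dtot <- tgt(l1) - tgt(l0)
        if (is.finite(dtot) && log(runif(1)) < dtot) {
          lam[k] <- l1
          acc$lam[k] <- acc$lam[k] + 1
        }
        try_n$lam[k] <- try_n$lam[k] + 1
      }
      ## joint (lam, Phi) move: rescale the field in the eigenbasis of
      ## D - W so the Leroux prior term cancels exactly; the acceptance
      ## ratio is the likelihood ratio (plus logit Jacobians). This
      ## decouples lam from the slow single-site drift of the field.
      for (k in seq_len(K)) {
        l0 <- lam[k]
        el0 <- stats::qlogis(min(max(l0, 1e-12), 1 - 1e-12))
        l1 <- stats::plogis(el0 + rnorm(1) * exp(ls_lamj[k]))
        q0 <- l0 * gamma + 1 - l0
        q1 <- l1 * gamma + 1 - l1
        z <- crossprod(V, Phi[, k])
        phi_new <- as.vector(V %*% (z * sqrt(q0 / q1)))
        dtot <- log(l1) + log1p(-l1) - log(l0) - log1p(-l0)
        if (use_lik) {
          mk <- M[k, ]
          neta <- eta + tcrossprod(phi_new - Phi[, k], mk)
          dtot <- dtot + sum(O * (neta - eta) - E * (exp(neta) - exp(eta)))
        }
        if (is.finite(dtot) && log(runif(1)) < dtot) {
          lam[k] <- l1
          Phi[, k] <- phi_new
          if (use_lik) eta <- neta
          acc$lamj[k] <- acc$lamj[k] + 1
        }
        try_n$lamj[k] <- try_n$lamj[k] + 1
      }
    }
    ## --- adaptation during burn-in only ---
    if (in_burn && it %% config$adapt_window == 0L) {
      batch <- batch + 1L
      gain <- 1 / sqrt(batch)
      adj <- function(ls, a, t) ls + gain * (a / pmax(t, 1) - 0.3)
      ls_phi <- adj(ls_phi, acc$phi, try_n$phi)
      ls_M <- adj(ls_M, acc$M, try_n$M)
      if (!fix_sigma) ls_sig <- adj(ls_sig, acc$sigma, try_n$sigma)
      if (!fix_lam) {
        ls_lam <- adj(ls_lam, acc$lam, try_n$lam)
        ls_lamj <- adj(ls_lamj, acc$lamj, try_n$lamj)
      }
      acc <- zero_acc()
      try_n <- zero_acc()
      eta <- Phi %*% M                 # guard against incremental drift
    }
    ## --- retain ---
    if (!in_burn && (it - config$n_burnin) %% config$thin == 0L) {
      kept <- kept + 1L
      theta_d[kept, ] <- exp(as.vector(eta))
      Sigma_d[kept, ] <- as.vector(crossprod(M))
      lam_d[kept, ] <- lam
      sigma_d[kept, ] <- sigma
      M_d[kept, ] <- as.vector(M)
    }
  }
  an <- dimnames(O)[[1]]; cn <- dimnames(O)[[2]]
  colnames(theta_d) <- as.vector(outer(an, cn, function(a, b) paste0("theta[", a, ",", b, "]")))
  colnames(Sigma_d) <- as.vector(outer(cn, cn, function(a, b) paste0("Sigma[", a, ",", b, "]")))
  colnames(lam_d) <- paste0("lam[", seq_len(K), "]")
  colnames(sigma_d) <- paste0("sigma[", cn, "]")
  colnames(M_d) <- as.vector(outer(seq_len(K), cn, function(a, b) paste0("M[", a, ",", b, "]")))
  out <- list(theta = theta_d, Sigma = Sigma_d, lam = lam_d, sigma = sigma_d,
              M = M_d)
  rates <- mapply(function(a, t) sum(a) / max(sum(t), 1), acc, try_n)
  attr(out, "acceptance") <- rates
  out
}

leroux_quad_parts <- function(A, phi) {
  list(struct = sum(phi * as.vector(A %*% phi)), ss = sum(phi^2))
}
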