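test_that("poisson_loglik matches direct evaluation and the pmf oracle", {
  m1 <- function(x) matrix(x, 1, 1)
  expect_equal(poisson_loglik(m1(0), m1(1), m1(1)), -1)
  expect_equal(poisson_loglik(m1(1), m1(1), m1(1)), -1)
  expect_equal(poisson_loglik(m1(2), m1(1), m1(2)), log(2) - 2)
  set.seed(51)
  O <- matrix(rpois(12, 5), 3); E <- matrix(runif(12, 0.5, 3), 3)
  E[2, 2] <- 0; O[2, 2] <- 0
  th <- matrix(runif(12, 0.5, 2), 3)
  expect_equal(poisson_loglik(O, E, th), loglik_oracle(O, E, th),
               tolerance = 1e-12)
  expect_error(poisson_loglik(matrix(-1), m1(1), m1(1)),
               class = "mortmap_invalid_input")
  expect_error(poisson_loglik(m1(3), m1(0), m1(1)),
               class = "mortmap_invalid_input")
})

test_that("derive_sigma is the cross-product of the loading matrix", {
  expect_equal(derive_sigma(diag(2)), diag(2))
  expect_equal(derive_sigma(diag(c(1, 2))), diag(c(1, 4)))
  expect_equal(derive_sigma(matrix(c(1, 0, 1, 1), 2)),
               matrix(c(1, 1, 1, 2), 2))
  set.seed(3)
  M <- matrix(rnorm(6), 2)
  S <- derive_sigma(M)
  expect_equal(S, t(S))
  expect_true(all(eigen(S, only.values = TRUE)$values > -1e-12))
})

test_that("log_posterior decomposes into independently coded terms", {
  tc <- toy_city(2, 1, J = 1, seed = 5)        # 2-area, 1-cause toy
  g <- tc$graph; oe <- tc$oe
  cfg <- mmodel_config(n_chains = 2, n_iter = 10, thin = 1)
  set.seed(61)
  st <- mmodel_state(Phi = matrix(rnorm(2), 2, 1), M = matrix(0.5, 1, 1),
                     lam = 0.3, sigma = 0.8)
  # term-by-term oracle
  ref <- loglik_oracle(oe$O, oe$E, exp(st$Phi %*% st$M)) +
    {
      Q <- leroux_dense_oracle(g, 0.3, 1)
      0.5 * determinant(Q)$modulus[1] - 1 * log(2 * pi) -
        0.5 * drop(t(st$Phi) %*% Q %*% st$Phi)
    } +
    dnorm(0.5, 0, 0.8, log = TRUE) +
    dunif(0.8, 0, cfg$prior_sd_M, log = TRUE) + dunif(0.3, 0, 1, log = TRUE)
  expect_equal(log_posterior(st, oe, g, cfg), as.numeric(ref), tolerance = 1e-10)

  # M = 0: the likelihood term collapses to poisson_loglik at theta = 1
  st0 <- mmodel_state(st$Phi, matrix(0, 1, 1), lam = 0.3, sigma = 0.8)
  prior_terms <- log_posterior(st0, oe, g, mmodel_config(n_chains = 2,
                                                         likelihood = FALSE))
  expect_equal(log_posterior(st0, oe, g, cfg) - prior_terms,
               poisson_loglik(oe$O, oe$E, matrix(1, 2, 1)))

  # lam = 0: Leroux term is a sum of iid standard-normal log-densities
  stl <- mmodel_state(st$Phi, st$M, lam = 0, sigma = 0.8)
  expect_equal(dleroux(stl$Phi[, 1], g, 0),
               sum(dnorm(stl$Phi[, 1], log = TRUE)))
})

test_that("likelihood and theta are invariant under loading rotations", {
  set.seed(71)
  tc <- toy_city(3, 3, J = 3, seed = 8)
  Phi <- matrix(rnorm(9 * 3, 0, 0.3), 9, 3)
  M <- matrix(rnorm(9, 0, 0.5), 3, 3)
  for (rep in 1:5) {
    R <- random_orthogonal(3)
    theta1 <- exp(Phi %*% M)
    theta2 <- exp((Phi %*% R) %*% (t(R) %*% M))
    expect_equal(theta2, theta1, tolerance = 1e-8)
    expect_equal(poisson_loglik(tc$oe$O, tc$oe$E, theta2),
                 poisson_loglik(tc$oe$O, tc$oe$E, theta1), tolerance = 1e-8)
    expect_equal(derive_sigma(t(R) %*% M), derive_sigma(M), tolerance = 1e-8)
  }
})

test_that("the sampler is bitwise reproducible for a fixed seed", {
  tc <- toy_city(2, 2, J = 1, seed = 12)
  cfg <- mmodel_config(n_latent = 1, n_chains = 2, n_burnin = 50, n_iter = 50,
                       thin = 1, seed = 33)
  f1 <- mmodel(tc$oe, tc$graph, cfg)
  f2 <- mmodel(tc$oe, tc$graph, cfg)
  expect_identical(f1$chains, f2$chains)
  # retained draw count contract
  expect_equal(sum(vapply(f1$chains, function(ch) nrow(ch$theta), 0)),
               cfg$n_chains * cfg$n_iter / cfg$thin)
})

test_that("posterior mean risk approaches O/E as expected counts grow", {
  # univariate collapse with abundant data: shrinkage vanishes
  g <- build_lattice_graph(2, 2)
  O <- matrix(c(10500L, 9400L, 11000L, 9000L), 4, 1,
              dimnames = list(g$area_ids, "c1"))
  E <- matrix(10000, 4, 1, dimnames = list(g$area_ids, "c1"))
  fit <- mmodel(mortality_matrices(O, E), g,
                mmodel_config(n_latent = 1, n_chains = 2, n_burnin = 1000,
                              n_iter = 2000, thin = 2, seed = 4,
                              lam_fixed = 0))
  post <- fitted(fit)
  expect_true(all(abs(post - O / E) / (O / E) < 0.02))
})

test_that("with spatial independence the posterior shrinks crude risks inward", {
  set.seed(81)
  g <- build_lattice_graph(3, 3)
  E <- matrix(30, 9, 1, dimnames = list(g$area_ids, "c1"))
  O <- matrix(rpois(9, 30 * exp(rnorm(9, 0, 0.4))), 9, 1,
              dimnames = list(g$area_ids, "c1"))
  fit <- mmodel(mortality_matrices(O, E), g,
                mmodel_config(n_latent = 1, n_chains = 2, n_burnin = 1500,
                              n_iter = 1500, thin = 3, seed = 14,
                              lam_fixed = 0))
  post <- fitted(fit)[, 1]
  crude <- (O / E)[, 1]
  centre <- mean(crude)
  # smoothing moves every estimate from the crude rate toward the centre
  inward <- (crude >= centre & post <= crude + 0.02) |
            (crude <= centre & post >= crude - 0.02)
  expect_true(all(inward))
})

test_that("prior-only sampling reproduces the declared priors", {
  tc <- toy_city(2, 2, J = 2, seed = 20)
  cfg <- mmodel_config(n_chains = 2, n_burnin = 500, n_iter = 4000, thin = 2,
                       seed = 99, sigma_fixed = c(0.7, 1.3),
                       likelihood = FALSE)
  fit <- mmodel(tc$oe, tc$graph, cfg)
  Md <- posterior_draws(fit, "M")          # columns: M[k, cause]
  sds <- apply(Md, 2, sd)
  # M[k,j] ~ Normal(0, sigma_j^2), column scales (0.7, 0.7, 1.3, 1.3)
  expect_equal(unname(sds), c(0.7, 0.7, 1.3, 1.3), tolerance = 0.12)
  expect_lt(max(abs(colMeans(Md))), 0.15)
  lam1 <- posterior_draws(fit, "lam")[, 1]
  expect_gt(ks.test(lam1[seq(1, length(lam1), by = 10)], "punif")$p.value,
            0.01)
})

test_that("an all-zero cause is retained with a warning", {
  g <- build_lattice_graph(2, 2)
  O <- matrix(c(5L, 6L, 4L, 7L, 0L, 0L, 0L, 0L), 4, 2,
              dimnames = list(g$area_ids, c("c1", "c2")))
  E <- matrix(c(rep(5, 4), rep(2, 4)), 4, 2,
              dimnames = list(g$area_ids, c("c1", "c2")))
  expect_warning(
    fit <- mmodel(mortality_matrices(O, E), g,
                  mmodel_config(n_chains = 2, n_burnin = 100, n_iter = 100,
                                thin = 1, seed = 2)),
    "zero observed deaths")
  expect_equal(ncol(fitted(fit)), 2)
})

test_that("mismatched data and graph are rejected", {
  tc <- toy_city(2, 2, J = 1, seed = 1)
  g_other <- build_lattice_graph(3, 2)
  expect_error(mmodel(tc$oe, g_other, mmodel_config(n_chains = 2)),
               class = "mortmap_invalid_input")
})

test_that("simulation-based calibration: posterior ranks of Sigma_11 are uniform", {
  # E fixed, parameters drawn from the model's own prior (sigma, lam fixed in
  # both generator and fit); ranks of the true Sigma_11 within thinned
  # posterior draws must be uniform if the sampler targets the right posterior
  g <- build_lattice_graph(5, 5)
  n <- 25; J <- 2; s_fix <- c(0.4, 0.4); lam_fix <- 0.6
  E <- matrix(40, n, J, dimnames = list(g$area_ids, c("c1", "c2")))
  n_rep <- 48
  seeds <- derive_seeds(20240917, n_rep)
  ranks <- integer(n_rep)
  n_draw_used <- 39                          # ranks in 0..39 -> 8 bins of 5
  for (r in seq_len(n_rep)) {
    set.seed(seeds[r])
    Phi <- sapply(1:J, function(k) as.vector(
      sample_leroux_field(g, lam_fix, 1, n_draws = 1)))
    M <- matrix(rnorm(J * J, 0, rep(s_fix, each = J)), J, J)
    O <- matrix(rpois(n * J, E * exp(Phi %*% M)), n, J,
                dimnames = dimnames(E))
    fit <- mmodel(mortality_matrices(O, E), g,
                  mmodel_config(n_chains = 2, n_burnin = 600, n_iter = 600,
                                thin = 12, seed = seeds[r],
                                sigma_fixed = s_fix, lam_fixed = lam_fix))
    draws <- posterior_draws(fit, "Sigma")[, 1]
    draws <- draws[seq_len(n_draw_used)]
    ranks[r] <- sum(draws < crossprod(M)[1, 1])
  }
  bins <- table(cut(ranks, breaks = seq(-0.5, n_draw_used + 0.5, by = 5)))
  p <- stats::chisq.test(as.vector(bins))$p.value
  expect_gt(p, 0.01)
})
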