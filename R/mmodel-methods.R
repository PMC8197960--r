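#' @export
print.mmodel <- function(x, ...) {
  cfg <- x$config
  cat("Multivariate spatial M-model fit\n")
  cat(sprintf("  %d areas x %d causes, %d latent fields\n",
              nrow(x$data$O), ncol(x$data$O), x$n_latent))
  cat(sprintf("  %d chains x %d kept draws (burn-in %d, thin %d), seed %d\n",
              cfg$n_chains, cfg$n_iter %/% cfg$thin, cfg$n_burnin, cfg$thin,
              cfg$seed))
  invisible(x)
}

#' Pooled draws of one monitored quantity group
#'
#' @param fit an [mmodel].
#' @param what one of `"theta"`, `"Sigma"`, `"lam"`, `"sigma"`, `"M"`.
#' @return matrix of pooled (all chains stacked) draws, one column per
#'   scalar quantity.
#' @export
posterior_draws <- function(fit, what = c("theta", "Sigma", "lam", "sigma", "M")) {
  stop_if_not(inherits(fit, "mmodel"), "`fit` must be an mmodel")
  what <- match.arg(what)
  do.call(rbind, lapply(fit$chains, `[[`, what))
}

#' @export
summary.mmodel <- function(object, ...) {
  sm <- summarize_draws(object)
  conv <- check_convergence(object)
  out <- list(smr = sm, convergence = conv,
              sigma_mean = matrix(colMeans(posterior_draws(object, "Sigma")),
                                  ncol(object$data$O),
                                  dimnames = list(object$data$causes,
                                                  object$data$causes)),
              lam_mean = colMeans(posterior_draws(object, "lam")),
              acceptance = object$acceptance)
  class(out) <- "summary.mmodel"
  out
}

#' @export
print.summary.mmodel <- function(x, ...) {
  cat("Posterior mean between-cause covariance (Sigma = M'M):\n")
  print(round(x$sigma_mean, 3))
  cat("\nPosterior mean Leroux mixing parameters:",
      paste(round(x$lam_mean, 3), collapse = ", "), "\n\n")
  print(x$convergence)
  cat("\nSmoothed SMRs (first areas):\n")
  print(head(round(x$smr$smr_mean, 1)))
  invisible(x)
}

#' @export
coef.mmodel <- function(object, ...) {
  list(Sigma = matrix(colMeans(posterior_draws(object, "Sigma")),
                      ncol(object$data$O),
                      dimnames = list(object$data$causes, object$data$causes)),
       lam = colMeans(posterior_draws(object, "lam")),
       sigma = colMeans(posterior_draws(object, "sigma")))
}

#' @export
fitted.mmodel <- function(object, ...) {
  th <- colMeans(posterior_draws(object, "theta"))
  matrix(th, nrow(object$data$O),
         dimnames = list(object$data$area_ids, object$data$causes))
}

#' Pearson residuals of a fitted M-model
#'
#' `(O - E*thetahat) / sqrt(E*thetahat)` on modeled cells, `NA` elsewhere.
#' @param object an [mmodel].
#' @param ... unused.
#' @export
residuals.mmodel <- function(object, ...) {
  mu <- object$data$E * fitted(object)
  r <- (object$data$O - mu) / sqrt(mu)
  r[!object$modeled] <- NA_real_
  r
}

#' Posterior-predictive death counts
#'
#' Draws replicate observed-count matrices `O* ~ Poisson(E * theta)` using
#' posterior draws of `theta` sampled at random.
#'
#' @param object an [mmodel].
#' @param nsim number of replicate matrices.
#' @param seed optional seed.
#' @param ... unused.
#' @return list of `nsim` `area x cause` count matrices.
#' @export
simulate.mmodel <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  th <- posterior_draws(object, "theta")
  E <- object$data$E
  pick <- sample.int(nrow(th), nsim, replace = TRUE)
  lapply(pick, function(i) {
    mu <- E * matrix(th[i, ], nrow(E))
    matrix(rpois(length(mu), mu), nrow(E), dimnames = dimnames(E))
  })
}

#' Shrinkage plot for a fitted M-model
#'
#' Plots smoothed against raw SMRs, per cause, with the identity line: the
#' vertical distance to the line is the smoothing applied to each area.
#'
#' @param x an [mmodel].
#' @param ... passed to [graphics::plot].
#' @export
plot.mmodel <- function(x, ...) {
  raw <- raw_smr(x$data)
  sm <- 100 * fitted(x)
  J <- ncol(raw)
  op <- graphics::par(mfrow = grDevices::n2mfrow(J), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (j in seq_len(J)) {
    graphics::plot(raw[, j], sm[, j], xlab = "raw SMR", ylab = "smoothed SMR",
                   main = colnames(raw)[j], ...)
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}
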