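#' Split-chain potential scale reduction factor (R-hat)
#'
#' Each chain is split into halves; with `W` the mean within-half-chain
#' variance and `B/n` the variance of half-chain means,
#' `R-hat = sqrt(((n-1)/n * W + B/n) / W)`. Values near 1 indicate that the
#' chains have mixed; the conventional pass threshold is 1.1.
#'
#' @param chains list of numeric vectors (one per chain) or a matrix with
#'   one chain per column.
#' @return scalar R-hat; `NA` with a warning when the pooled variance is
#'   zero (diagnostic undefined, e.g. a constant quantity).
#' @export
rhat <- function(chains) {
  ch <- as_chain_list(chains)
  stop_if_not(length(ch) >= 2, "at least 2 chains are required")
  stop_if_not(all(lengths(ch) >= 4), "each chain must have length >= 4")
  halves <- split_halves(ch)
  n <- length(halves[[1]])
  mns <- vapply(halves, mean, 0)
  vrs <- vapply(halves, var, 0)
  W <- mean(vrs)
  B_over_n <- var(mns)                     # = B/n
  if (!is.finite(W) || W == 0) {
    if (all(abs(unlist(ch) - mean(unlist(ch))) < .Machine$double.eps^0.5)) {
      warning("zero variance: R-hat undefined")
      return(NA_real_)
    }
    return(Inf)
  }
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

split_halves <- function(ch) {
  out <- list()
  for (x in ch) {
    m <- length(x) %/% 2L
    out <- c(out, list(x[seq_len(m)], x[seq.int(length(x) - m + 1L, length(x))]))
  }
  out
}

as_chain_list <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  stop_if_not(is.list(chains) && all(vapply(chains, is.numeric, TRUE)),
              "`chains` must be a list of numeric vectors or a matrix")
  chains
}

#' Effective sample size of MCMC chains
#'
#' `ESS = N / (1 + 2 * sum_t rho_t)` where the lag autocorrelations
#' `rho_t` are combined across chains (within-chain autocovariances against
#' the pooled variance) and summed while Geyer's initial positive-sequence
#' condition holds: accumulation stops at the first negative paired sum
#' `rho_{2t} + rho_{2t+1}`.
#'
#' @param chains list of numeric vectors or matrix, one chain per column.
#' @return scalar ESS; `NA` with a warning for zero-variance chains.
#' @export
effective_sample_size <- function(chains) {
  ch <- as_chain_list(chains)
  stop_if_not(all(lengths(ch) >= 4), "each chain must have length >= 4")
  n <- min(lengths(ch))
  ch <- lapply(ch, function(x) x[seq_len(n)])
  m <- length(ch)
  vrs <- vapply(ch, var, 0)
  W <- mean(vrs)
  mns <- vapply(ch, mean, 0)
  varp <- (n - 1) / n * W + (if (m > 1) var(mns) else 0)
  if (!is.finite(varp) || varp == 0) {
    warning("zero variance: ESS undefined")
    return(NA_real_)
  }
  # within-chain autocovariances, biased (divisor n), averaged over chains
  acov <- sapply(ch, function(x) {
    a <- acf(x, lag.max = n - 1L, type = "covariance", plot = FALSE,
             demean = TRUE)$acf[, 1, 1]
    a * (n - 1) / n
  })
  acov <- if (is.matrix(acov)) rowMeans(acov) else acov
  rho <- 1 - (W - acov) / varp             # rho[1] is lag 0 (= approx 1)
  s <- 0
  t <- 2L
  while (t + 1L <= length(rho)) {
    pair <- rho[t] + rho[t + 1L]
    if (!is.finite(pair) || pair < 0) break
    s <- s + pair
    t <- t + 2L
  }
  max(m * n / (1 + 2 * s), 1e-8)
}

#' Convergence report for a fitted M-model
#'
#' Computes split R-hat and ESS for every identifiable monitored quantity:
#' each modeled `theta_ij` (cells with `E = 0` are prior-predictive and
#' skipped), each unique entry of `Sigma`, each `lam_k` and each `sigma_j`.
#' `Phi` and `M` are not monitored: they are not identified (rotation).
#' The run passes when every R-hat < 1.1 and every ESS > 100; quantities
#' with undefined diagnostics (zero variance) pass with a warning.
#'
#' @param fit an [mmodel].
#' @param rhat_limit,ess_limit pass thresholds.
#' @return object of class `mmodel_convergence`: data frame of per-quantity
#'   diagnostics, `passed` flag, and the offender list.
#' @export
check_convergence <- function(fit, rhat_limit = 1.1, ess_limit = 100) {
  stop_if_not(inherits(fit, "mmodel"), "`fit` must be an mmodel")
  mon <- monitored_matrix(fit)
  nm <- colnames(mon[[1]])
  rh <- es <- setNames(numeric(length(nm)), nm)
  for (q in seq_along(nm)) {
    cols <- lapply(mon, function(m) m[, q])
    rh[q] <- suppressWarnings(rhat(cols))
    es[q] <- suppressWarnings(effective_sample_size(cols))
  }
  undefined <- is.na(rh) | is.na(es)
  ok <- (is.na(rh) | rh < rhat_limit) & (is.na(es) | es > ess_limit)
  if (any(undefined))
    warning(sum(undefined), " monitored quantities have undefined diagnostics ",
            "(zero variance); treated as passed")
  structure(list(table = data.frame(quantity = nm, rhat = rh, ess = es,
                                    passed = ok, row.names = NULL),
                 rhat = rh, ess = es, passed = all(ok),
                 offenders = nm[!ok],
                 rhat_limit = rhat_limit, ess_limit = ess_limit),
            class = "mmodel_convergence")
}

# per-chain matrices of the monitored (identifiable) quantities
monitored_matrix <- function(fit) {
  J <- length(fit$data$causes)
  keep_sigma_cols <- which(upper.tri(matrix(0, J, J), diag = TRUE))
  modeled <- as.vector(fit$modeled)
  lapply(fit$chains, function(chn) {
    cbind(chn$theta[, modeled, drop = FALSE],
          chn$Sigma[, keep_sigma_cols, drop = FALSE],
          chn$lam, chn$sigma)
  })
}

#' @export
print.mmodel_convergence <- function(x, ...) {
  cat("M-model convergence:", if (x$passed) "PASSED" else "FAILED", "\n")
  cat(sprintf("  max R-hat = %.3f (limit %.2f), min ESS = %.0f (limit %.0f)\n",
              max(x$rhat, na.rm = TRUE), x$rhat_limit,
              min(x$ess, na.rm = TRUE), x$ess_limit))
  if (!x$passed)
    cat("  offenders:", paste(head(x$offenders, 8), collapse = ", "),
        if (length(x$offenders) > 8) "..." else "", "\n")
  invisible(x)
}
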