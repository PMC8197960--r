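#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rpois dpois sd cor var quantile aov t.test
#'   ks.test pf setNames median acf simulate coef fitted residuals
#' @importFrom utils read.csv write.csv head
NULL

stop_if_not <- function(cond, msg, class = "mortmap_invalid_argument") {
  if (!isTRUE(cond)) {
    stop(structure(class = c(class, "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
  }
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

#' Derive reproducible sub-seeds from a master seed
#'
#' Splits one master seed into `n` sub-seeds by a fixed rule (a dedicated
#' RNG stream seeded with the master seed), so that the stream used by, say,
#' chain 2 does not change when more chains or cities are added.
#'
#' @param seed master seed (integer).
#' @param n number of sub-seeds.
#' @return integer vector of length `n`, all below 2^31.
#' @export
derive_seeds <- function(seed, n) {
  stop_if_not(is_count(n), "`n` must be a positive integer")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

# two-pass Pearson correlation used nowhere in the fitting path; exported for
# completeness of the summary checks
pearson2 <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
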