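#' Posterior SMR summaries
#'
#' Reduces the posterior `theta` draws of a fitted M-model to the smoothed
#' SMR surface (`100 * posterior mean of theta`), the posterior mean
#' log-SMR (`mean of log theta`), and the exceedance probability
#' `P(theta > 1 | data)` (strict inequality). Cells with `E = 0` are
#' prior-predictive only and flagged.
#'
#' @param fit an [mmodel], or a list with elements `theta` (draws matrix,
#'   one column per area-cause cell), `n_areas`, `causes`, `area_ids` and
#'   optionally `modeled`.
#' @return object of class `smr_summary` with matrices `smr_mean`,
#'   `log_smr_mean`, `exceed_prob` (`area x cause`) and the logical flag
#'   matrix `modeled`.
#' @export
summarize_draws <- function(fit) {
  if (inherits(fit, "mmodel")) {
    th <- posterior_draws(fit, "theta")
    n <- nrow(fit$data$O)
    dn <- list(fit$data$area_ids, fit$data$causes)
    modeled <- fit$modeled
    city <- fit$data$city
  } else {
    th <- fit$theta
    n <- fit$n_areas
    dn <- list(fit$area_ids, fit$causes)
    modeled <- if (!is.null(fit$modeled)) fit$modeled else
      matrix(TRUE, n, length(fit$causes))
    city <- if (!is.null(fit$city)) fit$city else NA_character_
  }
  stop_if_not(nrow(th) >= 1, "no posterior draws")
  shape <- function(v) matrix(v, n, dimnames = dn)
  structure(list(smr_mean = shape(100 * colMeans(th)),
                 log_smr_mean = shape(colMeans(log(th))),
                 exceed_prob = shape(colMeans(th > 1)),
                 modeled = modeled, city = city),
            class = "smr_summary")
}

#' @export
print.smr_summary <- function(x, ...) {
  cat("smr_summary:", nrow(x$smr_mean), "areas x", ncol(x$smr_mean), "causes\n")
  cat("  smoothed SMR range:", paste(round(range(x$smr_mean), 1), collapse = " - "), "\n")
  invisible(x)
}

#' Risk classes for choropleth maps
#'
#' Classifies relative risks (`theta = SMR/100`) into the seven fixed map
#' classes delimited by the cuts 0.7, 0.8, 0.9, 1.1, 1.2 and 1.3. Intervals
#' are closed on the left and open on the right; the lowest class is
#' `(0, 0.7)` and the highest `[1.3, Inf)`.
#'
#' @param theta positive numeric vector of relative risks.
#' @return ordered factor of class labels.
#' @export
classify_risk <- function(theta) {
  stop_if_not(is.numeric(theta) && all(is.finite(theta)) && all(theta > 0),
              "`theta` must be positive", class = "mortmap_invalid_input")
  cuts <- c(0.7, 0.8, 0.9, 1.1, 1.2, 1.3)
  labs <- c("<0.7", "[0.7,0.8)", "[0.8,0.9)", "[0.9,1.1)", "[1.1,1.2)",
            "[1.2,1.3)", ">=1.3")
  idx <- findInterval(theta, cuts, left.open = FALSE) + 1L
  factor(labs[idx], levels = labs, ordered = TRUE)
}

#' Spatial variability of the log-SMR surface
#'
#' The sample standard deviation (divisor `n - 1`) of the posterior-mean
#' log-SMRs across a city's areas for one cause: the quantity tabulated per
#' city and cause in the variability tables.
#'
#' @param summary an [smr_summary].
#' @param cause cause label or column index; default all causes.
#' @return named numeric vector of standard deviations.
#' @export
logsmr_sd <- function(summary, cause = NULL) {
  stop_if_not(inherits(summary, "smr_summary"), "`summary` must be an smr_summary")
  stop_if_not(nrow(summary$log_smr_mean) >= 2,
              "variability is undefined for a single area")
  m <- summary$log_smr_mean
  if (!is.null(cause)) m <- m[, cause, drop = FALSE]
  apply(m, 2, sd)
}

#' Variability table (cities x causes) with margins
#'
#' Assembles the per-city, per-cause standard deviations of the log-SMR
#' surfaces into one table with a mean row and column (unweighted arithmetic
#' means, always recomputed from the cells). Causes are ordered by
#' decreasing average variability.
#'
#' @param values named numeric `city x cause` matrix of standard deviations,
#'   or a named list of per-city named vectors sharing the cause set (e.g.
#'   outputs of [logsmr_sd()]).
#' @param printed_margins optional list with `row` and `col` means as
#'   printed in an external source; carried as an attribute, never used in
#'   computation unless explicitly requested.
#' @return object of class `variability_table`: `values` (cause-ordered),
#'   `row_means`, `col_means`.
#' @export
variability_table <- function(values, printed_margins = NULL) {
  if (is.list(values) && !is.data.frame(values)) {
    causes <- names(values[[1]])
    stop_if_not(!is.null(causes) && all(vapply(values, function(v)
      identical(names(v), causes), TRUE)),
      "cities disagree on the cause list", class = "mortmap_invalid_input")
    values <- do.call(rbind, values)
  }
  values <- as.matrix(values)
  stop_if_not(!is.null(rownames(values)) && !is.null(colnames(values)),
              "`values` needs city row names and cause column names")
  stop_if_not(all(values >= 0), "standard deviations must be non-negative",
              class = "mortmap_invalid_input")
  ord <- order(colMeans(values), decreasing = TRUE)
  values <- values[, ord, drop = FALSE]
  structure(list(values = values,
                 row_means = rowMeans(values),
                 col_means = colMeans(values),
                 printed_margins = printed_margins),
            class = "variability_table")
}

#' @rdname variability_table
#' @param per_city_summaries named list (city -> [smr_summary]) from which
#'   the standard deviations are computed.
#' @export
build_variability_table <- function(per_city_summaries) {
  variability_table(lapply(per_city_summaries, logsmr_sd))
}

#' @export
print.variability_table <- function(x, ...) {
  v <- cbind(x$values, Mean = x$row_means)
  v <- rbind(v, Mean = c(x$col_means, NA))
  print(round(v, 2), na.print = "")
  invisible(x)
}

#' Correlation of spatial variability between men and women
#'
#' Pearson correlation between the per-cause average variabilities (table
#' column means) of two variability tables, restricted to the causes they
#' share. With `margins = "printed"`, tables carrying externally printed
#' margins use those (at their published rounding) instead of the
#' full-precision recomputed means; this is how a published correlation
#' computed from rounded margins is reproduced.
#'
#' @param men,women [variability_table] objects.
#' @param shared_causes optional explicit cause subset (default: intersection).
#' @param margins `"recomputed"` (default) or `"printed"`.
#' @return scalar Pearson correlation.
#' @export
cross_gender_variability_correlation <- function(men, women,
                                                 shared_causes = NULL,
                                                 margins = c("recomputed", "printed")) {
  margins <- match.arg(margins)
  cm_m <- table_col_means(men, margins)
  cm_w <- table_col_means(women, margins)
  if (is.null(shared_causes)) shared_causes <- intersect(names(cm_m), names(cm_w))
  stop_if_not(length(shared_causes) >= 3,
              "at least 3 shared causes are required",
              class = "mortmap_invalid_input")
  stop_if_not(all(shared_causes %in% names(cm_m)) &&
              all(shared_causes %in% names(cm_w)),
              "`shared_causes` missing from a table", class = "mortmap_invalid_input")
  cor(cm_m[shared_causes], cm_w[shared_causes])
}

table_col_means <- function(tab, margins) {
  stop_if_not(inherits(tab, "variability_table"),
              "expected a variability_table")
  if (margins == "printed" && !is.null(tab$printed_margins))
    return(tab$printed_margins$col)
  tab$col_means
}

#' Between-cause correlations of the smoothed log-SMR surfaces
#'
#' Pearson correlation across areas between the posterior-mean log-SMR
#' vectors of each cause pair in one city. Zero-variance causes yield `NA`
#' for their pairs.
#'
#' @param summary an [smr_summary].
#' @return `J x J` correlation matrix with unit diagonal.
#' @export
pairwise_logsmr_correlations <- function(summary) {
  stop_if_not(inherits(summary, "smr_summary"), "`summary` must be an smr_summary")
  m <- summary$log_smr_mean
  stop_if_not(nrow(m) >= 3, "at least 3 areas are required")
  sds <- apply(m, 2, sd)
  r <- suppressWarnings(cor(m))
  r[sds == 0, ] <- NA_real_; r[, sds == 0] <- NA_real_
  diag(r) <- 1
  r
}

#' Cross-city aggregation of correlation matrices
#'
#' Element-wise mean and empirical 2.5/97.5 percentiles (linear
#' interpolation between order statistics) of the per-city between-cause
#' correlation matrices. Causes are ordered by decreasing mean correlation
#' with the other causes.
#'
#' @param per_city named list (city -> `J x J` correlation matrix).
#' @return object of class `correlation_summary`: `per_city`,
#'   `mean_matrix`, `lo`, `hi` (all cause-ordered), `cause_order`, and the
#'   count of missing cells per pair.
#' @export
aggregate_correlations <- function(per_city) {
  stop_if_not(is.list(per_city) && length(per_city) >= 2,
              "at least 2 cities are required")
  cn <- colnames(per_city[[1]])
  stop_if_not(!is.null(cn) && all(vapply(per_city, function(m)
    identical(colnames(m), cn), TRUE)),
    "cities disagree on the cause list", class = "mortmap_invalid_input")
  arr <- simplify2array(per_city)
  mean_m <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  lo <- apply(arr, c(1, 2), quantile, probs = 0.025, na.rm = TRUE, type = 7)
  hi <- apply(arr, c(1, 2), quantile, probs = 0.975, na.rm = TRUE, type = 7)
  n_missing <- apply(arr, c(1, 2), function(v) sum(is.na(v)))
  # order causes by mean correlation with the rest
  off <- mean_m; diag(off) <- NA
  ord <- order(rowMeans(off, na.rm = TRUE), decreasing = TRUE)
  reorder2 <- function(m) m[ord, ord, drop = FALSE]
  structure(list(per_city = lapply(per_city, reorder2),
                 mean_matrix = reorder2(mean_m),
                 lo = reorder2(lo), hi = reorder2(hi),
                 n_missing = reorder2(n_missing),
                 cause_order = cn[ord]),
            class = "correlation_summary")
}

#' @export
print.correlation_summary <- function(x, ...) {
  cat("correlation_summary over", length(x$per_city), "cities;",
      "causes (ordered):", paste(x$cause_order, collapse = ", "), "\n")
  cat("mean off-diagonal correlation:",
      round(mean_offdiagonal_correlation(x), 3), "\n")
  invisible(x)
}

#' Mean of the off-diagonal correlations
#'
#' Average of the upper triangle (diagonal excluded) of the cross-city mean
#' correlation matrix: one number summarizing how strongly the causes'
#' spatial patterns agree.
#'
#' @param summary a [correlation_summary] or a square correlation matrix.
#' @return scalar.
#' @export
mean_offdiagonal_correlation <- function(summary) {
  m <- if (inherits(summary, "correlation_summary")) summary$mean_matrix else summary
  stop_if_not(is.matrix(m) && nrow(m) == ncol(m) && nrow(m) >= 2,
              "need a square matrix with J >= 2")
  mean(m[upper.tri(m)], na.rm = TRUE)
}

#' Compare mean correlations between two groups
#'
#' Pooled-variance two-sample Student t-test on two sets of pairwise mean
#' correlations (e.g. the upper-triangle entries of the men's and women's
#' aggregated matrices).
#'
#' @param men_pairs,women_pairs numeric vectors (length >= 2 each).
#' @return list with `t`, `df`, `p_value` and the group means.
#' @export
compare_mean_correlations <- function(men_pairs, women_pairs) {
  stop_if_not(length(men_pairs) >= 2 && length(women_pairs) >= 2,
              "both groups need at least 2 values")
  stop_if_not(var(men_pairs) + var(women_pairs) > 0,
              "zero pooled variance: t-test undefined")
  tt <- t.test(men_pairs, women_pairs, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value,
       mean_men = mean(men_pairs), mean_women = mean(women_pairs))
}

#' Two-way ANOVA of the variability table
#'
#' Additive two-way analysis of variance (no interaction: one observation
#' per cell) of the log-SMR standard deviations on the factors city and
#' cause, testing whether cities and causes differ in the strength of their
#' spatial risk patterns.
#'
#' @param table a [variability_table] with complete cells.
#' @return object of class `mmodel_anova`: per-term sums of squares,
#'   degrees of freedom, mean squares, F and p values.
#' @export
anova_variability <- function(table) {
  stop_if_not(inherits(table, "variability_table"),
              "`table` must be a variability_table")
  v <- table$values
  stop_if_not(!anyNA(v), "missing cells: ANOVA requires a complete table",
              class = "mortmap_invalid_input")
  df <- data.frame(value = as.vector(v),
                   city = factor(rep(rownames(v), ncol(v))),
                   cause = factor(rep(colnames(v), each = nrow(v))))
  fit <- aov(value ~ city + cause, data = df)
  s <- summary(fit)[[1]]
  terms <- trimws(rownames(s))
  get <- function(term, col) s[match(term, terms), col]
  tot <- sum(s[, "Sum Sq"])
  zero_ss <- function(term) tot > 0 && s[match(term, terms), "Sum Sq"] / tot < 1e-12
  Fv <- function(term) if (zero_ss(term)) 0 else get(term, "F value")
  pv <- function(term) if (zero_ss(term)) 1 else get(term, "Pr(>F)")
  res <- list(ss = setNames(s[, "Sum Sq"], terms),
              df = setNames(s[, "Df"], terms),
              ms = setNames(s[, "Mean Sq"], terms),
              F_city = Fv("city"), p_city = pv("city"),
              F_cause = Fv("cause"), p_cause = pv("cause"),
              degenerate = isTRUE(all.equal(unname(get("Residuals", "Sum Sq") / max(tot, 1)), 0)))
  if (res$degenerate)
    warning("zero residual sum of squares: F tests are degenerate")
  class(res) <- "mmodel_anova"
  res
}

#' @export
print.mmodel_anova <- function(x, ...) {
  tab <- data.frame(Df = x$df, `Sum Sq` = x$ss, `Mean Sq` = x$ms,
                    `F` = c(x$F_city, x$F_cause, NA),
                    `Pr(>F)` = c(x$p_city, x$p_cause, NA),
                    check.names = FALSE)
  print(tab)
  invisible(x)
}

#' Export per-area summary products as CSV
#'
#' Writes smoothed SMRs, exceedance probabilities and risk classes keyed by
#' `area_id`, joinable back to the input geometries.
#'
#' @param summary an [smr_summary].
#' @param path output CSV path.
#' @export
write_summary_csv <- function(summary, path) {
  sm <- summary$smr_mean
  cls <- apply(sm / 100, 2, function(v) as.character(classify_risk(v)))
  df <- data.frame(area_id = rownames(sm),
                   setNames(as.data.frame(sm), paste0("smr_", colnames(sm))),
                   setNames(as.data.frame(summary$exceed_prob),
                            paste0("pexc_", colnames(sm))),
                   setNames(as.data.frame(cls, stringsAsFactors = FALSE),
                            paste0("class_", colnames(sm))),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(summary)
}
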