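fake_fit <- function(theta_draws, area_ids, causes) {
  list(theta = theta_draws, n_areas = length(area_ids),
       area_ids = area_ids, causes = causes)
}

test_that("summarize_draws computes SMR means and strict exceedance", {
  f <- fake_fit(matrix(1, 100, 2), c("a1", "a2"), "c1")
  sm <- summarize_draws(f)
  expect_equal(unname(sm$smr_mean), matrix(100, 2, 1))
  expect_equal(unname(sm$exceed_prob), matrix(0, 2, 1))   # strict inequality

  f2 <- fake_fit(matrix(rep(c(0.5, 2), each = 1, times = 50), 100, 1),
                 "a1", "c1")
  sm2 <- summarize_draws(f2)
  expect_equal(sm2$exceed_prob[1, 1], 0.5)
  expect_equal(sm2$log_smr_mean[1, 1], 0)

  set.seed(111)
  th <- matrix(exp(rnorm(1000, 0, 0.25)), 1000, 1)
  sm3 <- summarize_draws(fake_fit(th, "a1", "c1"))
  se <- sqrt(0.25 / 1000)
  expect_lt(abs(sm3$exceed_prob[1, 1] - 0.5), 4 * se)
})

test_that("risk classes use left-closed intervals at the fixed cuts", {
  expect_equal(as.character(classify_risk(1.0)), "[0.9,1.1)")
  expect_equal(as.character(classify_risk(0.7)), "[0.7,0.8)")
  expect_equal(as.character(classify_risk(1.35)), ">=1.3")
  expect_equal(as.character(classify_risk(c(0.1, 0.8, 1.1, 1.3))),
               c("<0.7", "[0.8,0.9)", "[1.1,1.2)", ">=1.3"))
  expect_equal(nlevels(classify_risk(1)), 7)
  expect_error(classify_risk(0), class = "mortmap_invalid_input")
})

test_that("log-SMR variability follows the sample sd closed forms", {
  mk <- function(v) {
    structure(list(smr_mean = matrix(100 * exp(v), ncol = 1),
                   log_smr_mean = matrix(v, ncol = 1,
                                         dimnames = list(paste0("a", seq_along(v)), "c1")),
                   exceed_prob = matrix(0.5, length(v), 1),
                   modeled = matrix(TRUE, length(v), 1)),
              class = "smr_summary")
  }
  expect_equal(unname(logsmr_sd(mk(rep(0.3, 5)))), 0)
  x <- 0.25
  expect_equal(unname(logsmr_sd(mk(c(-x, x)))), x * sqrt(2))
  expect_equal(unname(logsmr_sd(mk(c(0, 0, 0, 0.2)))), 0.1)
  expect_error(logsmr_sd(mk(0.1)), "single area")
})

test_that("variability tables recompute margins and order causes", {
  v <- matrix(c(0.2, 0.4, 0.1, 0.3), 2,
              dimnames = list(c("cityA", "cityB"), c("c1", "c2")))
  tab <- variability_table(v)
  expect_equal(unname(tab$col_means),
               unname(sort(colMeans(v), decreasing = TRUE)))
  expect_equal(tab$row_means, rowMeans(tab$values))
  # single city, single cause: margins equal the value
  t1 <- variability_table(matrix(0.42, 1, 1, dimnames = list("x", "c")))
  expect_equal(unname(t1$row_means), 0.42)
  expect_equal(unname(t1$col_means), 0.42)
  expect_error(variability_table(list(a = c(x = 1), b = c(y = 1))),
               class = "mortmap_invalid_input")
})

test_that("the published variability tables reproduce their printed margins", {
  fx <- tables_fixture()
  expect_equal(fx$men$values["Córdoba", "AIDS"], 0.84)
  expect_equal(fx$women$values["Palma de Mallorca", "Dementia"], 0.40)
  expect_lt(abs(fx$men$col_means[["AIDS"]] - 0.48), 0.011)
  expect_lt(abs(fx$women$col_means[["Haematological c."]] - 0.07), 0.011)
  for (tab in fx) {
    pm <- tab$printed_margins
    expect_true(all(abs(tab$col_means[names(pm$col)] - pm$col) <= 0.01))
    expect_true(all(abs(tab$row_means[names(pm$row)] - pm$row) <= 0.01))
  }
  # men's causes by decreasing average variability start AIDS, cirrhosis, COPD
  expect_identical(colnames(fx$men$values)[1:3], c("AIDS", "Cirrhosis", "COPD"))
})

test_that("cross-gender variability correlation matches closed cases and 0.38", {
  fx <- tables_fixture()
  r <- cross_gender_variability_correlation(fx$men, fx$women,
                                            margins = "printed")
  expect_equal(round(r, 2), 0.38)
  # identical columns -> 1; affine anti-correlation -> -1
  v <- matrix(c(0.2, 0.4, 0.3, 0.1, 0.5, 0.25), 2,
              dimnames = list(c("u", "v"), c("c1", "c2", "c3")))
  tab <- variability_table(v)
  expect_equal(cross_gender_variability_correlation(tab, tab), 1)
  anti <- variability_table(matrix(1 - v, 2, dimnames = dimnames(v)))
  expect_equal(cross_gender_variability_correlation(tab, anti), -1)
  expect_error(cross_gender_variability_correlation(
    variability_table(v[, 1:2]), variability_table(v[, 1:2])),
    class = "mortmap_invalid_input")
})

test_that("pairwise log-SMR correlations follow the Pearson oracle", {
  mk <- function(m) structure(list(log_smr_mean = m,
                                   smr_mean = 100 * exp(m),
                                   exceed_prob = m * 0 + 0.5,
                                   modeled = m == m),
                              class = "smr_summary")
  a <- c(1, 2, 3, 4, 5, 6); b <- c(2, 1, 4, 3, 6, 5)
  m <- cbind(A = a, B = b, C = -a)
  rownames(m) <- paste0("t", 1:6)
  r <- pairwise_logsmr_correlations(mk(m))
  expect_equal(round(r["A", "B"], 4), 0.8286)
  expect_equal(r["A", "C"], -1)
  expect_equal(diag(r), c(A = 1, B = 1, C = 1))
  # duplicate surface -> correlation 1
  r2 <- pairwise_logsmr_correlations(mk(cbind(A = a, B = a)))
  expect_equal(r2["A", "B"], 1)
  # zero-variance cause flagged missing
  r3 <- pairwise_logsmr_correlations(mk(cbind(A = a, Z = rep(1, 6))))
  expect_true(is.na(r3["A", "Z"]))
  # two-pass oracle agreement on random surfaces
  set.seed(121)
  mm <- matrix(rnorm(40), 10, 4, dimnames = list(paste0(1:10), paste0("c", 1:4)))
  rr <- pairwise_logsmr_correlations(mk(mm))
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(rr[i, j], pearson2(mm[, i], mm[, j]), tolerance = 1e-12)
})

test_that("cross-city aggregation averages, bounds and orders correlations", {
  m1 <- matrix(c(1, 0.2, 0.2, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  m2 <- matrix(c(1, 0.6, 0.6, 1), 2, dimnames = dimnames(m1))
  agg <- aggregate_correlations(list(x = m1, y = m2))
  expect_equal(agg$mean_matrix["a", "b"], 0.4)
  expect_gte(agg$lo["a", "b"], 0.2)
  expect_lte(agg$hi["a", "b"], 0.6)
  # identical matrices: lo = mean = hi
  agg2 <- aggregate_correlations(list(x = m1, y = m1, z = m1))
  expect_equal(agg2$lo, agg2$mean_matrix)
  expect_equal(agg2$hi, agg2$mean_matrix)
  # city-order invariance
  agg3 <- aggregate_correlations(list(y = m2, x = m1))
  expect_equal(agg3$mean_matrix, agg$mean_matrix)
  expect_equal(agg3$lo, agg$lo)
  # percentiles of uniform draws across 26 cities
  set.seed(131)
  mats <- lapply(1:26, function(i) {
    r <- runif(1)
    matrix(c(1, r, r, 1), 2, dimnames = dimnames(m1))
  })
  agg4 <- aggregate_correlations(setNames(mats, paste0("city", 1:26)))
  rs <- vapply(mats, function(m) m[1, 2], 0)
  expect_equal(agg4$lo["a", "b"], unname(quantile(rs, 0.025, type = 7)))
  expect_equal(agg4$hi["a", "b"], unname(quantile(rs, 0.975, type = 7)))
})

test_that("mean off-diagonal correlation averages the upper triangle", {
  expect_equal(mean_offdiagonal_correlation(diag(3)), 0)
  m <- matrix(0.5, 3, 3); diag(m) <- 1
  expect_equal(mean_offdiagonal_correlation(m), 0.5)
  m2 <- diag(3)
  m2[upper.tri(m2)] <- c(0.1, 0.2, 0.6)
  expect_equal(mean_offdiagonal_correlation(m2), 0.3)
})

test_that("the pooled t-test on pairwise correlations matches hand values", {
  same <- c(0.3, 0.4, 0.5)
  res <- compare_mean_correlations(same, same)
  expect_equal(res$t, 0)
  expect_equal(res$p_value, 1)
  set.seed(141)
  res2 <- compare_mean_correlations(1 + rnorm(4, 0, 1e-4), rnorm(4, 0, 1e-4))
  expect_lt(res2$p_value, 0.001)
  res3 <- compare_mean_correlations(c(0.5, 0.6, 0.7), c(0.2, 0.3, 0.4))
  expect_equal(res3$t, 3.674, tolerance = 1e-3)
  expect_equal(res3$df, 4)
  expect_equal(res3$p_value, 0.0213, tolerance = 0.01)
  expect_error(compare_mean_correlations(c(1, 1), c(1, 1)), "pooled variance")
})

test_that("two-way ANOVA of the variability table matches the hand decomposition", {
  dn <- list(paste0("city", 1:3), paste0("cause", 1:3))
  tab139 <- variability_table(matrix(1:9, 3, 3, byrow = TRUE, dimnames = dn))
  res <- suppressWarnings(anova_variability(tab139))
  expect_equal(unname(res$ss["city"]), 54)
  expect_equal(unname(res$ss["cause"]), 6)
  expect_equal(unname(res$ss["Residuals"]), 0, tolerance = 1e-9)
  expect_true(res$degenerate)
  expect_equal(unname(res$df), c(2, 2, 4))

  same_rows <- variability_table(matrix(rep(c(1, 2, 3), each = 3), 3,
                                        dimnames = dn))
  expect_warning(res2 <- anova_variability(same_rows), "degenerate")
  expect_equal(unname(res2$ss["city"]), 0, tolerance = 1e-12)
  expect_equal(unname(res2$F_city), 0, tolerance = 1e-9)

  # noisy table: recomputed against the printed-tables fixture shape
  fx <- tables_fixture()
  res3 <- anova_variability(fx$men)
  expect_equal(unname(res3$df), c(25, 14, 25 * 14))
  expect_lt(res3$p_cause, 1e-10)
  expect_lt(res3$p_city, 1e-10)
})
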