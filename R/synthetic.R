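#' Synthetic multi-city study configuration
#'
#' Describes the generative conditions for synthetic cities that follow the
#' model's own law: a rook lattice of census-tract-like areas, latent
#' unit-scale Leroux fields mixed by a loading matrix (`log theta = Phi M`),
#' a 5-band age schedule of baseline rates shared by the whole city, and
#' Poisson deaths with mean `person_years * rate * theta` (the relative
#' risk acts multiplicatively and identically on every age band, the
#' assumption implicit in indirect standardization).
#'
#' Defaults emulate census-tract-sized areas observed over a 20-year
#' period: area populations uniform on (500, 3000), five 5-year-style age
#' bands with geometrically increasing annual baseline rates
#' `1e-4 * 3^(band-1)` and age mix (0.25, 0.25, 0.2, 0.2, 0.1).
#'
#' @param n_cities number of cities.
#' @param rows,cols lattice dimensions per city.
#' @param causes cause labels (or a count).
#' @param n_latent latent field count (default: one per cause).
#' @param lam per-latent Leroux mixing parameters (recycled).
#' @param sigma per-cause loading scales used when `M` is not given.
#' @param M optional fixed `latent x cause` loading matrix shared by all
#'   cities (e.g. from [loading_from_sigma()] for a known Sigma).
#' @param age_bands age band labels.
#' @param baseline_rates annual baseline death rate per age band (per
#'   cause; a matrix `band x cause` is accepted).
#' @param age_dist population share per age band.
#' @param pop_range range of the uniform area-population draw.
#' @param n_years study-period length (person-years = population * years).
#' @param seed master seed.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cities = 1, rows = 10, cols = 10,
                             causes = 2, n_latent = NULL,
                             lam = 0.8, sigma = 0.4, M = NULL,
                             age_bands = paste0("age", 1:5),
                             baseline_rates = 1e-4 * 3^(0:4),
                             age_dist = c(0.25, 0.25, 0.2, 0.2, 0.1),
                             pop_range = c(500, 3000), n_years = 20,
                             seed = 1) {
  if (is.numeric(causes) && length(causes) == 1)
    causes <- sprintf("cause%02d", seq_len(causes))
  J <- length(causes)
  K <- if (is.null(n_latent)) J else n_latent
  stop_if_not(is_count(n_cities) && is_count(rows) && is_count(cols),
              "counts must be positive integers")
  stop_if_not(K >= 1, "`n_latent` must be positive")
  stop_if_not(all(lam >= 0 & lam < 1), "`lam` must lie in [0, 1)")
  stop_if_not(all(sigma > 0), "`sigma` must be positive")
  stop_if_not(length(age_bands) == length(age_dist),
              "age bands and age distribution disagree")
  stop_if_not(all(baseline_rates >= 0) && all(age_dist > 0),
              "rates must be >= 0 and age shares positive")
  if (!is.null(M)) {
    M <- as.matrix(M)
    stop_if_not(ncol(M) == J && nrow(M) == K, "`M` has wrong dimensions")
  }
  rates <- if (is.matrix(baseline_rates)) baseline_rates else
    matrix(baseline_rates, length(age_bands), J)
  stop_if_not(nrow(rates) == length(age_bands) && ncol(rates) == J,
              "`baseline_rates` has wrong dimensions")
  dimnames(rates) <- list(age_bands, causes)
  structure(list(n_cities = as.integer(n_cities), rows = as.integer(rows),
                 cols = as.integer(cols), causes = causes, n_latent = K,
                 lam = rep(lam, length.out = K),
                 sigma = rep(sigma, length.out = J), M = M,
                 age_bands = age_bands, rates = rates,
                 age_dist = age_dist / sum(age_dist),
                 pop_range = pop_range, n_years = n_years,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Loading matrix with a prescribed between-cause covariance
#'
#' Returns the upper-triangular Cholesky factor `M` with `M'M = Sigma`, for
#' generating synthetic data with a known covariance.
#'
#' @param Sigma symmetric positive-definite `cause x cause` matrix.
#' @export
loading_from_sigma <- function(Sigma) chol(Sigma)

#' Generate one synthetic city
#'
#' Draws a complete stratified dataset and its generating truth for city
#' `city_index` of the configured study. The per-city seed is derived from
#' the master seed by a fixed rule, so city `c` is identical whether
#' generated alone or within [generate_multicity()].
#'
#' @param config a [synthetic_config].
#' @param city_index which city to generate.
#' @return list with `data` (a [stratified_mortality]), `graph` (the
#'   lattice [area_graph]) and `truth` (Phi, M, Sigma, lam, theta, seed).
#' @export
generate_city <- function(config, city_index = 1) {
  stop_if_not(inherits(config, "synthetic_config"),
              "`config` must be a synthetic_config")
  stop_if_not(is_count(city_index) && city_index <= config$n_cities,
              "`city_index` out of range")
  seed_c <- derive_seeds(config$seed, config$n_cities)[city_index]
  graph <- build_lattice_graph(config$rows, config$cols)
  n <- graph$n_areas
  J <- length(config$causes)
  K <- config$n_latent
  set.seed(seed_c)
  Phi <- sapply(seq_len(K), function(k)
    as.vector(sample_leroux_field(graph, config$lam[k], scale = 1, n_draws = 1)))
  Phi <- matrix(Phi, n, K)
  M <- if (!is.null(config$M)) config$M else
    matrix(rnorm(K * J, 0, rep(config$sigma, each = K)), K, J)
  theta <- exp(Phi %*% M)
  pop_total <- runif(n, config$pop_range[1], config$pop_range[2]) * config$n_years
  pop <- outer(pop_total, config$age_dist)
  dimnames(pop) <- list(graph$area_ids, config$age_bands)
  A <- length(config$age_bands)
  mu <- array(0, c(n, A, J))
  for (j in seq_len(J))
    mu[, , j] <- pop * matrix(config$rates[, j], n, A, byrow = TRUE) * theta[, j]
  deaths <- array(rpois(length(mu), mu), dim(mu),
                  dimnames = list(graph$area_ids, config$age_bands, config$causes))
  data <- stratified_mortality(sprintf("city%02d", city_index), "all",
                               deaths, pop)
  dimnames(theta) <- list(graph$area_ids, config$causes)
  list(data = data, graph = graph,
       truth = list(Phi = Phi, M = M, Sigma = crossprod(M),
                    lam = config$lam, theta = theta, seed = seed_c))
}

#' Generate the full multi-city study
#'
#' @param config a [synthetic_config].
#' @return list of [generate_city()] results, one per city.
#' @export
generate_multicity <- function(config) {
  stop_if_not(inherits(config, "synthetic_config"),
              "`config` must be a synthetic_config")
  lapply(seq_len(config$n_cities), function(cc) generate_city(config, cc))
}

#' Write a synthetic city to the standard CSV inputs
#'
#' Emits the long-format deaths and population CSVs read by
#' [read_stratified_csv()], an edge-list file for the graph, and the truth
#' as JSON.
#'
#' @param city result of [generate_city()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_city_csv <- function(city, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- city$data
  idx <- which(d$deaths > 0, arr.ind = TRUE)
  deaths_df <- data.frame(city = d$city, sex = d$sex,
                          area_id = d$area_ids[idx[, 1]],
                          age_group = d$age_groups[idx[, 2]],
                          cause = d$causes[idx[, 3]],
                          deaths = d$deaths[idx])
  # keep every cause present even if it drew zero deaths overall
  missing_causes <- setdiff(d$causes, unique(deaths_df$cause))
  if (length(missing_causes))
    deaths_df <- rbind(deaths_df,
                       data.frame(city = d$city, sex = d$sex,
                                  area_id = d$area_ids[1],
                                  age_group = d$age_groups[1],
                                  cause = missing_causes, deaths = 0L))
  pop_df <- data.frame(city = d$city, sex = d$sex,
                       area_id = rep(d$area_ids, length(d$age_groups)),
                       age_group = rep(d$age_groups, each = length(d$area_ids)),
                       person_years = as.vector(d$population))
  paths <- file.path(dir, c("deaths.csv", "population.csv", "edges.txt",
                            "truth.json"))
  write.csv(deaths_df, paths[1], row.names = FALSE)
  write.csv(pop_df, paths[2], row.names = FALSE)
  e <- city$graph$edges
  writeLines(paste(city$graph$area_ids[e[, 1]], city$graph$area_ids[e[, 2]]),
             paths[3])
  tr <- city$truth
  jsonlite::write_json(list(M = tr$M, Sigma = tr$Sigma, lam = tr$lam,
                            theta = tr$theta, Phi = tr$Phi, seed = tr$seed),
                       paths[4], digits = NA, auto_unbox = TRUE)
  invisible(paths)
}
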