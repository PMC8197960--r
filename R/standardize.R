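#' Stratified mortality data
#'
#' Container for one city-and-sex stratum of the input data: deaths by area,
#' 5-year age group and cause, and person-years by area and age group
#' (summed over the study period).
#'
#' @param city,sex labels.
#' @param deaths integer array `[area, age_group, cause]` with dimnames.
#' @param population numeric matrix `[area, age_group]` of person-years.
#' @return object of class `stratified_mortality`.
#' @export
stratified_mortality <- function(city, sex, deaths, population) {
  stop_if_not(length(dim(deaths)) == 3L, "`deaths` must be a 3-d array")
  stop_if_not(is.matrix(population), "`population` must be a matrix")
  dn <- dimnames(deaths)
  stop_if_not(!is.null(dn) && !any(vapply(dn, is.null, TRUE)),
              "`deaths` needs full dimnames (area, age_group, cause)")
  stop_if_not(identical(dim(deaths)[1:2], dim(population)),
              "deaths and population disagree on areas/age groups",
              class = "mortmap_invalid_input")
  stop_if_not(all(deaths >= 0) && all(population >= 0),
              "counts and person-years must be non-negative",
              class = "mortmap_invalid_input")
  zero_pop <- population == 0
  if (any(zero_pop)) {
    d2 <- apply(deaths, c(1, 2), sum)
    stop_if_not(all(d2[zero_pop] == 0),
                "deaths recorded in strata with zero person-years",
                class = "mortmap_inconsistency")
  }
  structure(list(city = city, sex = sex,
                 area_ids = dn[[1]], age_groups = dn[[2]], causes = dn[[3]],
                 deaths = deaths, population = population),
            class = "stratified_mortality")
}

#' @export
print.stratified_mortality <- function(x, ...) {
  cat("stratified_mortality:", x$city, "/", x$sex, "-",
      length(x$area_ids), "areas,", length(x$age_groups), "age groups,",
      length(x$causes), "causes;", sum(x$deaths), "deaths,",
      format(sum(x$population), big.mark = ","), "person-years\n")
  invisible(x)
}

#' Expected deaths by internal indirect standardization
#'
#' Computes, for every cause, the city-wide age-specific reference rates
#' `r_aj = sum_i deaths[i,a,j] / sum_i population[i,a]` and applies them to
#' each area's age structure: `E_ij = sum_a population[i,a] * r_aj`. Observed
#' deaths are summed over age. Because the reference is internal, the
#' expected counts satisfy `sum_i E_ij = sum_i O_ij` for every cause.
#' Age bands with zero city-wide person-years contribute nothing.
#'
#' @param data a [stratified_mortality].
#' @return object of class `mortality_matrices` with fields `O` and `E`
#'   (`area x cause`), plus labels.
#' @export
expected_counts <- function(data) {
  stop_if_not(inherits(data, "stratified_mortality"),
              "`data` must be a stratified_mortality")
  pop_a <- colSums(data$population)                  # person-years per age band
  stop_if_not(any(pop_a > 0), "all person-years are zero",
              class = "mortmap_invalid_input")
  deaths_aj <- apply(data$deaths, c(2, 3), sum)      # age x cause
  rates <- deaths_aj / ifelse(pop_a > 0, pop_a, 1)   # zero-pop bands: rate 0
  rates[pop_a == 0, ] <- 0
  E <- data$population %*% rates                     # area x cause
  O <- apply(data$deaths, c(1, 3), sum)
  dimnames(E) <- dimnames(O) <- list(data$area_ids, data$causes)
  mortality_matrices(O, E, city = data$city, sex = data$sex)
}

#' Observed/expected mortality matrices
#'
#' @param O,E `area x cause` matrices of observed and expected deaths with
#'   matching dimnames.
#' @param city,sex optional labels carried along.
#' @return object of class `mortality_matrices`.
#' @export
mortality_matrices <- function(O, E, city = NA_character_, sex = NA_character_) {
  stop_if_not(is.matrix(O) && is.matrix(E) && identical(dim(O), dim(E)),
              "O and E must be matrices of equal dimension",
              class = "mortmap_invalid_input")
  stop_if_not(all(O >= 0) && all(E >= 0), "O and E must be non-negative",
              class = "mortmap_invalid_input")
  structure(list(O = O, E = E, area_ids = rownames(O), causes = colnames(O),
                 city = city, sex = sex),
            class = "mortality_matrices")
}

#' @export
print.mortality_matrices <- function(x, ...) {
  cat("mortality_matrices:", nrow(x$O), "areas x", ncol(x$O), "causes;",
      sum(x$O), "observed deaths\n")
  invisible(x)
}

#' Raw standardized mortality ratios
#'
#' `SMR_ij = 100 * O_ij / E_ij`. Cells with `E_ij = 0` cannot be
#' standardized and are returned as `NA` (flagged missing, not zero).
#'
#' @param mat a [mortality_matrices].
#' @return `area x cause` matrix of raw SMRs.
#' @export
raw_smr <- function(mat) {
  stop_if_not(inherits(mat, "mortality_matrices"),
              "`mat` must be a mortality_matrices")
  s <- 100 * mat$O / mat$E
  s[mat$E == 0] <- NA_real_
  s
}

#' Read stratified mortality data from long-format CSV files
#'
#' `deaths_csv` columns: `city, sex, area_id, age_group, cause, deaths`;
#' `population_csv` columns: `city, sex, area_id, age_group, person_years`.
#' One city and sex per call; missing strata count as zero.
#'
#' @param deaths_csv,population_csv file paths.
#' @param city,sex stratum to extract (defaults: the single one present).
#' @return a [stratified_mortality].
#' @export
read_stratified_csv <- function(deaths_csv, population_csv,
                                city = NULL, sex = NULL) {
  d <- read.csv(deaths_csv, check.names = FALSE)
  p <- read.csv(population_csv, check.names = FALSE)
  need_d <- c("city", "sex", "area_id", "age_group", "cause", "deaths")
  need_p <- c("city", "sex", "area_id", "age_group", "person_years")
  stop_if_not(all(need_d %in% names(d)), "deaths CSV lacks required columns",
              class = "mortmap_invalid_input")
  stop_if_not(all(need_p %in% names(p)), "population CSV lacks required columns",
              class = "mortmap_invalid_input")
  if (is.null(city)) city <- unique(p$city)
  if (is.null(sex)) sex <- unique(p$sex)
  stop_if_not(length(city) == 1 && length(sex) == 1,
              "specify `city` and `sex` when files hold several strata",
              class = "mortmap_invalid_input")
  d <- d[d$city == city & d$sex == sex, ]
  p <- p[p$city == city & p$sex == sex, ]
  stop_if_not(nrow(p) > 0, "no population rows for this city/sex",
              class = "mortmap_invalid_input")
  areas <- sort(unique(p$area_id))
  ages <- sort(unique(p$age_group))
  causes <- sort(unique(d$cause))
  pop <- matrix(0, length(areas), length(ages), dimnames = list(areas, ages))
  pop[cbind(match(p$area_id, areas), match(p$age_group, ages))] <- p$person_years
  deaths <- array(0L, c(length(areas), length(ages), length(causes)),
                  dimnames = list(areas, ages, causes))
  if (nrow(d)) {
    deaths[cbind(match(d$area_id, areas), match(d$age_group, ages),
                 match(d$cause, causes))] <- as.integer(d$deaths)
  }
  stratified_mortality(city, sex, deaths, pop)
}

#' Write observed/expected matrices as CSV
#'
#' One file per matrix, areas as rows (column `area_id`), causes as columns.
#'
#' @param mat a [mortality_matrices].
#' @param o_path,e_path output file paths.
#' @export
write_oe_csv <- function(mat, o_path, e_path) {
  for (nm in c("O", "E")) {
    df <- data.frame(area_id = mat$area_ids, mat[[nm]], check.names = FALSE)
    write.csv(df, if (nm == "O") o_path else e_path, row.names = FALSE)
  }
  invisible(mat)
}
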