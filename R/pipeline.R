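#' Pipeline entry points
#'
#' These functions tie the stages into the reproducible per-city pipeline:
#' simulate synthetic cities, fit the M-model per city, summarize each fit,
#' and aggregate across cities. Each writes its products plus a JSON run
#' manifest (`manifest.json`: command, configuration snapshot, seeds, input
#' hashes, timestamps, convergence flag) into its output directory. A thin
#' command-line wrapper over these functions ships in
#' `inst/scripts/mortmap-cli.R`.
#'
#' @name pipeline
NULL

write_manifest <- function(dir, command, config, extra = list()) {
  files <- setdiff(list.files(dir, recursive = TRUE), "manifest.json")
  hashes <- vapply(files, function(f)
    unname(tools::md5sum(file.path(dir, f))), "")
  m <- c(list(command = command, config = config,
              files = as.list(hashes),
              r_version = as.character(getRversion()),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
         extra)
  jsonlite::write_json(m, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(m)
}

read_config_file <- function(path) {
  stop_if_not(file.exists(path), "config file not found",
              class = "mortmap_invalid_input")
  if (grepl("\\.ya?ml$", path)) {
    stop_if_not(requireNamespace("yaml", quietly = TRUE),
                "yaml package required for YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' @rdname pipeline
#' @param config a [synthetic_config], or the path of a JSON/YAML file whose
#'   keys mirror its arguments.
#' @param out output directory.
#' @return `run_simulate`: invisibly, the per-city output directories.
#' @export
run_simulate <- function(config, out) {
  if (is.character(config)) config <- do.call(synthetic_config,
                                              read_config_file(config))
  stop_if_not(inherits(config, "synthetic_config"), "invalid config")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stop_if_not(dir.exists(out), "cannot create output directory",
              class = "mortmap_invalid_input")
  cities <- generate_multicity(config)
  dirs <- character(length(cities))
  for (i in seq_along(cities)) {
    dirs[i] <- file.path(out, sprintf("city%02d", i))
    write_city_csv(cities[[i]], dirs[i])
  }
  write_manifest(out, "simulate", unclass(config)[setdiff(names(config), "rates")],
                 list(n_cities = length(cities)))
  invisible(dirs)
}

#' @rdname pipeline
#' @param city_dir directory holding `deaths.csv`, `population.csv` and
#'   `edges.txt` (as written by `run_simulate`).
#' @param fit_config an [mmodel_config] or config file path.
#' @param force write summary products even when convergence fails.
#' @return `run_fit`: invisibly, the fitted [mmodel].
#' @export
run_fit <- function(city_dir, out, fit_config = mmodel_config(),
                    force = FALSE) {
  if (is.character(fit_config)) fit_config <- do.call(mmodel_config,
                                                      read_config_file(fit_config))
  data <- read_stratified_csv(file.path(city_dir, "deaths.csv"),
                              file.path(city_dir, "population.csv"))
  graph <- graph_from_edgelist(file.path(city_dir, "edges.txt"),
                               area_ids = data$area_ids)
  oe <- expected_counts(data)
  fit <- mmodel(oe, graph, fit_config)
  conv <- check_convergence(fit)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(passed = conv$passed,
                            max_rhat = max(conv$rhat, na.rm = TRUE),
                            min_ess = min(conv$ess, na.rm = TRUE),
                            offenders = conv$offenders),
                       file.path(out, "convergence.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!conv$passed && !force) {
    write_manifest(out, "fit", unclass(fit_config), list(converged = FALSE))
    stop_if_not(FALSE, "convergence failed; rerun with longer chains or force = TRUE",
                class = "mortmap_convergence_failure")
  }
  write_oe_csv(oe, file.path(out, "observed.csv"), file.path(out, "expected.csv"))
  for (grp in c("theta", "Sigma", "lam", "sigma")) {
    dr <- lapply(seq_along(fit$chains), function(ch) {
      m <- fit$chains[[ch]][[grp]]
      data.frame(chain = ch, iteration = seq_len(nrow(m)), m,
                 check.names = FALSE)
    })
    write.csv(do.call(rbind, dr), file.path(out, paste0("draws_", grp, ".csv")),
              row.names = FALSE)
  }
  write_manifest(out, "fit", unclass(fit_config),
                 list(converged = conv$passed, seeds = fit$chain_seeds))
  invisible(fit)
}

#' @rdname pipeline
#' @param fit an [mmodel] (or a fit output directory containing
#'   `draws_theta.csv`).
#' @return `run_summarize`: invisibly, the [smr_summary].
#' @export
run_summarize <- function(fit, out) {
  if (is.character(fit)) {
    path <- file.path(fit, "draws_theta.csv")
    stop_if_not(file.exists(path), "no draws found in directory",
                class = "mortmap_invalid_input")
    dr <- read.csv(path, check.names = FALSE)
    th <- as.matrix(dr[, -(1:2), drop = FALSE])
    labs <- sub("^theta\\[(.*)\\]$", "\\1", colnames(th))
    areas <- unique(sub(",.*$", "", labs))
    causes <- unique(sub("^.*,", "", labs))
    fit <- list(theta = th, n_areas = length(areas), area_ids = areas,
                causes = causes)
  }
  sm <- summarize_draws(fit)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_summary_csv(sm, file.path(out, "smr_summary.csv"))
  sds <- logsmr_sd(sm)
  write.csv(data.frame(cause = names(sds), logsmr_sd = sds),
            file.path(out, "variability.csv"), row.names = FALSE)
  cm <- pairwise_logsmr_correlations(sm)
  write.csv(data.frame(cause = rownames(cm), cm, check.names = FALSE),
            file.path(out, "correlations.csv"), row.names = FALSE)
  write_manifest(out, "summarize", list())
  invisible(sm)
}

#' @rdname pipeline
#' @param summary_dirs named character vector (city -> summarize output dir).
#' @return `run_aggregate`: invisibly, a list with the cross-city
#'   [variability_table], [correlation_summary] and [anova_variability()]
#'   result.
#' @export
run_aggregate <- function(summary_dirs, out) {
  stop_if_not(length(summary_dirs) >= 2, "at least 2 cities are required")
  if (is.null(names(summary_dirs)))
    names(summary_dirs) <- sprintf("city%02d", seq_along(summary_dirs))
  sds <- lapply(summary_dirs, function(d) {
    v <- read.csv(file.path(d, "variability.csv"))
    setNames(v$logsmr_sd, v$cause)
  })
  cause_sets <- lapply(sds, names)
  stop_if_not(all(vapply(cause_sets, identical, TRUE, cause_sets[[1]])),
              paste("inconsistent cause lists in:",
                    paste(names(summary_dirs)[!vapply(cause_sets, identical,
                                                      TRUE, cause_sets[[1]])],
                          collapse = ", ")),
              class = "mortmap_invalid_input")
  vt <- variability_table(sds)
  cors <- lapply(summary_dirs, function(d) {
    m <- read.csv(file.path(d, "correlations.csv"), check.names = FALSE)
    cm <- as.matrix(m[, -1, drop = FALSE]); rownames(cm) <- m$cause
    cm
  })
  cs <- aggregate_correlations(cors)
  an <- anova_variability(vt)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write.csv(data.frame(city = rownames(vt$values), vt$values,
                       Mean = vt$row_means, check.names = FALSE),
            file.path(out, "variability_table.csv"), row.names = FALSE)
  long <- which(upper.tri(cs$mean_matrix), arr.ind = TRUE)
  write.csv(data.frame(cause_a = rownames(cs$mean_matrix)[long[, 1]],
                       cause_b = colnames(cs$mean_matrix)[long[, 2]],
                       mean = cs$mean_matrix[long],
                       lo = cs$lo[long], hi = cs$hi[long]),
            file.path(out, "correlation_summary.csv"), row.names = FALSE)
  grDevices::pdf(file.path(out, "correlation_plot.pdf"), width = 7, height = 7)
  plot(cs)
  grDevices::dev.off()
  write_manifest(out, "aggregate", list(n_cities = length(summary_dirs)))
  invisible(list(variability = vt, correlations = cs, anova = an))
}

#' Corrplot-style display of a correlation summary
#'
#' Upper triangle: cross-city mean correlation (disc area proportional to
#' |r|, blue positive / red negative). Lower triangle: the 2.5-97.5%
#' cross-city interval printed as text.
#'
#' @param x a [correlation_summary].
#' @param ... unused.
#' @export
plot.correlation_summary <- function(x, ...) {
  m <- x$mean_matrix
  J <- nrow(m)
  graphics::plot(NA, xlim = c(0.5, J + 0.5), ylim = c(0.5, J + 0.5),
                 axes = FALSE, xlab = "", ylab = "", asp = 1)
  graphics::axis(1, at = seq_len(J), labels = colnames(m), las = 2, cex.axis = 0.7)
  graphics::axis(2, at = seq_len(J), labels = rev(rownames(m)), las = 1, cex.axis = 0.7)
  for (i in seq_len(J)) for (j in seq_len(J)) {
    yy <- J + 1 - i
    if (j > i) {
      r <- m[i, j]
      graphics::symbols(j, yy, circles = sqrt(abs(r)) * 0.45, inches = FALSE,
                        add = TRUE, bg = if (is.na(r)) "grey" else
                          if (r > 0) "steelblue" else "firebrick", fg = NA)
    } else if (j < i) {
      graphics::text(j, yy, sprintf("%.2f\n%.2f", x$hi[i, j], x$lo[i, j]),
                     cex = 0.5)
    }
  }
  invisible(x)
}
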