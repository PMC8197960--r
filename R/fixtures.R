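#' Published spatial-variability tables
#'
#' Loads the package's copies of the published city-by-cause tables of
#' log-SMR standard deviations for 26 Spanish cities (15 causes for men, 11
#' for women, 1996-2015). Cell values are the published 2-decimal numbers;
#' the mean row and column are always recomputed from the cells, while the
#' margins as originally printed are kept alongside (`printed_margins`) for
#' comparison, since published margins were rounded from unrounded inputs.
#'
#' @return list with elements `men` and `women`, each a
#'   [variability_table].
#' @export
tables_fixture <- function() {
  load1 <- function(file) {
    path <- system.file("extdata", file, package = "mortmap")
    stop_if_not(nzchar(path), paste("missing fixture", file))
    raw <- read.csv(path, check.names = FALSE)
    cells <- raw[raw$city != "Mean", setdiff(names(raw), c("city", "Mean"))]
    cells <- as.matrix(cells)
    rownames(cells) <- raw$city[raw$city != "Mean"]
    printed <- list(
      row = setNames(raw$Mean[raw$city != "Mean"], rownames(cells)),
      col = setNames(as.numeric(raw[raw$city == "Mean",
                                    colnames(cells)]), colnames(cells)))
    variability_table(cells, printed_margins = printed)
  }
  list(men = load1("variability_men.csv"),
       women = load1("variability_women.csv"))
}
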