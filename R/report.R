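#' Box-whisker panel in the cohort-comparison style
#'
#' Box from the 25th to 75th percentile, line at the median, mean marked
#' with "+", whiskers at configurable percentiles: 10-90 for rate and
#' length cohorts, 5-95 for islet-volume cohorts.
#'
#' @param data data.frame with a grouping column and a value column.
#' @param group,value column names (strings).
#' @param whiskers length-2 probabilities (default `c(0.10, 0.90)`).
#' @param ylab axis label.
#' @return a ggplot object.
#' @export
plot_box_whisker <- function(data, group, value, whiskers = c(0.10, 0.90),
                             ylab = value) {
  qs <- function(v) {
    q <- stats::quantile(v, c(whiskers[1], 0.25, 0.5, 0.75, whiskers[2]),
                         names = FALSE)
    data.frame(ymin = q[1], lower = q[2], middle = q[3], upper = q[4],
               ymax = q[5])
  }
  ggplot2::ggplot(data, ggplot2::aes(x = .data[[group]],
                                     y = .data[[value]])) +
    ggplot2::stat_summary(fun.data = qs, geom = "boxplot",
                          width = 0.55, fill = "grey90") +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 3, size = 2.5) +
    ggplot2::labs(x = NULL, y = ylab) +
    ggplot2::theme_classic()
}

#' Assemble the figure-parity report for one pipeline run
#'
#' Renders the standard panels from the pipeline's CSV/tibble outputs —
#' clustering hull volume vs time, morphology box-whiskers (area,
#' circularity, solidity), filopodium rate and maximal-length box-whiskers
#' (10-90% whiskers), and islet-volume boxes (5-95% whiskers) — and writes
#' a markdown report linking the panel PNGs. Missing inputs are listed in
#' the report and replaced by a placeholder note; the report is still
#' produced. Output is deterministic for identical inputs.
#'
#' @param out_dir output directory.
#' @param clustering tibble from [clustering_series()] (or NULL).
#' @param morphology tibble from [morphology_table()] (or NULL).
#' @param filo_rates data.frame `group`, `rate_um_min` pooled over
#'   filopodia (or NULL).
#' @param filo_lengths data.frame `group`, `max_length_um` (or NULL).
#' @param islets tibble from [islet_report()] with `group`, `volume_um3`
#'   (or NULL).
#' @return path of the markdown report, invisibly; the report lists every
#'   panel written and every input that was missing.
#' @export
figure_parity_report <- function(out_dir, clustering = NULL,
                                 morphology = NULL, filo_rates = NULL,
                                 filo_lengths = NULL, islets = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lines <- c("# Islet morphogenesis analysis report", "")
  missing <- character(0)
  save_panel <- function(plot, name) {
    path <- file.path(out_dir, name)
    suppressMessages(ggplot2::ggsave(path, plot, width = 4.5, height = 3.2,
                                     dpi = 150))
    name
  }
  if (!is.null(clustering) && nrow(clustering) > 0) {
    f <- save_panel(plot_clustering_series(clustering), "clustering.png")
    lines <- c(lines, "## Cell clustering", "",
               "Convex-hull volume of tracked cell centers over time.",
               paste0("![clustering](", f, ")"), "")
  } else missing <- c(missing, "clustering series")
  if (!is.null(morphology) && nrow(morphology) > 0) {
    for (v in c("area_um2", "circularity", "solidity")) {
      f <- save_panel(plot_box_whisker(morphology, "group", v,
                                       whiskers = c(0.10, 0.90), ylab = v),
                      paste0("morphology_", v, ".png"))
      lines <- c(lines, paste0("![", v, "](", f, ")"))
    }
    lines <- c(lines, "")
  } else missing <- c(missing, "morphology table")
  if (!is.null(filo_rates) && nrow(filo_rates) > 0) {
    f <- save_panel(plot_box_whisker(filo_rates, "group", "rate_um_min",
                                     ylab = "rate (um/min)"),
                    "filopodia_rates.png")
    lines <- c(lines, "## Filopodia kinetics", "",
               paste0("![rates](", f, ")"))
  } else missing <- c(missing, "filopodium rates")
  if (!is.null(filo_lengths) && nrow(filo_lengths) > 0) {
    f <- save_panel(plot_box_whisker(filo_lengths, "group", "max_length_um",
                                     ylab = "maximal length (um)"),
                    "filopodia_lengths.png")
    lines <- c(lines, paste0("![lengths](", f, ")"), "")
  } else missing <- c(missing, "filopodium lengths")
  if (!is.null(islets) && nrow(islets) > 0) {
    f <- save_panel(plot_box_whisker(islets, "group", "volume_um3",
                                     whiskers = c(0.05, 0.95),
                                     ylab = "islet volume (um^3)"),
                    "islet_volumes.png")
    lines <- c(lines, "## Secondary islet volumes", "",
               paste0("![islets](", f, ")"), "")
  } else missing <- c(missing, "islet volume table")
  if (length(missing))
    lines <- c(lines, "## Missing inputs", "",
               paste0("- ", missing, ": no data supplied; panel omitted"))
  path <- file.path(out_dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}
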