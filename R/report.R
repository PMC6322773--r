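#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
print.weightape_report <- function(x, ...) {
  cat("<weightape_report> ", x$n_records, " records, ",
    length(x$methods), " methods\n",
    sep = ""
  )
  cat("Acceptability thresholds: p10 >= ", x$thresholds[["p10_min"]],
    "%, p20 >= ", x$thresholds[["p20_min"]], "%\n\n",
    sep = ""
  )
  print(as.data.frame(x$overall), digits = 3, row.names = FALSE)
  if (any(x$exclusions$excluded > 0)) {
    cat("\nExcluded (no estimate):\n")
    print(as.data.frame(x$exclusions), row.names = FALSE)
  }
  cat("\n", nrow(x$subgroups), " subgroup cells across ",
    length(unique(x$subgroups$dimension)), " dimensions\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy a validation report into one row per summary cell
#'
#' @param x A `weightape_report`.
#' @param ... Unused.
#' @return Tibble with the overall rows (`dimension = "overall"`) stacked
#'   on the subgroup cells: `dimension, bin, method, n, mpe, sd, loa_low,
#'   loa_high, rmspe, ape_sd, p10, p20, acceptable`.
#' @export
tidy.weightape_report <- function(x, ...) {
  overall <- dplyr::mutate(x$overall,
    dimension = "overall", bin = "overall", .before = 1
  )
  dplyr::bind_rows(overall, x$subgroups)
}

#' One-row-per-method overview of a validation report
#'
#' @param x A `weightape_report`.
#' @param ... Unused.
#' @return The overall summary joined with exclusion counts.
#' @export
glance.weightape_report <- function(x, ...) {
  dplyr::left_join(x$overall, x$exclusions, by = "method")
}

#' Forest-plot-ready bias/precision table
#'
#' One row per method: MPE with its Bland–Altman 95% limits of agreement —
#' the content of the classic bias/precision forest plot.
#'
#' @param report A `weightape_report`.
#' @return Tibble `method, mpe, loa_low, loa_high`.
#' @export
forest_data <- function(report) {
  stopifnot(inherits(report, "weightape_report"))
  report$overall[, c("method", "mpe", "loa_low", "loa_high")]
}

#' Plot a validation report
#'
#' `type = "forest"` draws the bias/precision forest plot (MPE point,
#' LOA whiskers, the ±5% acceptable-bias band and ±20% LOA guides);
#' `type = "accuracy"` draws per-method p10/p20 bars with the 70%/95%
#' acceptability lines.
#'
#' @param object A `weightape_report`.
#' @param type `"forest"` or `"accuracy"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.weightape_report <- function(object, type = c("forest", "accuracy"),
                                      ...) {
  type <- match.arg(type)
  if (type == "forest") {
    fd <- forest_data(object)
    ggplot2::ggplot(
      fd,
      ggplot2::aes(x = .data$mpe, y = stats::reorder(
        .data$method, .data$mpe
      ))
    ) +
      ggplot2::annotate("rect",
        xmin = -5, xmax = 5, ymin = -Inf, ymax = Inf,
        alpha = 0.15, fill = "darkgreen"
      ) +
      ggplot2::geom_vline(
        xintercept = c(-20, 20), linetype = "dashed", colour = "grey40"
      ) +
      ggplot2::geom_errorbarh(
        ggplot2::aes(xmin = .data$loa_low, xmax = .data$loa_high),
        height = 0.2
      ) +
      ggplot2::geom_point(size = 2) +
      ggplot2::labs(
        x = "Mean percentage error (%), whiskers = 95% LOA", y = NULL,
        title = "Bias and precision by weight-estimation method"
      )
  } else {
    acc <- tidyr::pivot_longer(
      object$overall[, c("method", "p10", "p20")],
      cols = c("p10", "p20"), names_to = "metric", values_to = "value"
    )
    thr <- tibble::tibble(
      metric = c("p10", "p20"),
      value = unname(object$thresholds)
    )
    ggplot2::ggplot(
      acc, ggplot2::aes(x = .data$method, y = .data$value)
    ) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::geom_hline(
        data = thr, ggplot2::aes(yintercept = .data$value),
        linetype = "dashed"
      ) +
      ggplot2::facet_wrap(~metric) +
      ggplot2::labs(
        x = NULL, y = "% of estimates within threshold",
        title = "Overall accuracy by method"
      ) +
      ggplot2::theme(
        axis.text.x = ggplot2::element_text(angle = 30, hjust = 1)
      )
  }
}

#' Write a validation report to disk
#'
#' Emits `summary.csv` (the tidy cell table), `comparisons.csv` when
#' comparisons are supplied, `forest.csv` (bias/precision table) and
#' `report.json` carrying everything plus a provenance block (config hash,
#' seed, package version) sufficient to reproduce the run.
#'
#' @param report A `weightape_report`.
#' @param dir Output directory (created if needed).
#' @param comparisons Optional tibble from [compare_all()].
#' @param seed Seed to record in provenance.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, comparisons = NULL, seed = NULL) {
  stopifnot(inherits(report, "weightape_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cells <- tidy(report)
  readr::write_csv(cells, file.path(dir, "summary.csv"))
  readr::write_csv(forest_data(report), file.path(dir, "forest.csv"))
  if (!is.null(comparisons)) {
    readr::write_csv(comparisons, file.path(dir, "comparisons.csv"))
  }
  payload <- list(
    provenance = list(
      package = "weightape",
      version = as.character(utils::packageVersion("weightape")),
      seed = seed,
      config_hash = rlang::hash(list(
        thresholds = report$thresholds, methods = report$methods
      )),
      n_records = report$n_records
    ),
    thresholds = as.list(report$thresholds),
    overall = report$overall,
    subgroups = report$subgroups,
    exclusions = report$exclusions,
    comparisons = comparisons
  )
  jsonlite::write_json(
    payload, file.path(dir, "report.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = 10, null = "null"
  )
  invisible(dir)
}
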