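#' Read / write cohort files
#'
#' Cohorts are comma-separated UTF-8 text with a header row and `.` decimal
#' marks, matching the distribution format of open anthropometric survey
#' datasets. Required columns: `country, year, sex, age_months, weight_kg,
#' height_cm, mac_cm`; optional pre-computed z-scores `whz, haz, waz` are
#' kept when present, as are any other columns.
#'
#' @param path File path.
#' @return `read_cohort()` returns a tibble with an `id` column added when
#'   absent.
#' @export
read_cohort <- function(path) {
  need <- c(
    "country", "year", "sex", "age_months", "weight_kg", "height_cm",
    "mac_cm"
  )
  data <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    stop(
      "cohort file is missing columns: ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(data$weight_kg <= 0 | data$height_cm <= 0 | data$mac_cm <= 0,
    na.rm = TRUE
  )) {
    stop("weight, height and MAC must all be positive", call. = FALSE)
  }
  if (!"id" %in% names(data)) data$id <- seq_len(nrow(data))
  tibble::as_tibble(data)
}

#' @rdname read_cohort
#' @param data Cohort tibble to write.
#' @export
write_cohort <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' Country-to-region lookup
#'
#' Reads the editable country → survey-region mapping (six regions:
#' Africa, Americas, South-East Asia, Eastern Europe, Middle East, Western
#' Pacific). The shipped file covers the countries the synthetic generator
#' emits; replace it to map a real survey's country list.
#'
#' @param path Lookup CSV with `country` and `region` columns; defaults to
#'   the file shipped with the package.
#' @return Tibble `country, region`.
#' @export
region_lookup <- function(path = system.file("extdata", "regions.csv",
                            package = "weightape"
                          )) {
  readr::read_csv(path, show_col_types = FALSE, comment = "#")
}

#' Attach regions to a cohort by country
#'
#' Countries absent from the lookup fall into an `"unassigned"` stratum
#' rather than erroring.
#'
#' @param data Cohort with a `country` column.
#' @param lookup Region lookup table; see [region_lookup()].
#' @return `data` with a `region` column (existing values overwritten).
#' @export
assign_region <- function(data, lookup = region_lookup()) {
  idx <- match(data$country, lookup$country)
  data$region <- ifelse(is.na(idx), "unassigned", lookup$region[idx])
  data
}
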