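#' LMS z-score from a measurement and reference parameters
#'
#' Converts a raw anthropometric measurement to a z-score under the LMS
#' (Box-Cox power, median, coefficient of variation) growth-reference
#' parameterisation:
#' \deqn{z = \frac{(X/M)^L - 1}{L S}} for \eqn{L \ne 0}, and
#' \eqn{z = \log(X/M)/S} when \eqn{L = 0}.
#'
#' For weight-based indicators, survey convention restricts extreme z-scores
#' so that the scale beyond 3 SD is linear in the measurement:
#' above \eqn{+3}, \eqn{z' = 3 + (X - SD3)/(SD3 - SD2)} where \eqn{SDk} is
#' the measurement at z = k, and symmetrically below \eqn{-3}. Enable with
#' `restrict = TRUE` (the pipeline does this for weight-for-age,
#' weight-for-height and BMI-for-age).
#'
#' @param value Measurement in the indicator's units (kg, cm or kg·m⁻²).
#'   Must be positive.
#' @param l,m,s LMS parameters; `m` and `s` must be positive. Vectorised and
#'   recycled against `value`.
#' @param restrict Apply the restricted adjustment beyond |z| > 3
#'   (default `FALSE`).
#' @return Numeric vector of z-scores.
#' @seealso [lms_value()] for the inverse, [lms_interpolate()] to obtain
#'   (L, M, S) from a reference table.
#' @examples
#' lms_zscore(11, l = 1, m = 10, s = 0.1) # 1
#' @export
lms_zscore <- function(value, l, m, s, restrict = FALSE) {
  if (any(!is.finite(value)) || any(value <= 0)) {
    stop("`value` must be positive and finite", call. = FALSE)
  }
  if (any(m <= 0) || any(s <= 0)) {
    stop("LMS parameters `m` and `s` must be positive", call. = FALSE)
  }
  n <- max(length(value), length(l), length(m), length(s))
  value <- rep_len(value, n)
  l <- rep_len(l, n)
  m <- rep_len(m, n)
  s <- rep_len(s, n)
  z <- ifelse(
    abs(l) < 1e-12,
    log(value / m) / s,
    ((value / m)^l - 1) / (l * s)
  )
  if (restrict) {
    hi <- !is.na(z) & z > 3
    lo <- !is.na(z) & z < -3
    if (any(hi)) {
      sd3 <- lms_value(3, l[hi], m[hi], s[hi])
      sd2 <- lms_value(2, l[hi], m[hi], s[hi])
      z[hi] <- 3 + (value[hi] - sd3) / (sd3 - sd2)
    }
    if (any(lo)) {
      sd3n <- lms_value(-3, l[lo], m[lo], s[lo])
      sd2n <- lms_value(-2, l[lo], m[lo], s[lo])
      z[lo] <- -3 + (value[lo] - sd3n) / (sd3n - sd2n)
    }
  }
  z
}

#' Measurement at a given z-score (inverse LMS transform)
#'
#' Exact inverse of the unrestricted [lms_zscore()]:
#' \eqn{X = M (1 + L S z)^{1/L}}, or \eqn{X = M e^{S z}} when \eqn{L = 0}.
#'
#' @inheritParams lms_zscore
#' @param z z-score; must satisfy \eqn{1 + L S z > 0}.
#' @return Measurement in indicator units.
#' @export
lms_value <- function(z, l, m, s) {
  if (any(m <= 0) || any(s <= 0)) {
    stop("LMS parameters `m` and `s` must be positive", call. = FALSE)
  }
  n <- max(length(z), length(l), length(m), length(s))
  z <- rep_len(z, n)
  l <- rep_len(l, n)
  m <- rep_len(m, n)
  s <- rep_len(s, n)
  base <- 1 + l * s * z
  linear <- abs(l) >= 1e-12
  if (any(base[linear] <= 0)) {
    stop("z outside the representable range: 1 + L*S*z must be positive",
      call. = FALSE
    )
  }
  ifelse(linear, m * base^(1 / l), m * exp(s * z))
}

.lms_indicators <- c(
  "bmi-for-age", "weight-for-age", "height-for-age", "weight-for-height"
)
.weight_based <- c("bmi-for-age", "weight-for-age", "weight-for-height")

#' Validate an LMS reference table
#'
#' An LMS table is a data frame with columns `indicator` (one of
#' `"bmi-for-age"`, `"weight-for-age"`, `"height-for-age"`,
#' `"weight-for-height"`), `sex` (`"male"`/`"female"`), `axis_value`
#' (age in completed months for age-based indicators, length in cm for
#' weight-for-height), `l`, `m`, `s`. Within each (indicator, sex) grid the
#' axis must be strictly increasing and `m`, `s` positive.
#'
#' @param table Data frame to validate.
#' @return The table, invisibly, as a tibble; errors describe the offending
#'   grid.
#' @export
validate_lms_table <- function(table) {
  need <- c("indicator", "sex", "axis_value", "l", "m", "s")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols) > 0) {
    stop(
      "LMS table is missing columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  table <- tibble::as_tibble(table)
  bad_ind <- setdiff(unique(table$indicator), .lms_indicators)
  if (length(bad_ind) > 0) {
    stop("unknown indicator(s): ", paste(bad_ind, collapse = ", "),
      call. = FALSE
    )
  }
  if (!all(table$sex %in% c("male", "female"))) {
    stop("`sex` must be 'male' or 'female'", call. = FALSE)
  }
  if (nrow(table) == 0) stop("LMS table is empty", call. = FALSE)
  if (any(table$m <= 0) || any(table$s <= 0)) {
    stop("LMS table requires m > 0 and s > 0 in every row", call. = FALSE)
  }
  check <- table |>
    dplyr::group_by(.data$indicator, .data$sex) |>
    dplyr::summarise(
      ok = all(diff(.data$axis_value) > 0),
      .groups = "drop"
    )
  if (any(!check$ok)) {
    bad <- check[!check$ok, ]
    stop(
      "axis_value not strictly increasing for ",
      paste(bad$indicator, bad$sex, sep = "/", collapse = ", "),
      call. = FALSE
    )
  }
  invisible(table)
}

#' Interpolate (L, M, S) from a reference table
#'
#' Linear interpolation of each of L, M and S between the bracketing grid
#' rows of one (indicator, sex) grid; an exact grid hit returns that row.
#'
#' @param table LMS table (see [validate_lms_table()]).
#' @param indicator One of the four supported indicators.
#' @param sex `"male"` or `"female"`; vectorised with `at`.
#' @param at Axis value(s): age in completed months, or length in cm for
#'   weight-for-height. Must lie within the grid range.
#' @return A tibble with columns `l`, `m`, `s`, one row per `at`.
#' @export
lms_interpolate <- function(table, indicator, sex, at) {
  indicator <- match.arg(indicator, .lms_indicators)
  n <- max(length(sex), length(at))
  sex <- rep_len(sex, n)
  at <- rep_len(at, n)
  out <- tibble::tibble(l = NA_real_, m = NA_real_, s = NA_real_, .rows = n)
  for (sx in unique(sex)) {
    grid <- table[table$indicator == indicator & table$sex == sx, ]
    if (nrow(grid) == 0) {
      stop("no LMS grid for indicator '", indicator, "', sex '", sx, "'",
        call. = FALSE
      )
    }
    grid <- grid[order(grid$axis_value), ]
    idx <- which(sex == sx)
    x <- at[idx]
    rng <- range(grid$axis_value)
    if (any(x < rng[1] | x > rng[2])) {
      stop(
        sprintf(
          "axis_value out of range for %s/%s: valid interval is [%g, %g]",
          indicator, sx, rng[1], rng[2]
        ),
        call. = FALSE
      )
    }
    out$l[idx] <- stats::approx(grid$axis_value, grid$l, xout = x)$y
    out$m[idx] <- stats::approx(grid$axis_value, grid$m, xout = x)$y
    out$s[idx] <- stats::approx(grid$axis_value, grid$s, xout = x)$y
  }
  out
}

#' Z-score an indicator against a reference table
#'
#' Convenience wrapper: interpolates (L, M, S) at `at` and applies
#' [lms_zscore()]. The restricted adjustment is applied by default for the
#' weight-based indicators, matching survey convention.
#'
#' @inheritParams lms_interpolate
#' @param value Measurement in the indicator's units.
#' @param restrict Apply the restricted |z| > 3 adjustment; default `TRUE`
#'   for weight-based indicators, `FALSE` for height-for-age.
#' @return Numeric vector of z-scores.
#' @export
reference_zscore <- function(table, indicator, value, sex, at,
                             restrict = indicator %in% .weight_based) {
  p <- lms_interpolate(table, indicator, sex, at)
  lms_zscore(value, p$l, p$m, p$s, restrict = restrict)
}

.growth_schemes <- list(
  bmi_for_age_5bin = list(
    labels = c("underweight", "thin", "normal", "overweight", "obese")
  ),
  wfh_3bin = list(
    labels = c("no wasting", "moderate wasting", "severe wasting")
  ),
  wfa_3bin = list(
    labels = c("normal weight", "moderately underweight",
               "severely underweight")
  ),
  hfa_3bin = list(
    labels = c("no stunting", "moderate stunting", "severe stunting")
  )
)

#' Classify a z-score into standard nutritional categories
#'
#' Two families of schemes are supported. `bmi_for_age_5bin` uses the
#' five habitus bins: Z ≤ −2.0 underweight; −2.0 < Z ≤ −1.4 thin;
#' −1.4 < Z < 1.4 normal; 1.4 ≤ Z < 2.0 overweight; Z ≥ 2.0 obese.
#' The three-bin schemes (`wfh_3bin`, `wfa_3bin`, `hfa_3bin`) use the WHO
#' malnutrition grades: Z ≥ −2.0 normal; −3.0 ≤ Z < −2.0 moderate;
#' Z < −3.0 severe, labelled wasting/underweight/stunting respectively.
#'
#' @param z Finite z-score(s).
#' @param scheme One of `"bmi_for_age_5bin"`, `"wfh_3bin"`, `"wfa_3bin"`,
#'   `"hfa_3bin"`.
#' @return A factor with the scheme's closed label set as levels.
#' @examples
#' classify_growth(c(-2.5, 0, 1.4), "bmi_for_age_5bin")
#' classify_growth(-2, "wfh_3bin") # "no wasting": -2.0 is inclusive
#' @export
classify_growth <- function(z, scheme = names(.growth_schemes)) {
  scheme <- match.arg(scheme)
  if (any(!is.finite(z))) stop("`z` must be finite", call. = FALSE)
  labs <- .growth_schemes[[scheme]]$labels
  if (scheme == "bmi_for_age_5bin") {
    lab <- ifelse(z <= -2, labs[1],
      ifelse(z <= -1.4, labs[2],
        ifelse(z < 1.4, labs[3],
          ifelse(z < 2, labs[4], labs[5])
        )
      )
    )
  } else {
    lab <- ifelse(z >= -2, labs[1], ifelse(z >= -3, labs[2], labs[3]))
  }
  factor(lab, levels = labs)
}

#' Read / write LMS reference tables as delimited text
#'
#' Column layout: `indicator, sex, axis_value, l, m, s`; UTF-8,
#' comma-separated, header row required.
#'
#' @param path File path.
#' @return `read_lms_table()` returns a validated tibble.
#' @export
read_lms_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  validate_lms_table(tab)
  tibble::as_tibble(tab)
}

#' @rdname read_lms_table
#' @param table LMS table to write.
#' @export
write_lms_table <- function(table, path) {
  validate_lms_table(table)
  readr::write_csv(table, path)
  invisible(path)
}
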