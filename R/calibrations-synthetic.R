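#' Synthetic (non-clinical) fixture calibrations
#'
#' Tape calibrations built from the synthetic growth reference so the whole
#' pipeline runs offline. Per-segment weights are median weight-for-length at
#' the segment midpoint; the PAWPER XL-MAC fixture spreads seven habitus
#' columns around the median using the reference's own LMS spread, with MAC
#' cut-offs placed by the package's MAC model at the habitus z boundaries.
#' The Ralston fixture scales its moderate and severe band tapes down from
#' the normal band.
#'
#' These are **not** the published clinical tapes: the clinical PAWPER
#' XL-MAC MAC cut-offs and segment weights are external artifacts to be
#' loaded with [read_calibration()]. Accuracy measured against fixtures
#' characterises the framework, not any marketed device.
#'
#' @param from,to,by Length coverage of the tape in cm (half-open segments
#'   `[from, to)` of width `by`).
#' @param reference LMS table used to derive median weights; defaults to
#'   [synthetic_reference()].
#' @return A `tape_calibration` object with
#'   `provenance = "synthetic-fixture"`.
#' @name synthetic_calibrations
NULL

.wfh_median_mixed <- function(reference, h) {
  m <- lms_interpolate(reference, "weight-for-height", "male", h)$m
  f <- lms_interpolate(reference, "weight-for-height", "female", h)$m
  (m + f) / 2
}

# age (months) at which the mixed-sex median height equals h
.age_at_height <- function(reference, h) {
  grid <- 0:66
  mm <- lms_interpolate(reference, "height-for-age", "male", grid)$m
  mf <- lms_interpolate(reference, "height-for-age", "female", grid)$m
  stats::approx((mm + mf) / 2, grid, xout = h, rule = 2)$y
}

#' @rdname synthetic_calibrations
#' @export
synthetic_pawper_calibration <- function(from = 55, to = 120, by = 2.5,
                                         reference = synthetic_reference()) {
  lower <- seq(from, to - by, by = by)
  upper <- lower + by
  mid <- (lower + upper) / 2
  med <- .wfh_median_mixed(reference, mid)
  # habitus columns at WHZ z = -3.3 ... 3.3; cut-offs at the z boundaries
  z_cols <- seq(-3.3, 3.3, by = 1.1)
  z_cuts <- seq(-2.75, 2.75, by = 1.1)
  l <- -0.35
  s <- 0.082
  col_factor <- (1 + l * s * z_cols)^(1 / l)
  age <- .age_at_height(reference, mid)
  cfg <- cohort_config()
  cutoffs <- lapply(seq_along(mid), function(i) {
    round(cfg$mac_intercept + cfg$mac_age_slope * (age[i] - 32.5) +
      cfg$mac_whz_slope * z_cuts, 1)
  })
  weights <- lapply(seq_along(mid), function(i) round(med[i] * col_factor, 1))
  pawper_calibration(
    data.frame(lower = lower, upper = upper),
    cutoffs = cutoffs, weights = weights,
    provenance = "synthetic-fixture"
  )
}

#' @rdname synthetic_calibrations
#' @param edition `"2007B"` or `"2011A"`; the two fixture editions differ by
#'   a fixed scale factor, emulating a recalibration between editions.
#' @export
synthetic_broselow_calibration <- function(edition = c("2007B", "2011A"),
                                           from = 50, to = 120, by = 5,
                                           reference = synthetic_reference()) {
  edition <- match.arg(edition)
  lower <- seq(from, to - by, by = by)
  upper <- lower + by
  mid <- (lower + upper) / 2
  scale <- if (edition == "2011A") 1.04 else 0.98
  w <- round(.wfh_median_mixed(reference, mid) * scale, 1)
  broselow_calibration(
    data.frame(lower = lower, upper = upper), w,
    edition = edition, provenance = "synthetic-fixture"
  )
}

#' @rdname synthetic_calibrations
#' @export
synthetic_ralston_calibration <- function(from = 50, to = 120, by = 5,
                                          reference = synthetic_reference()) {
  lower <- seq(from, to - by, by = by)
  upper <- lower + by
  mid <- (lower + upper) / 2
  med <- .wfh_median_mixed(reference, mid)
  band <- function(f, ed) {
    broselow_calibration(
      data.frame(lower = lower, upper = upper), round(med * f, 1),
      edition = ed, provenance = "synthetic-fixture"
    )
  }
  ralston_calibration(
    severe = band(0.78, "severe"),
    moderate = band(0.88, "moderate"),
    normal = band(1.00, "normal"),
    provenance = "synthetic-fixture"
  )
}

#' Default set of synthetic fixture calibrations
#'
#' @param reference LMS table; defaults to [synthetic_reference()].
#' @return Named list of four calibrations keyed by method id
#'   (`pawper_xl_mac`, `broselow_2007B`, `broselow_2011A`, `ralston`).
#' @export
synthetic_calibrations <- function(reference = synthetic_reference()) {
  list(
    pawper_xl_mac = synthetic_pawper_calibration(reference = reference),
    broselow_2007B = synthetic_broselow_calibration("2007B",
      reference = reference
    ),
    broselow_2011A = synthetic_broselow_calibration("2011A",
      reference = reference
    ),
    ralston = synthetic_ralston_calibration(reference = reference)
  )
}
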