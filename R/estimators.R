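#' Locate the length segment of a tape
#'
#' Segments are half-open `[lower, upper)` cm intervals: a length exactly on
#' a boundary belongs to the higher segment. Lengths outside the tape return
#' `NA` — out-of-range is a value, not an error, so that cohort pipelines
#' can count and report exclusions.
#'
#' @param segments Data frame with contiguous `lower`/`upper` columns (a
#'   calibration object works directly).
#' @param length_cm Positive length(s) in cm.
#' @return Integer segment index (1-based) or `NA` when out of range.
#' @export
locate_segment <- function(segments, length_cm) {
  if (any(length_cm <= 0, na.rm = TRUE)) {
    stop("`length_cm` must be positive", call. = FALSE)
  }
  breaks <- c(segments$lower, segments$upper[nrow(segments)])
  idx <- findInterval(length_cm, breaks)
  idx[idx < 1 | idx > nrow(segments)] <- NA_integer_
  idx
}

#' Estimate weight from a tape calibration
#'
#' Applies one tape's lookup rule to vectors of measurements:
#' * **PAWPER XL-MAC** — locate the length segment, then count that
#'   segment's MAC cut-offs less than or equal to the measured MAC (a MAC
#'   exactly on a cut-off belongs to the higher habitus category) and read
#'   the weight of that habitus column.
#' * **Broselow** — locate the length segment and read its single weight.
#' * **Ralston** — select the band tape by MAC (severe < 115 mm, moderate
#'   115–125 mm inclusive, normal > 125 mm), then do a Broselow-style
#'   length lookup on it.
#'
#' @param cal A `tape_calibration`.
#' @param length_cm Length/height in cm.
#' @param mac Mid-arm circumference (ignored by Broselow tapes).
#' @param mac_unit Unit of `mac`: `"cm"` (default) or `"mm"`. MAC is held
#'   in cm internally; results are identical for equivalent inputs in
#'   either unit.
#' @param ... Passed between methods.
#' @return A tibble with one row per input: `method`, `weight_kg`,
#'   `segment` (index, `NA` out of range), `habitus` (1-based habitus
#'   column for MAC-using methods, `NA` otherwise) and `in_range`.
#' @examples
#' cal <- synthetic_broselow_calibration("2007B")
#' estimate_weight(cal, length_cm = c(72, 30))
#' @export
estimate_weight <- function(cal, length_cm, mac = NULL, ...) {
  UseMethod("estimate_weight")
}

.norm_mac <- function(mac, mac_unit) {
  mac_unit <- match.arg(mac_unit, c("cm", "mm"))
  if (is.null(mac)) return(NULL)
  if (any(mac <= 0, na.rm = TRUE)) {
    stop("`mac` must be positive", call. = FALSE)
  }
  if (mac_unit == "mm") mac / 10 else mac
}

#' @rdname estimate_weight
#' @export
estimate_weight.pawper_calibration <- function(cal, length_cm, mac = NULL,
                                               mac_unit = "cm", ...) {
  mac <- .norm_mac(mac, mac_unit)
  if (is.null(mac)) stop("PAWPER XL-MAC requires `mac`", call. = FALSE)
  n <- max(length(length_cm), length(mac))
  length_cm <- rep_len(length_cm, n)
  mac <- rep_len(mac, n)
  seg <- locate_segment(cal, length_cm)
  habitus <- rep(NA_integer_, n)
  weight <- rep(NA_real_, n)
  ok <- !is.na(seg)
  if (any(ok)) {
    habitus[ok] <- mapply(
      function(s, m) sum(cal$cutoffs[[s]] <= m) + 1L,
      seg[ok], mac[ok]
    )
    weight[ok] <- mapply(
      function(s, h) cal$weights[[s]][h],
      seg[ok], habitus[ok]
    )
  }
  tibble::tibble(
    method = attr(cal, "method"), weight_kg = weight,
    segment = seg, habitus = habitus, in_range = ok
  )
}

#' @rdname estimate_weight
#' @export
estimate_weight.broselow_calibration <- function(cal, length_cm, mac = NULL,
                                                 ...) {
  seg <- locate_segment(cal, length_cm)
  ok <- !is.na(seg)
  weight <- ifelse(ok, cal$weight[seg], NA_real_)
  tibble::tibble(
    method = attr(cal, "method"), weight_kg = weight,
    segment = seg, habitus = NA_integer_, in_range = ok
  )
}

#' @rdname estimate_weight
#' @export
estimate_weight.ralston_calibration <- function(cal, length_cm, mac = NULL,
                                                mac_unit = "cm", ...) {
  mac <- .norm_mac(mac, mac_unit)
  if (is.null(mac)) stop("the Ralston method requires `mac`", call. = FALSE)
  n <- max(length(length_cm), length(mac))
  length_cm <- rep_len(length_cm, n)
  mac_mm <- rep_len(mac, n) * 10
  band <- ifelse(
    mac_mm < cal$band_mm[["severe_below"]], 1L,
    ifelse(mac_mm <= cal$band_mm[["normal_above"]], 2L, 3L)
  )
  weight <- rep(NA_real_, n)
  seg <- rep(NA_integer_, n)
  for (b in 1:3) {
    tape <- cal$tapes[[c("severe", "moderate", "normal")[b]]]
    sel <- band == b
    if (!any(sel)) next
    s <- locate_segment(tape, length_cm[sel])
    seg[sel] <- s
    weight[sel] <- ifelse(is.na(s), NA_real_, tape$weight[s])
  }
  tibble::tibble(
    method = attr(cal, "method"), weight_kg = weight,
    segment = seg, habitus = band, in_range = !is.na(seg)
  )
}
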