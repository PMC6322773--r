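#' Tape calibration objects
#'
#' A calibration is the machine-readable content of a weight-estimation tape:
#' an ordered set of contiguous, half-open length segments
#' `[lower, upper)` in cm, each carrying either a single weight (Broselow),
#' a set of MAC cut-offs defining habitus columns (PAWPER XL-MAC), or — for
#' the Ralston method — one Broselow-style tape per MAC band
#' (severe < 115 mm, moderate 115–125 mm inclusive, normal > 125 mm).
#'
#' All invariants are checked at construction: segments contiguous and
#' non-overlapping, MAC cut-offs strictly increasing, weights strictly
#' increasing across habitus columns and non-decreasing along the tape.
#'
#' @param segments Data frame with `lower` and `upper` columns (cm).
#' @param cutoffs List of numeric vectors, one per segment: MAC cut-offs in
#'   cm, strictly increasing, 0–6 values.
#' @param weights For `pawper_calibration()`, a list of numeric vectors
#'   (kg), each of length `length(cutoffs[[i]]) + 1`; for
#'   `broselow_calibration()`, a numeric vector with one weight per segment.
#' @param edition Broselow edition tag, e.g. `"2007B"` or `"2011A"`.
#' @param provenance Free-text origin tag; fixtures shipped with the package
#'   use `"synthetic-fixture"`. Real (clinical) tape data should be loaded
#'   from external files and tagged accordingly.
#' @return An object of class `pawper_calibration`, `broselow_calibration`
#'   or `ralston_calibration` (all also `tape_calibration`).
#' @name tape_calibration
NULL

.check_segments <- function(segments) {
  if (!all(c("lower", "upper") %in% names(segments))) {
    stop("segments need `lower` and `upper` columns", call. = FALSE)
  }
  n <- nrow(segments)
  if (n == 0) stop("calibration has no segments", call. = FALSE)
  bad <- which(!(segments$lower < segments$upper))
  if (length(bad) > 0) {
    stop("segment row ", bad[1], ": lower must be < upper", call. = FALSE)
  }
  if (n > 1) {
    step <- segments$lower[-1] - segments$upper[-n]
    ov <- which(step < 0)
    if (length(ov) > 0) {
      stop("segment rows ", ov[1], " and ", ov[1] + 1, ": overlap",
        call. = FALSE
      )
    }
    gap <- which(step > 1e-9)
    if (length(gap) > 0) {
      stop("segment rows ", gap[1], " and ", gap[1] + 1, ": not contiguous",
        call. = FALSE
      )
    }
  }
  invisible(segments)
}

#' @rdname tape_calibration
#' @export
pawper_calibration <- function(segments, cutoffs, weights,
                               provenance = "unspecified") {
  .check_segments(segments)
  n <- nrow(segments)
  stopifnot(length(cutoffs) == n, length(weights) == n)
  for (i in seq_len(n)) {
    co <- cutoffs[[i]]
    w <- weights[[i]]
    if (length(co) > 0 && any(diff(co) <= 0)) {
      stop("segment row ", i, ": cut-offs not increasing", call. = FALSE)
    }
    if (length(w) != length(co) + 1) {
      stop("segment row ", i, ": expected ", length(co) + 1,
        " weights (one per habitus category), got ", length(w),
        call. = FALSE
      )
    }
    if (length(w) > 7) {
      stop("segment row ", i, ": more than 7 habitus categories",
        call. = FALSE
      )
    }
    if (any(diff(w) <= 0)) {
      stop("segment row ", i, ": weights not increasing across habitus",
        call. = FALSE
      )
    }
  }
  out <- tibble::tibble(
    lower = segments$lower, upper = segments$upper,
    cutoffs = cutoffs, weights = weights
  )
  structure(out,
    class = c("pawper_calibration", "tape_calibration", class(out)),
    method = "pawper_xl_mac", provenance = provenance
  )
}

#' @rdname tape_calibration
#' @export
broselow_calibration <- function(segments, weights, edition = "2007B",
                                 provenance = "unspecified") {
  .check_segments(segments)
  stopifnot(length(weights) == nrow(segments))
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  if (any(diff(weights) < 0)) {
    stop("weights not non-decreasing along the tape", call. = FALSE)
  }
  out <- tibble::tibble(
    lower = segments$lower, upper = segments$upper, weight = weights
  )
  structure(out,
    class = c("broselow_calibration", "tape_calibration", class(out)),
    method = paste0("broselow_", edition), edition = edition,
    provenance = provenance
  )
}

#' @rdname tape_calibration
#' @param severe,moderate,normal `broselow_calibration`-style tapes (one per
#'   MAC band) for `ralston_calibration()`.
#' @export
ralston_calibration <- function(severe, moderate, normal,
                                provenance = "unspecified") {
  tapes <- list(severe = severe, moderate = moderate, normal = normal)
  for (nm in names(tapes)) {
    if (!inherits(tapes[[nm]], "broselow_calibration")) {
      stop("`", nm, "` must be a broselow_calibration-style tape",
        call. = FALSE
      )
    }
  }
  structure(
    list(
      tapes = tapes,
      # MAC band bounds in mm as printed on the tape
      band_mm = c(severe_below = 115, normal_above = 125)
    ),
    class = c("ralston_calibration", "tape_calibration"),
    method = "ralston", provenance = provenance
  )
}

#' @export
print.tape_calibration <- function(x, ...) {
  cat(
    "<", class(x)[1], "> method=", attr(x, "method"),
    " provenance=", attr(x, "provenance"), "\n",
    sep = ""
  )
  if (inherits(x, "ralston_calibration")) {
    cat("MAC bands (mm): severe <", x$band_mm[["severe_below"]],
      ", moderate", x$band_mm[["severe_below"]], "-",
      x$band_mm[["normal_above"]], ", normal >",
      x$band_mm[["normal_above"]], "\n"
    )
    for (nm in names(x$tapes)) {
      cat("--", nm, "band:", nrow(x$tapes[[nm]]), "segments\n")
    }
  } else {
    cat(nrow(x), "length segments, [",
      min(x$lower), ",", max(x$upper), ") cm\n"
    )
  }
  invisible(x)
}

#' Read a tape calibration from a delimited-text file
#'
#' File schemas (CSV, UTF-8, header row; `#` lines are comments):
#' * PAWPER XL-MAC: `segment_lower_cm, segment_upper_cm, cutoffs_cm,
#'   weights_kg` where the list columns are `;`-separated numbers.
#' * Broselow: `segment_lower_cm, segment_upper_cm, weight_kg, edition`.
#' * Ralston: `band` (`severe`/`moderate`/`normal`), `segment_lower_cm,
#'   segment_upper_cm, weight_kg`.
#'
#' All calibration invariants are validated at load time; violations raise
#' an error naming the offending row.
#'
#' @param path File path.
#' @param method `"pawper_xl_mac"`, `"broselow"` or `"ralston"`.
#' @param provenance Origin tag recorded on the object; defaults to the
#'   file name.
#' @return A `tape_calibration` object.
#' @export
read_calibration <- function(path,
                             method = c("pawper_xl_mac", "broselow",
                                        "ralston"),
                             provenance = basename(path)) {
  method <- match.arg(method)
  tab <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  parse_list <- function(x) {
    lapply(strsplit(as.character(x), ";", fixed = TRUE), function(v) {
      as.numeric(trimws(v[nzchar(trimws(v))]))
    })
  }
  segs <- function(t) {
    data.frame(lower = t$segment_lower_cm, upper = t$segment_upper_cm)
  }
  switch(method,
    pawper_xl_mac = pawper_calibration(
      segs(tab),
      cutoffs = parse_list(tab$cutoffs_cm),
      weights = parse_list(tab$weights_kg),
      provenance = provenance
    ),
    broselow = broselow_calibration(
      segs(tab),
      weights = tab$weight_kg,
      edition = as.character(tab$edition[1]),
      provenance = provenance
    ),
    ralston = {
      band <- function(b) {
        t <- tab[tab$band == b, ]
        if (nrow(t) == 0) stop("ralston file missing band '", b, "'",
          call. = FALSE
        )
        broselow_calibration(segs(t), t$weight_kg, edition = b,
          provenance = provenance
        )
      }
      ralston_calibration(band("severe"), band("moderate"), band("normal"),
        provenance = provenance
      )
    }
  )
}

#' @rdname read_calibration
#' @param cal Calibration to write.
#' @export
write_calibration <- function(cal, path) {
  fmt_list <- function(x) {
    vapply(x, function(v) paste(format(v, trim = TRUE), collapse = ";"), "")
  }
  if (inherits(cal, "pawper_calibration")) {
    out <- tibble::tibble(
      segment_lower_cm = cal$lower, segment_upper_cm = cal$upper,
      cutoffs_cm = fmt_list(cal$cutoffs), weights_kg = fmt_list(cal$weights)
    )
  } else if (inherits(cal, "broselow_calibration")) {
    out <- tibble::tibble(
      segment_lower_cm = cal$lower, segment_upper_cm = cal$upper,
      weight_kg = cal$weight, edition = attr(cal, "edition")
    )
  } else if (inherits(cal, "ralston_calibration")) {
    out <- dplyr::bind_rows(lapply(names(cal$tapes), function(nm) {
      t <- cal$tapes[[nm]]
      tibble::tibble(
        band = nm, segment_lower_cm = t$lower,
        segment_upper_cm = t$upper, weight_kg = t$weight
      )
    }))
  } else {
    stop("not a tape calibration", call. = FALSE)
  }
  readr::write_csv(out, path)
  invisible(path)
}
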