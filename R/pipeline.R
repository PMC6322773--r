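#' Derive BMI and growth-reference z-scores for a cohort
#'
#' Adds `bmi` (kg·m⁻², from weight and height) and the four z-score columns
#' `baz` (BMI-for-age), `waz`, `haz`, `whz`. Survey files often ship
#' pre-computed `waz`/`haz`/`whz`; with `use_existing = TRUE` (default)
#' those are passed through untouched and only missing ones are computed.
#' `baz` is always computed, since surveys typically do not carry it.
#'
#' Records outside the reference grid get `NA` z-scores and
#' `ref_in_range = FALSE` — they are flagged, never silently dropped.
#' Weight-based z-scores use the restricted |z| > 3 adjustment (survey
#' convention).
#'
#' @param data Cohort tibble with `sex`, `age_months`, `weight_kg`,
#'   `height_cm`.
#' @param reference LMS table; defaults to [synthetic_reference()].
#' @param use_existing Pass through pre-computed z-score columns when
#'   present.
#' @return `data` with `bmi`, `baz`, `waz`, `haz`, `whz`, `ref_in_range`.
#' @export
derive_indicators <- function(data, reference = synthetic_reference(),
                              use_existing = TRUE) {
  stopifnot(all(
    c("sex", "age_months", "weight_kg", "height_cm") %in% names(data)
  ))
  data <- tibble::as_tibble(data)
  data$bmi <- data$weight_kg / (data$height_cm / 100)^2

  in_range_of <- function(indicator, at) {
    grid <- reference[reference$indicator == indicator, ]
    at >= min(grid$axis_value) & at <= max(grid$axis_value)
  }
  compute_z <- function(indicator, value, at, restrict) {
    ok <- in_range_of(indicator, at) & !is.na(value) & value > 0
    z <- rep(NA_real_, nrow(data))
    if (any(ok)) {
      z[ok] <- reference_zscore(
        reference, indicator, value[ok], data$sex[ok], at[ok],
        restrict = restrict
      )
    }
    list(z = z, ok = ok)
  }

  ok_all <- rep(TRUE, nrow(data))
  want <- list(
    baz = list("bmi-for-age", data$bmi, data$age_months, TRUE),
    waz = list("weight-for-age", data$weight_kg, data$age_months, TRUE),
    haz = list("height-for-age", data$height_cm, data$age_months, FALSE),
    whz = list("weight-for-height", data$weight_kg, data$height_cm, TRUE)
  )
  for (nm in names(want)) {
    if (nm != "baz" && use_existing && nm %in% names(data) &&
        !all(is.na(data[[nm]]))) {
      next
    }
    w <- want[[nm]]
    res <- compute_z(w[[1]], w[[2]], w[[3]], w[[4]])
    data[[nm]] <- res$z
    ok_all <- ok_all & res$ok
  }
  data$ref_in_range <- ok_all
  data
}

#' Apply tape estimators to a cohort
#'
#' Runs each calibration's lookup over the cohort and adds one
#' `est_<method>` column (estimated weight in kg, `NA` when the child's
#' length — or the tape itself — puts them out of range) and one
#' `inrange_<method>` flag per method. Out-of-range counts are recorded in
#' the `exclusions` attribute.
#'
#' @param data Cohort tibble with `height_cm` and `mac_cm`.
#' @param calibrations Named list of `tape_calibration` objects; names are
#'   used as method ids. Defaults to [synthetic_calibrations()].
#' @return `data` with estimate columns added.
#' @export
apply_estimators <- function(data, calibrations = synthetic_calibrations()) {
  stopifnot(length(calibrations) > 0, !is.null(names(calibrations)))
  excl <- integer(0)
  for (m in names(calibrations)) {
    res <- estimate_weight(
      calibrations[[m]], data$height_cm, mac = data$mac_cm
    )
    data[[paste0("est_", m)]] <- res$weight_kg
    data[[paste0("inrange_", m)]] <- res$in_range
    excl[m] <- sum(!res$in_range)
  }
  attr(data, "exclusions") <- excl
  data
}

#' Default subgroup specifications
#'
#' The standard stratifications of a tape-validation report:
#' * `sex` — male / female;
#' * `age` — 6–12, 13–24, 25–36, 37–48, 49–59 completed months;
#' * `weight` — ≤10 kg, 10.1–15 kg (read as (10, 15]), >15 kg;
#' * `bmi_for_age_z` — the five habitus bins of
#'   [classify_growth()] (`bmi_for_age_5bin`);
#' * `weight_for_height_z` — the wasting grades (`wfh_3bin`);
#' * `region` — survey region.
#'
#' @return Named list of subgroup specs (`dimension`, `assign` function
#'   returning a factor).
#' @export
default_subgroups <- function() {
  list(
    sex = list(
      dimension = "sex", vars = "sex",
      assign = function(d) factor(d$sex, levels = c("male", "female"))
    ),
    age = list(
      dimension = "age", vars = "age_months",
      assign = function(d) {
        cut(d$age_months,
          breaks = c(6, 13, 25, 37, 49, 60), right = FALSE,
          labels = c(
            "6-12 months", "13-24 months", "25-36 months",
            "37-48 months", ">48 months"
          )
        )
      }
    ),
    weight = list(
      dimension = "weight", vars = "weight_kg",
      assign = function(d) {
        cut(d$weight_kg,
          breaks = c(-Inf, 10, 15, Inf), right = TRUE,
          labels = c("<=10kg", "10.1-15kg", ">15kg")
        )
      }
    ),
    bmi_for_age_z = list(
      dimension = "bmi_for_age_z", vars = "baz",
      assign = function(d) classify_growth(d$baz, "bmi_for_age_5bin")
    ),
    weight_for_height_z = list(
      dimension = "weight_for_height_z", vars = "whz",
      assign = function(d) classify_growth(d$whz, "wfh_3bin")
    ),
    region = list(
      dimension = "region", vars = "region",
      assign = function(d) factor(d$region)
    )
  )
}

.pe_columns <- function(data, methods) {
  for (m in methods) {
    est <- data[[paste0("est_", m)]]
    if (is.null(est)) {
      stop("no estimates for method '", m,
        "': run apply_estimators() or inject_error_structure() first",
        call. = FALSE
      )
    }
    data[[paste0("pe_", m)]] <- percentage_error(est, data$weight_kg)
  }
  data
}

.summarise_cell <- function(pe) {
  pe <- pe[!is.na(pe)]
  if (length(pe) < 2) {
    return(tibble::tibble(
      n = length(pe), mpe = NA_real_, sd = NA_real_,
      loa_low = NA_real_, loa_high = NA_real_, rmspe = NA_real_,
      ape_sd = NA_real_, p10 = NA_real_, p20 = NA_real_
    ))
  }
  accuracy_summary(pe)
}

#' Run the subgroup accuracy analysis
#'
#' Produces the full validation report: an overall [accuracy_summary()] per
#' method, one summary per (dimension, bin, method) cell, acceptability
#' flags and exclusion counts. Records whose estimate is missing for a
#' method (out of tape range) are excluded from that method's cells only,
#' and counted. Empty bins yield `n = 0` cells with `NA` statistics.
#'
#' @param data Cohort with indicators and `est_<method>` columns.
#' @param methods Character vector of method ids; default: every
#'   `est_*` column present.
#' @param specs Subgroup specs; see [default_subgroups()]. Dimensions whose
#'   variables are absent from `data` are skipped.
#' @param p10_min,p20_min Acceptability thresholds in percent.
#' @return A `weightape_report` object; see [tidy.weightape_report()],
#'   [glance.weightape_report()], [autoplot.weightape_report()].
#' @export
run_subgroups <- function(data, methods = NULL, specs = default_subgroups(),
                          p10_min = 70, p20_min = 95) {
  if (is.null(methods)) {
    methods <- sub("^est_", "", grep("^est_", names(data), value = TRUE))
  }
  stopifnot(length(methods) > 0)
  data <- .pe_columns(data, methods)

  overall <- purrr::map_dfr(methods, function(m) {
    dplyr::bind_cols(
      tibble::tibble(method = m),
      .summarise_cell(data[[paste0("pe_", m)]])
    )
  })
  overall <- evaluate_acceptability(overall,
    p10_min = p10_min, p20_min = p20_min
  )

  sub_rows <- list()
  unassigned <- list()
  for (spec in specs) {
    if (!is.null(spec$vars) && !all(spec$vars %in% names(data))) next
    bin <- tryCatch(spec$assign(data), error = function(e) NULL)
    if (is.null(bin)) next
    unassigned[[spec$dimension]] <- sum(is.na(bin))
    for (m in methods) {
      pe <- data[[paste0("pe_", m)]]
      cells <- purrr::map_dfr(levels(bin), function(lv) {
        dplyr::bind_cols(
          tibble::tibble(dimension = spec$dimension, bin = lv, method = m),
          .summarise_cell(pe[!is.na(bin) & bin == lv])
        )
      })
      sub_rows[[length(sub_rows) + 1]] <- cells
    }
  }
  subgroups <- dplyr::bind_rows(sub_rows)
  if (nrow(subgroups) > 0) {
    subgroups <- evaluate_acceptability(subgroups,
      p10_min = p10_min, p20_min = p20_min
    )
  }

  excl <- purrr::map_int(
    methods,
    function(m) sum(is.na(data[[paste0("pe_", m)]]))
  )
  structure(
    list(
      overall = overall,
      subgroups = subgroups,
      exclusions = tibble::tibble(method = methods, excluded = excl),
      unassigned = unassigned,
      n_records = nrow(data),
      thresholds = c(p10_min = p10_min, p20_min = p20_min),
      methods = methods
    ),
    class = "weightape_report"
  )
}

#' Flag summaries against the acceptability criterion
#'
#' A method is acceptable when p10 ≥ `p10_min` and p20 ≥ `p20_min`
#' (both inclusive; defaults 70% and 95%).
#'
#' @param summary Tibble with `p10` and `p20` columns (percent).
#' @param p10_min,p20_min Thresholds in percent.
#' @return `summary` with a logical `acceptable` column.
#' @export
evaluate_acceptability <- function(summary, p10_min = 70, p20_min = 95) {
  stopifnot(all(c("p10", "p20") %in% names(summary)))
  summary$acceptable <- summary$p10 >= p10_min & summary$p20 >= p20_min
  summary
}

#' Paired comparison of two methods on one cohort
#'
#' Restricts to records where both methods produced an estimate, then:
#' * p10 / p20 — McNemar test on the discordant within-threshold flags
#'   plus the matched odds ratio `b/c` and absolute/relative accuracy
#'   differences;
#' * mpe — paired t-test on the signed percentage errors;
#' * ape — paired t-test on the absolute percentage errors (the nearest
#'   per-record analogue of an RMSPE comparison, and labelled as such).
#'
#' Significance is flagged at `alpha` (default the conservative 0.001 used
#' with very large samples) and clinical importance at an absolute
#' difference greater than `clinical_margin` percentage points.
#'
#' @param data Cohort with `est_<method>` columns and `weight_kg`.
#' @param method_a,method_b Method ids; `method_a` is the candidate.
#' @param alpha Significance level.
#' @param clinical_margin Clinically important difference, percentage
#'   points.
#' @return Tibble with one row per metric (`p10`, `p20`, `mpe`, `ape`).
#' @export
compare_methods <- function(data, method_a, method_b,
                            alpha = 0.001, clinical_margin = 10) {
  data <- .pe_columns(data, c(method_a, method_b))
  pa <- data[[paste0("pe_", method_a)]]
  pb <- data[[paste0("pe_", method_b)]]
  keep <- !is.na(pa) & !is.na(pb)
  pa <- pa[keep]
  pb <- pb[keep]
  if (length(pa) < 2) {
    stop("fewer than 2 matched records between '", method_a, "' and '",
      method_b, "'",
      call. = FALSE
    )
  }

  prop_row <- function(metric, thr) {
    a_ok <- abs(pa) <= thr
    b_ok <- abs(pb) <= thr
    b <- sum(a_ok & !b_ok)
    c <- sum(!a_ok & b_ok)
    p_a <- 100 * mean(a_ok)
    p_b <- 100 * mean(b_ok)
    diffs <- difference_summary(p_a, p_b)
    or <- paired_odds_ratio(b, c)
    if (b + c >= 1) {
      mc <- mcnemar_paired(b, c)
      stat <- mc$statistic
      pv <- mc$p_value
    } else {
      # identical accuracy patterns: no discordant pairs, nothing to test
      stat <- NA_real_
      pv <- 1
    }
    tibble::tibble(
      metric = metric, method_a = method_a, method_b = method_b,
      n = length(pa), value_a = p_a, value_b = p_b,
      b = b, c = c,
      statistic = stat,
      p_value = pv,
      odds_ratio = or$odds_ratio, ci_low = or$ci_low, ci_high = or$ci_high,
      absolute_diff = diffs$absolute, relative_diff = diffs$relative,
      significant = pv < alpha,
      clinically_important = abs(diffs$absolute) > clinical_margin
    )
  }
  t_row <- function(metric, xa, xb) {
    tt <- paired_t(xa, xb)
    tibble::tibble(
      metric = metric, method_a = method_a, method_b = method_b,
      n = length(xa), value_a = mean(xa), value_b = mean(xb),
      b = NA_integer_, c = NA_integer_,
      statistic = tt$t, p_value = tt$p_value,
      odds_ratio = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
      absolute_diff = mean(xa) - mean(xb), relative_diff = NA_real_,
      significant = tt$p_value < alpha,
      clinically_important = abs(mean(xa) - mean(xb)) > clinical_margin
    )
  }
  dplyr::bind_rows(
    prop_row("p10", 10),
    prop_row("p20", 20),
    t_row("mpe", pa, pb),
    t_row("ape", abs(pa), abs(pb))
  )
}

#' Compare every method against a reference method
#'
#' Runs [compare_methods()] for each non-reference method, overall and —
#' when `specs` is supplied — within every subgroup bin.
#'
#' @inheritParams compare_methods
#' @param methods Method ids to compare; default: every `est_*` column.
#' @param reference_method The candidate method each other method is
#'   compared against (appears as `method_a`).
#' @param specs Optional subgroup specs for stratified comparisons.
#' @return Tibble of comparison rows with `dimension`/`bin` columns
#'   (`"overall"` for the unstratified rows).
#' @export
compare_all <- function(data, reference_method, methods = NULL,
                        specs = NULL, alpha = 0.001, clinical_margin = 10) {
  if (is.null(methods)) {
    methods <- sub("^est_", "", grep("^est_", names(data), value = TRUE))
  }
  stopifnot(reference_method %in% methods)
  others <- setdiff(methods, reference_method)
  rows <- list()
  add <- function(d, dimension, bin) {
    for (m in others) {
      cmp <- compare_methods(d, reference_method, m,
        alpha = alpha, clinical_margin = clinical_margin
      )
      cmp$dimension <- dimension
      cmp$bin <- bin
      rows[[length(rows) + 1]] <<- cmp
    }
  }
  add(data, "overall", "overall")
  if (!is.null(specs)) {
    for (spec in specs) {
      if (!is.null(spec$vars) && !all(spec$vars %in% names(data))) next
      bin <- tryCatch(spec$assign(data), error = function(e) NULL)
      if (is.null(bin)) next
      for (lv in levels(bin)) {
        d <- data[!is.na(bin) & bin == lv, ]
        if (nrow(d) < 2) next
        ok <- tryCatch(
          {
            add(d, spec$dimension, lv)
            TRUE
          },
          error = function(e) FALSE
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  dplyr::relocate(out, "dimension", "bin")
}
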