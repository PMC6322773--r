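#' Signed percentage error of a weight estimate
#'
#' \deqn{PE = 100 \times (\hat{W} - W)/W}
#' Negative values indicate underestimation.
#'
#' @param estimated,actual Weights in kg; `actual` must be positive.
#' @return Numeric vector of signed percentage errors (%).
#' @examples
#' percentage_error(8, 10) # -20
#' @export
percentage_error <- function(estimated, actual) {
  if (any(actual <= 0, na.rm = TRUE)) {
    stop("`actual` weight must be positive", call. = FALSE)
  }
  100 * (estimated - actual) / actual
}

#' Accuracy summary of a percentage-error sample
#'
#' Computes the standard weight-estimation performance panel from signed
#' percentage errors:
#' * bias: mean percentage error (MPE);
#' * precision: Bland–Altman 95% limits of agreement,
#'   \eqn{MPE \pm 1.96\,SD} (sample SD, n−1 denominator), and the root mean
#'   square percentage error \eqn{RMSPE = \sqrt{\sum PE^2 / n}};
#' * overall accuracy: p10 and p20, the percentage of estimates within
#'   ±10% and ±20% of actual weight (threshold inclusive).
#'
#' `ape_sd`, the SD of the absolute percentage error, is reported as a
#' companion spread measure alongside RMSPE.
#'
#' @param pe Numeric vector of finite signed percentage errors; at least 2.
#' @return One-row tibble: `n, mpe, sd, loa_low, loa_high, rmspe, ape_sd,
#'   p10, p20`.
#' @examples
#' accuracy_summary(c(-10, 10)) # mpe 0, rmspe 10, p10 100
#' @export
accuracy_summary <- function(pe) {
  pe <- pe[!is.na(pe)]
  if (length(pe) < 2) {
    stop("need at least 2 finite percentage errors", call. = FALSE)
  }
  if (any(!is.finite(pe))) {
    stop("percentage errors must be finite", call. = FALSE)
  }
  mpe <- mean(pe)
  sdev <- stats::sd(pe)
  tibble::tibble(
    n = length(pe),
    mpe = mpe,
    sd = sdev,
    loa_low = mpe - 1.96 * sdev,
    loa_high = mpe + 1.96 * sdev,
    rmspe = sqrt(mean(pe^2)),
    ape_sd = stats::sd(abs(pe)),
    p10 = 100 * mean(abs(pe) <= 10),
    p20 = 100 * mean(abs(pe) <= 20)
  )
}

#' Impute the proportion of estimates within a threshold from printed
#' summary statistics
#'
#' Published studies often report only MPE and the Bland–Altman 95% limits
#' of agreement for a method. Assuming the percentage errors are normally
#' distributed — N(μ, σ) with μ the MPE and σ recovered from the LOA width
#' as \eqn{\sigma = (LOA_{high} - LOA_{low}) / (2 \times 1.96)} — the
#' proportion within ±`threshold`% is the normal integral
#' \deqn{100 \left[\Phi\!\left(\frac{t-\mu}{\sigma}\right) -
#'   \Phi\!\left(\frac{-t-\mu}{\sigma}\right)\right].}
#' This recovers p10/p20 for methods whose per-record errors are not
#' available, enabling paired-style subgroup comparisons.
#'
#' The symmetric-width recovery of σ is robust to one-sided rounding of the
#' published LOA.
#'
#' @param mpe Mean percentage error (%).
#' @param loa_low,loa_high Published 95% limits of agreement (%);
#'   `loa_low < loa_high` required.
#' @param threshold Accuracy threshold in % (10 for p10, 20 for p20).
#' @return Imputed proportion within the threshold, in percent.
#' @examples
#' impute_p_within(-1.6, -23.2, 19.9, 10) # ~63.2
#' @export
impute_p_within <- function(mpe, loa_low, loa_high, threshold) {
  if (any(loa_high <= loa_low)) {
    stop("degenerate limits of agreement: need loa_low < loa_high",
      call. = FALSE
    )
  }
  if (any(threshold <= 0)) stop("`threshold` must be positive", call. = FALSE)
  sigma <- (loa_high - loa_low) / (2 * 1.96)
  100 * (stats::pnorm((threshold - mpe) / sigma) -
    stats::pnorm((-threshold - mpe) / sigma))
}

#' McNemar test from discordant-pair counts
#'
#' Paired comparison of two methods' accuracy indicators (e.g. within-10%
#' flags): `b` records accurate under A only, `c` accurate under B only.
#' With `b + c >=` `exact_limit` the continuity-corrected chi-square
#' statistic \eqn{(|b-c|-1)^2/(b+c)} on 1 df is used; below it, the exact
#' two-sided binomial test \eqn{X \sim Bin(b+c, 1/2)}.
#'
#' @param b,c Non-negative discordant counts, `b + c >= 1`.
#' @param exact_limit Switch point between the exact and chi-square
#'   variants (default 25).
#' @return One-row tibble: `b, c, statistic` (`NA` for the exact variant),
#'   `p_value, variant`.
#' @export
mcnemar_paired <- function(b, c, exact_limit = 25) {
  if (b < 0 || c < 0 || b + c < 1) {
    stop("need non-negative discordant counts with b + c >= 1",
      call. = FALSE
    )
  }
  n <- b + c
  if (n >= exact_limit) {
    stat <- (abs(b - c) - 1)^2 / n
    tibble::tibble(
      b = b, c = c, statistic = stat,
      p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
      variant = "chi-square (continuity corrected)"
    )
  } else {
    p <- min(1, 2 * stats::pbinom(min(b, c), n, 0.5))
    tibble::tibble(
      b = b, c = c, statistic = NA_real_, p_value = p,
      variant = "exact binomial"
    )
  }
}

#' Matched-pairs odds ratio with 95% confidence interval
#'
#' For discordant counts `b` (A-only) and `c` (B-only), the matched odds
#' ratio is `b / c` with log-scale CI
#' \eqn{\exp(\ln(b/c) \pm 1.96\sqrt{1/b + 1/c})}. When either cell is zero
#' the ratio is undefined; a continuity-corrected alternative (½ added to
#' both cells) is reported and flagged.
#'
#' @inheritParams mcnemar_paired
#' @return One-row tibble: `odds_ratio, ci_low, ci_high,
#'   continuity_corrected`.
#' @export
paired_odds_ratio <- function(b, c) {
  if (b < 0 || c < 0) stop("counts must be non-negative", call. = FALSE)
  corrected <- b == 0 || c == 0
  if (corrected) {
    b <- b + 0.5
    c <- c + 0.5
  }
  lor <- log(b / c)
  se <- sqrt(1 / b + 1 / c)
  tibble::tibble(
    odds_ratio = b / c,
    ci_low = exp(lor - 1.96 * se),
    ci_high = exp(lor + 1.96 * se),
    continuity_corrected = corrected
  )
}

#' Paired t-test on matched percentage-error vectors
#'
#' Standard paired t-test on the per-record differences `pe_a - pe_b`
#' (two-sided). A zero-variance difference vector is degenerate and flagged
#' rather than tested.
#'
#' @param pe_a,pe_b Matched percentage-error vectors of equal length >= 2.
#' @return One-row tibble: `t, df, p_value, mean_diff, degenerate`.
#' @export
paired_t <- function(pe_a, pe_b) {
  if (length(pe_a) != length(pe_b) || length(pe_a) < 2) {
    stop("need matched vectors of equal length >= 2", call. = FALSE)
  }
  d <- pe_a - pe_b
  if (stats::sd(d) == 0) {
    return(tibble::tibble(
      t = NA_real_, df = length(d) - 1, p_value = if (all(d == 0)) 1 else 0,
      mean_diff = mean(d), degenerate = TRUE
    ))
  }
  ht <- stats::t.test(pe_a, pe_b, paired = TRUE)
  tibble::tibble(
    t = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value, mean_diff = unname(ht$estimate),
    degenerate = FALSE
  )
}

#' Absolute and relative difference between two accuracy proportions
#'
#' @param p_a,p_b Accuracy proportions in percent (`p_b > 0` for the
#'   relative difference).
#' @return One-row tibble: `absolute` (percentage points), `relative` (%),
#'   plus integer-rounded versions `absolute_int`, `relative_int`.
#' @examples
#' difference_summary(79.3, 55.5) # relative rounds to 43
#' @export
difference_summary <- function(p_a, p_b) {
  absolute <- p_a - p_b
  relative <- ifelse(p_b > 0, 100 * (p_a - p_b) / p_b, NA_real_)
  tibble::tibble(
    absolute = absolute,
    relative = relative,
    absolute_int = round(absolute),
    relative_int = round(relative)
  )
}
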