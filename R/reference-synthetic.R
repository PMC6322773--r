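#' Synthetic LMS growth reference
#'
#' A smooth, WHO-shaped but entirely synthetic LMS reference covering the
#' four indicators the pipeline needs, for both sexes. Median curves are
#' simple parametric forms chosen to sit close to published preschool growth
#' curves (height-for-age logarithmic in age, weight-for-height allometric in
#' length, weight-for-age and BMI-for-age derived from those), with constant
#' Box-Cox power L and coefficient of variation S per indicator. It exists so
#' that the package builds, simulates and tests offline; it is **not** a
#' clinical reference and must not be used to z-score real children — load a
#' real reference with [read_lms_table()] for that.
#'
#' Grids: age-based indicators run 0–66 completed months in 1-month steps;
#' weight-for-height runs 45–125 cm in 0.5 cm steps.
#'
#' @return A validated LMS tibble (see [validate_lms_table()]) with attribute
#'   `provenance = "synthetic-fixture"`.
#' @export
synthetic_reference <- function() {
  sexes <- c("male", "female")
  age <- 0:66
  len <- seq(45, 125, by = 0.5)

  # median curves; sex offsets are small and fixed
  m_hfa <- function(a, sex) {
    -12.3 + 28.5 * log(a + 9) + ifelse(sex == "male", 0.6, -0.6)
  }
  m_wfh <- function(h, sex) {
    7.2 * (h / 65)^1.76 * ifelse(sex == "male", 1.01, 0.99)
  }
  m_wfa <- function(a, sex) m_wfh(m_hfa(a, sex), sex)
  m_bmi <- function(a, sex) m_wfa(a, sex) / (m_hfa(a, sex) / 100)^2

  rows <- list()
  for (sx in sexes) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      indicator = "height-for-age", sex = sx, axis_value = age,
      l = 1, m = m_hfa(age, sx), s = 0.045
    )
    rows[[length(rows) + 1]] <- tibble::tibble(
      indicator = "weight-for-height", sex = sx, axis_value = len,
      l = -0.35, m = m_wfh(len, sx), s = 0.082
    )
    rows[[length(rows) + 1]] <- tibble::tibble(
      indicator = "weight-for-age", sex = sx, axis_value = age,
      l = -0.2, m = m_wfa(age, sx), s = 0.11
    )
    rows[[length(rows) + 1]] <- tibble::tibble(
      indicator = "bmi-for-age", sex = sx, axis_value = age,
      l = -1.6, m = m_bmi(age, sx), s = 0.08
    )
  }
  out <- dplyr::bind_rows(rows)
  validate_lms_table(out)
  attr(out, "provenance") <- "synthetic-fixture"
  out
}
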