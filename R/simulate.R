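#' Configuration for the synthetic cohort generator
#'
#' Defaults target the marginal structure of pooled nutritional surveys of
#' children aged 6–59 months from low- and middle-income countries:
#' height-for-age z (HAZ) ~ N(−1.5, 1.5), weight-for-height z (WHZ) ~
#' N(−0.6, 1.2), proportion male 0.506, age uniform over 6–59 completed
#' months, and a MAC marginal of mean 14.2 cm, SD 1.3 cm. MAC is modelled
#' linearly in age and WHZ plus noise; the default slopes and residual SD
#' are calibrated analytically so the MAC marginal hits its target with
#' corr(MAC, WHZ) ≈ 0.7.
#'
#' @param sex_ratio Proportion male.
#' @param age_min,age_max Age range in completed months (uniform).
#' @param haz_mean,haz_sd,whz_mean,whz_sd Latent z-score distributions.
#' @param mac_intercept Mean MAC (cm) at age 32.5 months and WHZ 0.
#' @param mac_age_slope cm per month of age.
#' @param mac_whz_slope cm per WHZ unit.
#' @param mac_resid_sd Residual SD (cm).
#' @param round_length,round_weight,round_mac Measurement rounding
#'   precisions (cm, kg, cm); `NULL` disables rounding.
#' @param region_mix Named proportions over the six survey regions
#'   (must sum to 1).
#' @param year_range Survey years to sample from.
#' @param max_retries Redraw cap when a latent draw falls outside the
#'   growth reference.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(sex_ratio = 0.506,
                          age_min = 6, age_max = 59,
                          haz_mean = -1.5, haz_sd = 1.5,
                          whz_mean = -0.6, whz_sd = 1.2,
                          mac_intercept = 14.655,
                          mac_age_slope = 0.02,
                          mac_whz_slope = 0.7583,
                          mac_resid_sd = 0.876,
                          round_length = 0.1,
                          round_weight = 0.1,
                          round_mac = 0.1,
                          region_mix = c(
                            "Africa" = 0.45, "South-East Asia" = 0.25,
                            "Middle East" = 0.12, "Americas" = 0.08,
                            "Eastern Europe" = 0.06,
                            "Western Pacific" = 0.04
                          ),
                          year_range = c(1992L, 2017L),
                          max_retries = 20L) {
  stopifnot(
    sex_ratio >= 0, sex_ratio <= 1,
    haz_sd > 0, whz_sd > 0, mac_resid_sd > 0,
    age_min < age_max,
    abs(sum(region_mix) - 1) < 1e-8
  )
  structure(
    list(
      sex_ratio = sex_ratio, age_min = age_min, age_max = age_max,
      haz_mean = haz_mean, haz_sd = haz_sd,
      whz_mean = whz_mean, whz_sd = whz_sd,
      mac_intercept = mac_intercept, mac_age_slope = mac_age_slope,
      mac_whz_slope = mac_whz_slope, mac_resid_sd = mac_resid_sd,
      round_length = round_length, round_weight = round_weight,
      round_mac = round_mac, region_mix = region_mix,
      year_range = year_range, max_retries = max_retries
    ),
    class = "cohort_config"
  )
}

.round_to <- function(x, precision) {
  if (is.null(precision) || precision <= 0) return(x)
  round(x / precision) * precision
}

.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  )
  set.seed(seed)
  force(code)
}

#' Simulate a survey-style cohort of children aged 6–59 months
#'
#' Per child: sex and age are drawn from the configured marginals; latent
#' HAZ is drawn and inverted through the height-for-age reference to get
#' length; latent WHZ is drawn and inverted through weight-for-height at
#' that length to get weight; MAC comes from the linear MAC model on age
#' and WHZ plus noise. Measurements are then rounded to survey precision.
#' Latent (pre-rounding) values are retained in `*_true` columns for
#' recovery tests, and survey-style `haz`/`whz`/`waz` columns carry the
#' reference z-scores as a field survey file would.
#'
#' Draws whose inverted length falls outside the weight-for-height grid are
#' redrawn up to `config$max_retries` times; stubborn records are dropped
#' and counted in the `dropped` attribute.
#'
#' @param n Number of children (0 allowed).
#' @param seed Integer seed; the same (config, seed) reproduces the cohort
#'   exactly. `NULL` uses the session RNG stream.
#' @param config A [cohort_config()].
#' @param reference LMS table; defaults to [synthetic_reference()].
#' @return A tibble with columns `id, country, year, region, sex,
#'   age_months, weight_kg, height_cm, mac_cm, haz, whz, waz,
#'   haz_true, whz_true, height_true, weight_true, mac_true`, with
#'   attributes `config`, `seed`, `dropped`.
#' @export
simulate_cohort <- function(n, seed = NULL, config = cohort_config(),
                            reference = synthetic_reference()) {
  stopifnot(n >= 0)
  .with_seed(seed, {
    cols <- c(
      "id", "country", "year", "region", "sex", "age_months", "weight_kg",
      "height_cm", "mac_cm", "haz", "whz", "waz",
      "haz_true", "whz_true", "height_true", "weight_true", "mac_true"
    )
    if (n == 0) {
      out <- tibble::as_tibble(
        stats::setNames(rep(list(logical(0)), length(cols)), cols)
      )
      attr(out, "config") <- config
      attr(out, "seed") <- seed
      attr(out, "dropped") <- 0L
      return(out)
    }
    sex <- ifelse(stats::runif(n) < config$sex_ratio, "male", "female")
    age <- sample(seq(config$age_min, config$age_max), n, replace = TRUE)
    region <- sample(names(config$region_mix), n,
      replace = TRUE, prob = config$region_mix
    )
    lookup <- region_lookup()
    country <- character(n)
    for (r in unique(region)) {
      cands <- lookup$country[lookup$region == r]
      idx <- which(region == r)
      country[idx] <- cands[sample.int(length(cands), length(idx),
        replace = TRUE
      )]
    }
    year <- sample(seq(config$year_range[1], config$year_range[2]), n,
      replace = TRUE
    )

    hfa <- lms_interpolate(reference, "height-for-age", sex, age)
    wfh_grid <- reference[reference$indicator == "weight-for-height", ]
    len_rng <- range(wfh_grid$axis_value)

    haz <- stats::rnorm(n, config$haz_mean, config$haz_sd)
    height <- lms_value(haz, hfa$l, hfa$m, hfa$s)
    bad <- which(height < len_rng[1] | height > len_rng[2])
    tries <- 0L
    while (length(bad) > 0 && tries < config$max_retries) {
      haz[bad] <- stats::rnorm(length(bad), config$haz_mean, config$haz_sd)
      height[bad] <- lms_value(
        haz[bad], hfa$l[bad], hfa$m[bad], hfa$s[bad]
      )
      bad <- bad[height[bad] < len_rng[1] | height[bad] > len_rng[2]]
      tries <- tries + 1L
    }
    dropped <- length(bad)
    keep <- setdiff(seq_len(n), bad)

    whz <- stats::rnorm(n, config$whz_mean, config$whz_sd)
    mac <- config$mac_intercept +
      config$mac_age_slope * (age - 32.5) +
      config$mac_whz_slope * whz +
      stats::rnorm(n, 0, config$mac_resid_sd)

    sex <- sex[keep]; age <- age[keep]; region <- region[keep]
    country <- country[keep]; year <- year[keep]
    haz <- haz[keep]; whz <- whz[keep]; mac <- mac[keep]
    height <- height[keep]

    wfh <- lms_interpolate(reference, "weight-for-height", sex, height)
    weight <- lms_value(whz, wfh$l, wfh$m, wfh$s)
    wfa <- lms_interpolate(reference, "weight-for-age", sex, age)
    waz <- lms_zscore(weight, wfa$l, wfa$m, wfa$s, restrict = TRUE)

    out <- tibble::tibble(
      id = seq_along(keep),
      country = country, year = year, region = region, sex = sex,
      age_months = age,
      weight_kg = .round_to(weight, config$round_weight),
      height_cm = .round_to(height, config$round_length),
      mac_cm = .round_to(mac, config$round_mac),
      haz = haz, whz = whz, waz = waz,
      haz_true = haz, whz_true = whz,
      height_true = height, weight_true = weight, mac_true = mac
    )
    attr(out, "config") <- config
    attr(out, "seed") <- seed
    attr(out, "dropped") <- dropped
    if (dropped > 0) {
      message("simulate_cohort: dropped ", dropped,
        " record(s) outside the growth reference after ",
        config$max_retries, " redraws"
      )
    }
    out
  })
}

#' Inject a synthetic error structure as pseudo-method estimates
#'
#' Adds one estimate column per pseudo-method, with
#' `estimated = actual × (1 + e/100)` and `e ~ N(mu, sigma)` percentage
#' error. This lets the accuracy and reporting machinery be exercised (and
#' its parameter recovery verified against the analytic normal model)
#' without any tape calibration.
#'
#' @param cohort Cohort tibble with a `weight_kg` column.
#' @param error_spec Data frame with columns `method`, `mu`, `sigma`
#'   (percentage-error mean and SD per pseudo-method; `sigma >= 0`).
#' @param seed Optional integer seed.
#' @return The cohort with added `est_<method>` columns.
#' @export
inject_error_structure <- function(cohort, error_spec, seed = NULL) {
  stopifnot(all(c("method", "mu", "sigma") %in% names(error_spec)))
  if (any(error_spec$sigma < 0)) {
    stop("`sigma` must be non-negative", call. = FALSE)
  }
  .with_seed(seed, {
    n <- nrow(cohort)
    for (i in seq_len(nrow(error_spec))) {
      e <- stats::rnorm(n, error_spec$mu[i], error_spec$sigma[i])
      cohort[[paste0("est_", error_spec$method[i])]] <-
        cohort$weight_kg * (1 + e / 100)
    }
    cohort
  })
}
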