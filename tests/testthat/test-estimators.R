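test_that("locate_segment follows the half-open convention and flags
           out-of-range lengths", {
  cal <- tiny_broselow()
  expect_equal(locate_segment(cal, 60), 1L) # lower bound belongs to segment
  expect_equal(locate_segment(cal, 70), 2L)
  expect_equal(locate_segment(cal, 100), NA_integer_) # upper bound excluded
  expect_equal(locate_segment(cal, 59.9), NA_integer_)
  expect_error(locate_segment(cal, -3), "positive")
  # brute-force linear-scan oracle on random lengths
  set.seed(11)
  x <- stats::runif(1000, 40, 120)
  scan <- vapply(x, function(len) {
    hit <- which(cal$lower <= len & len < cal$upper)
    if (length(hit) == 1) hit else NA_integer_
  }, 1L)
  expect_equal(locate_segment(cal, x), scan)
})

test_that("PAWPER XL-MAC lookup reads the correct habitus column", {
  cal <- tiny_pawper()
  # hand evaluation: length 81 -> segment 2; mac 14.5 passes cut-offs
  # 13.0 and 14.0 -> third habitus column -> 11.5 kg
  res <- estimate_weight(cal, 81, mac = 14.5)
  expect_equal(res$weight_kg, 11.5)
  expect_equal(res$segment, 2L)
  expect_equal(res$habitus, 3L)
  expect_true(res$in_range)
  # mac below the first cut-off -> that segment's smallest weight
  expect_equal(estimate_weight(cal, 81, mac = 12.0)$weight_kg, 8.5)
  # mac exactly on a cut-off belongs to the higher habitus category
  expect_equal(estimate_weight(cal, 81, mac = 14.0)$weight_kg, 11.5)
  # out-of-range length: flagged, no weight
  oor <- estimate_weight(cal, 120, mac = 14)
  expect_false(oor$in_range)
  expect_true(is.na(oor$weight_kg))
  expect_error(estimate_weight(cal, 81), "requires")
})

test_that("PAWPER estimates are monotone in MAC and in length", {
  cal <- synthetic_pawper_calibration()
  set.seed(23)
  for (i in 1:20) {
    len <- stats::runif(1, min(cal$lower), max(cal$upper) - 1e-6)
    mac <- sort(stats::runif(50, 10, 20))
    w <- estimate_weight(cal, rep(len, 50), mac = mac)$weight_kg
    expect_true(all(diff(w) >= 0))
  }
  # fixed habitus column, increasing length across segments
  wmat <- do.call(rbind, cal$weights)
  expect_true(all(apply(wmat, 2, function(col) all(diff(col) >= 0))))
})

test_that("Broselow lookup is a non-decreasing step function with edition
           tags", {
  b07 <- tiny_broselow("2007B")
  b11 <- tiny_broselow("2011A")
  expect_equal(estimate_weight(b07, 85)$weight_kg, 11.5)
  expect_equal(estimate_weight(b07, 85)$method, "broselow_2007B")
  expect_equal(estimate_weight(b11, 85)$method, "broselow_2011A")
  w <- estimate_weight(synthetic_broselow_calibration("2007B"),
    seq(50, 119.9, by = 0.1)
  )$weight_kg
  expect_true(all(diff(w) >= 0))
  expect_equal(length(unique(w)), 14) # one step per segment
})

test_that("Ralston band selection follows the printed MAC bounds", {
  cal <- tiny_ralston()
  # severe < 115 mm; moderate 115-125 mm inclusive; normal > 125 mm
  expect_equal(estimate_weight(cal, 75, mac = 11.49)$habitus, 1L)
  expect_equal(estimate_weight(cal, 75, mac = 11.49)$weight_kg, 7.0)
  expect_equal(estimate_weight(cal, 75, mac = 11.5)$habitus, 2L)
  expect_equal(estimate_weight(cal, 75, mac = 12.5)$habitus, 2L)
  expect_equal(estimate_weight(cal, 75, mac = 12.51)$habitus, 3L)
  # mm input gives identical results to cm input
  expect_equal(
    estimate_weight(cal, 75, mac = 114.9, mac_unit = "mm"),
    estimate_weight(cal, 75, mac = 11.49, mac_unit = "cm")
  )
  # ordered band tapes: weight non-decreasing as mac sweeps up
  mac_sweep <- seq(10, 14, by = 0.05)
  w <- estimate_weight(cal, rep(82, length(mac_sweep)),
    mac = mac_sweep
  )$weight_kg
  expect_true(all(diff(w) >= 0))
})

test_that("every in-range (length, mac) maps to exactly one finite weight", {
  cals <- list(tiny_pawper(), tiny_broselow(), tiny_ralston())
  set.seed(31)
  for (cal in cals) {
    segs <- if (inherits(cal, "ralston_calibration")) cal$tapes$normal else cal
    len <- stats::runif(500, min(segs$lower), max(segs$upper) - 1e-9)
    mac <- stats::runif(500, 10, 18)
    res <- estimate_weight(cal, len, mac = mac)
    expect_true(all(res$in_range))
    expect_true(all(is.finite(res$weight_kg) & res$weight_kg > 0))
  }
})

test_that("calibration constructors reject malformed tapes by row", {
  expect_error(
    broselow_calibration(
      data.frame(lower = c(75, 79), upper = c(80, 85)), c(9, 10)
    ),
    "overlap"
  )
  expect_error(
    broselow_calibration(
      data.frame(lower = c(75, 81), upper = c(80, 85)), c(9, 10)
    ),
    "not contiguous"
  )
  expect_error(
    broselow_calibration(
      data.frame(lower = c(75, 80), upper = c(80, 85)), c(10, 9)
    ),
    "non-decreasing"
  )
  expect_error(
    pawper_calibration(
      data.frame(lower = 75, upper = 80),
      cutoffs = list(c(14.0, 13.0)),
      weights = list(c(8, 9, 10))
    ),
    "cut-offs not increasing"
  )
  expect_error(
    pawper_calibration(
      data.frame(lower = 75, upper = 80),
      cutoffs = list(c(13.0, 14.0)),
      weights = list(c(8, 9)) # needs 3 weights for 2 cut-offs
    ),
    "expected 3 weights"
  )
  expect_error(
    pawper_calibration(
      data.frame(lower = 75, upper = 80),
      cutoffs = list(c(13.0, 14.0)),
      weights = list(c(8, 10, 9))
    ),
    "weights not increasing"
  )
})

test_that("shipped fixture calibrations load, validate and round-trip", {
  p <- read_calibration(
    system.file("extdata", "pawper_xl_mac_synthetic.csv",
      package = "weightape"
    ),
    "pawper_xl_mac"
  )
  expect_true(all(vapply(p$weights, length, 1L) == 7))
  expect_true(all(vapply(p$cutoffs, length, 1L) == 6))
  r <- read_calibration(
    system.file("extdata", "ralston_synthetic.csv", package = "weightape"),
    "ralston"
  )
  expect_named(r$tapes, c("severe", "moderate", "normal"))
  # write -> read preserves the lookup exactly
  path <- withr::local_tempfile(fileext = ".csv")
  write_calibration(tiny_pawper(), path)
  back <- read_calibration(path, "pawper_xl_mac")
  set.seed(5)
  len <- stats::runif(200, 77.5, 85 - 1e-9)
  mac <- stats::runif(200, 12, 16)
  expect_equal(
    estimate_weight(back, len, mac = mac),
    estimate_weight(tiny_pawper(), len, mac = mac),
    ignore_attr = TRUE
  )
})
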