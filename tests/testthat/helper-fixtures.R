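# Shared in-code fixtures. The three-segment PAWPER tape is small enough to
# evaluate by hand; its middle segment is the worked reference case used in
# several tests.
tiny_pawper <- function() {
  pawper_calibration(
    data.frame(lower = c(77.5, 80, 82.5), upper = c(80, 82.5, 85)),
    cutoffs = list(
      c(12.8, 13.8, 14.8),
      c(13.0, 14.0, 15.0),
      c(13.2, 14.2, 15.2)
    ),
    weights = list(
      c(8.1, 9.6, 11.1, 12.6),
      c(8.5, 10.0, 11.5, 13.0),
      c(8.9, 10.4, 11.9, 13.4)
    ),
    provenance = "test-fixture"
  )
}

tiny_broselow <- function(edition = "2007B") {
  broselow_calibration(
    data.frame(lower = c(60, 70, 80, 90), upper = c(70, 80, 90, 100)),
    weights = c(7, 9, 11.5, 14),
    edition = edition,
    provenance = "test-fixture"
  )
}

tiny_ralston <- function() {
  segs <- data.frame(lower = c(60, 70, 80, 90), upper = c(70, 80, 90, 100))
  ralston_calibration(
    severe = broselow_calibration(segs, c(5.5, 7.0, 9.0, 11.0),
      edition = "severe", provenance = "test-fixture"
    ),
    moderate = broselow_calibration(segs, c(6.2, 8.0, 10.2, 12.4),
      edition = "moderate", provenance = "test-fixture"
    ),
    normal = broselow_calibration(segs, c(7.0, 9.0, 11.5, 14.0),
      edition = "normal", provenance = "test-fixture"
    ),
    provenance = "test-fixture"
  )
}

# small cohort with injected pseudo-method estimates, for report-level tests
tiny_cohort <- function(n = 500, seed = 42,
                        spec = data.frame(
                          method = c("alpha", "beta"),
                          mu = c(0, 4), sigma = c(5, 9)
                        )) {
  co <- simulate_cohort(n, seed = seed)
  co <- derive_indicators(co, use_existing = FALSE)
  inject_error_structure(co, spec, seed = seed + 1)
}
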