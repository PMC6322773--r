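# weightape

Virtual validation of paediatric weight-estimation tapes.

When a child cannot be weighed, drug doses are calculated from an estimated
weight. Length-based tapes (Broselow) map the child's recumbent length to a
weight; two-dimensional systems refine the estimate by habitus — the PAWPER
XL-MAC tape selects one of up to seven habitus columns within each length
segment by mid-arm circumference (MAC), and the Ralston method switches
between three parallel length tapes by the WHO wasting MAC bands
(severe < 115 mm, moderate 115–125 mm, normal > 125 mm). A *virtual*
validation study applies these lookup rules to a database of anthropometric
records (length, MAC, measured weight) rather than to children directly,
and scores the resulting estimates.

**weightape** is for researchers running such studies on survey-style
records of children aged 6–59 months. It provides:

* **Tape estimators** driven by pluggable, validated calibration files
  (`estimate_weight()`, `read_calibration()`), with half-open length
  segments and printed-edge MAC conventions;
* **LMS growth-reference machinery** (`lms_zscore()`, `lms_value()`,
  `reference_zscore()`, `classify_growth()`), including the survey-style
  restricted adjustment beyond ±3 SD;
* **The accuracy framework**: for percentage error
  `PE = 100 (Ŵ − W)/W`, the panel MPE, Bland–Altman 95% limits of
  agreement `MPE ± 1.96 SD`, `RMSPE = √(Σ PE²/n)`, and p10/p20 — the
  percentage of estimates within ±10%/±20% of measured weight
  (`accuracy_summary()`); the normal-integral imputation of p10/p20 from a
  published MPE and LOA (`impute_p_within()`); McNemar tests, matched odds
  ratios and paired t-tests for between-method comparisons
  (`mcnemar_paired()`, `paired_odds_ratio()`, `compare_methods()`);
* **A reporting pipeline** (`derive_indicators()`, `apply_estimators()`,
  `run_subgroups()`, `compare_all()`) producing subgroup tables by sex,
  age, weight, BMI-for-age habitus, wasting grade and region, with
  broom-style `tidy()`/`glance()` and `autoplot()` methods;
* **A synthetic cohort generator** (`simulate_cohort()`,
  `inject_error_structure()`) emulating the marginal structure of pooled
  LMIC nutritional surveys (HAZ ~ N(−1.5, 1.5), WHZ ~ N(−0.6, 1.2), MAC
  mean 14.2 SD 1.3 cm), so every stage runs and is tested offline.

The shipped calibrations and growth reference are **synthetic fixtures**
(clearly tagged as such): they exercise the machinery with realistic
shapes but are not the clinical tapes. Real tape tables, a real WHO
reference and the open survey dataset load through `read_calibration()`,
`read_lms_table()` and `read_cohort()`.

## Worked example

```r
library(weightape)

cohort <- simulate_cohort(20000, seed = 42)
cohort <- derive_indicators(cohort, use_existing = FALSE)
cohort <- apply_estimators(cohort)   # shipped synthetic calibrations
report <- run_subgroups(cohort)
glance(report)
#> # A tibble: 4 × 12
#>   method             n   mpe    sd loa_low loa_high rmspe ape_sd   p10   p20 acceptable excluded
#>   <chr>          <int> <dbl> <dbl>   <dbl>    <dbl> <dbl>  <dbl> <dbl> <dbl> <lgl>         <int>
#> 1 pawper_xl_mac  19913  3.12 10.2    -16.8     23.1  10.6   6.63  67.1  93.9 FALSE            87
#> 2 broselow_2007B 19982  3.40 10.5    -17.2     24.0  11.1   6.77  64.0  92.9 FALSE            18
#> 3 broselow_2011A 19982  9.80 11.2    -12.1     31.7  14.9   8.83  48.9  82.3 FALSE            18
#> 4 ralston        19982  3.88  9.80   -15.3     23.1  10.5   6.40  66.4  94.3 FALSE            18
```

Each row is one method's performance on the simulated cohort: bias (`mpe`,
in %), precision (the LOA and RMSPE), overall accuracy (`p10`, `p20`), the
acceptability flag (p10 ≥ 70% **and** p20 ≥ 95%) and how many records fell
outside that tape's length range. On this synthetic cohort the fixture
PAWPER XL-MAC tape is the most accurate within-10% estimator and the
fixture Broselow 2011A the least — a shape comparison of the *framework*,
not a statement about the physical tapes.

Paired comparisons against a reference method:

```r
cmp <- compare_all(cohort, reference_method = "pawper_xl_mac")
dplyr::filter(cmp, metric == "p10")[, c("method_b", "value_a", "value_b",
                                        "odds_ratio", "p_value")]
#>   method_b       value_a value_b odds_ratio   p_value
#> 1 broselow_2007B    67.1    64.0       1.15 8.53e- 11
#> 2 broselow_2011A    67.1    48.9       2.08 6.66e-278
#> 3 ralston           67.1    66.4       1.03 1.56e-  1
```

`odds_ratio` is the matched-pairs b/c ratio on discordant within-10%
flags; `p_value` the McNemar test (exact below 25 discordant pairs,
continuity-corrected chi-square above).

When a publication prints only a method's MPE and 95% LOA, its p10/p20 can
be imputed under normality:

```r
impute_p_within(mpe = -1.6, loa_low = -23.2, loa_high = 19.9, threshold = 10)
#> [1] 63.18589
```

i.e. an estimated 63.2% of that method's estimates fell within 10% of
measured weight.

Plots: `autoplot(report, type = "forest")` draws the bias/precision forest
plot (MPE points, LOA whiskers, ±5% bias band, ±20% LOA guides);
`autoplot(report, type = "accuracy")` the p10/p20 bars against the 70%/95%
acceptability lines.

A thin command-line wrapper is installed at `inst/cli/weightape.R`
(subcommands `simulate`, `estimate`, `evaluate`, `compare`, `report`,
`validate-calibration`).

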