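---
title: "Virtual validation of paediatric weight-estimation tapes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual validation of paediatric weight-estimation tapes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weightape)
```

## The problem

When a child cannot be weighed — during resuscitation, or in settings
without scales — drug doses must be calculated from an *estimated* weight.
Length-based tapes are the standard bedside tools: the child's recumbent
length selects a segment of the tape, and the segment carries a weight.
One-dimensional tapes (Broselow) stop there; two-dimensional systems add a
habitus adjustment, either visually or, in the PAWPER XL-MAC system,
objectively via mid-arm circumference (MAC): each length segment prints MAC
cut-off values, and the measured MAC selects one of up to seven habitus
columns. The Ralston method is a three-tape variant that switches between
parallel length tapes by the WHO wasting MAC bands (severe < 115 mm,
moderate 115–125 mm, normal > 125 mm).

A *virtual* validation study applies these lookup rules to a database of
anthropometric measurements rather than to children directly: every record
with length, MAC and a measured weight yields one estimate per method, and
the estimates are scored against the measured weights. **weightape**
implements that whole workflow — estimators, accuracy statistics, subgroup
reporting, paired method comparisons — plus a synthetic cohort generator so
each stage is testable offline.

## Accuracy framework

For measured weight $W$ and estimate $\hat W$, the signed percentage error
is

$$PE = 100 \times \frac{\hat W - W}{W},$$

negative for underestimation. A method's performance panel is:

* **bias** — mean percentage error, $MPE$;
* **precision** — the Bland–Altman 95% limits of agreement
  $MPE \pm 1.96\,SD(PE)$ (sample SD, $n-1$ denominator, the Bland–Altman
  convention) and the root mean square percentage error
  $RMSPE = \sqrt{\sum PE^2 / n}$;
* **overall accuracy** — $p10$ and $p20$, the percentage of estimates with
  $|PE|$ within 10% and 20% (threshold inclusive).

A method is *acceptable* when $p10 \ge 70\%$ and $p20 \ge 95\%$ (both
inclusive, configurable). Validation reports often print RMSPE with a
second parenthetical value whose definition varies between publications;
`accuracy_summary()` reports the SD of $|PE|$ (`ape_sd`) as a clearly
labelled companion spread measure, which is our interpretation, not a
standard.

### Imputing p10/p20 from printed summaries

Published tables sometimes print only MPE and LOA for a method. If the
percentage errors are approximately normal — $PE \sim N(\mu, \sigma)$ with
$\mu$ the MPE and $\sigma$ recovered from the LOA width as
$\sigma = (LOA_{high} - LOA_{low}) / (2 \times 1.96)$ — then

$$p_t = 100\left[\Phi\!\left(\frac{t-\mu}{\sigma}\right) -
        \Phi\!\left(\frac{-t-\mu}{\sigma}\right)\right]$$

for threshold $t$ (10 or 20). Two modelling points deserve emphasis. First,
the integral is taken over the *error* distribution on $[-t, +t]$, centred
at zero, not over the weight distribution: this is the only reading under
which published imputed subgroup cells reproduce from their printed MPE/LOA
inputs, and `impute_p_within()` implements it. Second, $\sigma$ is
recovered from the symmetric LOA *width* rather than from either limit
alone, which makes it robust to one-sided rounding of published limits.
The imputation's accuracy under normality is verified in the test suite
against quadrature and against Monte-Carlo samples of $10^6$ errors across
twelve $(\mu, \sigma)$ pairs spanning the range seen in published tables
(agreement within 0.2 percentage points).

### Paired comparisons

Two methods applied to the same records are compared pairwise on the
records where both produced an estimate:

* $p10$/$p20$ — McNemar's test on the discordant within-threshold flags.
  With $b$ = accurate-under-A-only and $c$ = accurate-under-B-only, the
  continuity-corrected chi-square $(|b-c|-1)^2/(b+c)$ (1 df) is used for
  $b + c \ge 25$ and the exact doubled-tail binomial test below that — the
  standard small-sample practice; the switch point is configurable. Effect
  size is the matched-pairs odds ratio $b/c$ with log-scale 95% CI
  $\exp(\ln(b/c) \pm 1.96\sqrt{1/b + 1/c})$; zero cells get a ½
  continuity correction and are flagged. The $b/c$ construction is an
  assumption: published reports rarely state how their matched odds ratios
  were formed.
* $MPE$ — the paired t-test on the signed errors.
* RMSPE has no per-record decomposition, so no exact paired test exists
  for it; the paired t-test on $|PE|$ is offered as the nearest defensible
  analogue and labelled `ape`.

Defaults follow large-database practice: significance at $p < 0.001$
(multiple comparisons on very large $n$), clinical importance at an
absolute difference above 10 percentage points. Both are arguments, not
constants.

## Growth reference machinery

Z-scores use the LMS parameterisation: $z = ((X/M)^L - 1)/(LS)$, with the
log-limit form when $L = 0$, and the exact inverse
$X = M(1 + LSz)^{1/L}$. For the weight-based indicators (weight-for-age,
weight-for-height, BMI-for-age) the survey-convention *restricted*
adjustment is applied beyond $\pm 3$ SD: $z' = 3 + (X - SD3)/(SD3 - SD2)$
above, mirrored below, making the extreme scale linear in the measurement.
It is on by default in the pipeline and off in the low-level transforms,
whose round-trip exactness (to $10^{-9}$) is a tested property.

(L, M, S) are linearly interpolated between grid rows; age-based
indicators use completed months, weight-for-height uses length in cm.
Out-of-grid queries raise an error carrying the valid interval at the
operation level, while the pipeline (`derive_indicators()`) flags such
records (`ref_in_range = FALSE`) instead of dropping them.

Classification bins follow the printed conventions exactly, including edge
inclusivity: BMI-for-age habitus bins ($Z \le -2.0$ underweight;
$-2.0 < Z \le -1.4$ thin; $-1.4 < Z < 1.4$ normal; $1.4 \le Z < 2.0$
overweight; $Z \ge 2.0$ obese) and the three-grade wasting/underweight/
stunting schemes ($Z \ge -2.0$ normal; $-3.0 \le Z < -2.0$ moderate;
$Z < -3.0$ severe). Published table footnotes occasionally typeset the
moderate band as "$-2.0 < Z \le -3.0$", which is internally inconsistent;
we follow the prose meaning, with $Z = -3.0$ moderate and $Z = -2.0$
normal.

Survey files usually ship pre-computed z-scores; `derive_indicators()`
passes them through by default (`use_existing = TRUE`) and only computes
what is missing, since a study may wish to preserve the source's own
reference version. BMI-for-age is always computed, as surveys typically
omit it.

## Estimator conventions

* Length segments are half-open $[lower, upper)$ cm intervals; a boundary
  length belongs to the higher segment. This removes double membership and
  matches head-to-heel tape reading.
* A MAC exactly equal to a printed cut-off selects the *higher* habitus
  category, mirroring the inclusive-lower reading of the Ralston "115 to
  125 mm" band. Stated once here, tested everywhere.
* Ralston bands: severe strictly below 115 mm, moderate the closed
  [115, 125] mm, normal strictly above 125 mm.
* MAC is held in cm internally; the mm boundary values are as printed on
  the tape, and `mac_unit = "mm"` inputs convert before lookup, so either
  unit yields identical estimates.
* Lengths outside a tape yield a flagged, counted non-estimate rather than
  an error; the reporting layer excludes such records from that method's
  cells only and always reports the counts.

Calibrations are pluggable data files validated at load time (contiguous
segments, increasing cut-offs and weights, habitus arity). The shipped
fixtures are **synthetic**: per-segment weights are the synthetic
reference's median weight-for-length, spread across habitus columns by the
reference's own LMS spread, with MAC cut-offs placed by the MAC model at
the habitus z boundaries. They exercise every code path with realistic
shapes but are non-clinical; results computed on them characterise the
framework, not any marketed tape. The clinical PAWPER XL-MAC cut-off
tables are published separately from validation reports and load through
`read_calibration()` like any other external artifact. Whether the
physical tape treats its topmost segment as open-ended is not modelled:
the loader requires explicit bounds.

## The synthetic cohort generator

`simulate_cohort()` emulates the marginal structure of pooled nutritional
surveys of children aged 6–59 months from low- and middle-income
countries:

| quantity | default | source of the target |
|---|---|---|
| proportion male | 0.506 | survey demographic tables |
| age | uniform over 6–59 completed months | median 30 months, configurable |
| HAZ | $N(-1.5, 1.5)$ | survey marginal |
| WHZ | $N(-0.6, 1.2)$ | survey marginal |
| MAC | linear model, marginal mean 14.2, SD 1.3 cm | survey marginal |
| rounding | 0.1 cm / 0.1 kg / 0.1 cm | survey convention |

Lengths are obtained by inverting the height-for-age reference at the
drawn HAZ; weights by inverting weight-for-height at the resulting length
and drawn WHZ. Draws whose length falls outside the weight-for-height grid
are redrawn up to a capped retry count and otherwise dropped with a
logged count.

Only marginals are published, so the joint structure is a modelling
choice: HAZ and WHZ independent given age, and MAC linear in age and WHZ
plus Gaussian noise,
$MAC = 14.655 + 0.02\,(age - 32.5) + 0.7583\,WHZ + \varepsilon$,
$\varepsilon \sim N(0, 0.876)$. The coefficients were derived analytically
from the targets: the WHZ slope gives corr(MAC, WHZ) $\approx 0.7$
($0.7583 \times 1.2 / 1.3$), the age slope contributes weakly, and the
residual SD closes the variance budget to $1.3^2$. The uniform age default
approximates the published median of 30 (uniform midpoint 32.5); an
interquartile-matched alternative is a configuration away. The real
MAC–WHZ dependence in source surveys is unknown; 0.7 is a free parameter,
not an estimate.

The generator retains latent (pre-rounding) values so that recovery is
testable: `derive_indicators()` applied to an unrounded cohort reproduces
the latent WHZ/HAZ exactly inside $\pm 3$ SD (outside, the restricted
adjustment intentionally departs from the plain LMS inverse). What the
generator does **not** emulate: survey design effects and clustering,
seasonality, country-level heterogeneity beyond a region label, secular
trends over the collection period, and measurement error correlated
between instruments. Passing tests on synthetic cohorts therefore
demonstrate correctness of the machinery and calibration of the
statistics, not field performance of any tape.

`inject_error_structure()` bypasses the estimators entirely, attaching
pseudo-method estimates with known $N(\mu, \sigma)$ percentage errors.
This is the backbone of the calibration tests: at $10^6$ children the
pipeline recovers an injected $(\mu = 2, \sigma = 8)$ to within 0.05 on
MPE, 0.1 on each LOA limit and 0.2 percentage points on p10 against the
analytic value — sizes chosen so Monte-Carlo error is well inside those
bands.

## Numerical and reporting choices

* Bin edges: "≤10 kg" inclusive, "10.1 to 15 kg" read as (10, 15],
  ">15 kg" exclusive-lower; age bins on completed months with 49–59
  rendered ">48 months"; subgroup assignment is tested to be a partition
  with unassigned records counted.
* Report cells are order-independent (floating-point sums aside) and empty
  bins produce $n = 0$ cells with `NA` statistics, never a crash.
* Report outputs (`write_report()`) carry a provenance block — package
  version, seed, config hash — sufficient to reproduce a run byte-for-byte;
  the CLI's determinism is a tested contract.
* Country → region mapping is an editable lookup file; unknown countries
  go to an `"unassigned"` stratum.

## Limitations

The headline accuracy figures of published large-database validations
(overall p10/p20 per method on ~1.7M children) are **not** reproducible
from this package alone: they require the external open survey dataset and
the clinical calibration tables, neither of which is shipped. The package
documents that path — `read_cohort()` for the survey file,
`read_calibration()` for real tapes, `read_lms_table()` for a real WHO
reference — and reproduces at desk scale exactly those published
quantities that are functions of printed inputs: the imputed Ralston
subgroup accuracy cells and the headline relative-accuracy contrasts.
Everything else is verified against constructions whose truth is known by
design.
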