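---
title: "Methods: repeated-measures agreement and trending for cardiac index monitors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeated-measures agreement and trending for cardiac index monitors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cicompare)
```

# The problem

A new cardiac output monitor is validated by reading it simultaneously with
a reference method — bolus thermodilution through a pulmonary artery
catheter — many times per patient across clinically distinct phases of
surgery and intensive care. The analysis must answer three questions:
does the device read systematically high or low (*bias*), how far can an
individual pair of readings disagree (*limits of agreement*, *percentage
error*), and does the device track changes in the right direction
(*trending*)? Because measurements repeat within patients, every one of
these statistics needs a clustered treatment; `cicompare` provides that
chain end to end.

Throughout, cardiac index (CI, L·min⁻¹·m⁻²) is used rather than raw cardiac
output, and the difference sign convention is **test − reference**: a
positive bias means the test device overestimates. Both conventions are
echoed in all outputs.

# Agreement model

## Variance components

For differences $d_{ij}$ (patient $i = 1..k$, repeat $j = 1..m_i$,
$N = \sum m_i$) we fit the one-way random-effects ANOVA

$$d_{ij} = \mu + a_i + e_{ij}, \qquad a_i \sim (0, \sigma_b^2),\;
e_{ij} \sim (0, \sigma_w^2),$$

estimated by the method-of-moments ANOVA estimator: $\hat\sigma_w^2 =
MS_w$, $\hat\sigma_b^2 = \max\{0, (MS_b - MS_w)/n_0\}$ with
$n_0 = (N^2-\sum m_i^2)/((k-1)N)$ the effective per-patient count for
unbalanced designs. This is the appropriate Bland–Altman adjustment when
the true quantity varies between the repeated measurements (the patient's
CI genuinely changes during surgery), as opposed to repeated measurements
of a constant quantity. The total SD entering the limits of agreement is
$\sqrt{\hat\sigma_b^2+\hat\sigma_w^2}$, and

$$\mathrm{LOA} = \bar d \pm z\,\mathrm{SD}_{tot}, \qquad z = 1.96
\text{ fixed}.$$

$z$ is deliberately not $t$-adjusted — the 1.96 convention is what the LOA
literature and clinical consumers expect; small-sample uncertainty is
expressed through the confidence intervals instead.

Assumptions worth stating: differences are exchangeable within patient
(no residual serial correlation of the *errors* — the underlying CI may
drift, but the device errors at different timepoints are independent), and
approximately normal. Negative between-patient variance estimates are
truncated at zero and flagged (`between_truncated`), standard practice for
ANOVA estimators.

Degenerate designs are handled explicitly: with one measurement per
patient the within component has zero degrees of freedom and the estimator
collapses, exactly, to the ordinary sample SD of the differences
(`n0 = 1`, $\sigma_w^2 = 0$); with a single patient the between component
is undefined and the function refuses.

## Confidence intervals

* **Bias**: $\bar d \pm t_{k-1}\sqrt{(\hat\sigma_b^2\sum m_i^2 +
  \hat\sigma_w^2 N)/N^2}$. The $t$ reference uses $k-1$ df because
  patients, not measurements, carry independent information.
* **LOA limits** (default **MOVER**): each mean square gets a chi-square
  interval on its own df; the intervals for the components of
  $\widehat{\mathrm{Var}} = MS_b/n_0 + (1-1/n_0)MS_w$ are combined by the
  square-and-add (method of variance estimates recovery) rule, converted
  to an interval for $\mathrm{SD}_{tot}$, and finally combined — again by
  squaring and adding margins — with the normal-theory uncertainty of
  $\bar d$. A first-order **delta**-method interval
  ($\mathrm{Var(limit)} = \mathrm{Var}(\bar d) + z^2\mathrm{Var(SD)}$,
  $\mathrm{Var(SD)} = \mathrm{Var}(\widehat{\mathrm{Var}})/(4\,\mathrm{SD}^2)$,
  $\mathrm{Var}(MS) = 2MS^2/df$) is available as an option. MOVER is the
  default because its small-$k$ coverage is better; the two agree closely
  on large balanced designs (the tests require within 10% of interval
  width at 200×30), and both reduce to within a few percent of the
  classical $SE(\mathrm{LOA}) = \mathrm{SD}\sqrt{3/N}$ formula when every
  patient contributes one measurement. With the default 20×29 design the
  test suite measures empirical coverage of bias and both limits over 500
  simulated cohorts and requires all three inside [0.92, 0.97].
* **Percentage error**: $PE = 100\,z\,\mathrm{SD}_{tot}/\overline{CI}$.
  The denominator is the mean of the *reference* device by default —
  percentage error is defined against the reference in the original
  precision literature — but the mean of the pairwise means is available
  (`denominator = "both"`), since part of the literature uses it; the
  choice is recorded in the result. The CI is a patient-level cluster
  bootstrap (resample patients with replacement, B = 2000 by default,
  percentile interval, explicit seed): no closed form respects the
  clustering, and the bootstrap's patient resampling does.
* **Proportional bias**: OLS of difference on pairwise mean; the slope's
  interval uses patient-clustered sandwich standard errors on $t_{k-1}$ —
  naive OLS SEs ignore within-patient correlation. The slope is reported
  unstandardized, sign preserved: reporting "absolute values" in the sense
  of magnitudes would discard the direction of the proportionality, and
  per-phase coefficient tables in this field do contain negative
  coefficients.

# Trending

Consecutive within-patient changes are computed per device relative to its
own earlier reading ($100(CI_t - CI_{t-1})/CI_{t-1}$) — the standard
four-quadrant convention; pairs never span patients, so a contiguous
series of $N$ measurements from $k$ patients yields exactly $N-k$ pairs.

**Error grid.** Each pair of changes is binned by magnitude — `none`
(<5%), `moderate` (5–15%, closed interval on both ends; the boundary
reading of "between 5–15%" is inclusive and tested at exactly 5 and 15) —
and `large` (>15%), then classified:

| zone | rule | clinical meaning |
|------|------|------------------|
| 1 | both `none`, or same sign and same bin | decisions agree |
| 2 | same sign, different bins | under-/over-treatment |
| 3 | exactly one `none` | unnecessary or withheld treatment |
| 4 | both ≥5%, opposite signs | opposite treatment |

A sub-5% change is treated as "no change", so two sub-5% changes are
concordant (zone 1) regardless of nominal sign. The classifier is verified
exhaustively against an independently written brute-force implementation
over a 49-cell grid and random sweeps. Grids computed from fewer than 30
pairs (configurable `min_n`) are flagged *not reported* — percentages from
two dozen changes are noise — which automatically suppresses output for
sparsely measured phases.

**Four-quadrant concordance.** Pairs where *both* devices moved less than
the exclusion threshold (default 10%, or an absolute L·min⁻¹·m⁻²
threshold in `absolute` mode) are excluded — tiny changes carry no
directional information; concordance is the percentage of retained pairs
with equal signs. The configured threshold and mode are always echoed in
the result, since published studies vary in their choice and a concordance
rate is uninterpretable without it.

**Phase stratification.** Deltas are formed on the full contiguous series
and assigned to the phase of their *endpoint*; an $N$-measurement,
$k$-patient study therefore contributes $N-k$ deltas in total, and per-phase
trending uses the endpoint subset. Forming deltas within phases instead
would discard every phase-boundary transition and change the total count.

# Sample-size calculations

Two designs are implemented:

* **TOST equivalence**, normal approximation, paired differences:
  $N = 2(z_{1-\alpha} + z_{1-\beta/2})^2 \mathrm{SD}^2 / (\delta - |\Delta|)^2$.
  The $z_{1-\beta/2}$ term (rather than $z_{1-\beta}$) is the two
  one-sided-tests convention: both tests must reject. With SD 0.7,
  margin 0.36, true difference 0.2, α 0.05, power 0.9 this gives
  414.29 → N = 414. The factor 2 comes from the cited convention for
  comparative designs and is kept for auditability (`z_alpha`,
  `z_beta_half` and the raw N are returned); at the resulting N the
  one-sample TOST power is well above nominal, which the test suite
  verifies empirically (rejection rate ≥ 0.88 over 2000 replicates).
  The calculation treats repeated measurements as independent — no
  design-effect correction — and the documentation of the result says so;
  users with strongly clustered data should treat the returned N as a
  lower bound on measurements, not patients.
* **LOA precision** (Bland): $SE(\mathrm{LOA}) \approx \mathrm{SD}\sqrt{3/N}$,
  so a target 95% CI half-width $h$ for a limit needs
  $N = 3(1.96\,\mathrm{SD}/h)^2$; SD 0.7 and $h$ = 0.2 give 141.18 → 141.
  The 0.2 here is interpreted as the *half*-width of one limit's CI: the
  full-width reading would quadruple N, contradicting the construction.

Both functions round to the *nearest* integer rather than ceiling — the
raw values are returned alongside, and nearest-integer is what reproduces
the published convention these formulas follow; a conservative user can
apply `ceiling()` to `n_raw`.

# The synthetic cohort generator

There is no public raw dataset of this design, so the package ships a
generator whose defaults emulate the study conditions such analyses face:
20 patients × 29 measurements (~580 pairs), cohort mean CI 2.4 with
between-patient SD 0.4, four named OPCAB phases in clinical order
(pre-induction baseline, aortic side-clamp, distal anastomoses at a true
CI 0.3 lower, pre-extubation ICU) in roughly the per-phase proportions of
such a series (24:27:85:104 named-phase measurements per 579), AR(1)
within-patient drift (coefficient 0.8, innovation SD 0.25 — the
autocorrelation of intraoperative CI is not identified by published
summary statistics, so this is a free parameter, and all tests treat it as
such), a reference device with multiplicative error CV 0.10 (the ±20%
precision conventionally quoted for thermodilution equals 1.96 × CV), and
a test device with constant bias 0.13, no proportional bias, patient-level
offset SD 0.3 and noise SD 0.58. The last two were chosen once so that the
implied total difference SD is ≈0.70 L·min⁻¹·m⁻², the scale reported for
bioreactance-vs-thermodilution comparisons; `expected_agreement()`
documents the implied decomposition term by term and the derivation is
verified against Monte-Carlo moments (within 2%) in the tests.

Design choices: reference noise is multiplicative (thermodilution
precision is quoted proportionally) while test-device noise is additive
(matching the additive bias/LOA scale of agreement tables). Truncation at
0.5 (true CI) and 0.1 (test reading) L·min⁻¹·m⁻² uses fixed floors rather
than rejection sampling so that row counts and seeds stay deterministic;
the floors sit below any physiological interest and are essentially never
hit at default settings, which is why the closed-form moments ignore them.
Phase effects shift the true CI only — there is no phase-specific device
error by default, though per-phase configs can emulate it.

What the generator does *not* emulate: calibration drift and step changes
after device recalibration, phase-dependent error structure, missingness,
alignment error between devices' clocks, and non-normal (e.g. skewed)
error distributions. Passing parameter-recovery and coverage tests on this
generator therefore shows the estimators are correct under the stated
model, not that any real device satisfies that model.

# Numerical and interface choices

* Time is an integer index; real clock times are accepted on import and
  converted to within-patient ranks (only order matters for deltas).
* Phase is an explicit column, never inferred from time: phases are
  defined clinically and data cannot reconstruct them.
* CSV round trips preserve numeric values to ≥12 significant digits
  (values are written at full double precision).
* Every stochastic step (generator, bootstrap) takes an explicit seed,
  restores the caller's RNG state, and records the seed in its output;
  reports are byte-identical across reruns with the same seed (modulo the
  optional timestamp).
* Zero-variance inputs degrade gracefully: zero-width CIs with a warning
  flag rather than NaNs.
* Test problem sizes: oracle sweeps use 200 random small ANOVA datasets;
  parameter recovery uses 200 patients × 30; Monte-Carlo moment checks use
  ≥10⁵ pairs; CI calibration uses 500 replicates of the 20×29 design and
  2000 TOST replicates.

# Limitations

The ANOVA estimator is method-of-moments, not REML; for severely
unbalanced designs with few patients a mixed-model fit would be more
efficient (deliberately out of scope — the transparent ANOVA chain is what
the agreement literature specifies). Devices are analyzed one at a time
against the reference; no fused multi-device statistic is computed.
Polar-plot trending is not implemented. The equivalence N ignores
clustering, as noted above.
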