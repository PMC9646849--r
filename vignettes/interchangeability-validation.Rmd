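---
title: "Validating automated measurements against a multi-reader panel: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating automated measurements against a multi-reader panel: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iecval)
```

## The problem

A core echocardiography laboratory asks whether a fully automated
measurement source can replace — not merely correlate with — expert human
readers. Correlation-style metrics cannot answer that question, because a
replacement claim is about *disagreement*: the machine is interchangeable
with a human reader exactly when swapping it into the reading panel adds no
more disagreement than swapping one human for another. This is the logic of
individual bioequivalence, transplanted to measurement readers.

`iecval` implements that framework for the standard design of a core-lab
validation: each study (one patient's echocardiogram, any of 23 catalogued
parameters) is read independently by three human experts `R1, R2, R3` and
by the automated source `AUTO`. Missing reads are represented by absent
records, never by sentinel values — the automated workflow in particular is
allowed to withhold output on quality grounds, which is why yield is a
first-class endpoint rather than a nuisance.

## The individual equivalence coefficient

For studies $i = 1..n$ with human reads $h_{i1}, h_{i2}, h_{i3}$ and
automated read $a_i$, define

$$Q_{TR} = \frac{1}{3n}\sum_i \sum_{j=1}^{3} (a_i - h_{ij})^2, \qquad
  Q_{RR} = \frac{1}{3n}\sum_i \sum_{j<k} (h_{ij} - h_{ik})^2,$$

the mean squared test-versus-reference and reference-versus-reference
differences. The individual equivalence coefficient is

$$\mathrm{IEC} = \frac{Q_{TR} - Q_{RR}}{Q_{RR}/2}.$$

Under additive within-patient errors — human reads
$h_{ij} = \mu_i + e_{ij}$ with $e_{ij} \sim (0, \sigma_R^2)$ and automated
reads $a_i = \mu_i + u_i$ with $u_i \sim (0, \sigma_T^2)$ —
$E[Q_{TR}] = \sigma_T^2 + \sigma_R^2$ and $E[Q_{RR}] = 2\sigma_R^2$, so the
IEC estimates $\sigma_T^2/\sigma_R^2 - 1$: it is 0 when the automated
source is exactly as variable as a human reader, negative when it agrees
with the humans *better* than they agree with each other, and +0.25 when
its error variance is 25% higher. The statistic is dimensionless and
invariant under affine rescaling of the measurements, so the 23
heterogeneous parameters (mm, ml, %, cm/s, ...) share one decision scale.

### Non-inferiority rule

The decision rule is one-sided with margin $\Delta = 0.25$: the automated
source is judged non-inferior when

$$\mathrm{IEC} + 1.96 \cdot \mathrm{SD}(\mathrm{IEC}) \le 0.25,$$

with $\mathrm{SD}(\mathrm{IEC})$ estimated by bootstrap over studies
(10,000 replicates by default). Three choices here were genuinely open and
are fixed as follows:

* **Resampling unit.** Whole studies (quadruples) are resampled, never
  individual readers, preserving the within-study correlation that the
  statistic is about.
* **Interval form.** The bound is the normal approximation
  `point ± 1.96·sd_boot`, because the decision rule is stated in terms of
  the SD of the IEC; percentile 2.5/97.5% bounds are computed and reported
  alongside but never drive the verdict.
* **Boundary.** Equality with the margin counts as non-inferior, since
  inferiority is declared only when the bound strictly exceeds it.

A bootstrap replicate whose resampled $Q_{RR}$ is exactly zero leaves the
IEC undefined; such replicates are redrawn and counted (`n_redraws`), so
`n_boot` is always honoured. With continuous measurements this is a
measure-zero event; it matters only for pathological inputs such as
constant readers.

## Yield

Per parameter, the yield is $x/n$: of the $n$ studies with all three human
reads, the fraction $x/n$ for which the automated workflow also emitted a
value. Its interval is formed from the 0.05 and 0.95 quantiles of
$\mathrm{Binomial}(n, x/n)$, divided by $n$, with the usual quantile
convention (smallest $k$ with CDF $\ge q$). This is a quantile band of the
fitted binomial rather than a coverage-calibrated confidence procedure; we
implement the stated rule exactly and expose the quantile levels as
arguments rather than silently substituting a Clopper–Pearson or Wilson
interval. The package ships the published core-lab counts
(`corelab_yield_counts()`) as a worked example; their unweighted mean
yield is 0.88.

## Secondary agreement battery

All secondary metrics operate on a complete-case studies × readers matrix
for a chosen reader set (all four readers, or the three humans only).
Several definitions had to be pinned down where convention varies:

* **ICC.** Two-way random-effects, absolute-agreement, single-measurement
  — ICC(2,1) — computed in closed form from the crossed-ANOVA mean
  squares. Readers are a random sample of a reader population and
  systematic reader offsets should count against agreement, which rules
  out the consistency and one-way forms; the closed form replaces an
  iterative mixed-model fit for exactness and is cross-checked in the
  tests against R's own `lm`/`anova` route.
* **MAD.** Mean over studies of the mean absolute difference over all
  unordered reader pairs, in measurement units.
* **wCV.** $100\sqrt{\mathrm{mean}_i(s_i^2/m_i^2)}$ — the root mean
  squared per-study coefficient of variation. One auditable definition is
  implemented; pooled-SD-over-grand-mean variants are not.
* **RMSE.** Root mean square of the double-centred residuals
  $y_{ij} - \bar y_{i.} - \bar y_{.j} + \bar y_{..}$ on $(n-1)(k-1)$
  degrees of freedom, i.e. the spread left after additive study and
  reader effects. It is exactly zero when each reader is a constant
  offset from the others, which is the natural notion of
  "additive-perfect" agreement.
* **CCC.** Lin's concordance correlation with population ($1/n$) moments.
* **LOA.** Bland–Altman mean difference ± 1.96 × sample SD of the
  differences.
* **CP.** Coverage probability: the fraction of paired differences within
  a tolerance `cp_delta`. No universal tolerance exists across parameters
  measured in different units, so `cp_delta` is a required user input
  (per parameter if desired) and is reported back alongside the value.
* **Pairing.** CCC, LOA and CP compare the automated read against the
  per-study mean of the three human reads, giving one summary per
  parameter; per-individual-reader pairings can be formed with
  `generalized_iec()` and the vector-level functions.
* **Relative absolute differences.** For box-plot style comparisons, the
  human–human distribution pools $|h_j - h_k| / \frac{h_j+h_k}{2}$ over
  the three pairs and the automated–human distribution pools
  $|a - h_j| / \frac{a+h_j}{2}$ over the three readers. The denominator
  is the pair mean, keeping the statistic symmetric in its two arguments;
  pairs with mean zero are excluded and counted. Summaries report median,
  quartiles and 1.5·IQR whiskers.

## The synthetic generator

Because core-lab images and reads are contractually private, the package
carries a generator that emulates the *statistical* structure the analysis
assumes, so every stage is testable and parameter recovery is checkable:

$$\mu_i \sim N(\texttt{truth\_mean}, \texttt{truth\_sd}^2), \quad
  y_{ij} = \mu_i + \beta_j + e_{ij}, \quad
  a_i = \mu_i + \beta_A + u_i,$$

with i.i.d. normal errors ($e_{ij} \sim N(0,\sigma_R^2)$,
$u_i \sim N(0,\sigma_T^2)$), reader biases $\beta$ defaulting to zero.
Normal errors are the natural choice because the IEC's interpretation as a
variance ratio presumes additive within-patient errors and nothing finer
is identifiable from study-level data.

The automated source's withholding behaviour is modelled by a confidence
score $c_i = 1 - \Phi(|u_i|/\sigma_T) + \varepsilon_i$ (clipped to
$[0,1]$, $\varepsilon_i \sim N(0, \texttt{confidence\_noise\_sd}^2)$); the
read is emitted only when $c_i \ge \tau$. With zero confidence noise the
gate is deliberately missing-not-at-random — exactly the largest automated
errors are suppressed, expected yield is $1 - 2\tau$, and relaxing $\tau$
raises yield while admitting worse reads, reproducing the direction of the
quality-threshold trade-off seen in practice. Setting
`confidence_noise_sd` very large makes suppression effectively independent
of the error (missing-completely-at-random), which is what clean
calibration tests want. The real missingness mechanism of a production
quality filter is not claimed to be either of these; the gate is an
abstraction with the right monotonicity.

`default_suite_configs()` assembles a 23-parameter, 600-study suite:
truth means and SDs at clinically typical magnitudes for a
heart-failure-enriched cohort, $\sigma_R$ at the scale of published
inter-sonographer residual spread, $\sigma_T^2 = \gamma\sigma_R^2$ with
$\gamma = 0.8$ by default (a modestly better-than-human automated source,
matching the direction of published validations), and per-parameter
$\tau$ and human-dropout rates calibrated so expected triple counts and
yields match the published core-lab counts. Calibration solves
$1 - 2\tau = x/n$ for the gate and $n/602 = (1-p_{\text{miss}})^3$ for the
per-read human dropout.

What the generator does **not** emulate: image or video content, beat
selection, heavy-tailed or skewed reader errors, study-level correlation
across parameters (each parameter draws its own truth), or drift in reader
behaviour over time. Passing tests on synthetic data therefore demonstrate
the correctness of the statistical machinery under its stated model, not
the performance of any particular automated workflow on real data.

## Power and sample size

`estimate_power()` answers the design question: with $n$ studies and a
true variance ratio $\gamma$, how often does the bootstrap upper bound
fall at or below the margin? Each simulated trial generates a dataset,
runs the bootstrap, and records the verdict. Two deliberate trade-offs:

* The inner bootstrap defaults to 500 replicates, not 10,000 — the SD
  estimate it feeds into the verdict is nearly as good, and the loop
  stays desk-scale. A confirmatory analysis should still use 10,000.
* Common random numbers across the sample-size grid are on by default, so
  the power curve is monotone up to genuine sample-size effects rather
  than simulation noise.

Under this generative model, $\gamma = 1$ and $n = 600$ put the expected
IEC a full margin below 0.25 and the design comfortably exceeds 80%
power; the test suite re-verifies a scaled-down version of that statement
(40–200 simulated trials with the reduced inner bootstrap) rather than the
full 10,000-simulation design run, which is a fidelity/runtime trade the
package makes explicit rather than hides.

## Numerical and degenerate-input policy

* Q computations precompute per-study squared-difference sums, so a
  bootstrap replicate is a single indexed mean — this is also why
  `iec()` agrees with brute-force enumeration to ~1e-12.
* `iec()` refuses degenerate references ($Q_{RR} = 0$) rather than
  returning ±Inf; `wcv()` refuses within-study means of zero; `ccc()`
  refuses two constant equal series; `coverage_probability()` requires a
  strictly positive tolerance.
* All stochastic entry points take an explicit integer seed, restore the
  caller's RNG state on exit, and derive per-parameter/per-trial
  sub-seeds deterministically (kept below $2^{31}$), so every result in a
  bundle is a pure function of (inputs, seed).
* Display rounding is half-up to 2 decimals where tables are printed;
  machine outputs always carry full precision.

## Known limitations

The IEC compares variances, not biases directly: a constant automated
offset enters through $Q_{TR}$ (raising the expected IEC by
$b^2/\sigma_R^2$) but a bias exactly compensated by reduced noise can
still pass; the Bland–Altman centre should always be read alongside the
verdict. The three human readers are treated as exchangeable draws from
one reader population with a common $\sigma_R$; strongly heterogeneous
reader quality violates that. Study-level reads are the finest granularity
— per-beat or per-video comparisons need a different data model.
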