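---
title: "Methods: simulating and analyzing a sex-stratified disc degeneration and pain study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing a sex-stratified disc degeneration and pain study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivdnet)
```

## The study this package models

`ivdnet` implements the full analysis chain of a preclinical study design
in which male and female rats receive either a sham surgery or an annular
puncture of the lumbar L3/4--L5/6 intervertebral discs (IVDs), and the
relationship between structural disc degeneration and pain is then probed
per sex with a trait--trait correlation network. The design is 2 x 2
(sex x injury) with n = 12 per cell; by default one male-injury and one
female-injury animal are removed after generation, mimicking surgical
attrition, so a default study has 46 animals and per-sex trait tables of
23 rows.

No public data exist for this design, so the package ships a seeded
synthetic study generator that produces every *raw* record -- biomechanical
test traces, von Frey filament response tables, qPCR Ct values,
radiographic disc heights, rater histology subscores -- and the analysis
modules never see anything the generator knows; they reduce raw records
exactly as they would reduce imported real data laid out in the same
long-format CSV schemas (`write_study_csv()` / `read_study_csv()`).

## The latent-variable generator

Each animal carries two latent scores: a degeneration severity
(`injury x (1 + noise)`, so shams are exactly zero) and a nociceptive
sensitivity expressed as a latent log paw-withdrawal threshold. The effect
block of `study_config()` maps these latents to signals, and its defaults
encode the sex-specific effect structure the emulated study reported:

* **Behavior.** The latent threshold starts at 12 g for everyone. Injury
  multiplies the male threshold by 0.35 from week 2 onward; the female
  injury effect is zero *on average*, but the between-animal SD of the
  female injury group is inflated threefold (on the log scale), producing
  highly variable female thresholds without a mean shift.
* **Structure.** Injury raises the histology severity of all five
  subcategories and removes 15% of disc height at the three punctured
  levels in both sexes.
* **Function.** Injury leaves axial, torsional and creep biomechanics
  unchanged (effect ratios of 1); males have ~25% greater torsional
  stiffness, and hence torque range, than females.
* **Expression.** Ct values are `baseline - log2(fold) + noise`, with a
  2-fold up-shift for *Calca* at the L2 DRG and *Tac1* at the L5 DRG in
  injured males only. *Gapdh* carries no effects.

Estrous stage is drawn uniformly over the four stages, independent of all
other latents: the emulated study found no estrous correlate of any
variable, so the generator deliberately builds none in. Surgery date is a
cohort index (six cohorts) independent of everything else.

Every stochastic component is scaled by an entry of the noise block, so
`zero_noise()` yields a fully deterministic generator; the binomial
von Frey sampling is then replaced by its p >= 0.5 step, which is what
makes the zero-noise round trip (below) exact. Where the emulated study
reported no value (noise SDs, baseline heights ~0.9 mm, Ct baselines,
body weights), defaults were chosen once at magnitudes typical for adult
Sprague-Dawley rats and bench qPCR/radiography, and are all configurable.

### Raw signal models

**Creep.** Displacement under constant load F follows the five-parameter
viscoelastic solid model

$$d(t) = F\left[\frac{1}{k_e} + \frac{1}{k_f}\left(1 - e^{-t/\tau_f}\right)
        + \frac{1}{k_s}\left(1 - e^{-t/\tau_s}\right)\right],$$

an elastic stiffness plus fast and slow exponential arms, sampled at 1 Hz
for 1 h at F = -8 N, with additive Gaussian noise.

**Cyclic tests.** Axial tests are load-controlled (+/-8 N, 1 Hz, 20
cycles, 100 Hz sampling) with displacement from separate tensile and
compressive branch stiffnesses; torsional tests are rotation-controlled
(+/-10 deg) with a single stiffness. Hysteresis is generated by an
elliptic phase-lag lens added to the derived channel. The lens is confined
to the inner ~70% of the primary-channel range with a smooth cubic taper,
and its coefficient is calibrated against a high-resolution quadrature of
the unit lens shape so the enclosed per-cycle area equals the requested
hysteresis exactly. Confining the lens matters: the outer 20% of the
range -- the end-range windows where stiffness is fitted -- stays exactly
branch-linear, so the zero-noise generator-to-reduction round trip
recovers stiffness, range of motion and torque range to solver precision
rather than "to first order". A loop this shape must also nest inside the
elastic stroke; the default axial hysteresis (0.5 N mm) is sized so it
does, which is also the physically meaningful regime.

**Von Frey.** For filament force f and latent threshold theta, the
response probability is logistic in log force,
`p(f) = plogis(slope * log(f / theta))` with slope 6, and the observed
count is Binomial(5, p). The filament set is the standard ascending
Touch-Test series 0.4--26 g; the emulated study stated only the range, so
both the set and the response-curve family are configuration, not claims.

## Reductions

* **Paw withdrawal threshold**: the lowest filament with >= 3 of 5
  responses, censored at 26 g; reported as the left/right average, and
  normalized to the week-0 average as a *ratio* (the axis convention for
  a normalized threshold was ambiguous in the source; a ratio keeps the
  quantity positive and scale-free).
* **20th-cycle properties**: end-range stiffnesses are least-squares
  slopes over the loading-branch samples in the outer 20% of the force
  (axial) or rotation (torsional) range -- the loading branch being samples
  whose primary channel moves away from zero, detected by a
  central-difference slope. The 20% window is this package's definition
  (configurable via `window_frac`); the fraction is common practice for
  end-range stiffness in spine biomechanics. Hysteresis is the shoelace
  polygon area of the closed loop, orientation-independent, with the loop
  closed virtually if needed. At 100 samples/cycle the shoelace
  approximates a smooth loop's area to ~0.1%; that quadrature error, not
  the solver, limits the round-trip accuracy of hysteresis.
* **Creep fit**: nonlinear least squares of the model above. Because the
  model is linear in the three compliances once the time constants are
  fixed, initials come from a variable-projection sweep over a log-spaced
  (tau_f, tau_s) grid (5 x 5, inner linear solve per pair), and the best
  start is polished by Levenberg-Marquardt under positivity bounds.
  tau_f < tau_s is a labeling constraint enforced by relabeling, which
  makes the fit invariant to swapping the generator's arms. Total
  displacement is the fitted |d| at the last sample and therefore includes
  the instantaneous elastic jump (the source was silent on this; including
  it keeps `total >= |F|/k_e` as an invariant). Non-convergent fits
  propagate as missing traits, never as exceptions.
* **qPCR**: relative expression is `2^-(Ct_gene - Ct_Gapdh)` within the
  same animal and DRG level. Outliers are flagged per
  sex x injury x gene x level group by ROUT on the constant model:
  median center, robust scale = 68.27th percentile of |residuals| with an
  n/(n-1) correction, candidates tested outside-in by t-ratio against
  `alpha_k = (Q/100) k/n` (Q = 1% by default, at most 30% of a group
  flaggable). The commercial implementation named by the source is
  proprietary; this follows the published description of the procedure.
  Fold change is relative to the same-sex sham mean (outliers excluded
  from the mean); flagged values stay in the records but enter group
  statistics and trait tables as missing.
* **Radiology**: per-level percent height change is `100 (h6 - h0)/h0`;
  the punctured-level summary averages heights across L3/4--L5/6 *first*
  and then takes the percent change of the averages (not the mean of
  per-level changes). `ivd_height_from_borders()` defines disc height as
  the symmetrized mean point-to-polyline distance between evenly resampled
  cranial and caudal borders -- the original image-processing code is
  unavailable, so this geometric definition (with configurable resampling
  density) is the package's own, validated against analytic parallel-line
  and wedge geometries.
* **Histology**: per-category mean of three raters' 0--2 subscores; the
  total grade is the sum of the five category means (0--10).

## Group statistics

`two_way_anova()` fits `y ~ A * B` with sum-to-zero contrasts and reports
Type III sums of squares via `car::Anova`, matching the convention of the
commercial software the emulated analysis used and behaving sensibly on
its mildly unbalanced (n = 11--12) cells; Type II is available by
argument. The repeated-measures structure of the von Frey week factor is
deliberately ignored (crossed two-way ANOVA of injury and time), mirroring
the emulated analysis. Post-hoc comparisons use the Tukey--Kramer
studentized-range adjustment from the cell summaries; for two cells it
reduces exactly to the pooled t-test (q = sqrt(2)|t|), which the tests
exploit as an oracle alongside a projection-matrix decomposition of the
Type III sums of squares.

## Correlation networks

Per sex, `assemble_trait_table()` builds an animals x traits matrix from a
configurable trait dictionary (default 48 traits for males plus ordinal
estrous for females; the full variable roster of the emulated study is not
public, so the dictionary makes no claim to reproduce its exact count).
Injury enters as 0/1 and is correlated by Spearman like everything else;
estrous is coded ordinally in cycle order
(proestrus < estrus < metestrus < diestrus).

`spearman_matrix()` computes tie-corrected rho on pairwise-complete
observations (pairs below `min_n = 4` complete cases are untested) and
p-values the way base R's `cor.test` does: the AS89 Edgeworth null
distribution for untied pairs, the t approximation at df = n - 2 under
ties. This choice is load-bearing: at n ~ 23 the t approximation is ~40%
anti-conservative at the p ~ 1e-4 depths that a Benjamini--Hochberg
correction over ~1000 pairs actually probes, and with it the realized
false-edge rate of an all-null study exceeds the nominal 5%; with AS89 it
is consistent with nominal, which the test suite verifies by simulation.

`bh_adjust()` applies the step-up adjustment once across all testable
pairs within one sex's network (the FDR family is the within-sex network,
never pooled across sexes), and `build_network()` keeps edges with
q <= 0.05, signed by rho. `compare_networks()` reports shared/unique
edges, degrees, a Jaccard index over shared-trait edges, and presence
flags for named edges of interest such as injury--week-6 threshold.
`correlation_power()` gives the analytic two-sided power via Fisher's z
with the r/(2(n-1)) bias term and both rejection tails (the far tail is
negligible except near the null, where it is exactly what makes power
approach alpha); at n = 24 and r = 0.5 it evaluates to 0.726.

## What the simulations do and do not show

Passing tests demonstrate that the pipeline recovers the effect structure
*it generates*: sham/injury separation in grade and height, the male-only
injury--behavior coupling, male/female torsional differences, and FDR
control under independence. Real data differ in ways the generator does
not emulate: trait--trait dependence beyond what the shared latents induce,
non-lognormal biomechanical variation, drift across surgical cohorts,
missingness that is not completely at random, rater bias (as opposed to
rater noise), and any image-level artifacts (no radiographs or slides are
synthesized). Network edge rates measured here therefore validate the
machinery, not the biology.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: constant traits give undefined
rho and are excluded from the FDR family; empty ANOVA cells raise an error
naming the cell; groups of fewer than 4 values skip the ROUT test with a
warning; creep fits that fail from every start return a flagged result
with missing parameters. Tests and the acceptance script use the study's
own sizes where feasible (46 animals, 20 cycles, 3601 creep samples) and
scale Monte-Carlo checks to keep the suite quick: 20 replicate studies for
the network-structure rates, 200 all-null studies of 30 traits for FDR
control (the Monte-Carlo standard error of the mean false-discovery
proportion is then ~0.016, small enough for the 0.07 bound to be
informative), 20 noisy creep curves for parameter recovery, and 10^4
bivariate draws for the power cross-check.
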