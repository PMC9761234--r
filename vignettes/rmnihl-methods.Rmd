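---
title: "Methods: audiogram-shape diagnosis of military NIHL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: audiogram-shape diagnosis of military NIHL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmnihl)
```

## The diagnostic problem

Noise exposure during military service — weapon fire, explosions, often
asymmetric and impulsive — produces hearing loss concentrated at 3–8 kHz,
but not always the clean notch centered at 4 kHz that civilian NIHL
screens target. The methods implemented here diagnose NIHL from the
*shape* of the pure-tone audiogram relative to what age alone would
predict, with explicit, auditable criteria. They are intended for typical
military cases with greater loss at high than at low frequencies; rare
low-frequency or flat-audiogram presentations (e.g. from intense
low-frequency noise and vibration inside vehicles) are outside their
scope, and a negative call there does not rule NIHL out.

Both methods presuppose a clinical history establishing noise exposure of
sufficient intensity and duration and excluding other causes (R0). The
package treats R0 strictly as an input assertion (`exposure_evidence` on
each subject): it gates the individual-level call but is never inferred
from audiometry.

## Age correction: the AAHL surface

All shape statistics compare measured thresholds HTL(*f*) with the median
age-associated hearing loss AAHL(*f*) for the person's age and sex.
`aahl_surface()` models the median as

AAHL(*f*, age) = α(*f*) · (age − 18)²,

the standard ISO-7029 functional form: zero at the reference age 18 and
increasing quadratically. The male α values are calibrated so that the
age-52 surface reproduces the published reference row
(4.6, 7.5, 10.1, 12.4, 15.9, 18.6) dB at (1, 2, 3, 4, 6, 8) kHz, i.e.
α(*f*) = value(*f*)/1156. This is an interpolating model anchored at one
printed row, not a transcription of any particular ISO 7029 edition; users
with tabulated medians can bypass it entirely with the `fixture` backend,
and per-frequency α overrides are accepted. No female per-frequency anchor
row is published, so female use of the model backend requires
user-supplied α values (the female quadratic fits below are shipped as
printed).

`aahl_quadratic()` evaluates the published best-fitting quadratics
*y* = *a* + *b*·age + *c*·age² for the four aggregate measures the
magnitudes use (pairwise AAHL sums at 6+8, 4+8, 3+8 kHz and the 4/6/8 kHz
mean). These coefficients are rounded fits whose implied onset age is
around 23 rather than 18; they agree with the per-frequency surface to
within ~0.1 dB at the age-52 anchor but drift by 1–4 dB over ages 30–60
(the test suite asserts exactly this envelope). For that reason the
diagnosis always uses the per-frequency surface; the quadratics are
provided for completeness and display. Only 3–8 kHz enter the formulas;
1 and 2 kHz are carried for validation and display.

## The two methods

**R1** (both methods): some HTL at 3, 4, 6 or 8 kHz is at least 10 dB
above the HTL "at 1 or 2 kHz". The package reads the reference as
min(HTL(1), HTL(2)) — either low frequency suffices — the more permissive
reading, consistent with the methods' high-sensitivity intent; the
stricter max reference is available via `r1_reference = "max"`. The
published worked example has HTL(1) = HTL(2) and cannot discriminate
between the readings.

**M-NIHL** ear-level call: R1 ∧ (R2a ∨ R2b), with

- R2a: HTL(8) − HTL(6) ≤ AAHL(8) − AAHL(6) − 5, or the 8/4 or 8/3
  difference at least 10 dB smaller than its age expectation;
- R2b: HTL(*f*) ≥ AAHL(*f*) + 20 for some *f* ∈ {4, 6, 8}.

**rM-NIHL** ear-level call: R1 ∧ (Mag(Notch) ≥ 14.5 ∨ Mag(ExcessHF) ≥ 19),
with

- Mag(Notch) = max over *f* ∈ {3, 4, 6} of
  [HTL(*f*) − HTL(8)] − [AAHL(*f*) − AAHL(8)];
- Mag(ExcessHF) = mean(HTL(4, 6, 8)) − mean(AAHL(4, 6, 8)).

A note on the Mag(Notch) sign convention: the source material prints the
age-correction term once as an AAHL *sum* and once as an unbracketed
expression. The worked example (component 7.7 = 5 − (15.9 − 18.6) at the
6-kHz center) is consistent only with the AAHL *difference*, as is the
unbracketed expression parsed left to right, so the difference form is
implemented; a property test checks the two parses agree on random ears.

Numerical conventions: every "at least"/"≥" comparison is inclusive
(an ear with Mag(Notch) exactly 14.5 dB is positive); comparisons are made
on exact unrounded values, with 1-decimal rounding applied only for
display; HTLs are accepted as reals (5-dB clinical steps are not forced).

Individual-level calls combine the two ears under an either-ear or
both-ears rule (each-ear scoring treats ears independently, doubling the
denominator). The revised method does **not** imply the original: the
worked example in the README is M-NIHL-positive yet rM-NIHL-negative, and
the suite keeps such a discordant case.

## Evaluation machinery

`evaluate_cohorts()` scores a case cohort (assumed affected) against a
control cohort (assumed unaffected): sensitivity = positives/cases,
specificity = negatives/controls, and
d′ = Z(sensitivity) − Z(1 − specificity) with Z the inverse normal CDF.
Degenerate proportions (0 or 1) are clamped with the standard 1/(2n)
continuity correction before Z (a fixed ε = 10⁻⁴ when counts are
unknown); the published data never reach these bounds.

`roc_sweep()` fixes one criterion threshold and sweeps the other over a
grid (default step 1 dB, matching the published figure ranges 13–25 dB for
Mag(ExcessHF) and 7.5–20.5 dB for Mag(Notch); the source never states its
step). Because only plausible threshold ranges are swept, the resulting
curves deliberately cover a limited portion of ROC space.
`iso_dprime_curve()` draws the constant-d′ reference curve
sensitivity = Φ(d′ + Z(fpr)).

`select_criteria()` implements the published selection procedure on a
development pair: among candidate (Mag(Notch), Mag(ExcessHF)) threshold
pairs (default 0.5-dB grids) satisfying specificity(either-ear) > 0.6 and
sensitivity(both-ears) > 0.75, it picks the pair that best balances the
two single-trigger false-positive proportions on control ears — the
proportion of ears that are R1-positive and cross the notch threshold
alone versus the excess threshold alone. "Similar" is operationalized as
minimizing the absolute difference (the source reports achieved values
0.124 and 0.108 but no tolerance), and the R1 gate is kept in both
proportions since the requirement structure is unchanged. Infeasible grids
raise an error naming the best infeasible pair.

## The synthetic cohort simulator

Only group-level marginal moments of the four study databases are
published: per-ear, per-frequency HTL means and SDs and age means/SDs for
two noise-exposed databases (n = 143, 142) and two screened control
databases (n = 93, 92), all men aged 29–60. `builtin_cohort_spec()` ships
these moments; `simulate_cohort()` draws:

- age from a normal truncated to 29–60 years;
- the twelve HTLs from a multivariate normal with the spec's marginal
  means/SDs and an exchangeable correlation ρ between every pair of
  frequencies, within and across ears (default ρ = 0.7, a typical
  inter-frequency audiometric correlation — the joint structure is
  unpublished, so this is a modelling choice and all tests of the
  simulator are tolerance-based rather than dependent on ρ);
- HTLs are clipped to the audiometer range [−10, 120] dB HL and, by
  default, quantized to the 5-dB clinical step (set `quantize_step = NULL`
  for continuity-sensitive work);
- control specs apply the published inclusion screen — cross-ear
  asymmetry ≥ 10 dB averaged over 1, 2, 3, 4, 6 kHz is rejected and
  redrawn; screening only removes draws, never edits them.

What the simulator does and does not emulate: it reproduces the marginal
HTL moments (the suite checks every mean to within 3·SD/√n and every SD to
within 15% at n = 1000, screening off) and the exposed groups' average
left-worse-than-right high-frequency asymmetry, which arises from the
marginal means alone. It does not reproduce the joint audiogram shapes of
real claimants — notch prevalence and depth depend on within-ear
correlation structure the source does not report — so published
cohort-level sensitivities/specificities are *not* targets for simulated
cohorts, and passing tests on simulated data show structural correctness
(monotonicity, rule orderings, d′ consistency), not field performance.
Age is drawn independently of HTL (no joint information is published), and
truncating age to the study range shifts the realized age mean slightly
above the nominal control means; both are accepted limitations.

## Problem sizes and determinism

The test suite exercises the full pipeline at sizes chosen to keep the
default run fast while leaving no code path untested: simulated cohorts of
60–185 subjects for evaluation properties, n = 1000 per builtin spec for
moment recovery, and 10,000 random ears for the brute-force oracle checks
of Mag(Notch) and the R2a disjunction. All simulation is seeded;
`simulate_cohort(spec, seed =)` restores the caller's RNG state, and the
CLI `simulate` subcommand is byte-reproducible for a given seed.

## Known limitations

- The per-frequency AAHL model is anchored at a single published age-52
  male row; extrapolation far above age 70 is not guaranteed, and
  percentiles other than the median are out of scope.
- No confidence intervals on sensitivity/specificity/d′, and no
  significance test for comparing d′ between methods.
- No handling of asymmetric-exposure attribution, tinnitus/hyperacusis
  scoring, bone-conduction or masking data, or the low-frequency/flat
  NIHL presentation.
- The criterion defaults (14.5/19 dB) were selected on development
  databases of UK military compensation claimants; transfer to other
  populations should be re-evaluated with `select_criteria()` on local
  data.
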