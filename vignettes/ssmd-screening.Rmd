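---
title: "Scoring single-well plate screens with SSMD*"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring single-well plate screens with SSMD*}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssmdscreen)
```

## The problem

In a phenotypic screen run with live zebrafish embryos, each well of a
96-well plate holds a single embryo exposed to a single compound, and the
readout is one fluorescence number per well (here, a heat-shock-promoter
DsRed reporter of neuronal stress). There is no within-plate replication:
a compound is observed once per plate, and the whole screen is repeated as
a second, independent replicate. Classical assay-window statistics (Z',
S/N, S/B) compare the two control groups and say nothing about how a
single test well should be judged. The estimator this package is built
around — the strictly standardized median difference for single wells,
SSMD*, also called the B value — solves that by treating the plate itself
as the reference: if most compounds on a plate are inert, the plate's test
wells estimate the null distribution, and a well is scored by how far it
sits from that null in robust noise units.

## The model and the estimator

For a plate with ok test-well readings \(X_1, \dots, X_n\), the reference
location is the median \(\tilde X\) and the reference scale is
\(\hat\sigma = 1.4826 \times \mathrm{MAD}\), the usual consistent robust
estimate of the well noise SD. Each ok well \(i\) (test wells and both
control types alike) is scored as

\[
\mathrm{SSMD}^*_i \;=\; \frac{X_i - \tilde X}{\sqrt{2}\,\hat\sigma}.
\]

The \(\sqrt 2\) reflects that the score contrasts one noisy well against a
reference population with the same noise, so the implicit single-well
difference has twice the variance. The published description names the
method but not the estimator variant, so the constant is exposed as
`denominator_constant` in `analysis_config()` and other conventions (for
example, no \(\sqrt 2\)) can be matched exactly. Two consequences worth
keeping in mind:

* The score is invariant under any positive affine transform of a plate's
  readings. Multiplicative plate and day effects — the dominant batch
  structure when the animals differ from clutch to clutch — cancel
  entirely. This invariance is property-tested.
* Because the reference population is itself scored, an inert well's score
  has spread close to \(1/\sqrt 2 \approx 0.707\) *whatever the raw noise
  level is* — shrinking the CV shrinks the denominator by the same factor.
  Single-replicate false positives at a \(\pm 0.5\) cutoff are therefore
  structural, which is exactly why the screen requires concordance across
  two independent replicates before calling a hit.

The replicated-control form `ssmd_controls()` (median of all pairwise
positive-minus-negative differences over their sample SD) and the
conventional metrics (`comparison_metrics()`: Z', S/N, S/B) are provided
for side-by-side comparison, not for hit calling.

## Hit calling and concordance

Per replicate, a test well is classified from its score and status, status
first: a dead embryo is `toxic` and a defective/excluded well `excluded`
before any score is consulted. For ok wells the defaults are strict
inequalities: score \(< -0.5\) inhibitor, \(< -1.0\) strong inhibitor,
\(> +1.0\) activator, otherwise inactive. (The published methods mention a
\(\pm 0.5\) cutoff while the results use \(+1.0\) for activators; the
package defaults follow the results, and all three thresholds are
configurable.)

A final call requires the same hit class in both replicates. A strong
inhibitor in one replicate and a moderate one in the other is concordant
at the \(-0.5\) level, so it is a final `inhibitor`; only a pair of strong
calls is a final `strong_inhibitor`. A hit in one replicate that is
inactive in the other — the pattern made famous by a compound that showed
efficacy once and never again — is `not_replicated` and is never emitted
as a hit. Death in either replicate makes the compound `toxic`,
conservatively, and puts it on the rescreen manifest at 1 and 0.1 uM.
Activator calls carry an informational `autofluorescence_suspect` flag,
because compounds that fluoresce on their own inflate the readout without
touching the pathway; no computational correction is attempted.

## Quality control

Controls carry their own truth, so each plate yields a contingency table
at any threshold: sensitivity \(= 100\,\mathrm{TP}/(\mathrm{TP} +
\mathrm{FN})\) over positive controls, specificity \(=
100\,\mathrm{TN}/(\mathrm{TN}+\mathrm{FP})\) over negative controls, with
a control exactly at the threshold counting as a non-hit (matching the
strict "below threshold" hit definition). `screen_qc()` aggregates plates
as mean ± SD per replicate and threshold; the SD is across plates, since
the per-plate rate is the natural QC unit. Moving the cutoff from
\(-0.5\) to \(-1.0\) can only drop sensitivity and raise specificity on
any fixed screen — this monotonicity is a theorem about nested threshold
sets, and is asserted per plate in the tests. Pass/fail
(`plate_pass_fail()`) is advisory only: a plate fails when its positive
controls show no activity or its reference was degenerate, but no data
are deleted, mirroring a screen in which the positive control was active
on every plate. `control_variability()` reports within-plate and
between-plate CVs of the raw control readings, with a per-day breakdown
when day labels exist.

## Dose-response

`dose_summary()` reports per-dose means, SDs and percent reduction versus
vehicle, and tests for monotone dose-dependence with the Spearman
correlation between dose and per-well fluorescence. Significance comes
from a permutation test (default 1000 permutations, seeded, two-sided on
\(|\rho|\), add-one corrected) because per-dose group sizes are small
(the emulated design uses 12 embryos per dose); no IC50 or Hill model is
fitted, since monotone reduction — not potency — is the claim being
validated. The permutation p-value is uniform under a flat series, which
the acceptance suite checks over 200 seeded runs at coarse resolution.

## What the generators emulate — and what they do not

Two generators cover two distinct validation needs.

`simulate_screen()` draws the study conditions: log-normal well
fluorescence (positive, right-skewed) with CV 15 % by default, a
riluzole-like positive control at a 0.5 multiplicative effect (the
validation experiment showed roughly 50 % reduction with n = 19 per
group), 12 + 12 + 48 occupied wells per plate, one embryo per well, two
replicates, multiplicative plate effects (SD 0.05 on the log scale) and
day effects (SD 0.10, five plates per day), a 2 % background rate of
dead/defective wells, and a mostly inert library with small planted
minorities. The CV and batch SDs are simulator parameters chosen to look
like a healthy live-embryo screen — the real line's between-fish CV is
not published, and nothing here is a claim about it. This generator is
used for power, recovery and QC property tests: recall rising with
planted effect size, percent-reduction recovery, day-effect monotonicity
in the between-plate CV.

`simulate_planted_screen()` answers a different question: does the
score → classify → concordance → summary chain reproduce an exactly known
answer? Under any i.i.d. noise model that is impossible to guarantee —
the \(1/\sqrt 2\) score spread above means a few percent of 1800 inert
compounds would be concordant false inhibitors in every run, and a
moderate inhibitor cannot be confined to the \((-1.0, -0.5)\) band in
both replicates. So the benchmark generator inverts the score map
instead: each plate's scored test wells are constructed so that their
median and MAD are fixed exactly, inert wells sit strictly inside
\((-0.5, 0.5)\) (the tightest possible envelope is \(\pm 0.477\), since
the largest |offset| can never be below the MAD), moderate inhibitors in
\((-0.9, -0.6)\), strong inhibitors in \((-2.2, -1.5)\) and activators in
\((1.5, 2.2)\), with jitter inside each band and random plate/day effects
on top. Classification is then deterministic for every seed while the
data still exercise the full pipeline, including the plate-wise
invariance. Passing this benchmark shows the machinery is exact; it does
not show detection power on noisy data — that is what the stochastic
generator's tests are for. Neither generator models spatial (edge/row)
effects, autofluorescent compounds, or reporter induction kinetics.

## Numerical and design choices

* Readings are long-format CSV (one row per well), so partial plates and
  mixed replicates need no special cases; a plate-shaped grid importer is
  deliberately out of scope.
* A missing reading on an `ok` well is a hard error, never a silent drop:
  silent dropouts would bias the plate median.
* The scored well stays in its own reference by default (the median is
  insensitive to one well of 48); `reference_policy = "test_loo"` gives
  the leave-one-out variant, and `"test_plus_negative"` adds the vehicle
  wells for plates where the inert-majority assumption is doubtful.
* Degenerate references (MAD 0) and references below `min_reference`
  (default 8 wells) are scoring errors, not NA scores; `score_screen()`
  can collect them as flagged plates instead of aborting.
* Percentages in the hit summary are stored exact (`100 * count / n`) and
  only rounded for display, so a 7/2000 rate prints as 0.35 %.
* Problem sizes in the tests (plates of 5–10 wells for oracle
  equivalence, screens of 2–10 plates for properties, 200 runs for null
  calibration, one 2000-compound benchmark screen) keep the whole suite
  in the tens of seconds while leaving every property at the scale where
  it is informative.

## Known limitations

The package analyses one readout per well; image-derived or
multi-channel readouts, spatial normalization (B-score/median polish) and
replicated-design SSMD estimators (UMVUE/MM) are out of scope. Real
screens may violate the inert-majority assumption on pathological plates
(for example, a plate full of actives), in which case the plate reference
is biased — the `test_plus_negative` policy is the escape hatch. Observed
sensitivity/specificity in a real screen depends on biology the
simulators do not model; the package reproduces the formulas, the
threshold trade-off and the limiting behaviour, not any particular
published percentage.

## A worked run

```{r example, eval = FALSE}
sim <- simulate_planted_screen(n_compounds = 2000, seed = 1)
screen <- score_screen(sim$dataset)
hits <- concordant_hits(classify_screen(screen))
hit_summary(hits)
#> Screen hit summary (replicated hits)
#>     threshold n_hits n_screened pct_hits
#>    below -0.5     38       2000    1.9 %
#>      below -1      7       2000   0.35 %
#>       above 1     20       2000      1 %
#>  caused death    142       2000    7.1 %
```
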