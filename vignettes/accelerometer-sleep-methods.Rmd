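---
title: "Methods: diary-free sleep phenotyping from wrist accelerometry, GWAS post-processing and Mendelian randomisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diary-free sleep phenotyping from wrist accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actisleep)
```

## The problem

Large-scale genetic studies of sleep have mostly relied on questionnaire
phenotypes, which approximate a handful of traits and carry recall bias.
Wrist-worn tri-axial accelerometers measure sleep more objectively, but
without a sleep diary there is no annotated bedtime, so sleep must be
located in the signal itself.  `actisleep` implements a heuristic that
does this from the *z-angle* — the angle of the device z-axis relative to
the horizontal plane,

$$\theta = \arctan\!\left(\frac{a_z}{\sqrt{a_x^2 + a_y^2}}\right)\cdot\frac{180}{\pi},$$

which proxies forearm posture and is near-constant while a person sleeps.
The package derives eight phenotypes per individual (nocturnal sleep
duration and its night-to-night SD, sleep efficiency, number of nocturnal
sleep episodes, sleep midpoint, L5 and M10 timing, diurnal inactivity),
applies a quality-control exclusion cascade, and provides the downstream
statistical machinery a sleep GWAS needs: summary-statistic
post-processing and two-sample Mendelian randomisation (MR).

## The detection model

For each recording, summarised at 5-s epochs:

1. **Change metric.** The absolute successive z-angle change is smoothed
   with a *centered* rolling median over 5-min windows
   (`change_metric()`).  The median makes the metric robust to isolated
   posture shifts; centering avoids phase-shifting detected onsets.
   Whether the original implementation centers or trails its window is
   not documented; centering is our choice, isolated behind
   `detection_control(window_minutes=)` and pinned bit-exactly by
   oracle tests.  At the series edges the window shrinks to the
   available range, and an even in-window count uses the interpolated
   median.  The smoothed change series (one shorter than the epoch
   grid) is re-aligned by assigning each change to its earlier epoch
   and repeating the final value; this choice keeps quiet-run
   boundaries within one epoch of the underlying posture change, which
   the noise-free recovery property requires.
2. **Threshold.** Per noon-to-noon day, movement is separated from
   non-movement at `multiplier` x the 10th percentile of the day's
   metric over worn epochs (`day_threshold()`).  The percentile rule is
   the published one; the multiplier 15 and the 0.13 deg floor come from
   the companion open-source implementation and are single named
   configuration values.  Percentiles use type-7 linear interpolation,
   fixed so thresholds are reproducible to the bit.
3. **Bouts and blocks.** Maximal sub-threshold runs of at least 30 min
   are *inactivity bouts*; bouts separated by strictly less than 60 min
   merge transitively into *inactivity blocks*.  The longest block of
   the day is the sleep period time window (SPT-window).  Ties are
   broken by lower mean metric, then earlier start — the source
   publication is silent, and a deterministic rule is required for
   reproducibility.
4. **Sleep episodes.** Inside the SPT-window, maximal runs of epochs
   whose successive raw z-angle changes never exceed 5 deg (strict `>`
   breaks a run, mirroring "no change larger than 5 degrees") and
   lasting at least 5 min are sleep episodes.  The raw angles are used
   here, not the smoothed metric.

Days run noon-to-noon so a nocturnal sleep bout is never split, and
timestamps are reported as hours since the previous midnight, which may
exceed 24 (2 a.m. = 26).

## Phenotypes and exclusions

Sleep duration is the summed episode length; efficiency divides it by
the SPT-window length; the midpoint averages first-episode start and
last-episode end.  L5/M10 are the midpoints of the least-active 5 h and
most-active 10 h, found by sliding windows at epoch resolution over the
ENMO magnitude (Euclidean norm minus 1 g, floored at zero — the
"average acceleration" of the source is not further specified, and ENMO
is the convention of its processing toolchain).  Days with under 16 h of
valid wear contribute no L5/M10.

**A boundary subtlety:** the L5 window (population mean 27.3 h, i.e.
~3:20 a.m.) is interior to a noon-to-noon day, but the M10 window
(population mean 13.7 h) straddles noon.  Computing M10 inside a
noon-aligned segment clips the optimum at the segment edge and
degenerates into the tie-break.  M10 is therefore computed on
midnight-to-midnight segments, L5 on noon-to-noon segments; each
alignment keeps its window interior.  This is the one deliberate
departure from treating a single noon-noon segment as the universal day
container.

The exclusion cascade (`apply_exclusions()`) applies, in order:
device-QC flags; a per-counter Q3 + 1.5 x IQR outlier rule (type-7
quartiles, strict `>`); mean sleep duration outside (3 h, 12 h) (strict
bounds); and mean episode count <= 5 or >= 30 (closed bounds).  The last
two rules apply only to SPT-window-based phenotypes — L5/M10 remain
usable — and every exclusion is logged with a rule id.  Phenotypes can
be prepared for association analysis on the original scale or via the
rank-based inverse-normal transform (Blom offsets, mean ranks for ties),
with `residualize()` as the ordinary-least-squares covariate-adjustment
utility; mixed-model association itself is out of scope.

## The synthetic cohort: what it emulates, and what a green test means

Since the original cohort data cannot ship with a package, every
downstream stage is tested against `generate_cohort()`, whose defaults
*are* the stated world the detector targets:

| parameter | default | why |
|---|---|---|
| nightly sleep duration | 7.30 h, between-person SD 0.86 h | cohort calibration |
| night-to-night SD | 0.93 h | matches the duration-variability phenotype |
| sleep onset | 23.5 h clock, SD 0.75 h | plausible adult bedtime |
| WASO bouts / night | Poisson(16), mean 8.6 min each | yields ~17 episodes and ~76% efficiency |
| micro-movement SD | 0.5 deg | keeps within-episode changes far below the 5-deg rule |
| posture shift | >= 10 deg | guarantees detectable episode boundaries |
| activity trough | 3.32 h after midnight, SD 1 h | puts the L5 midpoint at 27.32 h |
| naps / non-wear | 0.3 / 0.05 per day | optional daytime structure |

During sleep the z-angle is a held orientation (uniform in +-60 deg)
plus Gaussian micro-noise; WASO re-draws the held angle every 2 min with
a displacement of at least the posture-shift minimum (shifts are
directed away from the +-75 deg working range so the displacement is
always realised — a reflection scheme was found to occasionally fold a
shift back within 5 deg of the original angle and silently bridge two
episodes).  Wake is modelled as wide iid angle scatter (SD 15 deg).  The
magnitude is a sinusoid with its trough at the planted L5 phase plus
floored Gaussian noise, independent of the sleep state; this pins L5/M10
truth cleanly but means the generator does not emulate magnitude
*suppression* during sleep, device artefacts (temperature drift,
autocalibration error), sleep-stage structure, or realistic wake-time
angle dynamics.  A green recovery test therefore establishes that the
detector implements its stated rules faithfully on signals with the
stated contrast structure — not that it is accurate on any particular
real-world device or population.

Nights whose window would overflow the segment (onset + SPT past 11:00)
shift their onset earlier rather than shortening sleep: truncating sleep
was observed to bias the realised cohort duration mean ~0.1 h below
calibration by trimming the right tail.  Truth-diary intervals are
recorded on the epoch grid — exactly as the signal realises them —
so that the noise-free recovery property can be held to a one-epoch
tolerance without conflating detector error with sampling-grid
quantisation.

The recovery tests run the full chain on 100 individuals x 7 nights and
require the cohort mean sleep duration within +-0.15 h of 7.30 and the
mean L5 midpoint within +-0.2 h of 27.32.  With a between-person SD of
0.86 h the duration tolerance is ~1.7 standard errors at n = 100, so
these margins are dominated by Monte-Carlo sampling of the stated world,
not by detection error (detection agrees with the realised truth to
< 0.01 h); the suite fixes the cohort seed.

## GWAS post-processing

`read_sumstats()` validates tab-delimited summary statistics and keeps a
`log10_p` column parsed exactly from the mantissa/exponent form so that
thresholding at values like 2e-35 never relies on borderline float
arithmetic.  The packaged `table3.tsv` fixture (47 lead associations
across seven traits) drives exact accounting tests: 20 associations at
P < 8e-10, 3 of them for L5 timing, 21 episode-count rows.  Variance
explained uses 2f(1-f)b^2 on the unit-variance inverse-normal scale.
`sign_consistency_test()` is the exact binomial tail at p = 0.5; it is
one-sided by default and both options are exposed because the printed
consistency P-values in the source do not match either convention
exactly (18/20 gives 2.0e-4 one-sided, 4.0e-4 two-sided, vs a printed
3e-4).  `ivw_meta()` and `combined_effect_test()` re-implement
fixed-effect inverse-variance pooling (study-level and across aligned
lead SNPs respectively); `lambda_gc()` divides the median association
chi-square by the exact null median `qchisq(0.5, 1)`.
`effect_in_minutes()` converts SD-scale effects using a trait SD in
hours; note this conversion path gives 2.79 min for the strongest
duration variant where the source prints 2.7, plausibly because the
printed value came from the original-scale analysis — both
interpretations are left to the user.

## Mendelian randomisation

Per-variant Wald ratios (first-order SE) feed four estimators: IVW
(inverse-variance weighted mean; multiplicative random-effects SE
inflation by sqrt(Q/(n-1)) when over-dispersed, never deflated),
MR-Egger (weighted regression with free intercept, exposure effects
oriented positive; the intercept estimates mean directional pleiotropy),
and the weighted and penalised weighted median (weighted-percentile
interpolation at 50%; the penalty multiplies each weight by
min(1, 20 q_p) with q_p the chi-square(1) tail of the instrument's Q
contribution — the constant 20 is the usual convention, exposed as an
argument, since the source does not specify it).  Median SEs come from a
seeded parametric bootstrap (2000 draws by default).

Instrument pruning follows the quoted Bonferroni rule applied
iteratively: on the current set of n instruments, the largest per-SNP Q
contribution is removed if it exceeds chi-square(1) at 1 - 0.05/n, and
the IVW estimate and contributions are recomputed until none exceeds the
threshold.  The exact iterative weighting scheme of the method the
source cites is not reproduced in its text, so pruning defaults to
modified second-order ratio weights behind a strategy flag
(`weights = "second"`), with first-order weights available.
Harmonisation is a thin pre-step: allele matching with sign flips and
removal of strand-ambiguous palindromic variants with MAF > 0.42.

Validation is entirely by simulation under the stated generative model
(`simulate_instruments()`): parameter recovery (bias < 0.02 at n = 50
over 500 replicates for IVW, Egger and the weighted median), IVW type-I
error within [0.03, 0.07], Egger intercept recovery under constant
pleiotropy, >= 95% sensitivity of pruning to a planted 10x pleiotropic
outlier and < 10% false-removal rate on all-valid sets.

## Numerical choices and degenerate inputs

* Percentile/quartile convention: type 7 everywhere (threshold and IQR
  rules); documented because the source states neither.
* Strict vs closed bounds follow the quoted wording: bouts >= 30 min,
  merge gap < 60 min, episode break > 5 deg, duration exclusion < 3 h or
  > 12 h (strict), episode exclusion <= 5 or >= 30 (closed).
* All-zero acceleration vectors are an error by default
  (`z_angle(on_zero = "error")`) or carry the last valid angle forward.
* All-non-wear days raise a "no-threshold" condition and are reported as
  missing nights; zero-episode nights are invalid rather than
  zero-filled; individuals with no valid nights are dropped with a
  message.
* Constant vectors are rejected by `inverse_normal()`.
* The SD-of-duration phenotype requires the cohort-maximum number of
  wear days (7 by default).

## Known limitations

The generator's wake model is deliberately crude, so specificity against
realistic daytime stillness (reading, desk work) is not exercised; the
detector is known to score long motionless wakefulness as sleep, a
limitation inherited from actigraphy itself.  No shift-worker handling,
no sleep-stage structure, no raw 100 Hz synthesis (a 1 Hz raw mode
exists only to exercise the epoch aggregation), and no daylight-saving
transitions.  Association testing, LD-aware analyses (clumping,
fine-mapping, genetic correlation) and heritability estimation are out
of scope.
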