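# actisleep

Diary-free sleep phenotyping from wrist-worn accelerometer data, with
the GWAS summary-statistic post-processing and two-sample Mendelian
randomisation (MR) toolkit that a sleep genetics analysis needs — plus a
calibrated synthetic-cohort generator with ground truth so the whole
chain is testable without any data access.

## Who this is for

Sleep epidemiologists and statistical geneticists who want a
reproducible implementation of the heuristic actigraphy pipeline used in
large biobank sleep GWAS: no sleep diary, no polysomnography — sleep is
located directly in the posture signal of a wrist accelerometer.

## The method in brief

The **z-angle**, the angle of the device z-axis to the horizontal plane,

    theta = atan( z / sqrt(x^2 + y^2) ) * 180 / pi,

is near-constant during sleep.  Per 5-s epoch, the pipeline:

1. computes the rolling 5-min **median absolute z-angle change**;
2. thresholds it per noon-to-noon day at 15 x its 10th percentile
   (floor 0.13 deg) to separate movement from non-movement;
3. scores maximal sub-threshold runs >= 30 min as **inactivity bouts**,
   merges bouts < 60 min apart into blocks, and takes the longest block
   as the **sleep period time window (SPT-window)**;
4. scores **sleep episodes** inside it as runs >= 5 min with no raw
   z-angle change > 5 deg.

Eight phenotypes follow: mean nocturnal sleep duration (summed
episodes), its night-to-night SD (7-day wearers only), sleep efficiency
(duration / SPT length), number of nocturnal sleep episodes, sleep
midpoint, L5 and M10 timing (midpoints of the least-active 5 h /
most-active 10 h, in hours since the previous midnight: 2 a.m. = 26),
and diurnal inactivity (inactivity bouts outside the SPT-window).  A QC
cascade excludes device-quality outliers (Q3 + 1.5 x IQR per counter),
mean durations outside (3, 12) h and mean episode counts <= 5 or >= 30.

Downstream utilities: rank-based inverse-normal transform and OLS
residualisation; sumstats parsing, P-threshold accounting, variance
explained (2f(1-f)b^2), allele alignment, exact binomial sign tests,
fixed-effect inverse-variance meta-analysis and combined lead-SNP
effects, genomic inflation (lambda GC); MR by IVW, MR-Egger, weighted
and penalised weighted median, with iterative Bonferroni Cochran's-Q
instrument pruning.

## Worked example

```r
library(actisleep)

# simulate a small cohort with known truth, run the full chain
cfg <- generator_config(n_individuals = 20, seed = 7)
cohort <- generate_cohort(cfg)
ph <- derive_phenotypes(cohort$recordings)
res <- apply_exclusions(ph)
colMeans(res$retained[, c("mean_sleep_duration", "mean_efficiency",
                          "mean_n_episodes", "mean_l5")])
#> mean_sleep_duration     mean_efficiency     mean_n_episodes             mean_l5
#>           7.2841865           0.7716061          16.7928571          27.7784325

# compare with the generator's planted truth
tt <- cohort$truth_table
mean(tapply(tt$sleep_duration_h, tt$individual_id, mean))
#> [1] 7.283947
```

The detected cohort mean duration (7.284 h) matches the realised truth
(7.284 h) to under a second per night; the generator is calibrated so
that larger cohorts centre on 7.30 h.  `mean_l5` of 27.78 means the
least-active 5 h of these individuals is centred ~3:47 a.m.

```r
# association-table accounting on the packaged 47-row fixture
tab3 <- read_sumstats(table3_path())
count_below(tab3, 8e-10)                      # stricter threshold
#> [1] 20
mid <- tab3[tab3$trait == "Sleep midpoint", ]
round(100 * variance_explained(mid$eaf, mid$beta), 2)   # percent
#> [1] 0.04

# two-sample MR with a planted pleiotropic outlier
ins <- simulate_instruments(n = 20, theta = 0.3, n_invalid = 1,
                            constant_pleiotropy = 0.3, seed = 1)
res <- mr_run(ins, n_boot = 500)
res$excluded_snps
#> [1] "snp001"
res$estimates$ivw
#> MR ivw: estimate=0.3265 se=0.06632 p=8.54e-07 (n=19)
```

The pruning step finds the planted invalid instrument (`snp001`), and
IVW on the cleaned set recovers the true causal effect of 0.3.

## Layout

* `R/` — generator, signal features, detection, phenotypes, GWAS
  post-processing, MR.
* `src/rolling_median.cpp` — exact centered rolling median.
* `inst/extdata/table3.tsv` — packaged 47-row association fixture.
* `inst/cli/actisleep.R` — thin command-line dispatcher
  (`simulate`, `detect`, `derive`, `gwas-count`, `mr`).
* `vignettes/accelerometer-sleep-methods.Rmd` — model, assumptions,
  parameter choices, limitations.
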