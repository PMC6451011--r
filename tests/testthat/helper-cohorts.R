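# Shared fixture: one small synthetic cohort with detection results,
# generated once per session and reused across test files.
.fixture_env <- new.env(parent = emptyenv())

small_cohort <- function() {
  if (is.null(.fixture_env$small)) {
    cfg <- generator_config(n_individuals = 12, seed = 11)
    co <- generate_cohort(cfg)
    co$detections <- lapply(co$recordings, detect_nights)
    .fixture_env$small <- co
  }
  .fixture_env$small
}

# a hand-built phenotype table with planted QC violations
exclusion_fixture <- function() {
  ids <- sprintf("p%02d", 1:12)
  ph <- data.frame(
    individual_id = ids,
    mean_sleep_duration = c(2.9, rep(7.2, 11)),       # p01: rule 3
    sd_sleep_duration = 0.9,
    mean_efficiency = 0.76,
    mean_n_episodes = c(17, 5.0, rep(17, 10)),        # p02: rule 4 (<= 5)
    mean_midpoint = 27, mean_l5 = 27.3, mean_m10 = 15,
    mean_diurnal_inactivity = 1,
    n_nights_used = 7L, n_days_used = 7L, n_days_worn = 7L)
  # counters: eleven 1s and one 100 -> Q3 = 1, IQR = 0, cutoff 1.
  # p03 (100) violates the strict > rule; p04 sits exactly at the
  # cutoff and must be retained.
  counters <- data.frame(
    individual_id = ids,
    recording_errors = c(1, 1, 100, rep(1, 9)))
  list(phenotypes = ph, counters = counters)
}
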