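#' Configuration for the synthetic accelerometer cohort generator
#'
#' The generator emulates a wrist-worn tri-axial recording summarised at
#' the epoch level: a held forearm orientation with sub-degree
#' micro-movement during sleep, abrupt posture shifts at episode
#' boundaries and during wake-after-sleep-onset (WASO), a smooth diurnal
#' activity rhythm that pins down L5/M10 timing, and optional naps and
#' non-wear gaps.  Defaults are calibrated to the population the
#' detector is meant to process: nightly sleep duration 7.30 h
#' (between-person SD 0.86 h, within-person SD 0.93 h), sleep onset
#' around 23.5 h, about 16 brief nocturnal wake interruptions per night
#' (so ~17 sleep episodes and ~76% sleep efficiency), and an activity
#' trough centred 3.32 h after midnight (L5 midpoint 27.32 h on the
#' hours-since-previous-midnight clock).
#'
#' @param n_individuals number of individuals in a cohort.
#' @param n_days days of continuous wear, 1-7.
#' @param epoch_s epoch length in seconds; must divide 60.
#' @param sleep_onset_mean,sleep_onset_sd nightly sleep-onset clock time,
#'   hours from midnight (23.5 = 11:30 p.m.).
#' @param true_duration_mean mean nightly sleep duration (summed sleep
#'   episodes), hours.
#' @param true_duration_sd_between between-individual SD of the personal
#'   mean duration, hours.
#' @param true_duration_sd_within night-to-night SD around the personal
#'   mean, hours.
#' @param waso_bouts_per_night Poisson rate of nocturnal wake bouts.
#' @param waso_bout_minutes mean length of one wake bout, minutes.
#' @param micro_movement_sd SD of within-episode z-angle noise, degrees.
#'   Must keep successive-epoch changes well below the 5 degree
#'   episode-break rule (validated: `<= 1.5`).
#' @param posture_shift_min_deg minimum z-angle displacement at episode
#'   boundaries and WASO posture changes, degrees; must exceed 5.
#' @param wake_angle_sd SD of epoch-to-epoch z-angle scatter while awake
#'   and active, degrees.
#' @param nap_probability per-day probability of one afternoon nap.
#' @param nonwear_probability per-day probability of one non-wear gap.
#' @param activity_day_amplitude peak-to-trough amplitude of the diurnal
#'   ENMO rhythm, g.
#' @param activity_noise_sd per-epoch magnitude noise, g.
#' @param l5_trough_hour cohort-mean clock hour (after midnight) of the
#'   diurnal activity trough; 3.32 puts the L5 midpoint at 27.32 h.
#' @param l5_phase_sd between-individual SD of the trough phase, hours.
#' @param seed master seed for [generate_cohort()].
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_individuals = 100, n_days = 7, epoch_s = 5,
                             sleep_onset_mean = 23.5, sleep_onset_sd = 0.75,
                             true_duration_mean = 7.3,
                             true_duration_sd_between = 0.86,
                             true_duration_sd_within = 0.93,
                             waso_bouts_per_night = 16,
                             waso_bout_minutes = 8.6,
                             micro_movement_sd = 0.5,
                             posture_shift_min_deg = 10,
                             wake_angle_sd = 15,
                             nap_probability = 0.3,
                             nonwear_probability = 0.05,
                             activity_day_amplitude = 0.08,
                             activity_noise_sd = 0.005,
                             l5_trough_hour = 3.32,
                             l5_phase_sd = 1.0,
                             seed = 1L) {
  cfg <- as.list(environment())
  if (n_individuals < 1) stop("n_individuals must be >= 1")
  if (n_days < 1 || n_days > 7) stop("n_days must be in [1, 7]")
  if (60 %% epoch_s != 0) stop("epoch_s must divide 60 seconds")
  rates <- c(sleep_onset_sd, true_duration_sd_between, true_duration_sd_within,
             waso_bouts_per_night, waso_bout_minutes, micro_movement_sd,
             nap_probability, nonwear_probability, activity_day_amplitude,
             activity_noise_sd, l5_phase_sd, wake_angle_sd)
  if (any(rates < 0)) stop("rates and dispersions must be non-negative")
  if (micro_movement_sd > 1.5)
    stop("micro_movement_sd too large: expected successive-epoch changes ",
         "must stay below the 5 degree episode-break rule")
  if (posture_shift_min_deg <= 5)
    stop("posture_shift_min_deg must exceed the 5 degree break rule")
  if (nap_probability > 1 || nonwear_probability > 1)
    stop("probabilities must be <= 1")
  class(cfg) <- "generator_config"
  cfg
}

# truncated-normal draw by resampling; bounds are wide relative to the
# SD so rejection is cheap
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

# posture shift away from a held angle: displacement of at least
# min_deg, directed toward the centre when the angle is near the
# +-75 degree working range so the full displacement is always realised
shift_held <- function(held, min_deg) {
  dir <- if (held > 45) -1 else if (held < -45) 1 else sample(c(-1, 1), 1)
  held + dir * runif(1, min_deg, min_deg + 20)
}

#' Generate one individual's epoch recording with ground truth
#'
#' The recording starts at local noon and spans `n_days` noon-to-noon
#' day segments, so one nocturnal sleep bout is never split by a segment
#' boundary.  During true sleep episodes the z-angle is a held
#' orientation plus Gaussian micro-noise; at episode boundaries and
#' within WASO bouts the held angle is re-drawn with a displacement of
#' at least `posture_shift_min_deg`.  The activity magnitude follows a
#' sinusoidal diurnal rhythm whose trough fixes the true L5 midpoint.
#' Identical `(config, seed)` yield bit-identical output.
#'
#' @param config a [generator_config()].
#' @param individual_id identifier stored in the series.
#' @param seed integer seed for this recording.
#' @return A list with elements `series` (an [epoch_series()]) and
#'   `truth` (the truth diary: `nights`, `episodes`, `naps`, `nonwear`
#'   data frames; interval columns are hours from recording start).
#' @export
generate_recording <- function(config, individual_id = "ind1",
                               seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(as.integer(seed))
  eph <- config$epoch_s / 3600            # epoch length in hours
  n <- as.integer(round(config$n_days * 24 / eph))
  h <- (seq_len(n) - 1) * eph             # hours since recording start (noon)
  clock <- (12 + h) %% 24

  # ---- individual-level parameters ----------------------------------
  dur_i <- rnorm_trunc(1, config$true_duration_mean,
                       config$true_duration_sd_between, 4, 10.5)
  trough_i <- config$l5_trough_hour + rnorm(1, 0, config$l5_phase_sd)

  # ---- baseline wake signal -----------------------------------------
  wake_base <- runif(1, -30, 30)
  z <- pmin(pmax(wake_base + rnorm(n, 0, config$wake_angle_sd), -90), 90)
  mag <- pmax(config$activity_day_amplitude *
                (1 - cos(2 * pi * (clock - trough_i) / 24)) / 2 +
                rnorm(n, 0, config$activity_noise_sd), 0)
  wear <- rep(TRUE, n)

  idx <- function(hours) pmin(pmax(as.integer(floor(hours / eph)) + 1L, 1L), n)
  hold <- function(i1, i2, held, noise_sd) {
    m <- i2 - i1 + 1L
    if (m > 0) z[i1:i2] <<- pmin(pmax(held + rnorm(m, 0, noise_sd), -90), 90)
  }

  nights <- episodes <- naps <- nonwear <- list()
  min_ep <- 0.1                          # 6 min: safely above the 5-min rule

  for (k in seq_len(config$n_days)) {
    seg0 <- (k - 1) * 24                 # segment start, hours from origin
    onset_clock <- rnorm_trunc(1, config$sleep_onset_mean,
                               config$sleep_onset_sd, 21.5, 25.5)
    sleep_k <- rnorm_trunc(1, dur_i, config$true_duration_sd_within, 3.2, 11)
    n_waso <- rpois(1, config$waso_bouts_per_night)
    n_ep <- n_waso + 1L
    if (sleep_k < (min_ep + 0.02) * n_ep)
      n_ep <- max(1L, as.integer(floor(sleep_k / (min_ep + 0.02))))
    n_waso <- n_ep - 1L
    waso_len <- if (n_waso > 0)
      pmin(pmax(rexp(n_waso, 60 / config$waso_bout_minutes), 1 / 60), 0.75)
    else numeric(0)
    # keep the window inside the segment (wake by 11:00 at the latest):
    # overflowing nights move their onset earlier rather than shortening
    # sleep, so the planted duration distribution is untouched
    spt_len <- sleep_k + sum(waso_len)
    if (onset_clock + spt_len > 35) {
      onset_clock <- max(19, 35 - spt_len)
      if (onset_clock + spt_len > 35) {     # pathological waso draw
        f <- (35 - onset_clock) / spt_len
        sleep_k <- sleep_k * f
        waso_len <- waso_len * f
        spt_len <- 35 - onset_clock
      }
    }
    props <- rgamma(n_ep, shape = 3)
    ep_len <- min_ep + (sleep_k - min_ep * n_ep) * props / sum(props)

    # truth intervals are recorded on the epoch grid, i.e. exactly as
    # the signal realises them, so noise-free detection can be held to
    # a one-epoch tolerance
    onset_h <- seg0 + onset_clock - 12
    cur <- onset_h
    held <- runif(1, -60, 60)
    for (e in seq_len(n_ep)) {
      i1 <- idx(cur); i2 <- idx(cur + ep_len[e]) - 1L
      hold(i1, i2, held, config$micro_movement_sd)
      episodes[[length(episodes) + 1L]] <-
        data.frame(night = k, start_h = (i1 - 1) * eph, end_h = i2 * eph)
      cur <- cur + ep_len[e]
      if (e <= n_waso) {
        # WASO: posture re-drawn every 2 min so no 5-min quiet run forms
        w1 <- idx(cur); w2 <- idx(cur + waso_len[e]) - 1L
        j <- w1
        while (j <= w2) {
          held <- shift_held(held, config$posture_shift_min_deg)
          hold(j, min(j + as.integer(120 / config$epoch_s) - 1L, w2), held,
               config$micro_movement_sd)
          j <- j + as.integer(120 / config$epoch_s)
        }
        cur <- cur + waso_len[e]
      }
      held <- shift_held(held, config$posture_shift_min_deg)
    }
    ep_night <- do.call(rbind, episodes[vapply(episodes, function(d) d$night, 0) == k])
    spt_start <- ep_night$start_h[1]
    spt_end <- ep_night$end_h[nrow(ep_night)]
    midpoint <- hours_since_prev_midnight((spt_start + spt_end) / 2, k)
    nights[[k]] <- data.frame(
      individual_id = as.character(individual_id), night = k,
      spt_start_h = spt_start, spt_end_h = spt_end,
      sleep_duration_h = sum(ep_night$end_h - ep_night$start_h),
      n_episodes = n_ep,
      midpoint_hspm = midpoint,
      l5_hspm = 24 + trough_i, m10_hspm = 12 + trough_i)

    # ---- afternoon events (before this night's sleep) ---------------
    has_nonwear <- runif(1) < config$nonwear_probability
    if (has_nonwear) {
      s <- seg0 + runif(1, 0.5, 6); len <- runif(1, 1, 3)
      i1 <- idx(s); i2 <- idx(s + len) - 1L
      wear[i1:i2] <- FALSE; mag[i1:i2] <- 0
      z[i1:i2] <- z[i1]                  # device at rest: angle frozen
      nonwear[[length(nonwear) + 1L]] <-
        data.frame(night = k, start_h = s, end_h = s + len)
    } else if (runif(1) < config$nap_probability) {
      s <- seg0 + runif(1, 1.5, 5.5); len <- runif(1, 0.5, 1.5)
      i1 <- idx(s); i2 <- idx(s + len) - 1L
      hold(i1, i2, runif(1, -60, 60), config$micro_movement_sd)
      naps[[length(naps) + 1L]] <-
        data.frame(night = k, start_h = s, end_h = s + len)
    }
  }

  series <- epoch_series(individual_id, z, mag, wear, config$epoch_s)
  truth <- list(
    individual_id = as.character(individual_id),
    nights = do.call(rbind, nights),
    episodes = do.call(rbind, episodes),
    naps = if (length(naps)) do.call(rbind, naps) else
      data.frame(night = integer(), start_h = numeric(), end_h = numeric()),
    nonwear = if (length(nonwear)) do.call(rbind, nonwear) else
      data.frame(night = integer(), start_h = numeric(), end_h = numeric()))
  list(series = series, truth = truth)
}

#' Generate a synthetic cohort
#'
#' Per-individual seeds are derived deterministically from the master
#' seed, so a fixed `config$seed` reproduces the whole cohort.
#'
#' @param config a [generator_config()].
#' @return A list with `recordings` (list of [epoch_series()]), `truth`
#'   (one truth diary per individual) and `truth_table` (row per
#'   individual-night).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  ids <- sprintf("ind%03d", seq_len(config$n_individuals))
  seeds <- (as.integer(config$seed) + 7919L * seq_len(config$n_individuals)) %%
    2147483647L
  out <- lapply(seq_along(ids), function(i)
    generate_recording(config, ids[i], seeds[i]))
  list(recordings = lapply(out, `[[`, "series"),
       truth = lapply(out, `[[`, "truth"),
       truth_table = do.call(rbind, lapply(out, function(o) o$truth$nights)))
}

#' Export cohort ground truth to TSV
#'
#' One row per individual-night; interval bounds as ISO-8601 timestamps
#' on the recording clock.
#'
#' @param cohort result of [generate_cohort()].
#' @param path output file.
#' @param origin recording start time shared by the cohort.
#' @return `path`, invisibly.
#' @export
write_truth <- function(cohort, path,
                        origin = as.POSIXct("2024-01-01 12:00:00", tz = "UTC")) {
  tt <- cohort$truth_table
  iso <- function(hrs) format(origin + hrs * 3600, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  out <- data.frame(
    individual_id = tt$individual_id, night = tt$night,
    spt_start = iso(tt$spt_start_h), spt_end = iso(tt$spt_end_h),
    sleep_duration_h = tt$sleep_duration_h, n_episodes = tt$n_episodes,
    midpoint_hspm = tt$midpoint_hspm, l5_hspm = tt$l5_hspm,
    m10_hspm = tt$m10_hspm)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Simulate raw tri-axial samples at a held orientation
#'
#' A minimal raw-mode helper used to exercise
#' [aggregate_raw_to_epochs()]: samples a unit-gravity vector at a fixed
#' z-angle plus isotropic sensor noise.
#'
#' @param n_seconds duration of the snippet.
#' @param hz sampling rate.
#' @param angle_deg held z-angle of the gravity vector.
#' @param noise_g per-axis Gaussian noise SD, g.
#' @return Data frame with `time_s`, `x`, `y`, `z` columns.
#' @export
simulate_raw_samples <- function(n_seconds, hz = 1, angle_deg = 30,
                                 noise_g = 0.01) {
  n <- as.integer(n_seconds * hz)
  a <- angle_deg * pi / 180
  data.frame(
    time_s = (seq_len(n) - 1) / hz,
    x = cos(a) + rnorm(n, 0, noise_g),
    y = rnorm(n, 0, noise_g),
    z = sin(a) + rnorm(n, 0, noise_g))
}
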