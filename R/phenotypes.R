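#' Summarise one night from its SPT-window and sleep episodes
#'
#' Sleep duration is the summed duration of the night's sleep episodes;
#' efficiency divides it by the SPT-window length; the midpoint is the
#' mean of the first episode's start and the last episode's end,
#' reported in hours since the previous midnight (2 a.m. = 26).  Nights
#' with zero episodes are flagged invalid (efficiency undefined).
#'
#' @param spt list with `start_h`, `end_h`: SPT-window bounds in hours
#'   from recording start (recordings start at local noon).
#' @param episodes data frame with `start_h`, `end_h` for the night's
#'   episodes, contained in the window.
#' @param night 1-based day-segment index, used for the midnight clock.
#' @return One-row data frame: `night`, `sleep_duration_h`,
#'   `spt_length_h`, `efficiency`, `n_episodes`, `midpoint_hspm`,
#'   `valid`.
#' @export
night_summary <- function(spt, episodes, night = 1L) {
  spt_len <- spt$end_h - spt$start_h
  if (nrow(episodes) == 0)
    return(data.frame(night = night, sleep_duration_h = NA_real_,
                      spt_length_h = spt_len, efficiency = NA_real_,
                      n_episodes = 0L, midpoint_hspm = NA_real_,
                      valid = FALSE))
  if (any(episodes$start_h < spt$start_h - 1e-9) ||
      any(episodes$end_h > spt$end_h + 1e-9))
    stop("episodes not contained in the SPT-window")
  dur <- sum(episodes$end_h - episodes$start_h)
  mid <- (min(episodes$start_h) + max(episodes$end_h)) / 2
  data.frame(night = night, sleep_duration_h = dur, spt_length_h = spt_len,
             efficiency = dur / spt_len, n_episodes = nrow(episodes),
             midpoint_hspm = hours_since_prev_midnight(mid, night),
             valid = TRUE)
}

#' L5 and M10 timing of one day segment
#'
#' Midpoints of the least-active 5 h and most-active 10 h of a 24-h day
#' segment, found by sliding the window at epoch resolution and
#' averaging the activity magnitude over worn epochs.  Midpoints are
#' reported in hours since the previous midnight (7 p.m. = 19,
#' 2 a.m. = 26); ties pick the earliest window.  Days with less than
#' `min_day_wear_hours` (default 16) of valid wear are returned as
#' missing.
#'
#' The nocturnal L5 window is interior to a noon-to-noon segment
#' (`hspm_offset = 12`, the default), whereas the diurnal M10 window is
#' interior to a midnight-to-midnight segment (`hspm_offset = 0`):
#' [derive_phenotypes()] calls this function on the respective
#' alignment for each measure so that neither window is clipped by its
#' segment boundary.
#'
#' @param magnitude ENMO magnitude values of one day segment (g).
#' @param wear logical wear mask, same length.
#' @param epoch_s epoch length, seconds.
#' @param night 1-based day-segment index.
#' @param control a [detection_control()].
#' @param hspm_offset hours from the previous midnight to the segment
#'   start: 12 for noon-aligned segments, 0 for midnight-aligned.
#' @return One-row data frame: `night`, `l5_hspm`, `m10_hspm`, `wear_h`.
#' @export
l5_m10 <- function(magnitude, wear = NULL, epoch_s = 5, night = 1L,
                   control = detection_control(), hspm_offset = 12) {
  n <- length(magnitude)
  if (is.null(wear)) wear <- rep(TRUE, n)
  eph <- epoch_s / 3600
  wear_h <- sum(wear) * eph
  if (wear_h < control$min_day_wear_hours)
    return(data.frame(night = night, l5_hspm = NA_real_, m10_hspm = NA_real_,
                      wear_h = wear_h))
  win_mid <- function(hours, minimise) {
    w <- as.integer(round(hours / eph))
    if (w > n) return(NA_real_)
    cs <- cumsum(c(0, magnitude * wear))
    cw <- cumsum(c(0, as.numeric(wear)))
    tot <- cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]
    cnt <- cw[(w + 1):(n + 1)] - cw[1:(n - w + 1)]
    avg <- ifelse(cnt > 0, tot / cnt, if (minimise) Inf else -Inf)
    pos <- if (minimise) which.min(avg) else which.max(avg)  # earliest tie
    (pos - 1) * eph + hours / 2
  }
  l5 <- win_mid(control$l5_hours, TRUE)
  m10 <- win_mid(control$m10_hours, FALSE)
  data.frame(night = night, l5_hspm = l5 + hspm_offset,
             m10_hspm = m10 + hspm_offset, wear_h = wear_h)
}

#' Diurnal inactivity of one day
#'
#' Total duration of inactivity bouts falling outside the SPT-window;
#' bouts straddling the window boundary contribute only their outside
#' portion.
#'
#' @param bouts data frame with `start_h`, `end_h` of the day's
#'   inactivity bouts.
#' @param spt list with `start_h`, `end_h` of the day's SPT-window (or
#'   `NULL` when no window was detected, in which case all bouts count).
#' @return Hours of diurnal inactivity.
#' @export
diurnal_inactivity <- function(bouts, spt = NULL) {
  if (nrow(bouts) == 0) return(0)
  if (is.null(spt)) return(sum(bouts$end_h - bouts$start_h))
  inside <- pmax(0, pmin(bouts$end_h, spt$end_h) - pmax(bouts$start_h, spt$start_h))
  sum((bouts$end_h - bouts$start_h) - inside)
}

#' Aggregate an individual's nights and days into a phenotype record
#'
#' Per-phenotype means over valid nights/days.  The night-to-night
#' standard deviation of sleep duration (sample SD, n-1 denominator) is
#' reported only for individuals who wore the device the maximum number
#' of days (`max_days`, default 7); nights without a detected SPT-window
#' reduce `n_nights_used` rather than contributing zeros.
#'
#' @param nights data frame of [night_summary()] rows.
#' @param days data frame of [l5_m10()] rows with an added
#'   `diurnal_inactivity_h` column.
#' @param individual_id identifier for the output row.
#' @param n_days_worn days of device wear for this individual.
#' @param max_days wear days required for the duration-SD phenotype.
#' @return One-row data frame with the eight phenotypes plus counts.
#' @export
aggregate_individual <- function(nights, days, individual_id,
                                 n_days_worn, max_days = 7L) {
  ok <- nights[nights$valid, , drop = FALSE]
  if (nrow(ok) == 0)
    stop("individual ", individual_id, " has zero valid nights")
  l5ok <- days$l5_hspm[!is.na(days$l5_hspm)]
  m10ok <- days$m10_hspm[!is.na(days$m10_hspm)]
  data.frame(
    individual_id = as.character(individual_id),
    mean_sleep_duration = mean(ok$sleep_duration_h),
    sd_sleep_duration = if (n_days_worn == max_days && nrow(ok) >= 2)
      stats::sd(ok$sleep_duration_h) else NA_real_,
    mean_efficiency = mean(ok$efficiency),
    mean_n_episodes = mean(ok$n_episodes),
    mean_midpoint = mean(ok$midpoint_hspm),
    mean_l5 = if (length(l5ok)) mean(l5ok) else NA_real_,
    mean_m10 = if (length(m10ok)) mean(m10ok) else NA_real_,
    mean_diurnal_inactivity = mean(days$diurnal_inactivity_h, na.rm = TRUE),
    n_nights_used = nrow(ok),
    n_days_used = length(l5ok),
    n_days_worn = n_days_worn)
}

#' Derive the eight sleep phenotypes for a cohort of recordings
#'
#' Runs the full chain (change metric, SPT-window and episode detection,
#' night and day summaries, per-individual aggregation) over a list of
#' epoch series.  Individuals with zero valid nights are dropped with a
#' message.
#'
#' @param recordings list of [epoch_series()] (e.g.
#'   `generate_cohort(cfg)$recordings`).
#' @param control a [detection_control()].
#' @return Data frame with one row per individual (see
#'   [aggregate_individual()]).
#' @export
derive_phenotypes <- function(recordings, control = detection_control()) {
  max_days <- max(vapply(recordings, function(es)
    length(es) %/% as.integer(round(24 * 3600 / es$epoch_s)), 0L))
  rows <- lapply(recordings, function(es) {
    det <- detect_nights(es, control)
    eph <- es$epoch_s / 3600
    seg_len <- as.integer(round(24 / eph))
    n_days <- length(es) %/% seg_len
    nights <- do.call(rbind, lapply(seq_len(n_days), function(k) {
      nk <- det$nights[k, ]
      if (!nk$detected)
        return(data.frame(night = k, sleep_duration_h = NA_real_,
                          spt_length_h = NA_real_, efficiency = NA_real_,
                          n_episodes = 0L, midpoint_hspm = NA_real_,
                          valid = FALSE))
      eps <- det$episodes[det$episodes$night == k, , drop = FALSE]
      night_summary(list(start_h = nk$spt_start_h, end_h = nk$spt_end_h),
                    eps, k)
    }))
    days <- do.call(rbind, lapply(seq_len(n_days), function(k) {
      sel <- ((k - 1L) * seg_len + 1L):(k * seg_len)
      d <- l5_m10(es$magnitude[sel], es$wear[sel], es$epoch_s, k, control,
                  hspm_offset = 12)
      d$m10_hspm <- NA_real_
      # M10 on the midnight-aligned day so the diurnal peak is interior
      m0 <- (k - 1L) * seg_len + seg_len %/% 2L
      if (m0 + seg_len <= length(es)) {
        selm <- (m0 + 1L):(m0 + seg_len)
        dm <- l5_m10(es$magnitude[selm], es$wear[selm], es$epoch_s, k,
                     control, hspm_offset = 0)
        d$m10_hspm <- dm$m10_hspm
      }
      nk <- det$nights[k, ]
      spt <- if (nk$detected)
        list(start_h = nk$spt_start_h, end_h = nk$spt_end_h) else NULL
      bt <- det$bouts[det$bouts$night == k, , drop = FALSE]
      d$diurnal_inactivity_h <- if (nk$detected)
        diurnal_inactivity(bt, spt) else NA_real_
      d
    }))
    tryCatch(aggregate_individual(nights, days, es$id, n_days, max_days),
             error = function(e) { message(conditionMessage(e)); NULL })
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  out
}

#' Quality-control exclusion cascade
#'
#' Sequential application of the cohort exclusion rules:
#' \enumerate{
#'   \item device-QC flags (any `TRUE` flag column in `qc_flags`);
#'   \item per-counter outlier rule: counter value strictly greater than
#'     its 3rd quartile + 1.5 x IQR (quartiles by linear interpolation,
#'     type 7);
#'   \item mean sleep duration strictly below 3 h or above 12 h;
#'   \item mean number of nocturnal sleep episodes <= 5 or >= 30
#'     (closed bounds).
#' }
#' Rules 1-2 exclude an individual from all analyses; rules 3-4 apply
#' only to SPT-based phenotypes, leaving L5/M10 timing usable.  Every
#' exclusion is logged with its rule id.  Deterministic and order-stable;
#' re-running rules 3-4 on the retained set removes no one.
#'
#' @param cohort phenotype table from [derive_phenotypes()].
#' @param qc_flags optional data frame: `individual_id` plus logical
#'   flag columns (rule 1).
#' @param qc_counters optional data frame: `individual_id` plus numeric
#'   counter columns (rule 2).
#' @return List with `cohort` (input plus `excluded_spt`,
#'   `excluded_all`, `exclusion_reasons` columns), `retained` (rows
#'   clean for SPT-based analyses) and `log` (one row per individual and
#'   violated rule: `individual_id`, `rule`, `detail`).
#' @export
apply_exclusions <- function(cohort, qc_flags = NULL, qc_counters = NULL) {
  stopifnot(nrow(cohort) > 0)
  log <- list()
  note <- function(id, rule, detail)
    log[[length(log) + 1L]] <<- data.frame(individual_id = id, rule = rule,
                                           detail = detail)
  all_excl <- setNames(rep(FALSE, nrow(cohort)), cohort$individual_id)

  if (!is.null(qc_flags)) {
    flag_cols <- setdiff(names(qc_flags), "individual_id")
    for (id in qc_flags$individual_id) {
      r <- qc_flags[qc_flags$individual_id == id, flag_cols, drop = FALSE]
      bad <- flag_cols[vapply(r, isTRUE, TRUE)]
      if (length(bad) && id %in% names(all_excl)) {
        all_excl[id] <- TRUE
        note(id, "rule1_device_flag", paste(bad, collapse = ","))
      }
    }
  }
  if (!is.null(qc_counters)) {
    cnt_cols <- setdiff(names(qc_counters), "individual_id")
    for (cc in cnt_cols) {
      v <- qc_counters[[cc]]
      q <- stats::quantile(v, c(0.25, 0.75), type = 7, na.rm = TRUE)
      cutoff <- q[2] + 1.5 * (q[2] - q[1])
      bad <- qc_counters$individual_id[!is.na(v) & v > cutoff]
      for (id in bad) if (id %in% names(all_excl)) {
        all_excl[id] <- TRUE
        note(id, "rule2_counter_iqr", sprintf("%s > %.6g", cc, cutoff))
      }
    }
  }
  spt_excl <- all_excl
  d <- cohort$mean_sleep_duration
  bad <- which(!is.na(d) & (d < 3 | d > 12))
  for (i in bad) {
    spt_excl[i] <- TRUE
    note(cohort$individual_id[i], "rule3_duration_bounds",
         sprintf("mean_sleep_duration=%.3f", d[i]))
  }
  e <- cohort$mean_n_episodes
  bad <- which(!is.na(e) & (e <= 5 | e >= 30))
  for (i in bad) {
    spt_excl[i] <- TRUE
    note(cohort$individual_id[i], "rule4_episode_bounds",
         sprintf("mean_n_episodes=%.3f", e[i]))
  }
  cohort$excluded_all <- unname(all_excl)
  cohort$excluded_spt <- unname(spt_excl)
  log <- if (length(log)) do.call(rbind, log) else
    data.frame(individual_id = character(), rule = character(),
               detail = character())
  reasons <- vapply(cohort$individual_id, function(id)
    paste(log$rule[log$individual_id == id], collapse = ";"), "")
  cohort$exclusion_reasons <- unname(reasons)
  list(cohort = cohort,
       retained = cohort[!cohort$excluded_spt, , drop = FALSE],
       log = log)
}

#' Rank-based inverse-normal transform
#'
#' Blom offsets: `qnorm((r - 3/8) / (n + 1/4))` with mean ranks for
#' ties; output order matches input order.  `NA`s are ignored and
#' returned as `NA`.
#'
#' @param values numeric vector, at least two distinct non-missing
#'   values.
#' @return Transformed vector, same length.
#' @export
inverse_normal <- function(values) {
  ok <- !is.na(values)
  v <- values[ok]
  if (length(v) < 2) stop("need at least 2 non-missing values")
  if (length(unique(v)) < 2) stop("constant vector cannot be transformed")
  r <- rank(v, ties.method = "average")
  out <- rep(NA_real_, length(values))
  out[ok] <- stats::qnorm((r - 3 / 8) / (length(v) + 1 / 4))
  out
}

#' Residualise a phenotype on covariates
#'
#' Ordinary-least-squares residualisation used to prepare phenotypes for
#' association analysis (age, sex, centre, season, genotyping array;
#' time in bed for the episode-count phenotype).  Rows with missing
#' phenotype or covariates return `NA`.
#'
#' @param values numeric phenotype vector.
#' @param covariates data frame of covariates (factors allowed), same
#'   number of rows.
#' @return Residual vector, same length and order.
#' @export
residualize <- function(values, covariates) {
  stopifnot(nrow(covariates) == length(values))
  df <- cbind(data.frame(.y = values), covariates)
  ok <- stats::complete.cases(df)
  out <- rep(NA_real_, length(values))
  if (sum(ok) <= ncol(covariates)) stop("too few complete rows")
  fit <- stats::lm(.y ~ ., data = df[ok, , drop = FALSE])
  out[ok] <- stats::resid(fit)
  out
}
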