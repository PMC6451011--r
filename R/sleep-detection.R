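#' Tuning constants of the sleep detection pipeline
#'
#' Every constant of the heuristic in one place.  Defaults follow the
#' published algorithm where it states them (5-min rolling window,
#' 30-min inactivity bouts merged across gaps shorter than 60 min,
#' 5-degree / 5-min sleep-episode rule) and the companion open-source
#' implementation where it does not (threshold = 15 times the 10th
#' percentile of the day's change metric, floored at 0.13 degrees).
#'
#' @param multiplier threshold multiplier applied to the 10th percentile
#'   of the day's change metric.
#' @param threshold_floor,threshold_cap bounds on the movement threshold,
#'   degrees.
#' @param percentile percentile of the day's metric entering the
#'   threshold (fraction).
#' @param window_minutes rolling-median window of the change metric.
#' @param bout_min_minutes minimum length of an inactivity bout.
#' @param merge_gap_minutes bouts closer than this merge into blocks
#'   (strict `<`).
#' @param episode_max_change sleep-episode break rule: successive
#'   z-angle changes strictly larger than this end an episode, degrees.
#' @param episode_min_minutes minimum sleep-episode duration.
#' @param min_threshold_wear_hours minimum wear time in a day for the
#'   threshold to be computable.
#' @param l5_hours,m10_hours least-active / most-active window lengths.
#' @param min_day_wear_hours days with less valid wear than this are
#'   excluded from L5/M10 estimates.
#' @return List of class `detection_control`.
#' @export
detection_control <- function(multiplier = 15, threshold_floor = 0.13,
                              threshold_cap = Inf, percentile = 0.10,
                              window_minutes = 5, bout_min_minutes = 30,
                              merge_gap_minutes = 60, episode_max_change = 5,
                              episode_min_minutes = 5,
                              min_threshold_wear_hours = 1,
                              l5_hours = 5, m10_hours = 10,
                              min_day_wear_hours = 16) {
  ctl <- as.list(environment())
  stopifnot(multiplier > 0, threshold_floor >= 0, percentile > 0, percentile < 1)
  class(ctl) <- "detection_control"
  ctl
}

#' Movement threshold for one day segment
#'
#' `multiplier` times the 10th percentile (linear-interpolation, type 7)
#' of the day's change-metric values over worn epochs, clamped to
#' `[threshold_floor, threshold_cap]`.
#'
#' @param metric change-metric values of one noon-to-noon day segment
#'   (see [change_metric()]).
#' @param wear logical wear mask, same length (default all worn).
#' @param epoch_s epoch length, seconds.
#' @param control a [detection_control()].
#' @return Threshold in degrees.
#' @export
day_threshold <- function(metric, wear = NULL, epoch_s = 5,
                          control = detection_control()) {
  if (is.null(wear)) wear <- rep(TRUE, length(metric))
  vals <- metric[wear & is.finite(metric)]
  if (length(vals) * epoch_s / 3600 < control$min_threshold_wear_hours)
    stop("no-threshold: day has under ", control$min_threshold_wear_hours,
         " h of wear-time metric values")
  thr <- control$multiplier *
    as.numeric(stats::quantile(vals, control$percentile, type = 7))
  min(max(thr, control$threshold_floor), control$threshold_cap)
}

# maximal runs of TRUE in a logical vector -> data.frame(start, end),
# inclusive indices
runs_of <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Inactivity bouts
#'
#' Maximal runs of consecutive epochs with metric strictly below the
#' threshold, lasting at least `bout_min_minutes` (default 30).
#' Non-wear epochs never count as inactivity.
#'
#' @param metric change-metric values of one day segment.
#' @param threshold movement threshold from [day_threshold()].
#' @param wear logical wear mask.
#' @param epoch_s epoch length, seconds.
#' @param control a [detection_control()].
#' @return Data frame `start`, `end` (inclusive epoch indices into the
#'   segment), disjoint and sorted.
#' @export
inactivity_bouts <- function(metric, threshold, wear = NULL, epoch_s = 5,
                             control = detection_control()) {
  stopifnot(threshold > 0)
  if (is.null(wear)) wear <- rep(TRUE, length(metric))
  runs <- runs_of(metric < threshold & wear)
  min_ep <- control$bout_min_minutes * 60 / epoch_s
  runs[(runs$end - runs$start + 1L) >= min_ep, , drop = FALSE]
}

#' Merge inactivity bouts into blocks
#'
#' Bouts separated by a gap strictly shorter than `merge_gap_minutes`
#' (default 60) are combined, transitively, into inactivity blocks
#' spanning first start to last end.  Idempotent.
#'
#' @param bouts data frame from [inactivity_bouts()] (disjoint, sorted).
#' @param epoch_s epoch length, seconds.
#' @param control a [detection_control()].
#' @return Data frame `start`, `end`, `n_bouts`.
#' @export
merge_bouts <- function(bouts, epoch_s = 5, control = detection_control()) {
  if (nrow(bouts) == 0)
    return(data.frame(start = integer(), end = integer(), n_bouts = integer()))
  bouts <- bouts[order(bouts$start), , drop = FALSE]
  gap_ep <- control$merge_gap_minutes * 60 / epoch_s
  # gap between bout i and i+1 in epochs; strict < rule
  new_block <- c(TRUE, (bouts$start[-1] - bouts$end[-nrow(bouts)] - 1L) >= gap_ep)
  grp <- cumsum(new_block)
  data.frame(
    start = tapply(bouts$start, grp, min),
    end = tapply(bouts$end, grp, max),
    n_bouts = as.integer(table(grp)), row.names = NULL)
}

#' Detect the SPT-window of one day segment
#'
#' Computes the day's movement threshold, finds inactivity bouts, merges
#' them into blocks, and returns the longest block as the sleep period
#' time window.  Ties are broken by lower mean metric within the block,
#' then by earlier start.  Returns `NULL` when no bout exists.
#'
#' @inheritParams inactivity_bouts
#' @return `NULL`, or a list with `start`, `end` (inclusive epoch
#'   indices into the segment), `threshold_used` and `n_bouts_merged`.
#' @export
detect_spt_window <- function(metric, wear = NULL, epoch_s = 5,
                              control = detection_control()) {
  thr <- day_threshold(metric, wear, epoch_s, control)
  bouts <- inactivity_bouts(metric, thr, wear, epoch_s, control)
  blocks <- merge_bouts(bouts, epoch_s, control)
  if (nrow(blocks) == 0) return(NULL)
  len <- blocks$end - blocks$start + 1L
  cand <- which(len == max(len))
  if (length(cand) > 1) {
    mm <- vapply(cand, function(i) mean(metric[blocks$start[i]:blocks$end[i]]), 0)
    cand <- cand[mm == min(mm)]
    cand <- cand[which.min(blocks$start[cand])]
  }
  i <- cand[1]
  list(start = as.integer(blocks$start[i]), end = as.integer(blocks$end[i]),
       threshold_used = thr, n_bouts_merged = as.integer(blocks$n_bouts[i]))
}

#' Detect sleep episodes within an SPT-window
#'
#' Sleep episodes are maximal runs of consecutive epochs whose
#' epoch-to-epoch absolute z-angle change never exceeds
#' `episode_max_change` degrees (strict `>` breaks a run, mirroring the
#' "no change larger than 5 degrees" rule), lasting at least
#' `episode_min_minutes`.  Applied to raw epoch z-angles, not the
#' smoothed metric.
#'
#' @param z_angles raw z-angles of the window, degrees.
#' @param epoch_s epoch length, seconds.
#' @param control a [detection_control()].
#' @return Data frame `start`, `end` (inclusive epoch indices into the
#'   window), disjoint and sorted.
#' @export
detect_sleep_episodes <- function(z_angles, epoch_s = 5,
                                  control = detection_control()) {
  n <- length(z_angles)
  if (n == 0) stop("empty window")
  if (n == 1) seg <- data.frame(start = 1L, end = 1L)
  else {
    brk <- which(abs(diff(z_angles)) > control$episode_max_change)
    starts <- c(1L, brk + 1L)
    ends <- c(brk, n)
    seg <- data.frame(start = starts, end = ends)
  }
  min_ep <- control$episode_min_minutes * 60 / epoch_s
  seg[(seg$end - seg$start + 1L) >= min_ep, , drop = FALSE]
}

#' Run the full detector on one recording
#'
#' Slices the recording into noon-to-noon day segments, detects the
#' SPT-window and sleep episodes per night, and keeps the inactivity
#' bouts needed for the diurnal-inactivity phenotype.  Days whose
#' threshold cannot be computed (all non-wear) are reported as missing
#' nights.
#'
#' @param es an [epoch_series()] starting at local noon.
#' @param control a [detection_control()].
#' @return List with data frames `nights` (one row per day segment:
#'   `night`, `detected`, `spt_start_h`, `spt_end_h` in hours from
#'   recording start, `threshold_used`, `n_bouts_merged`, `n_episodes`,
#'   `wear_h`), `episodes` and `bouts` (`night`, `start_h`, `end_h`).
#' @export
detect_nights <- function(es, control = detection_control()) {
  eph <- es$epoch_s / 3600
  seg_len <- as.integer(round(24 / eph))
  n_days <- length(es) %/% seg_len
  if (n_days < 1) stop("recording shorter than one noon-to-noon day")
  metric <- change_metric(es, control$window_minutes)
  nights <- vector("list", n_days)
  episodes <- list(); bouts <- list()
  for (k in seq_len(n_days)) {
    i0 <- (k - 1L) * seg_len
    sel <- (i0 + 1L):(i0 + seg_len)
    m <- metric[sel]; w <- es$wear[sel]; z <- es$z_angle[sel]
    wear_h <- sum(w) * eph
    spt <- tryCatch(detect_spt_window(m, w, es$epoch_s, control),
                    error = function(e) {
                      if (grepl("no-threshold", conditionMessage(e))) NULL
                      else stop(e)
                    })
    row <- data.frame(night = k, detected = FALSE, spt_start_h = NA_real_,
                      spt_end_h = NA_real_, threshold_used = NA_real_,
                      n_bouts_merged = NA_integer_, n_episodes = 0L,
                      wear_h = wear_h)
    if (!is.null(spt)) {
      thr <- spt$threshold_used
      bt <- inactivity_bouts(m, thr, w, es$epoch_s, control)
      if (nrow(bt))
        bouts[[length(bouts) + 1L]] <- data.frame(
          night = k, start_h = (i0 + bt$start - 1L) * eph,
          end_h = (i0 + bt$end) * eph)
      eps <- detect_sleep_episodes(z[spt$start:spt$end], es$epoch_s, control)
      if (nrow(eps))
        episodes[[length(episodes) + 1L]] <- data.frame(
          night = k,
          start_h = (i0 + spt$start - 1L + eps$start - 1L) * eph,
          end_h = (i0 + spt$start - 1L + eps$end) * eph)
      row$detected <- TRUE
      row$spt_start_h <- (i0 + spt$start - 1L) * eph
      row$spt_end_h <- (i0 + spt$end) * eph
      row$threshold_used <- thr
      row$n_bouts_merged <- spt$n_bouts_merged
      row$n_episodes <- if (nrow(eps)) nrow(eps) else 0L
    }
    nights[[k]] <- row
  }
  empty <- data.frame(night = integer(), start_h = numeric(), end_h = numeric())
  list(nights = do.call(rbind, nights),
       episodes = if (length(episodes)) do.call(rbind, episodes) else empty,
       bouts = if (length(bouts)) do.call(rbind, bouts) else empty)
}
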