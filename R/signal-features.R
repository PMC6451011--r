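#' z-angle of a tri-axial acceleration vector
#'
#' `atan(z / sqrt(x^2 + y^2))` in degrees, the angle of the device
#' z-axis relative to the horizontal plane.  With the device on the
#' wrist this proxies forearm posture and is near-constant during
#' sleep.  The angle is invariant to positive rescaling of the input
#' vector, so uncalibrated gain does not affect it.
#'
#' @param x,y,z axis accelerations (g); vectors are recycled to common
#'   length.
#' @param axes which axes play the (horizontal1, horizontal2, vertical)
#'   roles, for non-standard mounting; default `c("x", "y", "z")`.
#' @param on_zero behaviour when a vector is all-zero:
#'   `"error"` (default) or `"propagate"` (carry the last valid angle
#'   forward; leading zeros give `NA`).
#' @return Angle(s) in degrees, in \[-90, 90\].
#' @export
z_angle <- function(x, y, z, axes = c("x", "y", "z"), on_zero = "error") {
  v <- list(x = x, y = y, z = z)
  stopifnot(all(axes %in% c("x", "y", "z")), length(axes) == 3)
  h1 <- v[[axes[1]]]; h2 <- v[[axes[2]]]; vert <- v[[axes[3]]]
  denom <- sqrt(h1^2 + h2^2)
  zero <- denom == 0 & vert == 0
  if (any(zero)) {
    if (identical(on_zero, "error"))
      stop("undefined orientation: all-zero acceleration vector")
    ang <- atan2(vert, denom) * 180 / pi
    ang[zero] <- NA_real_
    # carry the last valid angle forward; leading NAs stay NA
    last <- cummax(seq_along(ang) * !is.na(ang))
    filled <- ifelse(last > 0, ang[pmax(last, 1L)], NA_real_)
    return(filled)
  }
  atan2(vert, denom) * 180 / pi
}

#' Aggregate raw samples to epoch level
#'
#' Per-epoch mean of each axis, then the z-angle of the mean vector;
#' the magnitude is the per-sample Euclidean norm minus one g, floored
#' at zero (ENMO), averaged within the epoch.  Empty epochs are marked
#' non-wear.
#'
#' @param raw data frame with `time_s`, `x`, `y`, `z` columns, sorted by
#'   time.
#' @param epoch_s epoch length in seconds.
#' @param id,origin passed to [epoch_series()].
#' @param on_zero passed to [z_angle()]; a near-zero epoch-mean vector
#'   (cancelled samples) triggers this handling.
#' @return An [epoch_series()].
#' @export
aggregate_raw_to_epochs <- function(raw, epoch_s = 5, id = "raw",
                                    origin = as.POSIXct("2024-01-01 12:00:00",
                                                        tz = "UTC"),
                                    on_zero = "error") {
  stopifnot(all(c("time_s", "x", "y", "z") %in% names(raw)), epoch_s > 0)
  if (is.unsorted(raw$time_s)) stop("sample timestamps must be sorted")
  bin <- floor(raw$time_s / epoch_s)
  bins <- seq(0, max(bin))
  f <- factor(bin, levels = bins)
  mx <- tapply(raw$x, f, mean)
  my <- tapply(raw$y, f, mean)
  mz <- tapply(raw$z, f, mean)
  enmo <- pmax(sqrt(raw$x^2 + raw$y^2 + raw$z^2) - 1, 0)
  mag <- tapply(enmo, f, mean)
  empty <- is.na(mx)
  mx[empty] <- 0; my[empty] <- 0; mz[empty] <- 1; mag[empty] <- 0
  ang <- z_angle(as.numeric(mx), as.numeric(my), as.numeric(mz),
                 on_zero = on_zero)
  epoch_series(id, ang, as.numeric(mag), wear = !empty, epoch_s = epoch_s,
               origin = origin)
}

#' Absolute successive change of a z-angle series
#'
#' `value[i] = |angle[i + 1] - angle[i]|`: length `n - 1`, aligned to
#' the later epoch.
#'
#' @param z_angles numeric vector, length >= 2.
#' @return Non-negative numeric vector of length `n - 1`.
#' @export
abs_change <- function(z_angles) {
  if (length(z_angles) < 2) stop("need at least 2 epochs")
  abs(diff(z_angles))
}

#' Centered rolling median
#'
#' Median over a centered window of `window` elements; at the series
#' edges the window shrinks to the available range.  Windows with an
#' even number of elements use the interpolated median (mean of the two
#' middle order statistics); for even `window` the full window is one
#' element heavier on the left.
#'
#' @param x numeric vector.
#' @param window window width in elements, `1 <= window <= length(x)`.
#' @return Numeric vector, same length and alignment as `x`.
#' @export
rolling_median <- function(x, window) {
  .rolling_median_cpp(as.numeric(x), as.integer(window))
}

#' Rolling-median absolute z-angle change metric
#'
#' The detector's change metric: median of the absolute successive
#' z-angle change over centered 5-min rolling windows.  The smoothed
#' change series (length `n - 1`) is re-aligned to the full epoch grid
#' by assigning each change to its earlier epoch — `metric[i]`
#' describes the movement beginning at epoch `i` — with the last value
#' repeated for the final epoch.  This keeps quiet-run boundaries
#' within one epoch of the underlying posture changes.
#'
#' @param es an [epoch_series()] (or numeric z-angle vector when
#'   `epoch_s` is given).
#' @param window_minutes rolling-window length, minutes.
#' @param epoch_s epoch length in seconds, taken from `es` when it is an
#'   `epoch_series`.
#' @return Numeric vector of the metric, degrees per epoch step,
#'   non-negative, length `length(es)`.
#' @export
change_metric <- function(es, window_minutes = 5,
                          epoch_s = if (inherits(es, "epoch_series")) es$epoch_s else 5) {
  z <- if (inherits(es, "epoch_series")) es$z_angle else as.numeric(es)
  w <- window_minutes * 60 / epoch_s
  if (abs(w - round(w)) > 1e-9 || w < 1)
    stop("window_minutes * 60 / epoch_s must be an integer >= 1")
  m <- rolling_median(abs_change(z), as.integer(round(w)))
  c(m, m[length(m)])
}
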