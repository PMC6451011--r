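#' Construct an epoch-level accelerometer series
#'
#' An `epoch_series` holds one individual's recording at fixed epoch
#' length: the z-angle of the device (degrees, in \[-90, 90\]), a
#' gravity-subtracted activity magnitude (ENMO, g, floored at zero) and a
#' wear indicator per epoch.  Timestamps are implicit: epoch `i` starts at
#' `origin + (i - 1) * epoch_s` seconds, strictly increasing and uniformly
#' spaced by construction.
#'
#' @param id individual identifier (scalar character).
#' @param z_angle numeric vector of z-angles in degrees.
#' @param magnitude numeric vector of ENMO values (g), same length.
#' @param wear logical vector, same length; `FALSE` marks non-wear.
#' @param epoch_s epoch length in seconds; must divide 60.
#' @param origin `POSIXct` start time of the first epoch (UTC clock,
#'   no daylight-saving transitions are modelled).
#' @return An object of class `epoch_series`.
#' @export
epoch_series <- function(id, z_angle, magnitude, wear = NULL, epoch_s = 5,
                         origin = as.POSIXct("2024-01-01 12:00:00", tz = "UTC")) {
  n <- length(z_angle)
  if (is.null(wear)) wear <- rep(TRUE, n)
  stopifnot(length(magnitude) == n, length(wear) == n)
  if (60 %% epoch_s != 0) stop("epoch_s must divide 60 seconds")
  if (any(z_angle < -90 - 1e-9 | z_angle > 90 + 1e-9, na.rm = TRUE))
    stop("z_angle outside [-90, 90]")
  if (any(magnitude < 0, na.rm = TRUE)) stop("magnitude must be >= 0")
  structure(
    list(id = as.character(id), z_angle = as.numeric(z_angle),
         magnitude = as.numeric(magnitude), wear = as.logical(wear),
         epoch_s = as.numeric(epoch_s), origin = origin),
    class = "epoch_series")
}

#' @export
length.epoch_series <- function(x) length(x$z_angle)

#' @export
print.epoch_series <- function(x, ...) {
  hrs <- length(x) * x$epoch_s / 3600
  cat(sprintf("<epoch_series> id=%s  %d epochs of %gs (%.1f h), %.1f%% wear\n",
              x$id, length(x), x$epoch_s, hrs, 100 * mean(x$wear)))
  invisible(x)
}

#' @export
as.data.frame.epoch_series <- function(x, ...) {
  data.frame(
    timestamp = x$origin + (seq_len(length(x)) - 1) * x$epoch_s,
    z_angle_deg = x$z_angle, magnitude_g = x$magnitude, wear = x$wear)
}

#' Epoch timestamps of a series
#'
#' @param es an [epoch_series()].
#' @return `POSIXct` vector of epoch start times.
#' @export
epoch_times <- function(es) {
  es$origin + (seq_len(length(es)) - 1) * es$epoch_s
}

# Hours elapsed since the start of the recording for epoch index i
# (epoch start).  Used internally; recordings start at local noon.
epoch_hours <- function(es, i) (i - 1) * es$epoch_s / 3600

# Convert hours-from-recording-start to hours since the previous
# midnight for a noon-to-noon day segment `night` (1-based).  Recordings
# start at local noon, so segment k spans hours [(k-1)*24, k*24) and its
# interior midnight sits 12 h in.  Values land in [12, 36): 7 p.m. = 19,
# 2 a.m. = 26.
hours_since_prev_midnight <- function(h, night) {
  (h - (night - 1) * 24) + 12
}

#' Write an epoch series to delimited text
#'
#' One file per individual with header
#' `timestamp,z_angle_deg,magnitude_g,wear` and ISO-8601 timestamps.
#'
#' @param es an [epoch_series()].
#' @param path output file path; defaults to `<id>.epochs.csv` in `dir`.
#' @param dir directory used when `path` is missing.
#' @return The path written, invisibly.
#' @export
write_epochs <- function(es, path = NULL, dir = ".") {
  if (is.null(path)) path <- file.path(dir, paste0(es$id, ".epochs.csv"))
  df <- as.data.frame(es)
  df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  df$wear <- ifelse(df$wear, "true", "false")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an epoch series from delimited text
#'
#' Strict schema validation of the dialect written by [write_epochs()];
#' malformed rows are reported with line numbers.
#'
#' @param path file written by [write_epochs()].
#' @param id individual id; defaults to the file name stem.
#' @return An [epoch_series()].
#' @export
read_epochs <- function(path, id = NULL) {
  if (is.null(id)) id <- sub("\\.epochs\\.csv$", "", basename(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "z_angle_deg", "magnitude_g", "wear")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("epoch file ", path, " missing column(s): ", paste(miss, collapse = ", "))
  ts <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  bad <- which(is.na(ts))
  if (length(bad))
    stop("unparseable timestamp at data line(s) ",
         paste(utils::head(bad, 5), collapse = ", "), " of ", path)
  step <- diff(as.numeric(ts))
  if (length(step) && (any(step <= 0) || any(abs(step - step[1]) > 1e-6)))
    stop("timestamps not strictly increasing with uniform spacing in ", path)
  bad <- which(!is.finite(df$z_angle_deg) | df$z_angle_deg < -90 | df$z_angle_deg > 90)
  if (length(bad))
    stop("z_angle_deg outside [-90, 90] at data line(s) ",
         paste(utils::head(bad, 5), collapse = ", "), " of ", path)
  epoch_series(id, df$z_angle_deg, pmax(df$magnitude_g, 0),
               df$wear %in% c("true", "TRUE", "True"),
               epoch_s = if (length(step)) step[1] else 5, origin = ts[1])
}
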