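# Accelerometer filtering, impact detection and lead-time-anchored window
# extraction.  Frames are 0-based and windows half-open [t_s, t_e), matching
# the annotation convention; the window spans
#   t_s = t_p - t_l - w,  t_e = t_p - t_l
# where t_p is the impact frame, t_l the lead time and w = 250 frames
# (500 ms at 500 Hz).  Lead times in ms are converted with
# lead_frames = ceiling(t_l / 2), so the realised lead is never shorter than
# requested.

butter_bandpass <- local({
  cache <- NULL
  function(sampling_rate) {
    if (is.null(cache))
      cache <<- signal::butter(4, c(0.1, 50) / (sampling_rate / 2), type = "pass")
    cache
  }
})

#' Zero-phase Butterworth band-pass filter (0.1-50 Hz)
#'
#' Order-4 band-pass Butterworth design applied forward-backward
#' (zero-phase).  The series mean is removed before filtering: the band-pass
#' has zero DC gain, so this changes nothing in exact arithmetic, but it
#' suppresses the step transient that the 0.1 Hz edge (settling time ~10 s)
#' would otherwise ring through records of typical length.
#'
#' @param x Numeric series (an accelerometer channel, in g).
#' @param sampling_rate Sampling rate in Hz; must be 500.
#' @return Filtered series of the same length.
#' @export
bandpass_filter <- function(x, sampling_rate = SAMPLING_RATE) {
  if (sampling_rate != SAMPLING_RATE)
    stopf("sampling_rate must be %d Hz", SAMPLING_RATE)
  if (length(x) < 50L)
    stopf("series too short to filter (%d samples; need >= 50)", length(x))
  if (!all(is.finite(x)))
    stopf("series contains non-finite samples")
  bf <- butter_bandpass(sampling_rate)
  as.numeric(signal::filtfilt(bf, x - mean(x)))
}

# Complex frequency response of the band-pass design at frequency f (Hz),
# single pass.  Used by tests as the analytic gain oracle.
bandpass_gain <- function(f, sampling_rate = SAMPLING_RATE) {
  bf <- butter_bandpass(sampling_rate)
  z <- exp(1i * 2 * pi * f / sampling_rate)
  Mod(sum(bf$b * z^-(seq_along(bf$b) - 1)) /
        sum(bf$a * z^-(seq_along(bf$a) - 1)))
}

#' Band-pass filter the accelerometer channels of a recording
#'
#' Gyroscope channels pass through unfiltered.  Channels containing missing
#' samples (defective events) are left untouched; their events are excluded
#' downstream.
#'
#' @param recording An `imu_recording`.
#' @return The recording with filtered accelerometer channels and attribute
#'   `"filtered"` set.
#' @export
filter_recording <- function(recording) {
  stopifnot(inherits(recording, "imu_recording"))
  if (isTRUE(attr(recording, "filtered"))) return(recording)
  for (ch in accel_channels()) {
    v <- recording$data[, ch]
    if (all(is.finite(v)))
      recording$data[, ch] <- bandpass_filter(v, recording$sampling_rate)
  }
  attr(recording, "filtered") <- TRUE
  recording
}

#' Detect the fall impact frame
#'
#' The impact time t_p is the frame of the maximum 3-axis acceleration-vector
#' magnitude, maximised over the three sensor locations, within the event
#' region.  Ties break to the earliest frame.  Expects filtered accelerometer
#' channels.
#'
#' @param recording An `imu_recording` (accelerometer channels filtered).
#' @param event One annotation row (a fall).
#' @return Integer impact frame t_p (0-based, within the region).
#' @export
detect_impact <- function(recording, event) {
  stopifnot(inherits(recording, "imu_recording"))
  if (event$activity_class != "fall")
    stopf("impact detection is defined for falls only (event %s is %s)",
          event$event_id, event$subtype)
  rows <- (event$region_start_frame + 1L):event$region_end_frame
  mag <- rep(-Inf, length(rows))
  for (loc in SENSOR_LOCATIONS) {
    m <- recording$data[rows, paste(loc, "acc", AXES, sep = "_"), drop = FALSE]
    loc_mag <- vec_mag(m)
    ok <- !is.na(loc_mag)
    mag[ok] <- pmax(mag[ok], loc_mag[ok])
  }
  if (!any(is.finite(mag)))
    stopf("event %s: all accelerometer samples missing", event$event_id)
  as.integer(event$region_start_frame + which.max(mag) - 1L)
}

#' Lead time in frames
#'
#' `ceiling(t_l * 500 / 1000)`: the realised lead is never shorter than
#' requested.
#'
#' @param lead_time_ms Lead time in milliseconds.
#' @return Integer frames.
#' @export
lead_frames <- function(lead_time_ms) as.integer(ceiling(lead_time_ms / 2))

new_event_window <- function(event, data, start_frame, end_frame, lead_time_ms) {
  structure(list(event_id = event$event_id, subject_id = event$subject_id,
                 activity_class = event$activity_class, subtype = event$subtype,
                 lead_time_ms = lead_time_ms,
                 start_frame = as.integer(start_frame),
                 end_frame = as.integer(end_frame),
                 data = data),
            class = "event_window")
}

#' @export
print.event_window <- function(x, ...) {
  cat(sprintf("<event_window %s (%s): frames [%d, %d), lead %s ms>\n",
              x$event_id, x$subtype, x$start_frame, x$end_frame,
              format(x$lead_time_ms)), sep = "")
  invisible(x)
}

#' Extract the pre-impact evaluation window of a fall
#'
#' The window spans frames `[t_p - lead - 250, t_p - lead)` (0-based,
#' half-open) with `lead = lead_frames(lead_time_ms)`.
#'
#' @param recording An `imu_recording`.
#' @param event Annotation row for the fall.
#' @param t_p Impact frame from [detect_impact()] (or the generator truth).
#' @param lead_time_ms Lead time t_l in milliseconds.
#' @return An `event_window` (250 x 18 matrix plus labels).  If the window
#'   would start before frame 0 a condition of class `window_infeasible` is
#'   signalled; pipeline callers catch it and log the exclusion.
#' @export
extract_fall_window <- function(recording, event, t_p, lead_time_ms) {
  lf <- lead_frames(lead_time_ms)
  t_e <- t_p - lf
  t_s <- t_e - WINDOW_FRAMES
  if (t_s < 0L)
    stop(structure(class = c("window_infeasible", "error", "condition"),
                   list(message = sprintf(
                     "event %s: window [%d, %d) starts before frame 0 at lead %s ms",
                     event$event_id, t_s, t_e, format(lead_time_ms)),
                     call = NULL)))
  data <- recording$data[(t_s + 1L):t_e, , drop = FALSE]
  new_event_window(event, data, t_s, t_e, lead_time_ms)
}

#' Extract a non-fall evaluation window
#'
#' The window end frame is drawn uniformly from the latter half of the event
#' region, `[midpoint, region_end]`; if the implied start precedes the region
#' start the draw is repeated (up to 10 times) and finally clipped to
#' `[region_start, region_start + 250)`.
#'
#' @param recording An `imu_recording`.
#' @param event Annotation row for the non-fall.
#' @param seed Integer seed making the draw reproducible.
#' @return An `event_window`.  Regions shorter than 250 frames signal a
#'   `window_infeasible` condition.
#' @export
extract_nonfall_window <- function(recording, event, seed) {
  if (event$activity_class != "non_fall")
    stopf("event %s is not a non-fall", event$event_id)
  rs <- event$region_start_frame
  re <- event$region_end_frame
  if (re - rs < WINDOW_FRAMES)
    stop(structure(class = c("window_infeasible", "error", "condition"),
                   list(message = sprintf(
                     "event %s: region of %d frames is shorter than the %d-frame window",
                     event$event_id, re - rs, WINDOW_FRAMES), call = NULL)))
  mid <- rs + (re - rs) %/% 2L
  withr::with_seed(seed, {
    t_e <- NA_integer_
    for (try in 1:10) {
      cand <- rs + sample.int(re - mid + 1L, 1L) + (mid - rs) - 1L  # uniform on [mid, re]
      if (cand - WINDOW_FRAMES >= rs) { t_e <- cand; break }
    }
    if (is.na(t_e)) t_e <- rs + WINDOW_FRAMES   # clip to region start
    t_s <- t_e - WINDOW_FRAMES
    data <- recording$data[(t_s + 1L):t_e, , drop = FALSE]
    new_event_window(event, data, t_s, t_e, NA_real_)
  })
}

#' Remove events flagged defective
#'
#' @param annotations Annotation data frame.
#' @return The surviving rows; the number excluded is recorded in attribute
#'   `"n_excluded"`.
#' @export
exclude_defective <- function(annotations) {
  keep <- !annotations$defective
  out <- annotations[keep, , drop = FALSE]
  attr(out, "n_excluded") <- sum(!keep)
  out
}
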