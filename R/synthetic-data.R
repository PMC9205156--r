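# Parametric generator of labelled multi-IMU fall / near-fall / ADL recordings.
#
# Falls follow a four-phase model: instability (growing angular velocity about
# the fall axis, roll-dominant for lateral falls, pitch-dominant for
# anterior-posterior falls), descent (acceleration magnitude dropping well
# below 1 g as the body approaches free fall), impact (a short spike of
# configured peak amplitude) and rest (static ~1 g in the terminal
# orientation).  Near-falls share the instability phase but end in a
# compensatory burst and recovery instead of an impact.  ADLs follow
# kind-specific templates; jumping is a deliberate hard negative with a
# sub-1 g flight phase and a landing spike.

EVENT_SUBTYPES <- c("lateral_fall", "ap_fall", "adl", "near_fall")
ADL_KINDS <- c("walk", "sit", "lie", "sit_to_stand", "jump")
FALL_SUBTYPES <- c("lateral_fall", "ap_fall")

# Cohort-level generating distributions for the kinematic parameters.
# Units: gait_speed m/s, gait_freq_hz steps/s, gait_asym unitless amplitude
# ratio, durations ms, instab_growth_dps deg/s per s, descent minima g,
# impact peak g, comp_gain unitless, noise SDs in g / deg/s.
kinematic_distributions <- function(cohort) {
  if (cohort == "control") {
    list(
      gait_speed       = c(1.22, 0.19),
      gait_freq_hz     = c(1.90, 0.15),
      gait_asym        = c(0.05, 0.02),
      instab_dur_ms    = c(450, 60),
      instab_growth_dps = c(320, 40),
      descent_dur_ms   = c(330, 40),
      descent_min_g    = c(0.15, 0.04),
      ap_descent_min_g = c(0.15, 0.04),
      ap_roll_mix      = c(0.05, 0.03),
      lat_pitch_mix    = c(0.05, 0.03),
      ap_tilt_gain     = c(1, 0.05),
      lat_tilt_gain    = c(1, 0.05),
      ap_gyro_gain     = c(1, 0.05),
      lat_gyro_gain    = c(1, 0.05),
      impact_peak_g    = c(8.0, 1.5),
      comp_gain        = c(1.20, 0.20)
    )
  } else {
    list(
      gait_speed       = c(0.88, 0.29),
      gait_freq_hz     = c(1.55, 0.18),
      gait_asym        = c(0.25, 0.08),
      instab_dur_ms    = c(700, 100),
      instab_growth_dps = c(240, 40),
      descent_dur_ms   = c(390, 50),
      descent_min_g    = c(0.25, 0.06),
      ap_descent_min_g = c(0.25, 0.06),
      ap_roll_mix      = c(0.05, 0.03),
      lat_pitch_mix    = c(0.05, 0.03),
      ap_tilt_gain     = c(1, 0.05),
      lat_tilt_gain    = c(1, 0.05),
      ap_gyro_gain     = c(1, 0.05),
      lat_gyro_gain    = c(1, 0.05),
      impact_peak_g    = c(8.0, 1.5),
      comp_gain        = c(0.75, 0.15)
    )
  }
}

# Parameter bounds enforced after drawing (sensor range, positivity).
KINEMATIC_BOUNDS <- list(
  gait_speed = c(0.2, 2.5), gait_freq_hz = c(0.6, 3), gait_asym = c(0, 0.6),
  instab_dur_ms = c(60, 2000), instab_growth_dps = c(40, 1500),
  descent_dur_ms = c(30, 1000), descent_min_g = c(0.02, 0.9),
  ap_descent_min_g = c(0.02, 0.9), ap_roll_mix = c(0, 1),
  lat_pitch_mix = c(0, 1), ap_tilt_gain = c(0.05, 1.5),
  lat_tilt_gain = c(0.05, 1.5), ap_gyro_gain = c(0.05, 1.5),
  lat_gyro_gain = c(0.05, 1.5), impact_peak_g = c(3, 16),
  comp_gain = c(0.2, 3)
)

# Multipliers applied to the kinematic-parameter means of unstable ambulators
# (more severe gait impairment: slower, more asymmetric, longer instability,
# weaker compensation).
UNSTABLE_MULTIPLIERS <- c(gait_speed = 0.85, gait_asym = 1.3,
                          instab_dur_ms = 1.3, comp_gain = 0.7)

#' Draw a subject profile from its cohort's generating distributions
#'
#' @param subject_id Character id.
#' @param cohort `"control"` or `"stroke"`.
#' @param severity `"stable"` or `"unstable"`; `"unstable"` is only valid for
#'   the stroke cohort and shifts parameter means toward more severe gait
#'   impairment.
#' @param seed Integer seed for the subject's parameter draw.
#' @param null_cohorts If `TRUE`, stroke subjects are drawn from the control
#'   cohort's generating distributions (null calibration: no kinematic cohort
#'   difference; labels are kept).
#' @param multipliers Optional named numeric vector of multipliers applied to
#'   this subject's parameter means (used to plant cohort effects).
#' @param noise_acc_g,noise_gyr_dps Channel noise standard deviations.
#' @return A `subject_profile` object: subject id, cohort, severity, gait
#'   speed and the named kinematic parameter set.
#' @export
subject_profile <- function(subject_id, cohort = c("control", "stroke"),
                            severity = c("stable", "unstable"),
                            seed = 1L, null_cohorts = FALSE,
                            multipliers = NULL,
                            noise_acc_g = 0.03, noise_gyr_dps = 1.5) {
  cohort <- match.arg(cohort)
  severity <- match.arg(severity)
  if (severity == "unstable" && cohort != "stroke")
    stopf("severity 'unstable' is only defined for the stroke cohort")
  dists <- kinematic_distributions(if (null_cohorts) "control" else cohort)
  mult <- rep(1, length(dists))
  names(mult) <- names(dists)
  if (severity == "unstable" && !null_cohorts)
    mult[names(UNSTABLE_MULTIPLIERS)] <-
      mult[names(UNSTABLE_MULTIPLIERS)] * UNSTABLE_MULTIPLIERS
  if (!is.null(multipliers)) {
    bad <- setdiff(names(multipliers), names(dists))
    if (length(bad)) stopf("unknown kinematic parameter(s): %s",
                           paste(bad, collapse = ", "))
    mult[names(multipliers)] <- mult[names(multipliers)] * multipliers
  }
  kin <- withr::with_seed(seed, {
    vals <- vapply(names(dists), function(nm) {
      d <- dists[[nm]]
      stats::rnorm(1, mean = d[1] * mult[[nm]], sd = d[2])
    }, numeric(1))
    vals
  })
  for (nm in names(kin)) {
    b <- KINEMATIC_BOUNDS[[nm]]
    kin[[nm]] <- min(max(kin[[nm]], b[1]), b[2])
  }
  kin <- c(as.list(kin), list(noise_acc_g = noise_acc_g,
                              noise_gyr_dps = noise_gyr_dps))
  structure(list(subject_id = subject_id, cohort = cohort,
                 severity = severity, gait_speed = kin$gait_speed,
                 kinematics = kin),
            class = "subject_profile")
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("<subject_profile %s: %s/%s, gait speed %.2f m/s>\n",
              x$subject_id, x$cohort, x$severity, x$gait_speed))
  invisible(x)
}

## ---- event synthesis primitives -------------------------------------------
## Each builder returns a list with gravity (n x 3, g), dynamic acceleration
## (n x 3, g), angular velocity (n x 3, deg/s) for the lower-back sensor, hip
## gains, and event-local phase boundaries / ground-truth impact offset.

# A fall's direction is an azimuth phi in the horizontal plane: the body
# tilts toward the unit vector u = (cos phi, sin phi) over (x = AP,
# y = lateral), rotating about the perpendicular horizontal axis
# (-sin phi, cos phi).  phi = 0 is a pure anterior-posterior fall
# (pitch-dominant gyro), phi = 90 deg a pure lateral fall (roll-dominant).
# The per-subject mixing parameters ap_roll_mix / lat_pitch_mix tilt these
# defaults, which lets cohort effects alter the rotation axis itself (e.g.
# paretic-side fall initiation).
fall_azimuth <- function(subtype, kin) {
  if (subtype == "ap_fall") kin$ap_roll_mix * pi / 2
  else (1 - kin$lat_pitch_mix) * pi / 2
}

synth_instability <- function(n, growth_dps, phi, dir, tilt_cap_deg = 25) {
  t <- seq_len(n) / SAMPLING_RATE
  omega <- growth_dps * t * (1 + 0.25 * sin(2 * pi * 5 * t))
  theta <- pmin(cumsum(omega) / SAMPLING_RATE, tilt_cap_deg) * pi / 180
  u <- c(cos(phi), sin(phi))          # tilt direction
  ax <- c(-sin(phi), cos(phi))        # rotation axis
  grav <- cbind(dir * sin(theta) * u[1], dir * sin(theta) * u[2], cos(theta))
  dyn <- cbind(0, 0, 0.04 * (t / max(t)) * sin(2 * pi * 7 * t))
  gyr <- cbind(dir * omega * ax[1], dir * omega * ax[2],
               0.15 * omega * sin(2 * pi * 3 * t))
  list(grav = grav, dyn = dyn, gyr = gyr,
       theta_end = theta[n] * 180 / pi, omega_end = omega[n])
}

synth_fall <- function(profile, subtype) {
  kin <- profile$kinematics
  phi <- fall_azimuth(subtype, kin)
  dir <- sample(c(-1, 1), 1)
  u <- c(cos(phi), sin(phi))
  ax <- c(-sin(phi), cos(phi))
  # tilt/gyro gains < 1 give a "collapse-type" fall: the body sinks with
  # little rotation until impact instead of toppling over
  tilt_gain <- if (subtype == "ap_fall") kin$ap_tilt_gain else kin$lat_tilt_gain
  gyro_gain <- if (subtype == "ap_fall") kin$ap_gyro_gain else kin$lat_gyro_gain
  n_i <- max(25L, as.integer(round(kin$instab_dur_ms / 2)))
  n_d <- max(15L, as.integer(round(kin$descent_dur_ms / 2)))
  n_imp <- as.integer(round(stats::runif(1, 20, 60) / 2))
  if (n_imp %% 2L == 0L) n_imp <- n_imp + 1L
  n_r <- as.integer(round(stats::runif(1, 400, 600) / 2))

  inst <- synth_instability(n_i, kin$instab_growth_dps * gyro_gain, phi, dir,
                            tilt_cap_deg = 25 * tilt_gain)

  min_g <- if (subtype == "ap_fall") kin$ap_descent_min_g else kin$descent_min_g
  s <- seq_len(n_d) / n_d
  mag <- min_g + (1 - min_g) * (1 + cos(pi * s)) / 2
  theta <- (inst$theta_end + (90 * tilt_gain - inst$theta_end) * s) * pi / 180
  grav_d <- cbind(dir * mag * sin(theta) * u[1], dir * mag * sin(theta) * u[2],
                  mag * cos(theta))
  omega_d <- inst$omega_end * (1 + 0.6 * s)
  gyr_d <- cbind(dir * omega_d * ax[1], dir * omega_d * ax[2],
                 0.1 * omega_d)

  prof_imp <- sin(pi * seq_len(n_imp) / (n_imp + 1L))
  grav_i <- cbind(dir * kin$impact_peak_g * prof_imp * u[1],
                  dir * kin$impact_peak_g * prof_imp * u[2],
                  0.5 * prof_imp)
  gyr_i <- cbind(dir * inst$omega_end * 1.6 * exp(-0.1 * seq_len(n_imp)) * ax[1],
                 dir * inst$omega_end * 1.6 * exp(-0.1 * seq_len(n_imp)) * ax[2],
                 0)

  grav_r <- matrix(0, n_r, 3)
  grav_r[, 1] <- dir * u[1]
  grav_r[, 2] <- dir * u[2]
  n <- n_i + n_d + n_imp + n_r
  peak_offset <- n_i + n_d + (n_imp + 1L) %/% 2L - 1L  # 0-based within event

  impact_vec <- c(dir * kin$impact_peak_g * u[1],
                  dir * kin$impact_peak_g * u[2], 0.5)

  list(grav = rbind(inst$grav, grav_d, grav_i, grav_r),
       dyn = rbind(inst$dyn, matrix(0, n_d + n_imp + n_r, 3)),
       gyr = rbind(inst$gyr, gyr_d, gyr_i, matrix(0, n_r, 3)),
       lgain = 1.05, rgain = 0.95,
       impact_offset = peak_offset,
       impact_vec = impact_vec,
       impact_peak_g = kin$impact_peak_g,
       phases = c(instability = 0L, descent = n_i, impact = n_i + n_d,
                  rest = n_i + n_d + n_imp, end = n))
}

synth_near_fall <- function(profile) {
  kin <- profile$kinematics
  phi <- fall_azimuth(sample(FALL_SUBTYPES, 1), kin)
  dir <- sample(c(-1, 1), 1)
  u <- c(cos(phi), sin(phi))
  ax <- c(-sin(phi), cos(phi))
  n_i <- max(25L, as.integer(round(0.9 * kin$instab_dur_ms / 2)))
  inst <- synth_instability(n_i, kin$instab_growth_dps, phi, dir,
                            tilt_cap_deg = 18)
  n_b <- 75L                                   # compensatory burst, 150 ms
  n_rec <- 250L                                # recovery, 500 ms
  tb <- seq_len(n_b) / SAMPLING_RATE
  burst <- -kin$comp_gain * inst$omega_end * sin(2 * pi * 4 * tb) *
    exp(-tb * 12)
  theta0 <- inst$theta_end * pi / 180
  s <- seq_len(n_b + n_rec) / (n_b + n_rec)
  theta <- theta0 * (1 - s)
  grav <- cbind(dir * sin(theta) * u[1], dir * sin(theta) * u[2], cos(theta))
  dyn <- matrix(0, n_b + n_rec, 3)
  dyn[seq_len(n_b), 3] <- -0.12 * kin$comp_gain * sin(pi * seq_len(n_b) / n_b)
  gyr <- matrix(0, n_b + n_rec, 3)
  gyr[seq_len(n_b), 1] <- dir * burst * ax[1]
  gyr[seq_len(n_b), 2] <- dir * burst * ax[2]
  n <- n_i + n_b + n_rec
  list(grav = rbind(inst$grav, grav), dyn = rbind(inst$dyn, dyn),
       gyr = rbind(inst$gyr, gyr), lgain = 1.05, rgain = 0.95,
       impact_offset = NA_integer_,
       phases = c(instability = 0L, burst = n_i, recovery = n_i + n_b, end = n))
}

synth_adl <- function(profile, kind) {
  kin <- profile$kinematics
  switch(kind,
    walk = {
      n <- as.integer(round(stats::rnorm(1, 2500, 250) / 2))
      n <- max(n, 2L * WINDOW_FRAMES + 50L)
      t <- seq_len(n) / SAMPLING_RATE
      f <- kin$gait_freq_hz
      amp <- 0.10 + 0.08 * kin$gait_speed
      grav <- matrix(0, n, 3); grav[, 3] <- 1
      dyn <- matrix(0, n, 3)
      dyn[, 3] <- amp * sin(2 * pi * f * t)
      dyn[, 1] <- 0.4 * amp * sin(2 * pi * f * t + pi / 3)
      dyn[, 2] <- 0.3 * amp * sin(2 * pi * f / 2 * t)
      gyr <- matrix(0, n, 3)
      gyr[, 2] <- (25 + 18 * kin$gait_speed) * sin(2 * pi * f * t + pi / 6)
      gyr[, 1] <- (12 + 10 * kin$gait_asym * 60) * sin(2 * pi * f / 2 * t)
      gyr[, 3] <- 8 * sin(2 * pi * f / 2 * t + pi / 4)
      list(grav = grav, dyn = dyn, gyr = gyr,
           lgain = 1 + kin$gait_asym / 2, rgain = 1 - kin$gait_asym / 2)
    },
    sit = {
      n <- 750L
      s <- seq_len(n) / n
      grav <- matrix(0, n, 3); grav[, 3] <- 1
      dyn <- matrix(0, n, 3)
      dyn[, 3] <- -0.2 * sin(pi * pmin(s / 0.6, 1)) +
        0.15 * sin(pi * pmax((s - 0.6) / 0.4, 0))
      gyr <- matrix(0, n, 3)
      gyr[, 2] <- 40 * sin(pi * pmin(s / 0.6, 1))
      list(grav = grav, dyn = dyn, gyr = gyr, lgain = 1.05, rgain = 0.95)
    },
    lie = {
      n <- 750L
      grav <- matrix(0, n, 3); grav[, 3] <- 1   # static, supine
      list(grav = grav, dyn = matrix(0, n, 3), gyr = matrix(0, n, 3),
           lgain = 1, rgain = 1)
    },
    sit_to_stand = {
      n <- 650L
      s <- seq_len(n) / n
      grav <- matrix(0, n, 3); grav[, 3] <- 1
      dyn <- matrix(0, n, 3)
      dyn[, 3] <- 0.22 * sin(pi * pmin(s / 0.5, 1)) -
        0.1 * sin(pi * pmax((s - 0.5) / 0.5, 0))
      gyr <- matrix(0, n, 3)
      gyr[, 2] <- -45 * sin(pi * pmin(s / 0.5, 1))
      list(grav = grav, dyn = dyn, gyr = gyr, lgain = 1.05, rgain = 0.95)
    },
    jump = {
      n_pre <- 150L; n_push <- 60L; n_fly <- 150L; n_land <- 21L; n_set <- 220L
      n <- n_pre + n_push + n_fly + n_land + n_set
      grav <- matrix(0, n, 3); grav[, 3] <- 1
      dyn <- matrix(0, n, 3)
      dyn[seq_len(n_pre), 3] <- -0.25 * sin(pi * seq_len(n_pre) / n_pre)
      i <- n_pre + seq_len(n_push)
      dyn[i, 3] <- 0.9 * sin(pi * seq_len(n_push) / n_push)
      i <- n_pre + n_push + seq_len(n_fly)
      dyn[i, 3] <- -0.8                               # flight: |a| ~ 0.2 g
      i <- n_pre + n_push + n_fly + seq_len(n_land)
      peak <- stats::runif(1, 3, 5)
      dyn[i, 3] <- (peak - 1) * sin(pi * seq_len(n_land) / (n_land + 1))
      gyr <- matrix(0, n, 3)
      gyr[, 2] <- 20 * sin(2 * pi * 2 * seq_len(n) / SAMPLING_RATE)
      list(grav = grav, dyn = dyn, gyr = gyr, lgain = 1.02, rgain = 0.98)
    },
    stopf("unknown ADL kind '%s'", kind))
}

# Quiet standing: static gravity plus channel noise (added at assembly).
# Deliberately the same process as static ADLs so that windows without any
# event signal are uninformative.
synth_baseline <- function(n, phase = 0) {
  grav <- matrix(0, n, 3); grav[, 3] <- 1
  list(grav = grav, dyn = matrix(0, n, 3), gyr = matrix(0, n, 3),
       lgain = 1, rgain = 1)
}

# Assemble an event/baseline block into the 18-channel layout with noise.
assemble_block <- function(block, noise_acc, noise_gyr) {
  n <- nrow(block$grav)
  out <- matrix(0, n, 18L)
  colnames(out) <- channel_names()
  gains <- c(lhip = block$lgain %||% 1, rhip = block$rgain %||% 1, back = 1)
  for (loc in SENSOR_LOCATIONS) {
    g <- gains[[loc]]
    acc <- block$grav + g * block$dyn
    gyr <- g * block$gyr
    if (noise_acc > 0) acc <- acc + matrix(stats::rnorm(n * 3, 0, noise_acc), n, 3)
    if (noise_gyr > 0) gyr <- gyr + matrix(stats::rnorm(n * 3, 0, noise_gyr), n, 3)
    out[, paste(loc, "acc", AXES, sep = "_")] <- acc
    out[, paste(loc, "gyr", AXES, sep = "_")] <- gyr
  }
  # the configured impact peak is attained exactly at the peak frame (sensor
  # pegged by the shock; noise there is negligible)
  if (!is.null(block$impact_offset) && !is.na(block$impact_offset %||% NA)) {
    i <- block$impact_offset + 1L
    for (loc in SENSOR_LOCATIONS) {        # same shock at all pelvis sensors
      cols <- paste(loc, "acc", AXES, sep = "_")
      out[i, cols] <- block$impact_vec
    }
  }
  acc_cols <- accel_channels(); gyr_cols <- gyro_channels()
  out[, acc_cols] <- pmin(pmax(out[, acc_cols], -ACCEL_RANGE_G), ACCEL_RANGE_G)
  out[, gyr_cols] <- pmin(pmax(out[, gyr_cols], -GYRO_RANGE_DPS), GYRO_RANGE_DPS)
  out
}

normalize_event_request <- function(events) {
  valid <- c(EVENT_SUBTYPES, ADL_KINDS)
  bad <- setdiff(events, valid)
  if (length(bad))
    stopf("unknown event subtype(s): %s (valid: %s)",
          paste(bad, collapse = ", "), paste(valid, collapse = ", "))
  events
}

#' Generate one subject's recording and event annotations
#'
#' Synthesises a single 18-channel recording containing the requested events
#' in randomised order, separated by quiet-standing baseline segments.  Fall
#' events follow the instability -> descent -> impact -> rest phase model;
#' annotations carry the generator's ground-truth impact frame and, as an
#' attribute `"phases"`, the event-local phase boundaries.
#'
#' @param profile A [subject_profile()].
#' @param events Character vector of requested event subtypes: any of
#'   `"lateral_fall"`, `"ap_fall"`, `"near_fall"`, `"adl"` (ADL kind drawn at
#'   random) or an explicit ADL kind (`"walk"`, `"sit"`, `"lie"`,
#'   `"sit_to_stand"`, `"jump"`).
#' @param seed Integer seed; the same profile, events and seed give a
#'   bit-identical recording and annotations.
#' @param gap_frames Baseline frames inserted before, between and after
#'   events.  Must be large enough that evaluation windows at the largest
#'   lead time of interest fit before the first event's impact.
#' @param shuffle Randomise event order within the session (default `TRUE`).
#' @param adl_kinds ADL kinds that an unspecific `"adl"` request draws from.
#' @return A list with elements `recording` (an `imu_recording`: subject id,
#'   sampling rate 500 Hz, and an n x 18 channel matrix) and `annotations`
#'   (one row per event; frames 0-based, regions half-open `[start, end)`).
#' @export
generate_subject <- function(profile, events, seed, gap_frames = 600L,
                             shuffle = TRUE, adl_kinds = ADL_KINDS) {
  stopifnot(inherits(profile, "subject_profile"))
  stopifnot(all(adl_kinds %in% ADL_KINDS))
  events <- normalize_event_request(events)
  if (!length(events)) stopf("no events requested")
  kin <- profile$kinematics
  withr::with_seed(seed, {
    order_idx <- if (shuffle) sample.int(length(events)) else seq_along(events)
    events <- events[order_idx]
    blocks <- vector("list", 2L * length(events) + 1L)
    ann <- vector("list", length(events))
    pha <- vector("list", length(events))
    pos <- 0L   # 0-based frame cursor
    blocks[[1L]] <- assemble_block(synth_baseline(gap_frames, stats::runif(1, 0, 2 * pi)),
                                   kin$noise_acc_g, kin$noise_gyr_dps)
    pos <- pos + gap_frames
    for (i in seq_along(events)) {
      ev <- events[i]
      if (ev %in% FALL_SUBTYPES) {
        blk <- synth_fall(profile, ev)
        subtype <- ev; class_ <- "fall"; kind <- NA_character_
      } else if (ev == "near_fall") {
        blk <- synth_near_fall(profile)
        subtype <- "near_fall"; class_ <- "non_fall"; kind <- NA_character_
      } else {
        kind <- if (ev == "adl") sample(adl_kinds, 1) else ev
        blk <- synth_adl(profile, kind)
        subtype <- "adl"; class_ <- "non_fall"
      }
      n_ev <- nrow(blk$grav)
      blocks[[2L * i]] <- assemble_block(blk, kin$noise_acc_g, kin$noise_gyr_dps)
      ann[[i]] <- data.frame(
        subject_id = profile$subject_id,
        event_id = sprintf("%s_e%03d", profile$subject_id, i),
        activity_class = class_, subtype = subtype, adl_kind = kind,
        region_start_frame = pos, region_end_frame = pos + n_ev,
        impact_frame = if (!is.null(blk$impact_offset) &&
                           !is.na(blk$impact_offset %||% NA))
          pos + blk$impact_offset else NA_integer_,
        defective = FALSE, stringsAsFactors = FALSE)
      if (!is.null(blk$phases))
        pha[[i]] <- data.frame(event_id = ann[[i]]$event_id,
                               phase = names(blk$phases),
                               frame = pos + unname(blk$phases),
                               stringsAsFactors = FALSE)
      pos <- pos + n_ev
      blocks[[2L * i + 1L]] <- assemble_block(
        synth_baseline(gap_frames, stats::runif(1, 0, 2 * pi)),
        kin$noise_acc_g, kin$noise_gyr_dps)
      pos <- pos + gap_frames
    }
    data <- do.call(rbind, blocks)
    annotations <- do.call(rbind, ann)
    attr(annotations, "phases") <- do.call(rbind, pha[!vapply(pha, is.null, logical(1))])
    recording <- structure(list(subject_id = profile$subject_id,
                                sampling_rate = SAMPLING_RATE, data = data),
                           class = "imu_recording")
    list(recording = recording, annotations = annotations)
  })
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording %s: %d frames x 18 channels @ %d Hz (%.1f s)>\n",
              x$subject_id, nrow(x$data), x$sampling_rate,
              nrow(x$data) / x$sampling_rate))
  invisible(x)
}

## ---- cohort dataset --------------------------------------------------------

default_control_counts <- function()
  c(lateral_fall = 283, ap_fall = 120, adl = 303, near_fall = 243)
default_stroke_counts <- function()
  c(lateral_fall = 327, ap_fall = 112, adl = 259, near_fall = 156)

#' Configure a synthetic cohort dataset
#'
#' Defaults follow the reference composition: 15 control and 20 stroke subjects
#' (5 unstable ambulators), with per-cohort event totals of 283/120 lateral/AP
#' falls and 303/243 ADLs/near-falls for control, and 327/112 and 259/156 for
#' stroke (842 falls and 961 non-falls in total).
#'
#' @param n_control,n_stroke,n_unstable Cohort sizes; `n_unstable` of the
#'   stroke subjects are labelled unstable ambulators.
#' @param control_counts,stroke_counts Named per-cohort event totals over
#'   `lateral_fall`, `ap_fall`, `adl`, `near_fall`; distributed as evenly as
#'   possible over subjects (each subject receives at least
#'   `floor(count / n)`).
#' @param null_cohorts If `TRUE`, stroke subjects' kinematics are drawn from
#'   the control distributions (no cohort effect; for null calibration).
#' @param stroke_multipliers,control_multipliers Optional named multipliers on
#'   the respective cohort's kinematic parameter means (used to plant
#'   effects).
#' @param unstable_multipliers Optional named multipliers applied, in addition,
#'   to unstable ambulators' means (on top of the built-in severity shift).
#' @param noise_acc_g,noise_gyr_dps Channel noise SDs (g, deg/s).
#' @param gap_frames Baseline frames between events.
#' @param adl_kinds ADL kinds drawn for `"adl"` events.
#' @param seed Master seed; all subject streams derive from it.
#' @return A `dataset_config` list.
#' @export
dataset_config <- function(n_control = 15L, n_stroke = 20L, n_unstable = 5L,
                           control_counts = default_control_counts(),
                           stroke_counts = default_stroke_counts(),
                           null_cohorts = FALSE,
                           stroke_multipliers = NULL,
                           control_multipliers = NULL,
                           unstable_multipliers = NULL,
                           noise_acc_g = 0.03, noise_gyr_dps = 1.5,
                           gap_frames = 600L, adl_kinds = ADL_KINDS,
                           seed = 1L) {
  for (cc in list(control_counts, stroke_counts)) {
    if (!all(EVENT_SUBTYPES %in% names(cc)))
      stopf("event counts must be named over: %s",
            paste(EVENT_SUBTYPES, collapse = ", "))
    if (any(cc < 0)) stopf("event counts must be >= 0")
  }
  if (n_unstable > n_stroke) stopf("n_unstable cannot exceed n_stroke")
  check_dist <- function(counts, n, label) {
    bad <- counts > 0 & counts < n
    if (any(bad))
      stopf("%s count(s) %s not distributable over %d subjects (need >= 1 each)",
            label, paste(names(counts)[bad], collapse = ", "), n)
  }
  check_dist(control_counts[EVENT_SUBTYPES], n_control, "control")
  check_dist(stroke_counts[EVENT_SUBTYPES], n_stroke, "stroke")
  structure(list(n_control = as.integer(n_control),
                 n_stroke = as.integer(n_stroke),
                 n_unstable = as.integer(n_unstable),
                 control_counts = control_counts[EVENT_SUBTYPES],
                 stroke_counts = stroke_counts[EVENT_SUBTYPES],
                 null_cohorts = isTRUE(null_cohorts),
                 stroke_multipliers = stroke_multipliers,
                 control_multipliers = control_multipliers,
                 unstable_multipliers = unstable_multipliers,
                 noise_acc_g = noise_acc_g, noise_gyr_dps = noise_gyr_dps,
                 gap_frames = as.integer(gap_frames),
                 adl_kinds = adl_kinds,
                 seed = as.integer(seed)),
            class = "dataset_config")
}

# Distribute `total` events over `n` subjects as evenly as possible
# (deterministic: the first `total %% n` subjects receive one extra).
distribute_counts <- function(total, n) {
  base <- total %/% n
  extra <- total %% n
  base + c(rep(1L, extra), rep(0L, n - extra))
}

#' Generate a full two-cohort dataset
#'
#' @param config A [dataset_config()].
#' @param keep_recordings If `FALSE`, channel data are dropped after
#'   annotation (composition audits need only the annotations).
#' @return A `fall_dataset` list: `profiles` (list of `subject_profile`),
#'   `recordings` (named list of `imu_recording`, or `NULL`s), `annotations`
#'   (one data frame over all subjects) and `config`.
#' @export
generate_cohort_dataset <- function(config = dataset_config(),
                                    keep_recordings = TRUE) {
  stopifnot(inherits(config, "dataset_config"))
  ids <- c(sprintf("C%02d", seq_len(config$n_control)),
           sprintf("S%02d", seq_len(config$n_stroke)))
  cohorts <- rep(c("control", "stroke"), c(config$n_control, config$n_stroke))
  unstable_ids <- withr::with_seed(derive_seed(config$seed, 0L), {
    sample(ids[cohorts == "stroke"], config$n_unstable)
  })
  profiles <- vector("list", length(ids))
  recordings <- stats::setNames(vector("list", length(ids)), ids)
  ann <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    cohort <- cohorts[i]
    severity <- if (ids[i] %in% unstable_ids) "unstable" else "stable"
    mult <- if (cohort == "stroke") config$stroke_multipliers
            else config$control_multipliers
    if (severity == "unstable" && !is.null(config$unstable_multipliers)) {
      um <- config$unstable_multipliers
      if (is.null(mult)) mult <- um
      else {
        shared <- intersect(names(mult), names(um))
        mult[shared] <- mult[shared] * um[shared]
        mult <- c(mult, um[setdiff(names(um), names(mult))])
      }
    }
    profiles[[i]] <- subject_profile(
      ids[i], cohort, severity, seed = derive_seed(config$seed, i),
      null_cohorts = config$null_cohorts && cohort == "stroke",
      multipliers = mult,
      noise_acc_g = config$noise_acc_g, noise_gyr_dps = config$noise_gyr_dps)
    counts <- if (cohort == "control") config$control_counts else config$stroke_counts
    idx_in_cohort <- if (cohort == "control") i else i - config$n_control
    n_cohort <- if (cohort == "control") config$n_control else config$n_stroke
    ev <- unlist(lapply(EVENT_SUBTYPES, function(st) {
      rep(st, distribute_counts(as.integer(counts[[st]]), n_cohort)[idx_in_cohort])
    }))
    out <- generate_subject(profiles[[i]], ev,
                            seed = derive_seed(config$seed, 1000L + i),
                            gap_frames = config$gap_frames,
                            adl_kinds = config$adl_kinds %||% ADL_KINDS)
    if (keep_recordings) recordings[[ids[i]]] <- out$recording
    ann[[i]] <- out$annotations
  }
  phases <- do.call(rbind, lapply(ann, attr, "phases"))
  annotations <- do.call(rbind, lapply(ann, function(a) { attr(a, "phases") <- NULL; a }))
  attr(annotations, "phases") <- phases
  structure(list(profiles = profiles, recordings = recordings,
                 annotations = annotations, config = config),
            class = "fall_dataset")
}

#' @export
print.fall_dataset <- function(x, ...) {
  a <- x$annotations
  cat(sprintf("<fall_dataset: %d subjects, %d events (%d falls / %d non-falls)>\n",
              length(x$profiles), nrow(a), sum(a$activity_class == "fall"),
              sum(a$activity_class == "non_fall")))
  invisible(x)
}

#' Flag a fraction of events as defective (channel dropout)
#'
#' Replaces one to three randomly chosen channels with missing values inside
#' the event region for exactly `floor(fraction * n_events)` events, and sets
#' their `defective` flag.  Mirrors hardware cable/connection damage that the
#' preprocessing stage must exclude.
#'
#' @param dataset A `fall_dataset`.
#' @param fraction Proportion of events to corrupt, in `[0, 1)`.
#' @param seed Integer seed; the corruption is reproducible.
#' @return The modified dataset.
#' @export
inject_defects <- function(dataset, fraction, seed = 1L) {
  stopifnot(inherits(dataset, "fall_dataset"))
  if (fraction < 0 || fraction >= 1) stopf("fraction must be in [0, 1)")
  n_bad <- as.integer(floor(fraction * nrow(dataset$annotations)))
  if (n_bad == 0L) return(dataset)
  withr::with_seed(seed, {
    idx <- sample.int(nrow(dataset$annotations), n_bad)
    for (i in idx) {
      ev <- dataset$annotations[i, ]
      rec <- dataset$recordings[[ev$subject_id]]
      if (!is.null(rec)) {
        ch <- sample(channel_names(), sample(1:3, 1))
        rows <- (ev$region_start_frame + 1L):ev$region_end_frame
        rec$data[rows, ch] <- NA_real_
        dataset$recordings[[ev$subject_id]] <- rec
      }
    }
    dataset$annotations$defective[idx] <- TRUE
  })
  dataset
}

#' Cohort manifest of generated subjects
#'
#' @param profiles List of `subject_profile` objects (or a `fall_dataset`).
#' @return Data frame with `subject_id`, `cohort`, `severity`, `gait_speed`.
#' @export
subject_manifest <- function(profiles) {
  if (inherits(profiles, "fall_dataset")) profiles <- profiles$profiles
  do.call(rbind, lapply(profiles, function(p)
    data.frame(subject_id = p$subject_id, cohort = p$cohort,
               severity = p$severity, gait_speed = p$gait_speed,
               stringsAsFactors = FALSE)))
}

#' Re-derive unstable-ambulator labels from generated kinematics
#'
#' A surrogate severity criterion: a stroke subject is labelled unstable when
#' generated gait speed falls below `speed_threshold` or the lower-trunk
#' (back-sensor) angular-velocity range during walking exceeds
#' `trunk_range_threshold`.  The generator assigns severity directly; this
#' operation exists to emulate deriving the label from a gait assessment.
#'
#' @param dataset A `fall_dataset` with recordings.
#' @param speed_threshold Gait speed cut-off, m/s.
#' @param trunk_range_threshold Back-sensor gyro range cut-off, deg/s.
#' @return Data frame `subject_id`, `cohort`, `derived_severity`.
#' @export
derive_severity_labels <- function(dataset, speed_threshold = 0.75,
                                   trunk_range_threshold = 120) {
  stopifnot(inherits(dataset, "fall_dataset"))
  man <- subject_manifest(dataset)
  res <- lapply(seq_len(nrow(man)), function(i) {
    sid <- man$subject_id[i]
    trunk_range <- NA_real_
    rec <- dataset$recordings[[sid]]
    walks <- dataset$annotations[dataset$annotations$subject_id == sid &
                                   !is.na(dataset$annotations$adl_kind) &
                                   dataset$annotations$adl_kind == "walk", ]
    if (!is.null(rec) && nrow(walks)) {
      g <- rec$data[, paste("back", "gyr", AXES, sep = "_"), drop = FALSE]
      rows <- unlist(lapply(seq_len(nrow(walks)), function(j)
        (walks$region_start_frame[j] + 1L):walks$region_end_frame[j]))
      trunk_range <- max(apply(g[rows, , drop = FALSE], 2,
                               function(v) diff(range(v, na.rm = TRUE))))
    }
    unstable <- man$cohort[i] == "stroke" &&
      (man$gait_speed[i] < speed_threshold ||
         (!is.na(trunk_range) && trunk_range > trunk_range_threshold))
    data.frame(subject_id = sid, cohort = man$cohort[i],
               derived_severity = if (unstable) "unstable" else "stable",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
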