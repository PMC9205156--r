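# Band-pass filtering, impact detection and window extraction.

test_that("the band-pass rejects DC and matches its analytic frequency response", {
  n <- 5000
  central <- (n * 0.1):(n * 0.9)
  y <- bandpass_filter(rep(1, n))
  expect_equal(length(y), n)
  expect_lt(abs(mean(y[central])), 1e-3)
  t <- (seq_len(n) - 1) / 500
  gain <- function(f) prefall:::bandpass_gain(f)   # single-pass |H|
  y10 <- bandpass_filter(sin(2 * pi * 10 * t))
  expect_equal(max(abs(y10[1000:4000])), gain(10)^2, tolerance = 0.01)
  y120 <- bandpass_filter(sin(2 * pi * 120 * t))
  expect_lte(max(abs(y120[1000:4000])), gain(120))
})

test_that("filtering is idempotent on band-limited content and rejects bad input", {
  t <- (0:4999) / 500
  x <- sin(2 * pi * 5 * t) + 0.5 * sin(2 * pi * 20 * t)
  y1 <- bandpass_filter(x)
  y2 <- bandpass_filter(y1)
  central <- 1000:4000
  expect_equal(y2[central], y1[central], tolerance = 0.01)
  expect_error(bandpass_filter(rnorm(20)), "too short")
  expect_error(bandpass_filter(c(rnorm(100), NA)), "non-finite")
  expect_error(bandpass_filter(rnorm(100), sampling_rate = 100), "500")
})

make_recording <- function(data) {
  colnames(data) <- channel_names()
  structure(list(subject_id = "T01", sampling_rate = 500L, data = data),
            class = "imu_recording")
}

spike_event <- function(region_end = 1000L) {
  data.frame(subject_id = "T01", event_id = "e1", activity_class = "fall",
             subtype = "lateral_fall", adl_kind = NA_character_,
             region_start_frame = 0L, region_end_frame = region_end,
             impact_frame = NA_integer_, defective = FALSE,
             stringsAsFactors = FALSE)
}

test_that("impact detection finds the magnitude peak with earliest-frame ties", {
  d <- matrix(0, 1000, 18)
  d[, 9] <- 1                               # back_acc_z ~ 1 g baseline
  d[501, 9] <- 8                            # single spike at frame 500
  rec <- make_recording(d)
  expect_equal(detect_impact(rec, spike_event()), 500L)
  d[101, 9] <- 8                            # equal spike earlier, frame 100
  expect_equal(detect_impact(make_recording(d), spike_event()), 100L)
  nonfall <- spike_event(); nonfall$activity_class <- "non_fall"
  nonfall$subtype <- "adl"
  expect_error(detect_impact(rec, nonfall), "falls only")
  d[] <- NA_real_
  expect_error(detect_impact(make_recording(d), spike_event()), "missing")
})

test_that("impact detection recovers generator ground truth within 50 ms", {
  p <- subject_profile("S01", "stroke", seed = 3)
  hits <- 0L
  n_events <- 0L
  for (s in 1:10) {
    out <- generate_subject(p, rep(c("lateral_fall", "ap_fall"), 5), seed = s)
    rec <- filter_recording(out$recording)
    for (i in seq_len(nrow(out$annotations))) {
      ev <- out$annotations[i, ]
      n_events <- n_events + 1L
      t_p <- detect_impact(rec, ev)
      hits <- hits + (abs(t_p - ev$impact_frame) <= 25L)
    }
  }
  expect_equal(n_events, 100L)
  expect_gte(hits / n_events, 0.95)
})

test_that("fall windows apply the lead-time equations exactly", {
  d <- matrix(rnorm(6000 * 18), 6000, 18)
  rec <- make_recording(d)
  ev <- spike_event(region_end = 6000L)
  w <- extract_fall_window(rec, ev, t_p = 5000L, lead_time_ms = 100)
  expect_equal(c(w$start_frame, w$end_frame), c(4700L, 4950L))
  expect_equal(dim(w$data), c(250L, 18L))
  expect_equal(w$data, d[4701:4950, ], ignore_attr = TRUE)
  w0 <- extract_fall_window(rec, ev, t_p = 5000L, lead_time_ms = 0)
  expect_equal(c(w0$start_frame, w0$end_frame), c(4750L, 5000L))
  # 75 ms rounds up to 38 frames so the realised lead is never shorter
  w75 <- extract_fall_window(rec, ev, t_p = 5000L, lead_time_ms = 75)
  expect_equal(w75$end_frame, 5000L - 38L)
  expect_error(extract_fall_window(rec, ev, t_p = 200L, lead_time_ms = 75),
               class = "window_infeasible")
})

test_that("increasing lead time strictly shifts fall windows earlier", {
  d <- matrix(0, 6000, 18)
  rec <- make_recording(d)
  ev <- spike_event(region_end = 6000L)
  leads <- c(0, 50, 75, 100, 150, 300, 500)
  ends <- vapply(leads, function(lt)
    extract_fall_window(rec, ev, 5000L, lt)$end_frame, numeric(1))
  expect_true(all(diff(ends) < 0))
  lens <- vapply(leads, function(lt) {
    w <- extract_fall_window(rec, ev, 5000L, lt)
    w$end_frame - w$start_frame
  }, numeric(1))
  expect_true(all(lens == 250))
})

nonfall_event <- function(start, end) {
  data.frame(subject_id = "T01", event_id = "e2", activity_class = "non_fall",
             subtype = "adl", adl_kind = "walk",
             region_start_frame = start, region_end_frame = end,
             impact_frame = NA_integer_, defective = FALSE,
             stringsAsFactors = FALSE)
}

test_that("non-fall windows fall in the latter half of the region", {
  rec <- make_recording(matrix(0, 1200, 18))
  ev <- nonfall_event(0L, 1000L)
  for (s in 1:25) {
    w <- extract_nonfall_window(rec, ev, seed = s)
    expect_equal(w$end_frame - w$start_frame, 250L)
    expect_gte(w$end_frame, 500L)
    expect_lte(w$end_frame, 1000L)
  }
  # degenerate region exactly one window long
  w <- extract_nonfall_window(make_recording(matrix(0, 250, 18)),
                              nonfall_event(0L, 250L), seed = 1)
  expect_equal(c(w$start_frame, w$end_frame), c(0L, 250L))
  expect_error(extract_nonfall_window(make_recording(matrix(0, 200, 18)),
                                      nonfall_event(0L, 200L), seed = 1),
               class = "window_infeasible")
})

test_that("non-fall window ends are uniform over the latter half", {
  rec <- make_recording(matrix(0, 1000, 18))
  ev <- nonfall_event(0L, 1000L)
  ends <- vapply(1:10000, function(s)
    extract_nonfall_window(rec, ev, seed = s)$end_frame, numeric(1))
  # chi-squared goodness of fit against the discrete uniform on [500, 1000]
  bins <- cut(ends, breaks = seq(499.5, 1000.5, length.out = 11))
  gof <- suppressWarnings(chisq.test(table(bins)))
  expect_gt(gof$p.value, 1e-4)
})

test_that("defective events are excluded; missingness outside windows is kept", {
  ann <- do.call(rbind, replicate(100, spike_event(), simplify = FALSE))
  ann$event_id <- sprintf("e%03d", 1:100)
  ann$defective[1:10] <- TRUE
  kept <- exclude_defective(ann)
  expect_equal(nrow(kept), 90L)
  expect_equal(attr(kept, "n_excluded"), 10L)
  expect_identical(exclude_defective(ann[11:100, ])$event_id, ann$event_id[11:100])

  # an event with NAs only outside its window survives the pipeline
  ds <- tiny_dataset()
  ds2 <- ds
  ev <- ds2$annotations[ds2$annotations$activity_class == "fall", ][1, ]
  rec <- ds2$recordings[[ev$subject_id]]
  rec$data[(ev$region_end_frame - 10):ev$region_end_frame, "back_gyr_x"] <- NA
  ds2$recordings[[ev$subject_id]] <- rec
  fm <- build_feature_matrix(ds2, lead_time_ms = 75, seed = 5)
  expect_true(ev$event_id %in% fm$event_id)

  # flagged events never reach the feature matrix
  bad <- inject_defects(ds, 0.1, seed = 8)
  fmb <- build_feature_matrix(bad, lead_time_ms = 75, seed = 5)
  flagged <- bad$annotations$event_id[bad$annotations$defective]
  expect_length(intersect(flagged, fmb$event_id), 0)
  excl <- attr(fmb, "exclusions")
  expect_setequal(excl$event_id[excl$reason == "defective"], flagged)
})
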