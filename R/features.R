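# Statistical feature extraction: 7 statistics per channel over the 250-frame
# evaluation window, 126 features in total.
#
# Conventions (centralised here so alternates are switchable in one place):
# std is the sample standard deviation (n-1 denominator); skew is the
# Fisher-Pearson standardised third moment (biased, moment type 1); kurtosis
# is excess kurtosis (normal -> 0, same moment type); the interquartile range
# uses linearly interpolated percentiles (quantile type 7).  Zero-variance
# channels yield skew = 0 and kurtosis = 0 by convention.

WINDOW_STATS <- c("min", "median", "max", "iqr", "std", "skew", "kurtosis")

#' Feature column names
#'
#' `{location}_{modality}_{axis}_{stat}` over the 18 channels and 7
#' statistics, sorted in C-locale lexicographic order for a reproducible
#' column layout.
#'
#' @return Character vector of length 126.
#' @export
feature_names <- function() {
  nm <- as.vector(outer(channel_names(), WINDOW_STATS, paste, sep = "_"))
  sort(nm, method = "radix")
}

FEATURE_LABELS <- c("event_id", "subject_id", "cohort", "activity_class",
                    "subtype", "lead_time_ms")

channel_stats <- function(v) {
  s <- stats::sd(v)
  c(min = min(v), median = stats::median(v), max = max(v),
    iqr = unname(diff(stats::quantile(v, c(0.25, 0.75), type = 7))),
    std = s,
    skew = if (s > 0) e1071::skewness(v, type = 1) else 0,
    kurtosis = if (s > 0) e1071::kurtosis(v, type = 1) else 0)
}

#' Extract the 126-feature statistical vector of a window
#'
#' @param window An `event_window` (250 frames x 18 channels, finite).
#' @return Named numeric vector of length 126 in [feature_names()] order.
#' @export
extract_features <- function(window) {
  stopifnot(inherits(window, "event_window"))
  m <- window$data
  if (nrow(m) != WINDOW_FRAMES || ncol(m) != 18L)
    stopf("window %s must be %d x 18", window$event_id, WINDOW_FRAMES)
  if (any(!is.finite(m)))
    stopf("window %s contains missing samples; defective events must be excluded upstream",
          window$event_id)
  vals <- vapply(channel_names(), function(ch) channel_stats(m[, ch]),
                 numeric(length(WINDOW_STATS)))
  out <- as.vector(vals)
  names(out) <- as.vector(vapply(channel_names(), function(ch)
    paste(ch, WINDOW_STATS, sep = "_"), character(length(WINDOW_STATS))))
  out[feature_names()]
}

#' Build the labelled feature matrix of a dataset
#'
#' Runs the preprocessing pipeline over every surviving event: accelerometer
#' channels are band-pass filtered, the fall impact is detected, the
#' lead-time-anchored fall window (or the random latter-half non-fall window)
#' is extracted, and the 126 statistics are computed.  Defective events,
#' events whose window is infeasible and windows containing missing samples
#' are excluded and logged.
#'
#' @param dataset A `fall_dataset` with recordings.
#' @param lead_time_ms Lead time t_l in ms (default 75, the device's minimal
#'   lead time).
#' @param nonfall_filter Which non-falls to keep: `"both"`, `"adl_only"` or
#'   `"nearfall_only"`.
#' @param seed Integer seed driving the non-fall window draws.
#' @param use_true_impact Use the generator's ground-truth impact frame
#'   instead of [detect_impact()] (for generator audits only).
#' @return A `fall_features` data frame: 126 feature columns plus label
#'   columns `event_id`, `subject_id`, `cohort`, `activity_class`, `subtype`,
#'   `lead_time_ms`.  Attribute `"exclusions"` is a data frame of excluded
#'   events and reasons.
#' @export
build_feature_matrix <- function(dataset, lead_time_ms = 75,
                                 nonfall_filter = c("both", "adl_only", "nearfall_only"),
                                 seed = 1L, use_true_impact = FALSE) {
  stopifnot(inherits(dataset, "fall_dataset"))
  nonfall_filter <- match.arg(nonfall_filter)
  ann <- exclude_defective(dataset$annotations)
  excl <- list()
  if (attr(ann, "n_excluded") > 0L) {
    bad <- dataset$annotations[dataset$annotations$defective, ]
    excl <- lapply(bad$event_id, function(id)
      data.frame(event_id = id, reason = "defective", stringsAsFactors = FALSE))
  }
  keep <- ann$activity_class == "fall" |
    switch(nonfall_filter,
           both = rep(TRUE, nrow(ann)),
           adl_only = ann$subtype == "adl",
           nearfall_only = ann$subtype == "near_fall")
  ann <- ann[keep, , drop = FALSE]
  cohorts <- stats::setNames(
    vapply(dataset$profiles, `[[`, character(1), "cohort"),
    vapply(dataset$profiles, `[[`, character(1), "subject_id"))
  filtered <- list()
  feat_mat <- matrix(NA_real_, nrow(ann), length(feature_names()),
                     dimnames = list(NULL, feature_names()))
  ok <- rep(FALSE, nrow(ann))
  for (i in seq_len(nrow(ann))) {
    ev <- ann[i, ]
    rec <- filtered[[ev$subject_id]]
    if (is.null(rec)) {
      rec <- dataset$recordings[[ev$subject_id]]
      if (is.null(rec)) stopf("no recording for subject %s", ev$subject_id)
      rec <- filter_recording(rec)
      filtered[[ev$subject_id]] <- rec
    }
    w <- tryCatch({
      if (ev$activity_class == "fall") {
        t_p <- if (use_true_impact) ev$impact_frame else detect_impact(rec, ev)
        extract_fall_window(rec, ev, t_p, lead_time_ms)
      } else {
        extract_nonfall_window(rec, ev, seed = derive_seed(seed, i))
      }
    }, window_infeasible = function(e) e)
    if (inherits(w, "window_infeasible")) {
      excl[[length(excl) + 1L]] <- data.frame(
        event_id = ev$event_id, reason = "window_infeasible",
        stringsAsFactors = FALSE)
      next
    }
    if (any(!is.finite(w$data))) {
      excl[[length(excl) + 1L]] <- data.frame(
        event_id = ev$event_id, reason = "missing_in_window",
        stringsAsFactors = FALSE)
      next
    }
    feat_mat[i, ] <- extract_features(w)
    ok[i] <- TRUE
  }
  if (!any(ok))
    stopf("no events survive filtering (filter '%s')", nonfall_filter)
  out <- data.frame(feat_mat[ok, , drop = FALSE], check.names = FALSE,
                    stringsAsFactors = FALSE)
  out$event_id <- ann$event_id[ok]
  out$subject_id <- ann$subject_id[ok]
  out$cohort <- unname(cohorts[ann$subject_id[ok]])
  out$activity_class <- ann$activity_class[ok]
  out$subtype <- ann$subtype[ok]
  out$lead_time_ms <- lead_time_ms
  rownames(out) <- NULL
  exclusions <- if (length(excl)) do.call(rbind, excl)
    else data.frame(event_id = character(), reason = character(),
                    stringsAsFactors = FALSE)
  structure(out, exclusions = exclusions,
            class = c("fall_features", "data.frame"))
}

#' Restrict a feature matrix by fall type and cohort
#'
#' @param features A `fall_features` data frame.
#' @param fall_type `"all"`, `"lateral"` or `"ap"`: which fall subtype to
#'   keep (non-falls are always kept).
#' @param cohort Optionally restrict to `"control"` or `"stroke"` rows.
#' @return The filtered `fall_features`.
#' @export
filter_features <- function(features, fall_type = c("all", "lateral", "ap"),
                            cohort = NULL) {
  fall_type <- match.arg(fall_type)
  keep <- rep(TRUE, nrow(features))
  if (fall_type != "all") {
    st <- paste0(fall_type, "_fall")
    keep <- features$activity_class == "non_fall" | features$subtype == st
  }
  if (!is.null(cohort)) keep <- keep & features$cohort == cohort
  out <- features[keep, , drop = FALSE]
  attr(out, "exclusions") <- attr(features, "exclusions")
  class(out) <- class(features)
  out
}

feature_columns <- function(features) {
  as.matrix(features[, feature_names(), drop = FALSE])
}
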