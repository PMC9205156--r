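# CSV interchange formats.  Recordings are wide CSV (frame + 18 channel
# columns); annotations, subject manifests and feature matrices are plain
# CSV with validated headers.  Frames are 0-based, regions half-open
# [start, end).

#' Write / read a recording as wide CSV
#'
#' One row per frame: column `frame` (0-based) then the 18 channel columns
#' in [channel_names()] order.
#'
#' @param recording An `imu_recording`.
#' @param path Output file.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns an `imu_recording`.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "imu_recording"))
  df <- data.frame(frame = seq_len(nrow(recording$data)) - 1L,
                   recording$data, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @param subject_id Subject id to attach on read (defaults to the file
#'   name).
#' @export
read_recording <- function(path, subject_id = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(c("frame", channel_names()), names(df))
  if (length(missing))
    stopf("recording file %s lacks column(s): %s", path,
          paste(missing, collapse = ", "))
  structure(list(subject_id = subject_id %||%
                   sub("\\.csv$", "", basename(path)),
                 sampling_rate = SAMPLING_RATE,
                 data = as.matrix(df[, channel_names()])),
            class = "imu_recording")
}

ANNOTATION_COLUMNS <- c("subject_id", "event_id", "activity_class", "subtype",
                        "adl_kind", "region_start_frame", "region_end_frame",
                        "impact_frame", "defective")

validate_annotations <- function(ann, context = "annotations") {
  missing <- setdiff(ANNOTATION_COLUMNS, names(ann))
  if (length(missing))
    stopf("%s lack column(s): %s", context, paste(missing, collapse = ", "))
  if (any(ann$region_start_frame >= ann$region_end_frame))
    stopf("%s: region_start_frame must be < region_end_frame", context)
  is_fall <- ann$activity_class == "fall"
  if (!all(ann$subtype[is_fall] %in% FALL_SUBTYPES) ||
      any(ann$subtype[!is_fall] %in% FALL_SUBTYPES))
    stopf("%s: subtype inconsistent with activity_class", context)
  if (any(is.na(ann$impact_frame[is_fall])))
    stopf("%s: fall events must carry an impact_frame", context)
  if (any(!is.na(ann$impact_frame[!is_fall])))
    stopf("%s: non-fall events must not carry an impact_frame", context)
  in_region <- is.na(ann$impact_frame) |
    (ann$impact_frame >= ann$region_start_frame &
       ann$impact_frame < ann$region_end_frame)
  if (!all(in_region)) stopf("%s: impact_frame outside its region", context)
  invisible(ann)
}

#' Write / read event annotations as CSV
#'
#' Columns `subject_id, event_id, activity_class, subtype, adl_kind,
#' region_start_frame, region_end_frame, impact_frame, defective`; frames
#' 0-based, regions half-open.  Reading validates the invariants (region
#' ordering, impact frame present exactly for falls and inside the region).
#'
#' @param annotations Annotation data frame.
#' @param path CSV file.
#' @export
write_annotations <- function(annotations, path) {
  validate_annotations(annotations)
  utils::write.csv(annotations[, ANNOTATION_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  ann$adl_kind <- as.character(ann$adl_kind)
  validate_annotations(ann, context = sprintf("annotation file %s", path))
  ann
}

#' Write the subject manifest plus kinematic ground-truth sidecar
#'
#' The manifest CSV holds `subject_id, cohort, severity, gait_speed`; the
#' sidecar JSON holds each subject's full generated kinematic parameter set.
#'
#' @param profiles List of `subject_profile`s or a `fall_dataset`.
#' @param path Manifest CSV path.
#' @param sidecar_path Optional JSON path for the kinematic parameters.
#' @export
write_manifest <- function(profiles, path, sidecar_path = NULL) {
  if (inherits(profiles, "fall_dataset")) profiles <- profiles$profiles
  utils::write.csv(subject_manifest(profiles), path, row.names = FALSE)
  if (!is.null(sidecar_path)) {
    kin <- lapply(profiles, `[[`, "kinematics")
    names(kin) <- vapply(profiles, `[[`, character(1), "subject_id")
    jsonlite::write_json(kin, sidecar_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Write / read a feature matrix as CSV
#'
#' 126 feature columns in [feature_names()] order followed by the label
#' columns `event_id, subject_id, cohort, activity_class, subtype,
#' lead_time_ms`.  Reading rejects files with a missing feature or label
#' column, naming it.
#'
#' @param features A `fall_features` data frame.
#' @param path CSV file.
#' @export
write_feature_matrix <- function(features, path) {
  cols <- c(feature_names(), FEATURE_LABELS)
  utils::write.csv(features[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(c(feature_names(), FEATURE_LABELS), names(df))
  if (length(missing))
    stopf("feature matrix %s lacks column(s): %s", path,
          paste(missing, collapse = ", "))
  structure(df, class = c("fall_features", "data.frame"))
}
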