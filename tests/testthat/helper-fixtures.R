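# Shared fixtures and independent oracles.  Datasets are generated in code
# (never stored) and cached per session so several test files can reuse them.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- force(expr)
  .fixture_env[[name]]
}

tiny_counts <- function(n) c(lateral_fall = 2L * n, ap_fall = 2L * n,
                             adl = 2L * n, near_fall = 2L * n)

tiny_config <- function(seed = 11L, n_control = 3L, n_stroke = 4L,
                        gap_frames = 400L, ...) {
  dataset_config(n_control = n_control, n_stroke = n_stroke, n_unstable = 0L,
                 control_counts = tiny_counts(n_control),
                 stroke_counts = tiny_counts(n_stroke),
                 gap_frames = gap_frames, seed = seed, ...)
}

tiny_dataset <- function() fixture("tiny_dataset", {
  generate_cohort_dataset(tiny_config())
})

tiny_features <- function() fixture("tiny_features", {
  build_feature_matrix(tiny_dataset(), lead_time_ms = 75, seed = 5)
})

# Build an event_window by hand from a 250 x 18 matrix.
make_window <- function(data, event_id = "w1", activity_class = "fall",
                        subtype = "lateral_fall") {
  colnames(data) <- channel_names()
  structure(list(event_id = event_id, subject_id = "T01",
                 activity_class = activity_class, subtype = subtype,
                 lead_time_ms = 75, start_frame = 0L, end_frame = 250L,
                 data = data),
            class = "event_window")
}

# --- independent oracles -----------------------------------------------------

# AUC as the Mann-Whitney pairwise concordance (ties count one half).
concordance_auc <- function(scores, truth) {
  pos <- scores[truth == "fall"]
  neg <- scores[truth == "non_fall"]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Literal Holm step-down: scan the sorted P values, rejecting while
# P_(k) < alpha / (m + 1 - k), stopping at the first failure.
brute_holm <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  reject <- logical(m)
  for (k in seq_len(m)) {
    if (p[ord[k]] < alpha / (m + 1 - k)) reject[ord[k]] <- TRUE
    else break
  }
  reject
}

# Exhaustive weighted decision-stump search over every feature, threshold
# midpoint and polarity; returns the minimal weighted error.
brute_stump_error <- function(x, y, w) {
  best <- Inf
  yp <- ifelse(y == "fall", 1, -1)
  for (j in seq_len(ncol(x))) {
    v <- sort(unique(x[, j]))
    if (length(v) < 2) next
    thr <- (v[-1] + v[-length(v)]) / 2
    for (t in thr) for (pol in c(1, -1)) {
      pred <- ifelse(x[, j] <= t, 1, -1) * pol
      best <- min(best, sum(w[pred != yp]))
    }
  }
  best
}
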