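# Cohort-dependent evaluation schemes: leave-one-subject-out on the stroke
# cohort, the control-trained model tested per stroke subject, the
# severity-stratified leave-one-group-out scheme, and the lead-time sweep.
# Every scheme asserts subject-level train/test disjointness.

METRIC_NAMES <- c("recall", "precision", "f1", "auc")

new_eval_report <- function(scheme, iterations, train_sets, config) {
  defined <- lapply(METRIC_NAMES, function(m) iterations[[m]][!is.na(iterations[[m]])])
  names(defined) <- METRIC_NAMES
  summary <- data.frame(
    metric = METRIC_NAMES,
    mean = vapply(defined, function(v) if (length(v)) mean(v) else NA_real_,
                  numeric(1)),
    sd = vapply(defined, function(v) if (length(v) > 1L) stats::sd(v) else NA_real_,
                numeric(1)),
    n_defined = vapply(defined, length, integer(1)),
    stringsAsFactors = FALSE)
  structure(list(scheme = scheme, iterations = iterations, summary = summary,
                 train_sets = train_sets, config = config),
            class = "fall_eval")
}

#' @export
print.fall_eval <- function(x, ...) {
  cat(sprintf("<fall_eval '%s': %d iteration(s)>\n", x$scheme,
              nrow(x$iterations)))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-9s mean %.3f  sd %s  (n = %d)\n", s$metric[i], s$mean[i],
                ifelse(is.na(s$sd[i]), "   NA", sprintf("%.3f", s$sd[i])),
                s$n_defined[i]))
  invisible(x)
}

#' @export
summary.fall_eval <- function(object, ...) object$summary

assert_no_leakage <- function(train_subjects, test_subjects) {
  common <- intersect(train_subjects, test_subjects)
  if (length(common))
    stopf("subject-level leakage: %s in both train and test",
          paste(common, collapse = ", "))
}

eval_one <- function(model, test_features) {
  scores <- predict(model, test_features, type = "score")
  predicted <- ifelse(scores > 0, POSITIVE_CLASS, NEGATIVE_CLASS)
  compute_metrics(scores, predicted, test_features$activity_class)
}

metrics_row <- function(test_unit, m) {
  data.frame(test_unit = test_unit, tp = m$tp, fp = m$fp, fn = m$fn, tn = m$tn,
             recall = m$recall, precision = m$precision, f1 = m$f1,
             auc = m$auc, stringsAsFactors = FALSE)
}

#' Leave-one-subject-out evaluation on one cohort
#'
#' Each subject is held out once; the classifier is trained on all remaining
#' subjects' rows and tested on the held-out subject's rows.
#'
#' @param features A `fall_features` matrix (typically the stroke cohort).
#' @param n_rounds,learning_rate Boosting hyperparameters.
#' @param seed Accepted for interface symmetry (training is deterministic).
#' @return A `fall_eval` report with one iteration per subject, per-iteration
#'   confusion counts and metrics, and means/SDs over defined iterations.
#' @export
evaluate_loso <- function(features, n_rounds = 50L, learning_rate = 1,
                          seed = NULL) {
  subjects <- sort(unique(features$subject_id))
  if (length(subjects) < 3L)
    stopf("leave-one-subject-out needs >= 3 subjects (have %d)",
          length(subjects))
  iters <- vector("list", length(subjects))
  train_sets <- list()
  for (k in seq_along(subjects)) {
    s <- subjects[k]
    train <- features[features$subject_id != s, , drop = FALSE]
    test <- features[features$subject_id == s, , drop = FALSE]
    class(train) <- class(test) <- class(features)
    assert_no_leakage(unique(train$subject_id), s)
    model <- fall_adaboost(feature_columns(train), train$activity_class,
                           n_rounds = n_rounds, learning_rate = learning_rate)
    iters[[k]] <- metrics_row(s, eval_one(model, test))
    train_sets[[s]] <- unique(train$subject_id)
  }
  new_eval_report("loso", do.call(rbind, iters), train_sets,
                  list(n_rounds = n_rounds, learning_rate = learning_rate))
}

#' Control-trained model tested per stroke subject
#'
#' One model is trained on all control rows and tested iteratively on each
#' stroke subject, so that iterations pair one-to-one with
#' [evaluate_loso()] run on the stroke cohort.
#'
#' @param control_features,stroke_features `fall_features` for the two
#'   cohorts.
#' @inheritParams evaluate_loso
#' @return A `fall_eval` report with one iteration per stroke subject.
#' @export
evaluate_control_trained <- function(control_features, stroke_features,
                                     n_rounds = 50L, learning_rate = 1,
                                     seed = NULL) {
  if (!nrow(control_features) || !nrow(stroke_features))
    stopf("both feature matrices must be non-empty")
  assert_no_leakage(unique(control_features$subject_id),
                    unique(stroke_features$subject_id))
  model <- fall_adaboost(feature_columns(control_features),
                         control_features$activity_class,
                         n_rounds = n_rounds, learning_rate = learning_rate)
  subjects <- sort(unique(stroke_features$subject_id))
  iters <- vector("list", length(subjects))
  for (k in seq_along(subjects)) {
    test <- stroke_features[stroke_features$subject_id == subjects[k], ,
                            drop = FALSE]
    class(test) <- class(stroke_features)
    iters[[k]] <- metrics_row(subjects[k], eval_one(model, test))
  }
  rep <- new_eval_report("control_trained", do.call(rbind, iters),
                         list(all = unique(control_features$subject_id)),
                         list(n_rounds = n_rounds,
                              learning_rate = learning_rate))
  rep$model <- model
  rep
}

#' Enumerate severity-stratified test subgroups
#'
#' All (or a seeded sample of) size-5 stroke subgroups containing exactly
#' `k_unstable` unstable ambulators.  When the number of feasible
#' combinations is at most `max_groups` every subgroup is returned (verified
#' against exhaustive enumeration in the tests); otherwise `max_groups`
#' distinct subgroups are sampled without replacement.  With the reference
#' composition (5 unstable / 15 other) and `max_groups = 100` this yields
#' 100, 100, 100, 100, 75 and 1 subgroups for k = 0..5.
#'
#' @param profiles List of `subject_profile`s, a `fall_dataset`, or a
#'   manifest data frame with `subject_id`, `cohort`, `severity`.
#' @param k_unstable Number of unstable ambulators per subgroup (0-5).
#' @param max_groups Cap on the number of subgroups.
#' @param seed Integer seed for the sampling branch.
#' @param group_size Subgroup size (5 in the reference design).
#' @return List of character vectors of subject ids (each sorted).
#' @export
enumerate_severity_subgroups <- function(profiles, k_unstable,
                                         max_groups = 100L, seed = 1L,
                                         group_size = 5L) {
  man <- if (is.data.frame(profiles)) profiles else subject_manifest(profiles)
  man <- man[man$cohort == "stroke", , drop = FALSE]
  unstable <- sort(man$subject_id[man$severity == "unstable"])
  stable <- sort(man$subject_id[man$severity != "unstable"])
  if (k_unstable < 0L || k_unstable > group_size)
    stopf("k_unstable must be between 0 and %d", group_size)
  if (k_unstable > length(unstable))
    stopf("infeasible: %d unstable requested but only %d available",
          k_unstable, length(unstable))
  k_stable <- group_size - k_unstable
  if (k_stable > length(stable))
    stopf("infeasible: %d stable requested but only %d available",
          k_stable, length(stable))
  total <- choose(length(unstable), k_unstable) *
    choose(length(stable), k_stable)
  pick <- function(pool, k) {
    if (k == 0L) list(character(0))
    else apply(utils::combn(pool, k), 2, identity, simplify = FALSE)
  }
  if (total <= max_groups) {
    groups <- list()
    for (u in pick(unstable, k_unstable))
      for (s in pick(stable, k_stable))
        groups[[length(groups) + 1L]] <- sort(c(u, s))
    return(groups)
  }
  withr::with_seed(seed, {
    seen <- character()
    groups <- list()
    while (length(groups) < max_groups) {
      g <- sort(c(if (k_unstable) sample(unstable, k_unstable),
                  if (k_stable) sample(stable, k_stable)))
      key <- paste(g, collapse = "+")
      if (!(key %in% seen)) {
        seen <- c(seen, key)
        groups[[length(groups) + 1L]] <- g
      }
    }
    groups
  })
}

#' Severity-stratified leave-one-group-out evaluation
#'
#' For each k (number of unstable ambulators in the 5-subject test subgroup)
#' and each subgroup: the stroke-trained model is trained on the stroke
#' subjects outside the subgroup, the control-trained model on all control
#' subjects; both are tested on the subgroup's rows.
#'
#' @param control_features,stroke_features `fall_features` for the cohorts.
#' @param profiles Profiles/manifest carrying the severity labels.
#' @param ks Values of k to evaluate (default 0:5).
#' @param max_groups Subgroup cap per k (study design: 100).
#' @param n_rounds,learning_rate Boosting hyperparameters.
#' @param seed Seed for subgroup sampling.
#' @return A `fall_logo` object: data frame `results` with one row per
#'   (k, subgroup, model) holding the iteration metrics, plus the per-k
#'   subgroup lists.
#' @export
evaluate_logo_severity <- function(control_features, stroke_features, profiles,
                                   ks = 0:5, max_groups = 100L,
                                   n_rounds = 50L, learning_rate = 1,
                                   seed = 1L) {
  man <- if (is.data.frame(profiles)) profiles else subject_manifest(profiles)
  if (!"severity" %in% names(man)) stopf("profiles carry no severity labels")
  control_model <- fall_adaboost(feature_columns(control_features),
                                 control_features$activity_class,
                                 n_rounds = n_rounds,
                                 learning_rate = learning_rate)
  rows <- list()
  groups_by_k <- list()
  for (k in ks) {
    groups <- tryCatch(
      enumerate_severity_subgroups(man, k, max_groups = max_groups,
                                   seed = derive_seed(seed, k)),
      error = function(e) NULL)
    if (is.null(groups)) next
    groups_by_k[[as.character(k)]] <- groups
    for (g in groups) {
      gid <- paste(g, collapse = "+")
      train <- stroke_features[!(stroke_features$subject_id %in% g), ,
                               drop = FALSE]
      test <- stroke_features[stroke_features$subject_id %in% g, , drop = FALSE]
      class(train) <- class(test) <- class(stroke_features)
      assert_no_leakage(unique(train$subject_id), g)
      stroke_model <- fall_adaboost(feature_columns(train),
                                    train$activity_class,
                                    n_rounds = n_rounds,
                                    learning_rate = learning_rate)
      for (model_name in c("control_trained", "stroke_trained")) {
        model <- if (model_name == "control_trained") control_model
                 else stroke_model
        m <- eval_one(model, test)
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(k = k, subgroup = gid, model = model_name,
                     stringsAsFactors = FALSE),
          metrics_row(gid, m)[, -1])
      }
    }
  }
  structure(list(results = do.call(rbind, rows), groups = groups_by_k,
                 config = list(max_groups = max_groups, n_rounds = n_rounds,
                               learning_rate = learning_rate)),
            class = "fall_logo")
}

#' @export
print.fall_logo <- function(x, ...) {
  cat("<fall_logo: severity-stratified leave-one-group-out>\n")
  agg <- stats::aggregate(cbind(recall, precision) ~ k + model, x$results,
                          mean, na.action = stats::na.omit)
  print(agg[order(agg$model, agg$k), ], row.names = FALSE)
  invisible(x)
}

#' Mean metric per k and model from a LOGO run
#'
#' @param logo A `fall_logo` object.
#' @param metric Metric column to summarise.
#' @return Data frame `k`, `model`, `mean`, `n`.
#' @export
logo_summary <- function(logo, metric = "recall") {
  r <- logo$results
  out <- stats::aggregate(list(mean = r[[metric]]),
                          by = list(k = r$k, model = r$model),
                          FUN = function(v) mean(v, na.rm = TRUE))
  n <- stats::aggregate(list(n = r[[metric]]),
                        by = list(k = r$k, model = r$model),
                        FUN = function(v) sum(!is.na(v)))
  merge(out, n, by = c("k", "model"))
}

#' Sweep the lead time and locate the optimum
#'
#' Re-runs the full pipeline (window extraction, feature extraction, scheme
#' evaluation) at each lead time on the grid and reports the mean AUC per
#' model; the optimal lead time t_l* is the grid argmax, ties breaking to the
#' smallest lead.  Grid points at which no fall window is feasible are
#' flagged rather than dropped.
#'
#' @param dataset A `fall_dataset`.
#' @param grid Lead times in ms (study grid: 50, 100, 150, 200, 300, 400,
#'   500).
#' @param fall_type `"all"`, `"lateral"` or `"ap"` fall windows.
#' @param nonfall_filter Passed to [build_feature_matrix()].
#' @param n_rounds,learning_rate Boosting hyperparameters.
#' @param seed Seed for non-fall window draws.
#' @return A `fall_sweep` object: data frame `results` (lead_time_ms, model,
#'   mean_auc, n_iterations, feasible) and `optimal` (per-model t_l*).
#' @export
lead_time_sweep <- function(dataset,
                            grid = c(50, 100, 150, 200, 300, 400, 500),
                            fall_type = c("ap", "lateral", "all"),
                            nonfall_filter = "both",
                            n_rounds = 50L, learning_rate = 1, seed = 1L) {
  stopifnot(all(grid >= 0))
  fall_type <- match.arg(fall_type)
  rows <- list()
  for (lt in grid) {
    fm <- build_feature_matrix(dataset, lead_time_ms = lt,
                               nonfall_filter = nonfall_filter, seed = seed)
    fm <- filter_features(fm, fall_type)
    feasible <- any(fm$activity_class == "fall")
    aucs <- c(control_trained = NA_real_, stroke_trained = NA_real_)
    n_it <- c(control_trained = 0L, stroke_trained = 0L)
    if (feasible) {
      stroke <- filter_features(fm, cohort = "stroke")
      control <- filter_features(fm, cohort = "control")
      loso <- evaluate_loso(stroke, n_rounds = n_rounds,
                            learning_rate = learning_rate)
      ct <- evaluate_control_trained(control, stroke, n_rounds = n_rounds,
                                     learning_rate = learning_rate)
      aucs["stroke_trained"] <- loso$summary$mean[loso$summary$metric == "auc"]
      aucs["control_trained"] <- ct$summary$mean[ct$summary$metric == "auc"]
      n_it["stroke_trained"] <-
        loso$summary$n_defined[loso$summary$metric == "auc"]
      n_it["control_trained"] <-
        ct$summary$n_defined[ct$summary$metric == "auc"]
    }
    for (model in names(aucs))
      rows[[length(rows) + 1L]] <- data.frame(
        lead_time_ms = lt, model = model, mean_auc = unname(aucs[model]),
        n_iterations = unname(n_it[model]), feasible = feasible,
        stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows)
  optimal <- do.call(rbind, lapply(split(results, results$model), function(d) {
    d <- d[d$feasible & !is.na(d$mean_auc), , drop = FALSE]
    if (!nrow(d)) return(NULL)
    d <- d[order(-d$mean_auc, d$lead_time_ms), , drop = FALSE]
    data.frame(model = d$model[1], optimal_lead_time_ms = d$lead_time_ms[1],
               mean_auc = d$mean_auc[1], stringsAsFactors = FALSE)
  }))
  rownames(optimal) <- NULL
  structure(list(results = results, optimal = optimal,
                 config = list(grid = grid, fall_type = fall_type,
                               nonfall_filter = nonfall_filter)),
            class = "fall_sweep")
}

#' @export
print.fall_sweep <- function(x, ...) {
  cat(sprintf("<fall_sweep: %d lead times, fall type '%s'>\n",
              length(x$config$grid), x$config$fall_type))
  print(x$results, row.names = FALSE)
  cat("Optimal lead times:\n")
  print(x$optimal, row.names = FALSE)
  invisible(x)
}

#' @export
plot.fall_sweep <- function(x, ...) {
  d <- x$results[x$results$feasible & !is.na(x$results$mean_auc), ]
  models <- unique(d$model)
  cols <- c(control_trained = "steelblue", stroke_trained = "firebrick")
  graphics::plot(NULL, xlim = range(x$config$grid),
                 ylim = range(d$mean_auc, 0.5, 1),
                 xlab = "lead time (ms)", ylab = "mean AUC",
                 main = sprintf("Lead-time sweep (%s falls)", x$config$fall_type))
  for (m in models) {
    dd <- d[d$model == m, ]
    graphics::lines(dd$lead_time_ms, dd$mean_auc, type = "b",
                    col = cols[[m]], pch = 19)
  }
  graphics::legend("bottomright", legend = models, col = cols[models], lty = 1,
                   pch = 19, bty = "n")
  invisible(x)
}
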