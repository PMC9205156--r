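# Evaluation schemes: LOSO, control-trained, subgroup enumeration, LOGO and
# the lead-time sweep.

stroke_features <- function() fixture("stroke_features", {
  filter_features(tiny_features(), cohort = "stroke")
})
control_features <- function() fixture("control_features", {
  filter_features(tiny_features(), cohort = "control")
})

test_that("LOSO runs one leakage-free iteration per subject", {
  fm <- stroke_features()
  rep <- evaluate_loso(fm)
  subjects <- sort(unique(fm$subject_id))
  expect_equal(rep$iterations$test_unit, subjects)
  for (s in subjects)
    expect_false(s %in% rep$train_sets[[s]])
  expect_error(evaluate_loso(fm[fm$subject_id == subjects[1], ]), ">= 3")
})

test_that("duplicated subjects yield identical LOSO iterations", {
  fm <- stroke_features()
  subjects <- sort(unique(fm$subject_id))
  dup <- fm[fm$subject_id %in% subjects[1:3], ]
  extra <- fm[fm$subject_id == subjects[1], ]
  extra$subject_id <- "S99"                    # exact copy, new id
  both <- rbind(dup, extra)
  class(both) <- class(fm)
  rep <- evaluate_loso(both)
  it <- rep$iterations
  expect_equal(it[it$test_unit == subjects[1], -1],
               it[it$test_unit == "S99", -1], ignore_attr = TRUE)
})

test_that("the control-trained scheme shares one model across iterations", {
  rep <- evaluate_control_trained(control_features(), stroke_features())
  loso <- evaluate_loso(stroke_features())
  expect_equal(rep$iterations$test_unit, loso$iterations$test_unit)
  expect_s3_class(rep$model, "fall_adaboost")
  expect_error(evaluate_control_trained(control_features()[0, ],
                                        stroke_features()),
               "non-empty")
})

test_that("high-separability synthetic stroke cohorts are recalled almost perfectly", {
  rep <- evaluate_loso(stroke_features(), seed = 11)
  expect_gte(rep$summary$mean[rep$summary$metric == "recall"], 0.95)
})

manifest_20 <- function() {
  data.frame(subject_id = sprintf("S%02d", 1:20), cohort = "stroke",
             severity = rep(c("unstable", "stable"), c(5, 15)),
             stringsAsFactors = FALSE)
}

test_that("subgroup enumeration matches the combinatorics of a 5/15 split", {
  man <- manifest_20()
  expect_length(enumerate_severity_subgroups(man, 4), 75)
  expect_length(enumerate_severity_subgroups(man, 5), 1)
  g2 <- enumerate_severity_subgroups(man, 2, seed = 3)
  expect_length(g2, 100)
  expect_length(unique(vapply(g2, paste, character(1), collapse = "+")), 100)
  n_unstable <- vapply(g2, function(g)
    sum(g %in% man$subject_id[man$severity == "unstable"]), integer(1))
  expect_true(all(n_unstable == 2L))
  expect_error(enumerate_severity_subgroups(man, 6), "between 0 and 5")
  man2 <- man; man2$severity <- "stable"
  expect_error(enumerate_severity_subgroups(man2, 1), "infeasible")
})

test_that("exhaustive enumeration is returned whenever it fits the cap", {
  man <- data.frame(subject_id = sprintf("S%02d", 1:7), cohort = "stroke",
                    severity = rep(c("unstable", "stable"), c(3, 4)),
                    stringsAsFactors = FALSE)
  got <- enumerate_severity_subgroups(man, 2)      # C(3,2) * C(4,3) = 12
  expect_length(got, 12)
  unstable <- man$subject_id[1:3]; stable <- man$subject_id[4:7]
  expected <- list()
  for (u in utils::combn(unstable, 2, simplify = FALSE))
    for (s in utils::combn(stable, 3, simplify = FALSE))
      expected[[length(expected) + 1]] <- sort(c(u, s))
  key <- function(gs) sort(vapply(gs, paste, character(1), collapse = "+"))
  expect_identical(key(got), key(expected))
})

test_that("LOGO keeps test subgroups out of the stroke training set", {
  ds <- fixture("sev_dataset", {
    generate_cohort_dataset(config_severity_gradient(seed = 2))
  })
  fm <- fixture("sev_features", {
    build_feature_matrix(ds, lead_time_ms = 75, seed = 2)
  })
  logo <- evaluate_logo_severity(filter_features(fm, cohort = "control"),
                                 filter_features(fm, cohort = "stroke"),
                                 ds$profiles, ks = 0:2, max_groups = 5,
                                 seed = 2)
  res <- logo$results
  expect_setequal(unique(res$model), c("control_trained", "stroke_trained"))
  expect_true(all(res$k %in% 0:2))
  # every subgroup has exactly 5 members and k unstable ambulators
  man <- subject_manifest(ds)
  unstable <- man$subject_id[man$severity == "unstable"]
  for (k in names(logo$groups)) {
    for (g in logo$groups[[k]]) {
      expect_length(g, 5)
      expect_equal(sum(g %in% unstable), as.integer(k))
    }
  }
})

test_that("severity-concentrated effects degrade the control model with k", {
  ds <- fixture("sev_dataset", {
    generate_cohort_dataset(config_severity_gradient(seed = 2))
  })
  fm <- fixture("sev_features", {
    build_feature_matrix(ds, lead_time_ms = 75, seed = 2)
  })
  logo <- evaluate_logo_severity(filter_features(fm, cohort = "control"),
                                 filter_features(fm, cohort = "stroke"),
                                 ds$profiles, ks = 0:3, max_groups = 8,
                                 seed = 2)
  sm <- logo_summary(logo, "recall")
  ctl <- sm[sm$model == "control_trained", ]
  expect_lte(cor(ctl$k, ctl$mean, method = "spearman"), 0)
})

test_that("the lead-time sweep covers the grid and breaks AUC ties low", {
  ds <- tiny_dataset()
  sw <- lead_time_sweep(ds, fall_type = "all", seed = 5)
  expect_equal(sort(unique(sw$results$lead_time_ms)),
               c(50, 100, 150, 200, 300, 400, 500))
  expect_equal(nrow(sw$results), 14)   # 7 grid points x 2 models
  expect_true(all(sw$results$mean_auc >= 0 & sw$results$mean_auc <= 1,
                  na.rm = TRUE))
  # the default cohorts separate perfectly at every lead: tie-break to 50 ms
  if (all(sw$results$mean_auc == 1, na.rm = TRUE))
    expect_true(all(sw$optimal$optimal_lead_time_ms == 50))
  for (m in sw$optimal$model) {
    d <- sw$results[sw$results$model == m & !is.na(sw$results$mean_auc), ]
    best <- max(d$mean_auc)
    expect_equal(sw$optimal$mean_auc[sw$optimal$model == m], best)
    expect_equal(sw$optimal$optimal_lead_time_ms[sw$optimal$model == m],
                 min(d$lead_time_ms[d$mean_auc == best]))
  }
})

test_that("infeasible grid points are flagged, not dropped", {
  ds <- tiny_dataset()
  # a lead longer than any recording leaves no fall window feasible
  longest <- max(vapply(ds$recordings, function(r) nrow(r$data), numeric(1)))
  lead_beyond <- (longest + 300) * 2     # frames -> ms
  sw <- lead_time_sweep(ds, grid = c(50, lead_beyond), fall_type = "all",
                        seed = 1)
  expect_equal(nrow(sw$results), 4)
  expect_false(any(sw$results$feasible[sw$results$lead_time_ms == lead_beyond]))
  expect_true(all(is.na(sw$results$mean_auc[!sw$results$feasible])))
  expect_true(all(sw$results$feasible[sw$results$lead_time_ms == 50]))
})
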