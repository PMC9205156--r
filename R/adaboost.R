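# Adaptive boosting (SAMME with depth-1 decision stumps) for binary fall /
# non-fall classification.  50 rounds, learning rate 1 by default.  The
# weighted stump search is exact: for every feature and every admissible
# threshold the weighted misclassification error is evaluated via cumulative
# sums over precomputed sort orders, and the global minimiser is taken
# (ties break to the lowest feature index, then the lowest threshold, then
# the "left predicts fall" polarity).

POSITIVE_CLASS <- "fall"
NEGATIVE_CLASS <- "non_fall"

#' Fit an adaptive-boosting fall classifier
#'
#' SAMME boosting of depth-1 decision stumps.  Each round fits the exact
#' weighted-error-minimising stump, receives weight
#' `alpha = learning_rate * log((1 - err) / err)`, and re-weights the
#' training rows.  Boosting stops early when a round is perfect (the stump
#' decides alone) or no stump beats chance.
#'
#' @param x Numeric feature matrix (rows = events), or a `fall_features`
#'   data frame from [build_feature_matrix()] (labels are then taken from its
#'   `activity_class` column).
#' @param y Class labels (`"fall"` / `"non_fall"`); ignored when `x` is a
#'   `fall_features`.
#' @param n_rounds Number of boosting rounds (default 50 estimators).
#' @param learning_rate Shrinkage on the stump weights (default 1).
#' @param seed Accepted for interface symmetry; the fit is deterministic and
#'   consumes no randomness.
#' @return A `fall_adaboost` object with `stumps` (feature, threshold,
#'   polarity, alpha, err per round), `feature_names`, `n_rounds` requested
#'   and class levels.
#' @export
fall_adaboost <- function(x, y = NULL, n_rounds = 50L, learning_rate = 1,
                          seed = NULL) {
  if (inherits(x, "fall_features")) {
    y <- x$activity_class
    x <- feature_columns(x)
  }
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (length(y) != nrow(x)) stopf("x and y lengths differ")
  if (anyNA(x) || anyNA(y)) stopf("missing values in training data")
  classes <- sort(unique(as.character(y)))
  if (length(classes) < 2L)
    stopf("training data contain a single class ('%s'); need both", classes)
  if (!all(classes %in% c(POSITIVE_CLASS, NEGATIVE_CLASS)))
    stopf("labels must be '%s' / '%s'", POSITIVE_CLASS, NEGATIVE_CLASS)
  yp <- ifelse(y == POSITIVE_CLASS, 1, -1)
  n <- nrow(x); p <- ncol(x)

  ord <- matrix(0L, n, p)
  for (j in seq_len(p)) ord[, j] <- order(x[, j])
  xs <- matrix(x[cbind(as.vector(ord), rep(seq_len(p), each = n))], n, p)
  ys_pos <- matrix(yp[ord] > 0, n, p)
  valid <- rbind(xs[-1L, , drop = FALSE] > xs[-n, , drop = FALSE], FALSE)
  if (!any(valid)) stopf("all features are constant; nothing to split on")

  w <- rep(1 / n, n)
  stumps <- vector("list", n_rounds)
  m_used <- 0L
  for (m in seq_len(n_rounds)) {
    wm <- matrix(w[ord], n, p)
    cpos <- col_cumsum(wm * ys_pos)
    cneg <- col_cumsum(wm * !ys_pos)
    w_pos <- cpos[n, 1L]
    # rule "left (x <= thr) predicts fall": err = cneg + (W+ - cpos)
    e1 <- cneg + (w_pos - cpos)
    e <- pmin(e1, 1 - e1)
    e[!valid] <- Inf
    idx <- which.min(e)            # column-major: lowest feature, then threshold
    j <- (idx - 1L) %/% n + 1L
    i <- (idx - 1L) %% n + 1L
    err <- e[idx]
    if (!is.finite(err)) break
    left_is_fall <- e1[idx] <= 1 - e1[idx]
    thr <- (xs[i, j] + xs[i + 1L, j]) / 2
    pred <- ifelse(x[, j] <= thr, 1, -1) * if (left_is_fall) 1 else -1
    if (err >= 0.5) {
      if (m_used == 0L)
        stopf("no stump beats chance on the training data")
      break
    }
    if (err < 1e-12) {
      # perfect stump: it decides alone (boosting cannot improve on it)
      m_used <- m_used + 1L
      stumps[[m_used]] <- list(feature = j, threshold = thr,
                               left_is_fall = left_is_fall, alpha = 1,
                               err = err)
      break
    }
    alpha <- learning_rate * log((1 - err) / err)
    m_used <- m_used + 1L
    stumps[[m_used]] <- list(feature = j, threshold = thr,
                             left_is_fall = left_is_fall, alpha = alpha,
                             err = err)
    w <- w * exp(alpha * (pred != yp))
    w <- w / sum(w)
  }
  stumps <- stumps[seq_len(m_used)]
  structure(list(stumps = stumps, feature_names = colnames(x),
                 n_rounds = n_rounds, learning_rate = learning_rate,
                 n_train = n, classes = c(NEGATIVE_CLASS, POSITIVE_CLASS)),
            class = "fall_adaboost")
}

#' Predict from a fitted boosting classifier
#'
#' @param object A `fall_adaboost` fit.
#' @param newdata Feature matrix or `fall_features` data frame.
#' @param type `"score"` for the continuous decision score in `[-1, 1]`
#'   (positive = fall; the alpha-weighted stump vote), `"class"` for hard
#'   labels.
#' @param ... Unused.
#' @return Numeric scores or a character vector of labels.
#' @export
predict.fall_adaboost <- function(object, newdata,
                                  type = c("score", "class"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "fall_features")) newdata <- feature_columns(newdata)
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)) &&
      all(object$feature_names %in% colnames(newdata)))
    newdata <- newdata[, object$feature_names, drop = FALSE]
  else if (ncol(newdata) != length(object$feature_names))
    stopf("newdata has %d columns; model expects %d", ncol(newdata),
          length(object$feature_names))
  score <- numeric(nrow(newdata))
  total <- 0
  for (s in object$stumps) {
    vote <- ifelse(newdata[, s$feature] <= s$threshold, 1, -1)
    if (!s$left_is_fall) vote <- -vote
    score <- score + s$alpha * vote
    total <- total + s$alpha
  }
  if (total > 0) score <- score / total
  if (type == "score") score
  else ifelse(score > 0, POSITIVE_CLASS, NEGATIVE_CLASS)
}

#' @export
print.fall_adaboost <- function(x, ...) {
  cat(sprintf("<fall_adaboost: %d stump(s) (of %d rounds, learning rate %g), %d training rows>\n",
              length(x$stumps), x$n_rounds, x$learning_rate, x$n_train))
  invisible(x)
}

#' @export
summary.fall_adaboost <- function(object, ...) {
  imp <- feature_importance(object)
  cat(sprintf("Adaptive boosting fall classifier: %d stumps, %d features\n",
              length(object$stumps), length(object$feature_names)))
  cat("Top features by importance:\n")
  print(utils::head(imp, 10), row.names = FALSE)
  invisible(imp)
}

#' Normalised feature importances of a boosting fit
#'
#' Each feature's importance is the sum of the stump weights (alpha) of the
#' rounds that split on it, normalised to sum to one.  Entries are sorted by
#' decreasing importance with ties broken by feature name.
#'
#' @param model A fitted `fall_adaboost`.
#' @return Data frame `feature`, `importance` (one row per model feature).
#' @export
feature_importance <- function(model) {
  if (!inherits(model, "fall_adaboost") || !length(model$stumps))
    stopf("feature_importance requires a fitted fall_adaboost model")
  imp <- stats::setNames(numeric(length(model$feature_names)),
                         model$feature_names)
  for (s in model$stumps)
    imp[s$feature] <- imp[s$feature] + s$alpha
  imp <- imp / sum(imp)
  ord <- order(-imp, names(imp), method = "radix")
  data.frame(feature = names(imp)[ord], importance = unname(imp[ord]),
             stringsAsFactors = FALSE)
}
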