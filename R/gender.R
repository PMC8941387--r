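#' Fit a two-class Fisher linear discriminant
#'
#' The discriminant axis is `Sw^{-1} (mu_pos - mu_neg)` with `Sw` the
#' pooled within-class covariance; classification assigns a sample to the
#' class whose projected mean is nearer (equivalently, thresholding the
#' projection at the midpoint of the projected class means).
#'
#' @param features data.frame or matrix of numeric features.
#' @param labels two-class vector (character or factor), one per row.
#' @param feature_subset optional character vector of feature columns to
#'   use (default: all numeric columns).
#' @param positive_class label projected to the positive side of the axis;
#'   default: the second class in sorted order.
#' @return An object of class `lda_fit`: feature names, axis weights,
#'   projected class means and midpoint.
#' @export
fit_lda <- function(features, labels, feature_subset = NULL,
                    positive_class = NULL) {
  X <- feature_matrix(features, feature_subset)
  labels <- as.character(labels)
  if (length(labels) != nrow(X)) stopf("labels/features length mismatch")
  classes <- sort(unique(labels))
  if (length(classes) != 2L) {
    stopf("need exactly 2 classes, got %d (%s)", length(classes),
          paste(classes, collapse = ", "))
  }
  positive_class <- positive_class %||% classes[2L]
  if (!positive_class %in% classes) stopf("positive_class '%s' not in labels",
                                          positive_class)
  negative_class <- setdiff(classes, positive_class)
  if (nrow(X) <= ncol(X) + 1L) {
    stopf("need more samples (%d) than features (%d)", nrow(X), ncol(X))
  }
  pos <- labels == positive_class
  n1 <- sum(pos); n2 <- sum(!pos)
  mu_p <- colMeans(X[pos, , drop = FALSE])
  mu_n <- colMeans(X[!pos, , drop = FALSE])
  Sw <- ((n1 - 1) * cov(X[pos, , drop = FALSE]) +
           (n2 - 1) * cov(X[!pos, , drop = FALSE])) / (n1 + n2 - 2)
  delta <- mu_p - mu_n
  w <- tryCatch(solve(Sw, delta), error = function(e) NULL)
  if (is.null(w) || any(!is.finite(w))) {
    lambda <- 1e-6 * mean(diag(Sw))
    if (lambda <= 0) lambda <- 1e-6
    warnf("pooled within-class covariance is singular; ridge-regularizing (lambda = %g)",
          lambda)
    w <- solve(Sw + diag(lambda, ncol(Sw)), delta)
  }
  proj_p <- sum(w * mu_p)
  proj_n <- sum(w * mu_n)
  structure(list(features = colnames(X), weights = setNames(as.numeric(w), colnames(X)),
                 classes = c(negative = negative_class, positive = positive_class),
                 class_means = c(negative = proj_n, positive = proj_p),
                 midpoint = (proj_p + proj_n) / 2),
            class = "lda_fit")
}

# Project samples onto the discriminant axis.
lda_project <- function(fit, features) {
  X <- feature_matrix(features, fit$features)
  drop(X %*% fit$weights)
}

#' Predict class labels from a fitted discriminant
#'
#' @param object an `lda_fit`.
#' @param newdata feature data.frame/matrix.
#' @param ... unused.
#' @return Character vector of predicted labels.
#' @export
predict.lda_fit <- function(object, newdata, ...) {
  p <- lda_project(object, newdata)
  pos_side <- object$class_means["positive"] >= object$class_means["negative"]
  ifelse((p >= object$midpoint) == pos_side,
         object$classes["positive"], object$classes["negative"])
}

feature_matrix <- function(features, feature_subset = NULL) {
  if (is.data.frame(features)) {
    num <- vapply(features, is.numeric, logical(1))
    if (is.null(feature_subset)) feature_subset <- names(features)[num]
    miss <- setdiff(feature_subset, names(features))
    if (length(miss) > 0L) stopf("missing feature column(s): %s",
                                 paste(miss, collapse = ", "))
    X <- as.matrix(features[, feature_subset, drop = FALSE])
  } else {
    X <- as.matrix(features)
    if (!is.null(feature_subset)) {
      miss <- setdiff(feature_subset, colnames(X))
      if (length(miss) > 0L) stopf("missing feature column(s): %s",
                                   paste(miss, collapse = ", "))
      X <- X[, feature_subset, drop = FALSE]
    }
  }
  if (!is.numeric(X)) stopf("features must be numeric")
  if (any(!is.finite(X))) stopf("non-finite feature values")
  X
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin to the k folds.
stratified_folds <- function(labels, k, seed = NULL) {
  labels <- as.character(labels)
  k <- as.integer(k)
  if (k < 2L) stopf("k must be >= 2")
  tab <- table(labels)
  if (any(tab < k)) {
    stopf("class '%s' has %d members, fewer than k = %d folds",
          names(tab)[which.min(tab)], min(tab), k)
  }
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in names(tab)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Cross-validated classification accuracy
#'
#' Stratified k-fold cross-validation of the Fisher discriminant: folds
#' preserve class proportions, each fold is predicted from a model fitted
#' on the remaining folds, and the pooled fraction of correct held-out
#' predictions is returned. Deterministic for a given seed.
#'
#' @inheritParams fit_lda
#' @param k number of folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @return Accuracy fraction in `[0, 1]`, with attribute `"folds"`.
#' @export
cross_validate <- function(features, labels, feature_subset = NULL, k = 10L,
                           seed = 1L) {
  labels <- as.character(labels)
  fold <- stratified_folds(labels, k, seed)
  X <- feature_matrix(features, feature_subset)
  correct <- logical(length(labels))
  for (f in seq_len(max(fold))) {
    hold <- fold == f
    fit <- fit_lda(X[!hold, , drop = FALSE], labels[!hold])
    correct[hold] <- predict(fit, X[hold, , drop = FALSE]) == labels[hold]
  }
  structure(mean(correct), folds = fold)
}

cv_with_folds <- function(X, labels, fold, subset) {
  correct <- logical(length(labels))
  for (f in seq_len(max(fold))) {
    hold <- fold == f
    fit <- fit_lda(X[!hold, subset, drop = FALSE], labels[!hold])
    correct[hold] <- predict(fit, X[hold, subset, drop = FALSE]) == labels[hold]
  }
  mean(correct)
}

#' Select maximally discriminating features
#'
#' Wrapper feature selection under cross-validated discriminant accuracy.
#' The default greedy forward search adds, at each step, the feature whose
#' inclusion most improves k-fold CV accuracy (folds fixed across the whole
#' search for paired comparisons), stopping when no candidate improves
#' accuracy by more than `tol` or `max_features` is reached. Accuracy ties
#' are broken by the larger absolute standardized class mean difference,
#' then by feature name, so selection is fully deterministic. The
#' exhaustive method scores every non-empty subset (feasible for at most
#' ~15 features) and serves as the optimality oracle for the greedy search.
#'
#' @inheritParams cross_validate
#' @param max_features maximum subset size (>= 1).
#' @param tol minimum CV-accuracy improvement to continue (default 0.005,
#'   i.e. half a percentage point; smaller improvements are within
#'   fold-assignment noise).
#' @param method `"greedy"` (default) or `"exhaustive"`.
#' @return Character vector of selected feature names (in selection order
#'   for the greedy method), with attribute `"accuracy"` (its CV accuracy).
#' @export
gefs_select <- function(features, labels, max_features = 10L, k = 10L,
                        seed = 1L, tol = 0.005,
                        method = c("greedy", "exhaustive")) {
  method <- match.arg(method)
  if (max_features < 1L) stopf("max_features must be >= 1")
  X <- feature_matrix(features)
  if (ncol(X) < 2L) stopf("need at least 2 candidate features")
  labels <- as.character(labels)
  fold <- stratified_folds(labels, k, seed)

  # tie-break key: |standardized mean difference| per feature
  classes <- sort(unique(labels))
  a <- labels == classes[1L]
  smd <- abs(colMeans(X[a, , drop = FALSE]) - colMeans(X[!a, , drop = FALSE])) /
    sqrt(((sum(a) - 1) * apply(X[a, , drop = FALSE], 2, var) +
            (sum(!a) - 1) * apply(X[!a, , drop = FALSE], 2, var)) /
           (nrow(X) - 2))

  if (method == "exhaustive") {
    p <- ncol(X)
    if (p > 15L) stopf("exhaustive search supports at most 15 features, got %d", p)
    best <- NULL; best_acc <- -Inf
    for (size in seq_len(min(p, max_features))) {
      sets <- combn(colnames(X), size, simplify = FALSE)
      for (s in sets) {
        acc <- cv_with_folds(X, labels, fold, s)
        if (acc > best_acc + 1e-12) { best <- s; best_acc <- acc }
      }
    }
    return(structure(best, accuracy = best_acc))
  }

  selected <- character(0)
  current_acc <- -Inf
  repeat {
    cand <- setdiff(colnames(X), selected)
    if (length(cand) == 0L || length(selected) >= max_features) break
    accs <- vapply(cand, function(f) {
      cv_with_folds(X, labels, fold, c(selected, f))
    }, numeric(1))
    top <- accs >= max(accs) - 1e-12
    pick <- cand[top]
    if (length(pick) > 1L) {
      key <- smd[pick]
      pick <- pick[key >= max(key) - 1e-12]
      pick <- sort(pick)[1L]
    }
    new_acc <- max(accs)
    if (length(selected) > 0L && new_acc <= current_acc + tol) break
    selected <- c(selected, pick[1L])
    current_acc <- new_acc
  }
  structure(selected, accuracy = current_acc)
}

#' Fit the full gender model
#'
#' Runs feature selection (unless a subset is supplied), fits the Fisher
#' discriminant for male versus female on the whole sample (the same sample
#' is then scored; cross-validation is used only to report classifier
#' accuracy), orients the axis male-positive, and records the projection
#' bounds over the training sample for the 0-1 score scaling.
#'
#' @param features data.frame of numeric facial features.
#' @param sex vector of `"male"`/`"female"` labels.
#' @param feature_subset optional preselected feature names; when `NULL`,
#'   [gefs_select()] chooses up to `max_features`.
#' @param max_features maximum number of selected features.
#' @param k CV folds.
#' @param seed integer seed (folds and selection).
#' @return An object of class `gender_model`.
#' @export
fit_gender_model <- function(features, sex, feature_subset = NULL,
                             max_features = 10L, k = 10L, seed = 1L) {
  sex <- as.character(sex)
  bad <- setdiff(unique(sex), c("male", "female"))
  if (length(bad) > 0L) stopf("unknown sex label(s): %s", paste(bad, collapse = ", "))
  if (length(unique(sex)) != 2L) stopf("both sexes must be present")
  if (is.null(feature_subset)) {
    feature_subset <- as.character(gefs_select(features, sex,
                                               max_features = max_features,
                                               k = k, seed = seed))
  }
  fit <- fit_lda(features, sex, feature_subset, positive_class = "male")
  proj <- lda_project(fit, features) - fit$midpoint
  if (fit$class_means["positive"] < fit$class_means["negative"]) {
    # orient male-positive
    fit$weights <- -fit$weights
    fit$class_means <- -fit$class_means[c("positive", "negative")]
    names(fit$class_means) <- c("negative", "positive")
    fit$midpoint <- -fit$midpoint
    proj <- -proj
  }
  cv_acc <- as.numeric(cross_validate(features, sex, feature_subset, k = k,
                                      seed = seed))
  structure(list(
    selected_features = feature_subset,
    weights = fit$weights,
    class_means = c(female = as.numeric(fit$class_means["negative"]) - fit$midpoint,
                    male = as.numeric(fit$class_means["positive"]) - fit$midpoint),
    midpoint = fit$midpoint,
    scale_bounds = range(proj),
    cv_accuracy = cv_acc,
    orientation = "male_positive",
    k = as.integer(k), seed = as.integer(seed)),
    class = "gender_model")
}

#' @export
print.gender_model <- function(x, ...) {
  cat(sprintf("<gender_model> %d features, CV accuracy %.1f%%\n",
              length(x$selected_features), 100 * x$cv_accuracy))
  cat("  features:", paste(x$selected_features, collapse = ", "), "\n")
  invisible(x)
}

#' Compute facial masculinity scores
#'
#' Each face's selected-feature vector is projected onto the discriminant
#' axis; the signed distance of the projection from the midpoint of the two
#' class means (male side positive) is min-max scaled with the training
#' bounds, so the training-sample minimum scores 0 (highly feminine) and
#' the maximum scores 1 (highly masculine). Out-of-sample projections
#' beyond the bounds are clipped to `[0, 1]` and counted in the
#' `"n_clipped"` attribute.
#'
#' @param model a [fit_gender_model()] result.
#' @param features data.frame containing the selected features (and
#'   optionally `subject_id`).
#' @return data.frame with `subject_id` (if present) and `score`, with
#'   attribute `"n_clipped"`.
#' @export
masculinity_score <- function(model, features) {
  stopifnot(inherits(model, "gender_model"))
  miss <- setdiff(model$selected_features,
                  if (is.data.frame(features)) names(features) else colnames(features))
  if (length(miss) > 0L) stopf("missing selected feature(s): %s",
                               paste(miss, collapse = ", "))
  X <- feature_matrix(features, model$selected_features)
  proj <- drop(X %*% model$weights) - model$midpoint
  b <- model$scale_bounds
  if (b[2] <= b[1]) stopf("degenerate scale bounds")
  score <- (proj - b[1]) / (b[2] - b[1])
  clipped <- sum(score < 0 | score > 1)
  if (clipped > 0) {
    message(sprintf("masculinity_score: %d score(s) outside [0, 1] clipped (out-of-sample)",
                    clipped))
  }
  score <- pmin(1, pmax(0, score))
  out <- if (is.data.frame(features) && "subject_id" %in% names(features)) {
    data.frame(subject_id = features$subject_id, score = score,
               stringsAsFactors = FALSE)
  } else {
    data.frame(score = score)
  }
  attr(out, "n_clipped") <- clipped
  out
}

#' Serialize a gender model to JSON
#'
#' @param model a `gender_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gender_model <- function(model, path) {
  stopifnot(inherits(model, "gender_model"))
  obj <- unclass(model)
  obj$weights <- as.list(obj$weights)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a gender model from JSON
#'
#' @param path JSON path written by [write_gender_model()].
#' @return A `gender_model`.
#' @export
read_gender_model <- function(path) {
  if (!file.exists(path)) stopf("model file not found: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$weights <- unlist(obj$weights)
  obj$selected_features <- as.character(obj$selected_features)
  obj$class_means <- unlist(obj$class_means)
  structure(obj, class = "gender_model")
}
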