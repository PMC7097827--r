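#' Classifier family and hyperparameters
#'
#' Defaults are the tuned values of the study protocol: KNN with 5 Euclidean
#' neighbors, SVM with a degree-4 polynomial kernel (cost 3, gamma 2.2), and
#' a Gini decision tree capped at 20 total nodes.
#'
#' @param family `"KNN"`, `"SVM"`, or `"DT"`.
#' @param knn_k odd neighbor count (ties impossible for a binary vote).
#' @param svm_degree,svm_cost,svm_gamma,svm_coef0 polynomial-kernel SVM
#'   parameters, kernel `(coef0 + gamma * x.y)^degree`.
#' @param dt_max_nodes maximum total node count (internal + leaves).
#' @return object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("KNN", "SVM", "DT"),
                            knn_k = 5L, svm_degree = 4, svm_cost = 3,
                            svm_gamma = 2.2, svm_coef0 = 1,
                            dt_max_nodes = 20L) {
  family <- match.arg(family)
  if (knn_k < 1 || knn_k %% 2 == 0) stop("knn_k must be odd and >= 1")
  if (svm_cost <= 0 || svm_gamma <= 0) stop("svm_cost and svm_gamma must be > 0")
  if (dt_max_nodes < 2) stop("dt_max_nodes must be >= 2")
  structure(list(family = family, knn_k = as.integer(knn_k),
                 svm_degree = svm_degree, svm_cost = svm_cost,
                 svm_gamma = svm_gamma, svm_coef0 = svm_coef0,
                 dt_max_nodes = as.integer(dt_max_nodes)),
            class = "classifier_spec")
}

# complete, labelled rows usable for training/evaluation
complete_rows <- function(features) {
  ok <- stats::complete.cases(features[, feature_columns]) &
    features$label %in% c("VIA_NEG", "VIA_POS")
  n_drop <- sum(!ok)
  if (n_drop > 0)
    message(n_drop, " row(s) with missing features or labels dropped")
  features[ok, , drop = FALSE]
}

#' Random holdout split of a feature table
#'
#' Shuffles rows with the given seed and splits them into training and test
#' subsets of sizes `ceiling(n * fraction)` and the remainder. When `group`
#' names a column (e.g. `"patient_id"`), whole groups are assigned to one
#' side, keeping a patient's slices together.
#'
#' @param features feature data.frame.
#' @param fraction training fraction.
#' @param seed integer seed.
#' @param group optional grouping column name, or `NULL` for row-level
#'   splitting.
#' @return list with `train` and `test` data.frames.
#' @export
holdout_split <- function(features, fraction = 0.5, seed = 1L, group = NULL) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  set.seed(seed)
  if (is.null(group)) {
    n <- nrow(features)
    ord <- sample.int(n)
    n_train <- ceiling(n * fraction)
    train <- features[ord[seq_len(n_train)], , drop = FALSE]
    test <- features[ord[-seq_len(n_train)], , drop = FALSE]
  } else {
    ids <- unique(features[[group]])
    ord <- sample(ids)
    n_train <- ceiling(length(ids) * fraction)
    train <- features[features[[group]] %in% ord[seq_len(n_train)], , drop = FALSE]
    test <- features[features[[group]] %in% ord[-seq_len(n_train)], , drop = FALSE]
  }
  for (side in list(train, test))
    if (length(unique(side$label[side$label != "UNKNOWN"])) < 2)
      warning("a split side contains a single class; some metrics will be undefined")
  list(train = train, test = test)
}

#' Per-feature standardization parameters from training rows
#'
#' Z-scoring with (optionally weighted) means and standard deviations
#' learned from the training rows only; the same parameters are applied
#' unchanged to validation and test rows. Weights default to uniform.
#'
#' @param train training feature data.frame.
#' @param weights optional non-negative sample weights.
#' @return object of class `standardization_params` with `center` and
#'   `scale` per feature column.
#' @export
standardize <- function(train, weights = NULL) {
  X <- as.matrix(train[, feature_columns])
  n <- nrow(X)
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  w <- w / sum(w)
  center <- colSums(X * w)
  scale <- sqrt(colSums((X - rep(center, each = n))^2 * w))
  bad <- names(which(scale <= 0 | !is.finite(scale)))
  if (length(bad))
    stop("zero-spread feature(s): ", paste(bad, collapse = ", "))
  structure(list(center = center, scale = scale),
            class = "standardization_params")
}

#' Apply standardization parameters to a feature table
#'
#' @param params a [standardize()] result (learned on training rows).
#' @param features any feature data.frame.
#' @return the data.frame with feature columns z-scored.
#' @export
apply_standardization <- function(params, features) {
  for (col in feature_columns)
    features[[col]] <- (features[[col]] - params$center[[col]]) / params$scale[[col]]
  features
}

#' Train a classifier on standardized features
#'
#' KNN stores the training matrix (prediction = majority vote of `knn_k`
#' Euclidean neighbors, score = positive-neighbor fraction). SVM fits a
#' polynomial-kernel maximum-margin model; its signed decision values are
#' mapped to (0, 1) scores by a monotone logistic link, so ranking (and
#' hence AUC) is unaffected. DT grows a full Gini tree and prunes it by
#' cost-complexity to the largest subtree within `dt_max_nodes` total nodes;
#' scores are leaf positive fractions.
#'
#' @param train standardized feature data.frame with labels.
#' @param spec a [classifier_spec()].
#' @return object of class `via_model` with a [predict_scores()] method.
#' @export
train_classifier <- function(train, spec) {
  train <- train[train$label %in% c("VIA_NEG", "VIA_POS"), , drop = FALSE]
  y <- factor(train$label, levels = c("VIA_NEG", "VIA_POS"))
  if (length(unique(y)) < 2) stop("training data contains a single class")
  X <- as.matrix(train[, feature_columns])
  fit <- switch(spec$family,
    KNN = list(X = X, y = y),
    SVM = e1071::svm(X, y, kernel = "polynomial", degree = spec$svm_degree,
                     cost = spec$svm_cost, gamma = spec$svm_gamma,
                     coef0 = spec$svm_coef0, scale = FALSE),
    DT = fit_capped_tree(X, y, spec$dt_max_nodes))
  structure(list(spec = spec, fit = fit), class = "via_model")
}

fit_capped_tree <- function(X, y, max_nodes) {
  df <- data.frame(X, y = y)
  fit <- rpart::rpart(y ~ ., data = df, method = "class",
                      parms = list(split = "gini"),
                      control = rpart::rpart.control(
                        cp = 0, minsplit = 2, minbucket = 1, xval = 0,
                        maxcompete = 0, maxsurrogate = 0, maxdepth = 30))
  cp <- fit$cptable
  nodes <- 2 * cp[, "nsplit"] + 1
  ok <- which(nodes <= max_nodes)
  best <- ok[which.max(cp[ok, "nsplit"])]
  rpart::prune(fit, cp = cp[best, "CP"])
}

#' Positive-class scores for new rows
#'
#' @param model a [train_classifier()] result.
#' @param features standardized feature data.frame (same transform as the
#'   model's training data).
#' @return numeric scores in [0, 1]; prediction threshold is 0.5.
#' @export
predict_scores <- function(model, features) {
  X <- as.matrix(features[, feature_columns])
  switch(model$spec$family,
    KNN = {
      pred <- class::knn(model$fit$X, X, model$fit$y,
                         k = model$spec$knn_k, prob = TRUE, use.all = TRUE)
      p <- attr(pred, "prob")
      ifelse(pred == "VIA_POS", p, 1 - p)
    },
    SVM = {
      dv <- attr(stats::predict(model$fit, X, decision.values = TRUE),
                 "decision.values")
      sgn <- if (grepl("^VIA_POS", colnames(dv)[1])) 1 else -1
      stats::plogis(sgn * dv[, 1])
    },
    DT = {
      stats::predict(model$fit, data.frame(X), type = "prob")[, "VIA_POS"]
    })
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps all score thresholds, records (FPR, TPR) points, and integrates by
#' the trapezoidal rule; the result equals the Mann-Whitney U statistic
#' divided by `n_pos * n_neg` with ties counted one half.
#'
#' @param scores numeric positive-class scores.
#' @param labels `"VIA_POS"`/`"VIA_NEG"` (or logical, `TRUE` = positive).
#' @return list with `roc_points` (data.frame `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else labels == "VIA_POS"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # collapse tied scores into single threshold steps
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(p)[last]; fp <- cumsum(!p)[last]
  tpr <- c(0, tp / n_pos); fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(roc_points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

summary_metrics <- function(scores, labels, threshold = 0.5) {
  pred <- ifelse(scores >= threshold, "VIA_POS", "VIA_NEG")
  cm <- confusion_matrix(
    tp = sum(pred == "VIA_POS" & labels == "VIA_POS"),
    fn = sum(pred == "VIA_NEG" & labels == "VIA_POS"),
    fp = sum(pred == "VIA_POS" & labels == "VIA_NEG"),
    tn = sum(pred == "VIA_NEG" & labels == "VIA_NEG"))
  bm <- binary_metrics(cm)
  kap <- cohen_kappa(cm)
  both <- length(unique(labels)) == 2
  roc <- if (both) roc_auc(scores, labels) else list(roc_points = NULL, auc = NA_real_)
  list(confusion = cm, accuracy = bm$accuracy, sensitivity = bm$sensitivity,
       specificity = bm$specificity, kappa = kap$kappa, auc = roc$auc,
       roc_points = roc$roc_points)
}

#' k-fold cross-validation of one classifier on the training half
#'
#' Rows are shuffled into `k` folds of size `floor(n/k)` or `ceiling(n/k)`.
#' For each fold, standardization is re-fit on the other k-1 folds
#' (leak-free by default; set `refit_per_fold = FALSE` to standardize once
#' on the full training table), a model is trained, and held-out scores are
#' recorded. Summary metrics are computed from the pooled held-out scores at
#' threshold 0.5.
#'
#' @param train unstandardized feature data.frame with labels.
#' @param spec a [classifier_spec()].
#' @param k number of folds.
#' @param seed integer seed fixing the fold assignment.
#' @param refit_per_fold re-fit standardization inside each fold.
#' @return list of class `cv_report`: accuracy, sensitivity, specificity
#'   (percent), kappa, auc, `roc_points`, `per_sample_scores` (in row
#'   order), `folds`.
#' @export
cross_validate <- function(train, spec, k = 10, seed = 1L,
                           refit_per_fold = TRUE) {
  train <- complete_rows(train)
  n <- nrow(train)
  if (k > n) stop("k exceeds the number of training rows")
  if (length(unique(train$label)) < 2) stop("both classes must be present")
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  scores <- rep(NA_real_, n)
  if (!refit_per_fold) {
    params0 <- standardize(train)
  }
  for (f in seq_len(k)) {
    tr <- train[fold != f, , drop = FALSE]
    va <- train[fold == f, , drop = FALSE]
    params <- if (refit_per_fold) standardize(tr) else params0
    model <- train_classifier(apply_standardization(params, tr), spec)
    scores[fold == f] <- predict_scores(model, apply_standardization(params, va))
  }
  res <- summary_metrics(scores, train$label)
  structure(c(res, list(per_sample_scores = scores, folds = fold,
                        spec = spec, n = n)), class = "cv_report")
}

#' Exhaustive hyperparameter grid search by cross-validation
#'
#' Evaluates every grid point with [cross_validate()] under the same seed
#' (hence the same folds) and returns the spec with the highest CV accuracy;
#' ties break by higher AUC, then by earlier grid order.
#'
#' @param train unstandardized feature data.frame.
#' @param family classifier family for all grid points.
#' @param grid data.frame (or list of named lists) of hyperparameter values;
#'   column names as in [classifier_spec()].
#' @param k folds.
#' @param seed integer seed.
#' @return list with `best` ([classifier_spec()]), `results` (one row per
#'   grid point with accuracy and AUC).
#' @export
grid_search <- function(train, family, grid, k = 10, seed = 1L) {
  if (is.data.frame(grid)) grid <- split(grid, seq_len(nrow(grid)))
  if (!length(grid)) stop("empty grid")
  rows <- list(); specs <- list()
  for (i in seq_along(grid)) {
    args <- c(list(family = family), as.list(grid[[i]]))
    spec <- try(do.call(classifier_spec, args), silent = TRUE)
    if (inherits(spec, "try-error")) {
      message("grid point ", i, " skipped: ", attr(spec, "condition")$message)
      next
    }
    cv <- cross_validate(train, spec, k = k, seed = seed)
    specs[[length(specs) + 1]] <- spec
    rows[[length(rows) + 1]] <- data.frame(point = i, accuracy = cv$accuracy,
                                           auc = cv$auc)
  }
  results <- do.call(rbind, rows)
  best_i <- order(-results$accuracy, -results$auc, results$point)[1]
  list(best = specs[[best_i]], results = results)
}

#' Evaluate a trained model on a held-out test table
#'
#' Applies the training standardization parameters, scores every complete
#' test row, and reports the confusion matrix, accuracy, sensitivity,
#' specificity, kappa and AUC at threshold 0.5.
#'
#' @param model a [train_classifier()] result.
#' @param test unstandardized feature data.frame.
#' @param params the [standardize()] parameters learned on training rows.
#' @return list of class `test_report` (same metric fields as `cv_report`,
#'   plus `predictions` data.frame with per-row scores and labels).
#' @export
evaluate_test <- function(model, test, params) {
  test <- complete_rows(test)
  if (!nrow(test)) stop("no usable test rows")
  scores <- predict_scores(model, apply_standardization(params, test))
  res <- summary_metrics(scores, test$label)
  pred <- data.frame(patient_id = test$patient_id, sector = test$sector,
                     score = scores,
                     predicted = ifelse(scores >= 0.5, "VIA_POS", "VIA_NEG"),
                     label = test$label, stringsAsFactors = FALSE)
  structure(c(res, list(predictions = pred)), class = "test_report")
}
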