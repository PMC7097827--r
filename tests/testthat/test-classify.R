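test_that("holdout split partitions rows reproducibly", {
  ft <- separable_features(120)  # 240 rows
  sp <- holdout_split(ft, 0.5, seed = 5)
  expect_identical(nrow(sp$train), 120L)
  expect_identical(nrow(sp$test), 120L)
  key <- function(d) sort(paste(d$patient_id, d$sector, d$d_ave))
  expect_identical(sort(c(key(sp$train), key(sp$test))), key(ft))
  sp2 <- holdout_split(ft, 0.5, seed = 5)
  expect_identical(sp$train, sp2$train)
  expect_error(holdout_split(ft, 0), "fraction")
})

test_that("group-wise holdout keeps a patient's slices together", {
  ft <- separable_features(120)
  sp <- holdout_split(ft, 0.5, seed = 5, group = "patient_id")
  expect_length(intersect(unique(sp$train$patient_id),
                          unique(sp$test$patient_id)), 0)
})

test_that("standardization uses weighted (population) moments", {
  ft <- separable_features(10)[1:2, ]
  ft$d_ave <- c(1, 3)
  p <- standardize(ft)
  expect_identical(unname(p$center["d_ave"]), 2)
  expect_identical(unname(p$scale["d_ave"]), 1)
  z <- apply_standardization(p, ft)
  expect_identical(z$d_ave, c(-1, 1))

  ft2 <- separable_features(40)
  p2 <- standardize(ft2)
  z2 <- apply_standardization(p2, ft2)
  for (col in cervia:::feature_columns) {
    expect_lt(abs(mean(z2[[col]])), 1e-10)
    expect_equal(sqrt(mean((z2[[col]] - mean(z2[[col]]))^2)), 1,
                 tolerance = 1e-10)
  }
  ftc <- separable_features(20); ftc$sd_blue <- 5
  expect_error(standardize(ftc), "sd_blue")
})

test_that("KNN scores are positive-neighbor fractions", {
  tr <- separable_features(10)[1:5, ]
  tr[, cervia:::feature_columns] <- 0
  tr$d_ave <- c(0.1, 0.2, 0.3, 5, 6)
  tr$label <- c("VIA_POS", "VIA_POS", "VIA_POS", "VIA_NEG", "VIA_NEG")
  model <- train_classifier(tr, classifier_spec("KNN", knn_k = 5))
  q <- tr[1, ]; q$d_ave <- 1
  expect_identical(unname(predict_scores(model, q)), 0.6)
})

test_that("KNN predictions equal exhaustive neighbor search", {
  for (seed in 1:30) {
    set.seed(seed)
    n <- sample(20:60, 1)
    tr <- separable_features(ceiling(n / 2), gap = 2, seed = seed)[1:n, ]
    te <- separable_features(10, gap = 2, seed = seed + 999)
    model <- train_classifier(tr, classifier_spec("KNN"))
    got <- ifelse(predict_scores(model, te) >= 0.5, "VIA_POS", "VIA_NEG")
    want <- knn_oracle(as.matrix(tr[, cervia:::feature_columns]), tr$label,
                       as.matrix(te[, cervia:::feature_columns]), 5)
    expect_identical(unname(got), unname(want))
  }
})

test_that("decision trees respect the total node cap", {
  set.seed(4)
  ft <- separable_features(100, gap = 0.5)  # hard problem forces big trees
  model <- train_classifier(ft, classifier_spec("DT", dt_max_nodes = 20))
  expect_lte(nrow(model$fit$frame), 20)
  m2 <- train_classifier(ft, classifier_spec("DT", dt_max_nodes = 5))
  expect_lte(nrow(m2$fit$frame), 5)
})

test_that("a one-threshold problem yields a depth-1 perfect tree", {
  ft <- separable_features(30, gap = 10, sd = 0.1)
  model <- train_classifier(ft, classifier_spec("DT"))
  expect_identical(nrow(model$fit$frame), 3L)  # root + two leaves
  acc <- mean((predict_scores(model, ft) >= 0.5) == (ft$label == "VIA_POS"))
  expect_identical(acc, 1)
})

test_that("SVM decision values separate a separable toy set", {
  ft <- separable_features(10, gap = 8, sd = 0.5)
  model <- train_classifier(ft, classifier_spec("SVM"))
  s <- predict_scores(model, ft)
  expect_true(all(s[ft$label == "VIA_POS"] > 0.5))
  expect_true(all(s[ft$label == "VIA_NEG"] < 0.5))
})

test_that("single-class training data is rejected", {
  ft <- separable_features(10)
  ft$label <- "VIA_NEG"
  expect_error(train_classifier(ft, classifier_spec("KNN")), "single class")
})

test_that("cross-validation scores each sample exactly once in equal folds", {
  ft <- separable_features(60)  # n = 120
  cv <- cross_validate(ft, classifier_spec("KNN"), k = 10, seed = 2)
  expect_identical(as.integer(table(cv$folds)), rep(12L, 10))
  expect_false(anyNA(cv$per_sample_scores))
  expect_identical(length(cv$per_sample_scores), 120L)
  cv2 <- cross_validate(ft, classifier_spec("KNN"), k = 10, seed = 2)
  expect_identical(cv$per_sample_scores, cv2$per_sample_scores)
  expect_identical(cv$accuracy, cv2$accuracy)
})

test_that("KNN cross-validation is near-perfect on separable features", {
  ft <- separable_features(60, gap = 6)
  cv <- cross_validate(ft, classifier_spec("KNN"), k = 10, seed = 3)
  expect_gte(cv$accuracy, 95)
  expect_gte(cv$auc, 0.99)
})

test_that("grid search is deterministic and honors the tie-break order", {
  ft <- separable_features(40, gap = 4)
  single <- grid_search(ft, "KNN", data.frame(knn_k = 5), k = 5, seed = 1)
  expect_identical(single$best$knn_k, 5L)

  g <- grid_search(ft, "KNN", data.frame(knn_k = c(1, 3, 5, 7)), k = 5,
                   seed = 1)
  g2 <- grid_search(ft, "KNN", data.frame(knn_k = c(1, 3, 5, 7)), k = 5,
                    seed = 1)
  expect_identical(g$best, g2$best)
  # the winner's accuracy is the grid maximum (paper spec or better)
  expect_identical(max(g$results$accuracy),
                   g$results$accuracy[g$results$point ==
                                      match(g$best$knn_k, c(1, 3, 5, 7))])
  expect_error(grid_search(ft, "KNN", list()), "empty grid")
})

test_that("invalid grid points are skipped with a message", {
  ft <- separable_features(40)
  expect_message(
    g <- grid_search(ft, "KNN", list(list(knn_k = 4), list(knn_k = 5)),
                     k = 5, seed = 1),
    "skipped")
  expect_identical(g$best$knn_k, 5L)
})

test_that("resubstitution with 1-NN is perfect; one-class test flags metrics", {
  ft <- separable_features(30)
  params <- standardize(ft)
  model <- train_classifier(apply_standardization(params, ft),
                            classifier_spec("KNN", knn_k = 1))
  rep <- evaluate_test(model, ft, params)
  expect_identical(rep$accuracy, 100)

  neg <- ft[ft$label == "VIA_NEG", ]
  rep2 <- evaluate_test(model, neg, params)
  expect_false(is.na(rep2$specificity))
  expect_true(is.na(rep2$sensitivity))
  expect_true(is.na(rep2$auc))
})

test_that("ROC/AUC matches worked examples and the tie convention", {
  perfect <- roc_auc(c(0.9, 0.8, 0.2, 0.1),
                     c("VIA_POS", "VIA_POS", "VIA_NEG", "VIA_NEG"))
  expect_identical(perfect$auc, 1)
  ties <- roc_auc(rep(0.5, 6), rep(c("VIA_POS", "VIA_NEG"), 3))
  expect_identical(ties$auc, 0.5)
  # 4 positive-negative pairs: 3 concordant, 1 discordant (0.35 < 0.4)
  ex <- roc_auc(c(0.1, 0.35, 0.4, 0.8),
                c("VIA_NEG", "VIA_POS", "VIA_NEG", "VIA_POS"))
  expect_identical(ex$auc, 0.75)
  expect_error(roc_auc(c(0.1, 0.2), c("VIA_POS", "VIA_POS")), "both classes")
})

test_that("AUC agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  for (i in 1:10) {
    labels <- sample(c("VIA_POS", "VIA_NEG"), 40, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- round(runif(40), 2)
    ref <- suppressMessages(pROC::auc(pROC::roc(
      labels == "VIA_POS", scores, quiet = TRUE,
      levels = c(FALSE, TRUE), direction = "<")))
    expect_equal(roc_auc(scores, labels)$auc, as.numeric(ref),
                 tolerance = 1e-12)
  }
})

test_that("AUC equals the Mann-Whitney pair-counting oracle", {
  for (seed in 1:40) {
    set.seed(seed)
    n <- sample(5:40, 1)
    labels <- c("VIA_POS", "VIA_NEG",
                sample(c("VIA_POS", "VIA_NEG"), n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # many ties
    expect_equal(roc_auc(scores, labels)$auc, auc_oracle(scores, labels),
                 tolerance = 1e-12)
  }
})
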