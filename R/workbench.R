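#' Default run configuration
#'
#' One object holding every tunable of the end-to-end pipeline: generator
#' settings, preprocessing thresholds, feature parameters, classifier
#' families, and the three seeds (cohort, split, folds) that make a run
#' bit-reproducible.
#'
#' @param n_patients cohort size.
#' @param fraction_abnormal fraction of patients with a CIN2+ sector.
#' @param image_size synthetic image side in pixels.
#' @param whitening_strength,noise_sd,n_specular_spots generator settings
#'   (see [scene_spec()]).
#' @param sr_threshold_fraction specular threshold.
#' @param roi_planes,roi_combine bit-plane ROI settings.
#' @param ratio_bins,glcm_levels,glcm_distance feature parameters.
#' @param families classifier families to compare.
#' @param holdout_fraction training fraction of the patient-level split.
#' @param cv_k cross-validation folds.
#' @param cohort_seed,split_seed,fold_seed integer seeds.
#' @param out_dir optional run directory; when given, the feature table,
#'   reports and annulus renders are written there.
#' @return list of class `run_config`.
#' @export
run_config <- function(n_patients = 20, fraction_abnormal = 0.6,
                       image_size = 512, whitening_strength = 0.5,
                       noise_sd = 4, n_specular_spots = 6,
                       sr_threshold_fraction = 0.6,
                       roi_planes = c(6, 7), roi_combine = "or",
                       ratio_bins = 256, glcm_levels = 8, glcm_distance = 5,
                       families = c("KNN", "SVM", "DT"),
                       holdout_fraction = 0.5, cv_k = 10,
                       cohort_seed = 1L, split_seed = 2L, fold_seed = 3L,
                       out_dir = NULL) {
  structure(as.list(environment()), class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Unspecified keys fall back to the [run_config()] defaults.
#'
#' @param path YAML file whose keys match [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals[intersect(names(vals), names(formals(run_config)))])
}

#' Preprocess, register and slice one synthetic scene
#'
#' @param scene a `cervia_scene`.
#' @param config a [run_config()].
#' @return list of 12 labelled `clock_slice`s.
#' @export
process_scene <- function(scene, config = run_config()) {
  pp_pre <- preprocess_image(scene$pre, config$sr_threshold_fraction,
                             config$roi_planes, config$roi_combine)
  pp_post <- preprocess_image(scene$post, config$sr_threshold_fraction,
                              config$roi_planes, config$roi_combine)
  pid <- if (is.null(scene$patient_id)) NA_character_ else scene$patient_id
  pair <- register_pair(pp_pre$image, pp_post$image,
                        scene$fiducials, scene$fiducials,
                        roi_pre = pp_pre$roi, roi_post = pp_post$roi,
                        patient_id = pid)
  attach_labels(slice_clock(pair), scene$truth$sector_labels)
}

#' Feature table for a whole synthetic cohort
#'
#' Runs preprocessing, registration, slicing and feature extraction for
#' every patient; 12 rows per patient.
#'
#' @param cohort a `cervia_cohort`.
#' @param config a [run_config()].
#' @return data.frame with `12 * n_patients` rows.
#' @export
cohort_features <- function(cohort, config = run_config()) {
  do.call(rbind, lapply(cohort$scenes, function(scene) {
    slices <- process_scene(scene, config)
    extract_feature_table(slices, ratio_bins = config$ratio_bins,
                          glcm_levels = config$glcm_levels,
                          glcm_distance = config$glcm_distance)
  }))
}

#' Run the full pipeline from one configuration
#'
#' Simulate, preprocess, register, slice, extract, split, cross-validate
#' each classifier family on the training half, train the best-accuracy
#' family on the full training half, evaluate it on held-out patients, and
#' aggregate sector predictions to patient-level calls. Reruns with an
#' identical configuration are bit-identical.
#'
#' @param config a [run_config()].
#' @return list of class `run_result`: `features`, `split`, `cv_reports`
#'   (per family), `comparison` (ranked table), `best_family`,
#'   `test_report`, `patient_calls`, `patient_confusion`, `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  cohort <- generate_cohort(
    config$n_patients, config$fraction_abnormal, seed = config$cohort_seed,
    image_size = config$image_size,
    whitening_strength = config$whitening_strength,
    noise_sd = config$noise_sd, n_specular_spots = config$n_specular_spots)
  features <- cohort_features(cohort, config)
  split <- holdout_split(features, config$holdout_fraction,
                         seed = config$split_seed, group = "patient_id")

  cv_reports <- lapply(config$families, function(fam)
    cross_validate(split$train, classifier_spec(fam), k = config$cv_k,
                   seed = config$fold_seed))
  names(cv_reports) <- config$families
  comparison <- rank_cv_reports(cv_reports)
  best_family <- comparison$family[1]

  train <- complete_rows(split$train)
  params <- standardize(train)
  model <- train_classifier(apply_standardization(params, train),
                            classifier_spec(best_family))
  test_report <- evaluate_test(model, split$test, params)

  pc <- patient_level_calls(test_report$predictions, cohort$manifest)

  result <- structure(list(
    features = features, split = split, cv_reports = cv_reports,
    comparison = comparison, best_family = best_family, model = model,
    standardization = params, test_report = test_report,
    patient_calls = pc$calls, patient_confusion = pc$confusion,
    config = config), class = "run_result")
  if (!is.null(config$out_dir)) write_run(result, cohort, config$out_dir)
  result
}

rank_cv_reports <- function(cv_reports) {
  tab <- do.call(rbind, lapply(names(cv_reports), function(fam) {
    r <- cv_reports[[fam]]
    data.frame(family = fam, accuracy = r$accuracy,
               sensitivity = r$sensitivity, specificity = r$specificity,
               kappa = r$kappa, auc = r$auc, stringsAsFactors = FALSE)
  }))
  tab[order(-tab$accuracy, -tab$auc), , drop = FALSE]
}

patient_level_calls <- function(predictions, manifest) {
  ids <- unique(predictions$patient_id)
  calls <- do.call(rbind, lapply(ids, function(id) {
    p <- predictions[predictions$patient_id == id, ]
    lab <- rep(NA_character_, 12); lab[p$sector] <- p$predicted
    truth_grades <- unlist(manifest[manifest$patient_id == id,
                                    paste0("label_", 1:12)])
    data.frame(patient_id = id,
               predicted = suppressMessages(aggregate_patient(lab)),
               truth = if (any(truth_grades == "CIN2PLUS")) "VIA_POS" else "VIA_NEG",
               stringsAsFactors = FALSE)
  }))
  cm <- confusion_matrix(
    tp = sum(calls$predicted == "VIA_POS" & calls$truth == "VIA_POS"),
    fn = sum(calls$predicted == "VIA_NEG" & calls$truth == "VIA_POS"),
    fp = sum(calls$predicted == "VIA_POS" & calls$truth == "VIA_NEG"),
    tn = sum(calls$predicted == "VIA_NEG" & calls$truth == "VIA_NEG"))
  list(calls = calls, confusion = cm)
}

#' Cross-validated comparison of the three classifier families
#'
#' @param features feature table (or `NULL` to simulate one from `config`).
#' @param config a [run_config()].
#' @return ranked data.frame: family, accuracy, sensitivity, specificity,
#'   kappa, AUC (CV, training half), best first; ties break by AUC.
#' @export
compare_classifiers <- function(features = NULL, config = run_config()) {
  if (is.null(features)) {
    cohort <- generate_cohort(
      config$n_patients, config$fraction_abnormal, seed = config$cohort_seed,
      image_size = config$image_size,
      whitening_strength = config$whitening_strength,
      noise_sd = config$noise_sd, n_specular_spots = config$n_specular_spots)
    features <- cohort_features(cohort, config)
  }
  split <- holdout_split(features, config$holdout_fraction,
                         seed = config$split_seed, group = "patient_id")
  cv <- lapply(config$families, function(fam)
    cross_validate(split$train, classifier_spec(fam), k = config$cv_k,
                   seed = config$fold_seed))
  names(cv) <- config$families
  rank_cv_reports(cv)
}

write_run <- function(result, cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$features, file.path(dir, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(result$comparison, file.path(dir, "comparison.csv"),
                   row.names = FALSE)
  utils::write.csv(result$test_report$predictions,
                   file.path(dir, "test_predictions.csv"), row.names = FALSE)
  report <- list(
    best_family = result$best_family,
    cv = lapply(result$cv_reports, function(r)
      r[c("accuracy", "sensitivity", "specificity", "kappa", "auc")]),
    test = result$test_report[c("accuracy", "sensitivity", "specificity",
                                "kappa", "auc")],
    patient = c(binary_metrics(result$patient_confusion)[
                  c("sensitivity", "specificity", "accuracy")],
                kappa = cohen_kappa(result$patient_confusion)$kappa),
    seeds = result$config[c("cohort_seed", "split_seed", "fold_seed")])
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  # annulus renders for held-out patients
  render_dir <- file.path(dir, "renders")
  dir.create(render_dir, showWarnings = FALSE)
  preds <- result$test_report$predictions
  for (id in unique(preds$patient_id)) {
    scene <- cohort$scenes[[match(id, cohort$manifest$patient_id)]]
    slices_pred <- rep("VIA_NEG", 12)
    p <- preds[preds$patient_id == id, ]
    slices_pred[p$sector] <- p$predicted
    pp <- preprocess_image(scene$post, result$config$sr_threshold_fraction)
    img <- render_annulus(scene$post, scene$fiducials$center, slices_pred,
                          truth_grades = unname(scene$truth$sector_labels),
                          roi = pp$roi)
    write_cervicogram(img, file.path(render_dir, paste0(id, "_annulus.png")))
  }
  invisible(dir)
}
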