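#' Column sets used by the prediction models
#'
#' @return Character vectors of demographic (8) and clinical (10) cohort
#'   columns.
#' @export
demographic_columns <- function() {
  c("gestational_age", "birth_weight", "sex", "multiple_birth",
    "prenatal_steroid_doses", "delivery_route", "apgar_1min", "apgar_5min")
}

#' @rdname demographic_columns
#' @export
clinical_columns <- function() {
  c("surfactant", "inotropes", "doxapram", "dexamethasone",
    "rbc_transfusion", "ino_therapy", "nec", "sepsis", "ivh", "pda")
}

#' Specification of the ten prediction models
#'
#' The model family compared in this pipeline: (1) all 13 physiological
#' feature families over days 1-30; (2) the families with a significant
#' cluster, days 1-30; (3) the same families restricted to days 5-15 (the
#' window holding most significant clusters); (4) the SpO2/FiO2 ratio
#' alone, days 1-30; (5) demographics only; (6) model 3 + demographics;
#' (7) model 4 + demographics; (8) clinical covariates only; (9) model 6 +
#' clinical; (10) model 7 + clinical.
#'
#' @param id Model id, 1-10.
#' @return list of class `model_spec` with fields `id`, `physiological`
#'   (`"all"`, `"significant"`, a family vector, or `NULL`), `day_window`,
#'   `demographics`, `clinical`, `uses_cluster_selection`.
#' @export
model_spec <- function(id) {
  stopifnot(id %in% 1:10)
  phys <- switch(id,
    "all", "significant", "significant", "mean_sf_ratio", NULL,
    "significant", "mean_sf_ratio", NULL, "significant", "mean_sf_ratio")
  window <- switch(id,
    c(1, 30), c(1, 30), c(5, 15), c(1, 30), NULL,
    c(5, 15), c(1, 30), NULL, c(5, 15), c(1, 30))
  structure(list(
    id = id, physiological = phys, day_window = window,
    demographics = id %in% c(5, 6, 7, 9, 10),
    clinical = id %in% c(8, 9, 10),
    uses_cluster_selection = !is.null(phys) && phys[1] == "significant"),
    class = "model_spec")
}

#' Assemble the per-infant feature table for a model
#'
#' One row per infant; physiological columns are `family_d<day>` for each
#' family x day of the model's window, demographic/clinical columns come
#' from the cohort table. Missing physiological cells remain `NA` (they
#' are median-imputed inside each training fold, never globally).
#'
#' @param fm Long feature matrix ([build_feature_matrix()]).
#' @param cohort Cohort table.
#' @param spec A [model_spec()].
#' @param scan A `cluster_scan`, required when the model selects
#'   significant families.
#' @return data.frame with rownames = infant ids.
#' @export
assemble_features <- function(fm, cohort, spec, scan = NULL) {
  ids <- cohort$infant_id
  cols <- list()
  if (!is.null(spec$physiological)) {
    fams <- if (identical(spec$physiological, "all")) feature_families()
    else if (identical(spec$physiological, "significant")) {
      if (is.null(scan))
        stop("model ", spec$id, " requires cluster results")
      significant_families(scan, spec$day_window)
    } else spec$physiological
    if (length(fams) == 0)
      stop("no significant feature families available for model ", spec$id)
    dw <- spec$day_window
    for (f in fams) {
      m <- feature_day_matrix(fm, f, ids = ids)[, dw[1]:dw[2], drop = FALSE]
      colnames(m) <- sprintf("%s_d%d", f, dw[1]:dw[2])
      cols[[f]] <- m
    }
  }
  if (spec$demographics)
    cols$demographics <- as.matrix(cohort[, demographic_columns()])
  if (spec$clinical)
    cols$clinical <- as.matrix(cohort[, clinical_columns()])
  if (length(cols) == 0) stop("empty feature set")
  X <- as.data.frame(do.call(cbind, unname(cols)))
  rownames(X) <- ids
  X
}

#' Random undersampling of the majority class
#'
#' Returns row indices keeping the whole minority class and a random
#' without-replacement subset of the majority class of equal size.
#'
#' @param labels 0/1 vector.
#' @param seed Integer seed.
#' @return Sorted integer indices into `labels`.
#' @export
undersample <- function(labels, seed = 1L) {
  tab <- table(factor(labels, levels = 0:1))
  if (any(tab == 0)) stop("both classes required for undersampling")
  minority <- as.integer(names(tab)[which.min(tab)])
  keep_min <- which(labels == minority)
  maj <- which(labels != minority)
  keep_maj <- with_seed(seed,
    maj[sample.int(length(maj), length(keep_min))])
  sort(c(keep_min, keep_maj))
}

# median imputation: learn on training rows, apply to any rows
impute_medians <- function(X_train) {
  vapply(X_train, function(col) {
    m <- median(col, na.rm = TRUE)
    if (is.na(m)) 0 else m
  }, 0)
}

apply_imputation <- function(X, med) {
  for (j in seq_along(X)) {
    nas <- is.na(X[[j]])
    if (any(nas)) X[[j]][nas] <- med[[j]]
  }
  X
}

# one ensemble fit: undersample, impute, bagged trees
fit_ensemble <- function(X, y, seed, ntree = 500) {
  idx <- undersample(y, seed = seed)
  med <- impute_medians(X[idx, , drop = FALSE])
  Xb <- apply_imputation(X[idx, , drop = FALSE], med)
  with_seed(derive_seed(seed, "forest"), {
    fit <- randomForest::randomForest(
      x = Xb, y = factor(y[idx], levels = 0:1), ntree = ntree)
    list(fit = fit, medians = med)
  })
}

predict_prob <- function(model, X) {
  Xi <- apply_imputation(X, model$medians)
  unname(predict(model$fit, Xi, type = "prob")[, "1"])
}

#' Leave-one-out cross-validated predictions
#'
#' For each infant, a bagged-tree ensemble is trained on the remaining
#' infants -- with random undersampling of the majority class and
#' training-fold median imputation applied inside the fold -- and the
#' held-out infant is scored by the mean tree vote. Each fold's seed is
#' derived from the master seed and the held-out infant's id, so
#' predictions do not depend on infant ordering.
#'
#' @param X Feature table from [assemble_features()].
#' @param labels 0/1 outcome per row.
#' @param seed Master seed.
#' @param ntree Trees per ensemble (default 500).
#' @param threshold Probability threshold for the predicted label
#'   (default 0.5).
#' @return A `prediction_set` data.frame: `infant_id`, `truth`, `prob`,
#'   `pred`, `fold`.
#' @export
loocv_evaluate <- function(X, labels, seed = 1L, ntree = 500,
                           threshold = 0.5) {
  n <- nrow(X)
  stopifnot(n >= 10, length(labels) == n)
  ids <- rownames(X) %||% as.character(seq_len(n))
  # canonical id order: bootstrap draws depend on row order, so sorting
  # first makes predictions invariant to how the cohort was arranged
  ord <- order(ids)
  X <- X[ord, , drop = FALSE]
  labels <- labels[ord]
  ids <- ids[ord]
  prob <- numeric(n)
  for (i in seq_len(n)) {
    ytr <- labels[-i]
    if (length(unique(ytr)) < 2)
      stop("training fold for ", ids[i], " has a single class")
    model <- fit_ensemble(X[-i, , drop = FALSE], ytr,
                          seed = derive_seed(seed, ids[i]), ntree = ntree)
    prob[i] <- predict_prob(model, X[i, , drop = FALSE])
  }
  structure(data.frame(infant_id = ids, truth = as.integer(labels),
                       prob = prob, pred = as.integer(prob >= threshold),
                       fold = seq_len(n), stringsAsFactors = FALSE),
            class = c("prediction_set", "data.frame"))
}

#' Confusion counts and metrics from a prediction set
#'
#' @param predictions A `prediction_set`.
#' @param threshold Probability threshold (default 0.5).
#' @param ... Passed to [confusion_metrics()].
#' @return An `evaluation_result`.
#' @export
evaluate_predictions <- function(predictions, threshold = 0.5, ...) {
  pred <- as.integer(predictions$prob >= threshold)
  truth <- predictions$truth
  confusion_metrics(tp = sum(pred == 1 & truth == 1),
                    fp = sum(pred == 1 & truth == 0),
                    fn = sum(pred == 0 & truth == 1),
                    tn = sum(pred == 0 & truth == 0), ...)
}

#' Sensitivity/specificity across probability thresholds
#'
#' Re-derives predicted labels (positive when probability >= threshold)
#' at each threshold. Sensitivity is non-increasing and specificity
#' non-decreasing in the threshold.
#'
#' @param predictions A `prediction_set`.
#' @param thresholds Thresholds to evaluate (default 0, 0.01, ..., 1).
#' @return data.frame `threshold`, `sensitivity`, `specificity`.
#' @export
threshold_sweep <- function(predictions, thresholds = seq(0, 1, 0.01)) {
  truth <- predictions$truth
  npos <- sum(truth == 1); nneg <- sum(truth == 0)
  out <- lapply(thresholds, function(th) {
    pred <- predictions$prob >= th
    data.frame(threshold = th,
               sensitivity = sum(pred & truth == 1) / npos,
               specificity = sum(!pred & truth == 0) / nneg)
  })
  do.call(rbind, out)
}

#' Train on one cohort, validate on an independent one
#'
#' A single ensemble is trained on the full training set (undersampled,
#' median-imputed) and applied with a fixed probability threshold to the
#' held-out test set.
#'
#' @param X_train,X_test Feature tables with infant-id rownames; ids must
#'   be disjoint.
#' @param y_train,y_test 0/1 outcomes.
#' @param seed Master seed.
#' @param ntree Trees per ensemble.
#' @param threshold Probability threshold (default 0.5).
#' @param ... Passed to [confusion_metrics()].
#' @return list with `predictions` (a `prediction_set`) and `evaluation`
#'   (an `evaluation_result`).
#' @export
holdout_validate <- function(X_train, y_train, X_test, y_test, seed = 1L,
                             ntree = 500, threshold = 0.5, ...) {
  if (nrow(X_test) == 0) stop("empty test set")
  if (length(intersect(rownames(X_train), rownames(X_test))) > 0)
    stop("training and test sets share infants")
  model <- fit_ensemble(X_train, y_train,
                        seed = derive_seed(seed, "holdout"), ntree = ntree)
  prob <- predict_prob(model, X_test)
  preds <- structure(
    data.frame(infant_id = rownames(X_test) %||%
                 as.character(seq_len(nrow(X_test))),
               truth = as.integer(y_test), prob = prob,
               pred = as.integer(prob >= threshold),
               fold = NA_integer_, stringsAsFactors = FALSE),
    class = c("prediction_set", "data.frame"))
  list(predictions = preds,
       evaluation = evaluate_predictions(preds, threshold, ...))
}

#' Retrain a model on a gestational-age subgroup
#'
#' Restricts the cohort to infants with gestational age at or below
#' `ga_max_weeks` (default 28, the subgroup in which most laser-treated
#' infants fall) and reruns the full LOOCV protocol.
#'
#' @param fm Long feature matrix.
#' @param cohort Cohort table (needs `gestational_age`).
#' @param spec A [model_spec()].
#' @param scan Cluster scan (when the model needs it).
#' @param ga_max_weeks Gestational-age cutoff in weeks.
#' @param seed,ntree,threshold Passed to [loocv_evaluate()].
#' @return list with `n`, `predictions`, `evaluation`.
#' @export
subgroup_retrain <- function(fm, cohort, spec, scan = NULL,
                             ga_max_weeks = 28, seed = 1L, ntree = 500,
                             threshold = 0.5) {
  sub <- cohort[cohort$gestational_age <= ga_max_weeks, , drop = FALSE]
  if (length(unique(sub$outcome)) < 2)
    stop("subgroup does not retain both classes")
  X <- assemble_features(fm, sub, spec, scan)
  preds <- loocv_evaluate(X, sub$outcome, seed = seed, ntree = ntree,
                          threshold = threshold)
  list(n = nrow(sub), predictions = preds,
       evaluation = evaluate_predictions(preds, threshold))
}
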