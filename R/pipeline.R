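#' Random 1:1 split of a cohort into training and test sets
#'
#' The split is performed before any exclusion criteria are applied (the
#' protocol of the study design this pipeline reproduces), so exclusions
#' never leak information across the split.
#'
#' @param cohort Cohort table.
#' @param ratio Fraction assigned to the training set (default 0.5).
#' @param seed Integer seed.
#' @return list with `train_ids` and `test_ids` (disjoint, exhaustive).
#' @export
split_cohort <- function(cohort, ratio = 0.5, seed = 1L) {
  n <- nrow(cohort)
  if (n == 0) stop("empty cohort")
  stopifnot(ratio > 0, ratio < 1)
  n_train <- floor(n * ratio)
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train_ids = cohort$infant_id[sort(idx)],
       test_ids = cohort$infant_id[sort(setdiff(seq_len(n), idx))])
}

#' Apply the cohort inclusion filters
#'
#' Excludes infants with gestational age above `ga_max` weeks, birth
#' weight above `bw_max` g, or less than `min_availability` valid monitor
#' time over the availability window (default postnatal days 1-14). Each
#' excluded infant is logged once with the first failing rule, in the
#' order gestational_age, birth_weight, availability.
#'
#' @param cohort Cohort table.
#' @param traces Long trace table (for the availability rule).
#' @param ga_max Gestational-age exclusion bound, weeks (exclusive; `> 32`
#'   excludes).
#' @param bw_max Birth-weight exclusion bound, g (exclusive).
#' @param min_availability Minimum availability fraction (inclusive at the
#'   bound: 0.80 is kept, 0.79 excluded).
#' @param avail_window Day window for availability, default `c(1, 14)`.
#' @return list with `included` (filtered cohort) and `exclusions`
#'   (data.frame `infant_id`, `reason`).
#' @export
apply_inclusion <- function(cohort, traces, ga_max = 32, bw_max = 1500,
                            min_availability = 0.80,
                            avail_window = c(1, 14)) {
  av <- availability(traces, avail_window[1], avail_window[2])
  av_map <- stats::setNames(av$availability, av$infant_id)
  avail <- av_map[cohort$infant_id]
  avail[is.na(avail)] <- 0
  reason <- rep(NA_character_, nrow(cohort))
  reason[avail < min_availability] <- "availability"
  reason[cohort$birth_weight > bw_max] <- "birth_weight"
  reason[cohort$gestational_age > ga_max] <- "gestational_age"
  excl <- !is.na(reason)
  list(included = cohort[!excl, , drop = FALSE],
       exclusions = data.frame(infant_id = cohort$infant_id[excl],
                               reason = reason[excl],
                               stringsAsFactors = FALSE))
}

#' Configuration for an end-to-end pipeline run
#'
#' @param generator A [generator_config()] describing the synthetic
#'   cohort (or `NULL` when `cohort`/`traces` are supplied to
#'   [run_pipeline()] directly).
#' @param seed Master seed; every stage derives its own sub-seed from it.
#' @param split_ratio Training fraction of the 1:1 split.
#' @param models Model ids to evaluate by LOOCV on the training set.
#' @param validate_models Model ids additionally trained on the full
#'   training set and validated on the test set.
#' @param n_perm Permutations for the cluster scan.
#' @param ntree Trees per ensemble.
#' @param threshold Probability threshold for predicted labels.
#' @param event_rules Event rules for feature extraction.
#' @param ga_max,bw_max,min_availability,avail_window Inclusion rules
#'   (see [apply_inclusion()]).
#' @return A `run_config` list.
#' @export
run_config <- function(generator = NULL, seed = 1L, split_ratio = 0.5,
                       models = c(1, 4, 5, 7),
                       validate_models = 7,
                       n_perm = 1999, ntree = 500, threshold = 0.5,
                       event_rules = default_event_rules(),
                       ga_max = 32, bw_max = 1500,
                       min_availability = 0.80, avail_window = c(1, 14)) {
  stopifnot(all(models %in% 1:10), all(validate_models %in% models))
  structure(as.list(environment()), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' simulate (or accept) a cohort -> 1:1 split -> inclusion filters ->
#' daily feature extraction -> baseline table -> cluster scan on the
#' training set -> LOOCV evaluation of the configured models ->
#' independent-test validation of the selected models -> threshold sweep.
#' All randomness derives from the master seed, so two runs with the same
#' configuration are identical.
#'
#' @param config A [run_config()].
#' @param cohort,traces Optional pre-existing cohort/traces (bypasses the
#'   generator).
#' @param out_dir Optional directory; when given, all tables are written
#'   there as tab-separated text together with a `manifest` of resolved
#'   seeds and sizes.
#' @return list of class `pipeline_result` with elements `cohort`,
#'   `split`, `inclusion`, `features`, `baseline`, `clusters`,
#'   `evaluations` (per model: predictions + evaluation), `validation`,
#'   `sweeps`, `manifest`.
#' @export
run_pipeline <- function(config, cohort = NULL, traces = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  if (is.null(cohort)) {
    gen <- config$generator
    if (is.null(gen)) stop("either a generator config or cohort+traces")
    sim <- generate_cohort(gen)
    cohort <- sim$cohort
    traces <- sim$traces
  }

  split <- split_cohort(cohort, config$split_ratio,
                        seed = derive_seed(seed, "split"))
  inc <- apply_inclusion(cohort, traces, config$ga_max, config$bw_max,
                         config$min_availability, config$avail_window)
  train <- inc$included[inc$included$infant_id %in% split$train_ids, ,
                        drop = FALSE]
  test <- inc$included[inc$included$infant_id %in% split$test_ids, ,
                       drop = FALSE]

  fm <- build_feature_matrix(traces, config$event_rules)
  baseline <- baseline_table(train)
  scan <- cluster_scan(fm, train, n_perm = config$n_perm,
                       seed = derive_seed(seed, "cluster"))

  evaluations <- lapply(config$models, function(mid) {
    spec <- model_spec(mid)
    X <- assemble_features(fm, train, spec, scan)
    preds <- loocv_evaluate(X, train$outcome,
                            seed = derive_seed(seed, paste0("loocv", mid)),
                            ntree = config$ntree,
                            threshold = config$threshold)
    list(model = mid, predictions = preds,
         evaluation = evaluate_predictions(preds, config$threshold))
  })
  names(evaluations) <- paste0("model", config$models)

  validation <- lapply(config$validate_models, function(mid) {
    spec <- model_spec(mid)
    Xtr <- assemble_features(fm, train, spec, scan)
    Xte <- assemble_features(fm, test, spec, scan)
    holdout_validate(Xtr, train$outcome, Xte, test$outcome,
                     seed = derive_seed(seed, paste0("holdout", mid)),
                     ntree = config$ntree, threshold = config$threshold)
  })
  names(validation) <- paste0("model", config$validate_models)

  sweeps <- lapply(evaluations, function(ev)
    threshold_sweep(ev$predictions))

  manifest <- list(
    seed = seed, n_cohort = nrow(cohort),
    n_excluded = nrow(inc$exclusions),
    n_train = nrow(train), n_test = nrow(test),
    n_positive_train = sum(train$outcome),
    n_perm = config$n_perm, ntree = config$ntree,
    models = config$models,
    stage_seeds = c(split = derive_seed(seed, "split"),
                    cluster = derive_seed(seed, "cluster")))

  res <- structure(list(cohort = cohort, split = split, inclusion = inc,
                        train = train, test = test, features = fm,
                        baseline = baseline, clusters = scan,
                        evaluations = evaluations, validation = validation,
                        sweeps = sweeps, manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(res, out_dir)
  res
}

# flat metric table for reporting (2-dp at the reporting layer only)
evaluation_row <- function(ev) {
  i <- ev$intervals
  data.frame(
    balanced_accuracy = ev$balanced_accuracy,
    sensitivity = ev$sensitivity, specificity = ev$specificity,
    mcc = ev$mcc, ppv = ev$ppv, npv = ev$npv,
    ba_lower = i$lower[i$metric == "balanced_accuracy"],
    ba_upper = i$upper[i$metric == "balanced_accuracy"],
    sens_lower = i$lower[i$metric == "sensitivity"],
    sens_upper = i$upper[i$metric == "sensitivity"],
    spec_lower = i$lower[i$metric == "specificity"],
    spec_upper = i$upper[i$metric == "specificity"])
}

#' Performance table across evaluated models
#'
#' @param result A `pipeline_result`.
#' @param digits Rounding (half away from zero) applied for display;
#'   `NULL` keeps full precision.
#' @return data.frame, one row per model.
#' @export
performance_table <- function(result, digits = NULL) {
  tab <- do.call(rbind, lapply(result$evaluations, function(ev)
    cbind(model = ev$model, evaluation_row(ev$evaluation))))
  rownames(tab) <- NULL
  if (!is.null(digits))
    tab[-1] <- lapply(tab[-1], round_away, digits = digits)
  tab
}

write_pipeline_result <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) data.table::fwrite(x, file.path(out_dir, f),
                                         sep = "\t")
  w(res$cohort, "cohort.tsv")
  w(res$inclusion$exclusions, "exclusions.tsv")
  w(res$features, "feature_matrix.tsv")
  w(res$baseline, "baseline_table.tsv")
  w(res$clusters$summary, "cluster_summary.tsv")
  w(performance_table(res), "performance.tsv")
  for (nm in names(res$evaluations))
    w(res$evaluations[[nm]]$predictions,
      paste0("predictions_", nm, ".tsv"))
  for (nm in names(res$sweeps))
    w(res$sweeps[[nm]], paste0("threshold_sweep_", nm, ".tsv"))
  man <- res$manifest
  writeLines(paste0(names(unlist(man)), "\t", unlist(man)),
             file.path(out_dir, "manifest.tsv"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat("Pipeline run (seed", m$seed, ")\n")
  cat("  cohort:", m$n_cohort, "infants;", m$n_excluded, "excluded;",
      m$n_train, "train /", m$n_test, "test\n")
  sig <- significant_families(x$clusters)
  cat("  significant feature families:",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
  print(performance_table(x, digits = 2))
  invisible(x)
}
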