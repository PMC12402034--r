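#' Task and scenario specification
#'
#' Two tasks are modelled: `diagnosis` (classify previously undiagnosed
#' individuals as newly T2D-positive at baseline) and `prognosis` (predict
#' incident T2D over follow-up from baseline features). Two scenarios
#' restrict the feature space: `ENV` uses environmental features only;
#' `HEA` uses environmental plus clinical features, so the ENV feature set
#' is always a subset of the HEA set.
#'
#' @param task `"diagnosis"` or `"prognosis"`.
#' @param scenario `"ENV"` or `"HEA"`.
#' @return object of class `task_spec`.
#' @export
task_spec <- function(task = c("diagnosis", "prognosis"),
                      scenario = c("ENV", "HEA")) {
  structure(list(task = match.arg(task), scenario = match.arg(scenario)),
            class = "task_spec")
}

#' Assemble the modelling sample for a task and scenario
#'
#' Applies the task's exclusion rules and the scenario's column
#' restriction. Individuals with a pre-study ("known") T2D diagnosis are
#' excluded from every task; the prognosis task additionally excludes
#' baseline-diagnosed individuals and those lacking complete follow-up.
#' Explanatory variables are always baseline values.
#'
#' @param cohort an engineered cohort bundle with labels.
#' @param spec a [task_spec()].
#' @return list with `X` (data frame), `y` (logical labels), `groups`
#'   (region labels), `rows` (row indices into the cohort), `spec`, and
#'   `exclusions` (named counts of individuals removed by each rule).
#' @export
build_task_sample <- function(cohort, spec) {
  stopifnot(inherits(cohort, "cohort_bundle"), inherits(spec, "task_spec"))
  lb <- cohort$labels
  req <- c("known_t2d", "baseline_new_diagnosis")
  if (spec$task == "prognosis")
    req <- c(req, "in_followup", "followup_complete", "incident_t2d")
  if (!all(req %in% colnames(lb)))
    stop_config("cohort labels lack required columns: %s",
                paste(setdiff(req, colnames(lb)), collapse = ", "))
  exclusions <- c(known_t2d = sum(lb$known_t2d))
  keep <- !lb$known_t2d
  if (spec$task == "diagnosis") {
    y <- lb$baseline_new_diagnosis[keep]
  } else {
    exclusions <- c(exclusions,
                    not_in_followup = sum(keep & !lb$in_followup),
                    baseline_diagnosed = sum(keep & lb$in_followup &
                                               lb$baseline_new_diagnosis),
                    followup_incomplete = sum(keep & lb$in_followup &
                                                !lb$baseline_new_diagnosis &
                                                !lb$followup_complete))
    keep <- keep & lb$in_followup & lb$followup_complete &
      !lb$baseline_new_diagnosis
    y <- lb$incident_t2d[keep]
  }
  domains <- if (spec$scenario == "ENV") "ENV" else c("ENV", "CLI")
  cols <- cohort$metadata$name[cohort$metadata$domain %in% domains]
  cols <- intersect(colnames(cohort$values), cols)
  rows <- which(keep)
  list(X = cohort$values[rows, cols, drop = FALSE],
       y = y,
       groups = region_groups(cohort)[rows],
       rows = rows, spec = spec, exclusions = exclusions)
}

#' Profile defaults for the analysis stages
#'
#' The `paper` profile uses the production settings (100 importance and
#' selection repetitions, 20 tuning folds, 100 tuning trials, 10 evaluation
#' folds); the `test` profile scales every repetition count down so the
#' full pipeline runs in well under a minute on small cohorts.
#'
#' @param profile `"test"` or `"paper"`.
#' @return named list of stage settings.
#' @export
pipeline_profile <- function(profile = c("test", "paper")) {
  profile <- match.arg(profile)
  if (profile == "paper")
    list(pi_reps = 100L, sfs_reps = 100L, tune_folds = 20L,
         tune_trials = 100L, eval_folds = 10L, test_fraction = 0.3)
  else
    list(pi_reps = 10L, sfs_reps = 10L, tune_folds = 3L,
         tune_trials = 5L, eval_folds = 5L, test_fraction = 0.3)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> geospatial augmentation -> feature engineering ->
#' per task/scenario: imputation -> quasi-constancy filtering ->
#' permutation importance -> backward selection -> hyperparameter tuning ->
#' group-disjoint cross-validated evaluation with Youden-threshold metrics
#' -> partial dependence on the selected features. Fully seeded: identical
#' configuration and seed reproduce identical reports.
#'
#' @param config a [cohort_config()]; use [small_cohort_config()] for smoke
#'   runs.
#' @param tasks data frame with columns `task` and `scenario` (default: all
#'   four models D-ENV, D-HEA, P-ENV, P-HEA).
#' @param profile `"test"` or `"paper"` (see [pipeline_profile()]).
#' @param qs_threshold,qc_threshold retention thresholds for imputation
#'   quality score and quasi-constancy index.
#' @param idw inverse-distance-weighting configuration.
#' @param seed master seed (fanned out to per-stage seeds).
#' @return object of class `report_bundle`: per-model reports (selected
#'   features, evaluation, Youden metrics, partial-dependence curves,
#'   exclusion accounting) plus the engineered cohort.
#' @export
run_pipeline <- function(config = small_cohort_config(),
                         tasks = expand.grid(task = c("diagnosis", "prognosis"),
                                             scenario = c("ENV", "HEA"),
                                             stringsAsFactors = FALSE),
                         profile = "test",
                         qs_threshold = 0.7, qc_threshold = 0.05,
                         idw = idw_config(), seed = NULL) {
  prof <- pipeline_profile(profile)
  seed <- seed %||% config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_config("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  cohort <- stage("simulate", {
    co <- generate_cohort(config)
    inject_missingness(co)
  })
  cohort <- stage("geospatial", augment_cohort_geospatial(cohort, cfg = idw))
  cohort <- stage("engineering", engineer_features(cohort))

  reports <- list()
  for (i in seq_len(nrow(tasks))) {
    spec <- task_spec(tasks$task[i], tasks$scenario[i])
    model_id <- paste0(toupper(substr(spec$task, 1, 1)), "-", spec$scenario)
    sample <- stage("task_sample", build_task_sample(cohort, spec))
    mseed <- derive_seed(seed, model_id)

    plan <- stage("imputation",
                  select_imputers(sample$X, qs_threshold = qs_threshold,
                                  seed = mseed, min_obs = 20L))
    X <- stage("imputation", apply_imputation(plan, sample$X,
                                              seed = mseed)$train)
    qc <- stage("quasi_constancy", filter_quasi_constant(X, qc_threshold))
    X <- X[, qc$retained, drop = FALSE]

    spw <- max(1, sum(!sample$y) / max(1, sum(sample$y)))
    params <- default_gbt_params(scale_pos_weight = spw)
    pi_res <- stage("importance",
                    permutation_importance(X, sample$y, sample$groups,
                                           params, n_reps = prof$pi_reps,
                                           test_fraction = prof$test_fraction,
                                           seed = mseed))
    sig <- significant_features(pi_res)
    if (length(sig) >= 2L) {
      sfs <- stage("selection",
                   backward_sfs(X, sample$y, sample$groups, sig, params,
                                n_reps = prof$sfs_reps,
                                test_fraction = prof$test_fraction,
                                seed = mseed))
      selected <- sfs$selected
    } else {
      sfs <- NULL
      selected <- if (length(sig)) sig else colnames(X)
    }

    Xs <- X[, selected, drop = FALSE]
    tuned <- stage("tuning", tune_hyperparameters(
      Xs, sample$y, sample$groups,
      space = default_search_space(max_scale_pos_weight = 2 * spw),
      n_folds = prof$tune_folds, n_trials = prof$tune_trials, seed = mseed))
    evaluation <- stage("evaluation", crossval_evaluate(
      Xs, sample$y, sample$groups, tuned$params,
      k = prof$eval_folds, seed = mseed))

    final_fit <- stage("explain", fit_gbt(Xs, sample$y, tuned$params,
                                          seed = mseed))
    pdp <- stage("explain", lapply(selected, function(f)
      partial_dependence(final_fit, Xs, f)))
    names(pdp) <- selected

    reports[[model_id]] <- list(
      spec = spec, n = nrow(Xs), n_positive = sum(sample$y),
      exclusions = sample$exclusions,
      imputation_plan = plan, quasi_constancy = qc$results,
      importance = pi_res, significant = sig, sfs = sfs,
      selected = selected, tuned = tuned, evaluation = evaluation,
      pdp = pdp)
  }
  structure(list(models = reports, cohort = cohort, profile = prof,
                 seed = seed),
            class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("report_bundle: %d model(s), seed %d\n",
              length(x$models), x$seed))
  for (id in names(x$models)) {
    m <- x$models[[id]]
    cat(sprintf("  %-6s n=%d (%d positive), %d selected, mean AUROC %.3f\n",
                id, m$n, m$n_positive, length(m$selected),
                m$evaluation$mean_auroc))
  }
  invisible(x)
}
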