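#' Configuration for the synthetic cohort generator
#'
#' Builds the configuration object consumed by [generate_municipality_table()],
#' [generate_cohort()] and [inject_missingness()]. The defaults reproduce the
#' composition of the population study the pipeline emulates: 4617
#' individuals of whom 417 carry a pre-study ("known") T2D diagnosis, leaving
#' 4200 eligible for the diagnosis task; 227 of those receive a new diagnosis
#' at baseline (5.4%); 1850 individuals enter the ~7.5-year follow-up, 1608 of
#' whom are prognosis-eligible (neither diagnosed at baseline nor missing
#' follow-up variables) with 125 incident cases (7.8%). Label counts are
#' matched exactly by thresholding a latent risk score at the corresponding
#' empirical quantile, so these counts are reproduced deterministically for
#' every seed.
#'
#' @param n_individuals total cohort size.
#' @param n_known_t2d individuals with a pre-study T2D diagnosis (excluded
#'   from all modelling tasks).
#' @param n_new_diagnosis baseline new diagnoses among the remaining
#'   individuals (the diagnosis-task positives).
#' @param n_followup individuals entering follow-up.
#' @param n_followup_eligible follow-up individuals that are
#'   prognosis-eligible (no baseline diagnosis, complete follow-up).
#' @param n_incident incident T2D cases among the prognosis-eligible.
#' @param n_municipalities,n_covered_municipalities number of municipalities
#'   and how many of them have pollution records.
#' @param n_uncovered_individuals individuals living in municipalities
#'   without pollution coverage (default reproduces a 50.4% uncovered
#'   fraction: 2327/4617).
#' @param n_regions number of administrative regions grouping municipalities;
#'   regions are the unit of all train/test splits.
#' @param income_missing_rate fraction of municipalities with missing income.
#' @param n_pollution_metrics,n_pollution_years pollution series shape.
#' @param feature_inventory data frame describing the raw feature layer; see
#'   [default_feature_inventory()].
#' @param effect_spec data frame with columns `feature` and `effect`: drivers
#'   of the latent log-odds risk score and their standardized coefficients.
#' @param missingness_spec list with elements `mcar_rate`, `always_complete`
#'   and `blocks` (named list of `list(features =, rate =)`), controlling
#'   [inject_missingness()].
#' @param followup_years_mean,followup_years_sd stored per-individual
#'   follow-up duration (no downstream use).
#' @param seed master seed.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_individuals = 4617L,
                          n_known_t2d = 417L,
                          n_new_diagnosis = 227L,
                          n_followup = 1850L,
                          n_followup_eligible = 1608L,
                          n_incident = 125L,
                          n_municipalities = 319L,
                          n_covered_municipalities = 56L,
                          n_uncovered_individuals = 2327L,
                          n_regions = 40L,
                          income_missing_rate = 0.20,
                          n_pollution_metrics = 12L,
                          n_pollution_years = 10L,
                          feature_inventory = NULL,
                          effect_spec = NULL,
                          missingness_spec = NULL,
                          followup_years_mean = 7.48,
                          followup_years_sd = 0.55,
                          seed = 1L) {
  counts <- c(n_individuals = n_individuals, n_known_t2d = n_known_t2d,
              n_new_diagnosis = n_new_diagnosis, n_followup = n_followup,
              n_followup_eligible = n_followup_eligible,
              n_incident = n_incident,
              n_municipalities = n_municipalities,
              n_covered_municipalities = n_covered_municipalities,
              n_regions = n_regions)
  if (any(counts < 0)) stop_config("all counts must be nonnegative")
  if (n_known_t2d + n_new_diagnosis > n_individuals)
    stop_config("n_known_t2d + n_new_diagnosis exceeds n_individuals")
  if (n_followup > n_individuals - n_known_t2d)
    stop_config("n_followup exceeds the number of non-known-T2D individuals")
  if (n_followup_eligible > n_followup)
    stop_config("n_followup_eligible exceeds n_followup")
  if (n_incident > n_followup_eligible)
    stop_config("n_incident exceeds n_followup_eligible")
  if (n_covered_municipalities > n_municipalities)
    stop_config("n_covered_municipalities exceeds n_municipalities")
  if (n_uncovered_individuals > n_individuals)
    stop_config("n_uncovered_individuals exceeds n_individuals")
  if (n_covered_municipalities == n_municipalities &&
      n_uncovered_individuals > 0)
    stop_config("cannot place individuals in uncovered municipalities: all are covered")
  check_fraction(income_missing_rate, "income_missing_rate")

  inv <- feature_inventory %||% default_feature_inventory()
  eff <- effect_spec %||% default_effect_spec()
  missing_eff <- setdiff(eff$feature, inv$name)
  if (length(missing_eff))
    stop_config("effect_spec names absent features: %s",
                paste(missing_eff, collapse = ", "))
  mspec <- missingness_spec %||% default_missingness_spec(inv)
  for (r in vapply(mspec$blocks, function(b) b$rate, numeric(1)))
    check_fraction(r, "block rate")
  check_fraction(mspec$mcar_rate, "mcar_rate")
  bad <- unlist(lapply(mspec$blocks, function(b) setdiff(b$features, inv$name)))
  if (length(bad))
    stop_config("missingness block references unknown features: %s",
                paste(unique(bad), collapse = ", "))

  structure(list(
    n_individuals = as.integer(n_individuals),
    n_known_t2d = as.integer(n_known_t2d),
    n_new_diagnosis = as.integer(n_new_diagnosis),
    n_followup = as.integer(n_followup),
    n_followup_eligible = as.integer(n_followup_eligible),
    n_incident = as.integer(n_incident),
    n_municipalities = as.integer(n_municipalities),
    n_covered_municipalities = as.integer(n_covered_municipalities),
    n_uncovered_individuals = as.integer(n_uncovered_individuals),
    n_regions = as.integer(n_regions),
    income_missing_rate = income_missing_rate,
    n_pollution_metrics = as.integer(n_pollution_metrics),
    n_pollution_years = as.integer(n_pollution_years),
    feature_inventory = inv,
    effect_spec = eff,
    missingness_spec = mspec,
    followup_years_mean = followup_years_mean,
    followup_years_sd = followup_years_sd,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Reduced-size configuration for fast experiments and tests
#'
#' Same structure as [cohort_config()] but with a small feature inventory and
#' proportionally scaled counts, so the whole pipeline runs in seconds.
#'
#' @param n_individuals cohort size (default 400).
#' @param seed master seed.
#' @param ... overrides passed on to [cohort_config()].
#' @return object of class `cohort_config`.
#' @export
small_cohort_config <- function(n_individuals = 400L, seed = 1L, ...) {
  inv <- default_feature_inventory(
    n_standalone_lifestyle = 6L,
    group_sizes = c(coffee_intake = 3L, vegetables_legumes_intake = 3L,
                    carbohydrate_rich_intake = 4L),
    n_disease = 3L, n_clinical = 4L)
  n <- as.integer(n_individuals)
  cohort_config(
    n_individuals = n,
    n_known_t2d = max(2L, as.integer(round(n * 0.09))),
    n_new_diagnosis = max(2L, as.integer(round(n * 0.05))),
    n_followup = as.integer(round(n * 0.4)),
    n_followup_eligible = as.integer(round(n * 0.33)),
    n_incident = max(2L, as.integer(round(n * 0.027))),
    n_municipalities = 30L, n_covered_municipalities = 12L,
    n_uncovered_individuals = as.integer(round(n * 0.5)),
    n_regions = 8L,
    feature_inventory = inv,
    effect_spec = {
      eff <- default_effect_spec()
      eff[eff$feature %in% inv$name, , drop = FALSE]
    },
    seed = seed, ...)
}

pollution_metric_names <- function(k = 12L) {
  base <- c("no2", "so2", "o3", "pm10", "pm25", "co",
            "benzene", "lead", "arsenic", "cadmium", "nickel", "toluene")
  if (k <= length(base)) base[seq_len(k)]
  else c(base, sprintf("metric%02d", seq_len(k - length(base))))
}

#' Default raw feature inventory
#'
#' Describes the raw (pre-engineering) feature layer the generator emits.
#' With the default sizes the inventory holds 242 raw environmental features
#' (220 lifestyle, 11 anthropometric including 4 redundant threshold flags,
#' 11 disease/treatment) plus 16 clinical-biochemistry features, and the
#' engineering stage deterministically collapses it to 51 lifestyle + 8
#' anthropometric + 11 disease = 70 environmental features, which the
#' geospatial block (12 pollution + population + income) completes to 84.
#'
#' @param n_standalone_lifestyle number of standalone lifestyle features in
#'   addition to `current_smoker` (default 37).
#' @param group_sizes named integer vector: questionnaire sum-groups and the
#'   number of raw items feeding each.
#' @param n_disease,n_clinical feature counts for the disease/treatment and
#'   clinical-biochemistry blocks.
#' @return data frame with columns `name`, `domain` (ENV/CLI), `source`,
#'   `role`, `group`, `period`, `whole_grain`, `parent`.
#' @export
default_feature_inventory <- function(
    n_standalone_lifestyle = 37L,
    group_sizes = c(tea_herbal_infusions = 12L, coffee_intake = 14L,
                    caffeinated_beverages = 16L, wine_consumption = 10L,
                    alcohol_consumption = 20L,
                    vegetables_legumes_intake = 22L,
                    fried_precooked_intake = 14L, eggs_dairy_intake = 16L,
                    carbohydrate_rich_intake = 16L,
                    sugar_snacks_desserts = 22L, fatty_sides_intake = 18L),
    n_disease = 11L, n_clinical = 16L) {
  row <- function(name, domain, source, role, group = NA_character_,
                  period = NA_character_, whole_grain = FALSE,
                  parent = NA_character_) {
    data.frame(name = name, domain = domain, source = source, role = role,
               group = group, period = period, whole_grain = whole_grain,
               parent = parent, stringsAsFactors = FALSE)
  }
  standalone_pool <- c(
    "physical_activity_workdays", "moderate_met_minutes_week",
    "vigorous_met_minutes_week", "walking_met_minutes_week",
    "hours_of_sleep", "sitting_hours_day", "meat_intake",
    "fresh_fish_seafood_intake", "sugar_soft_drinks",
    "sugar_free_soft_drinks", "fruit_intake", "olive_oil_consumption",
    "nuts_intake", "education_level", "employment_status",
    "alcohol_binge_frequency", "breakfast_habit", "snacking_frequency",
    "salt_added_at_table", "water_glasses_day", "tv_hours_day",
    "car_use_frequency", "walking_minutes_day", "stairs_flights_day",
    "night_shift_work", "sleep_quality_score", "diet_adherence_score",
    "weight_change_5y", "siesta_habit", "eating_out_frequency",
    "home_cooked_meals_week", "screen_time_evening",
    "commute_minutes_day", "gardening_hours_week", "pet_ownership",
    "social_meals_week", "supplement_use")
  if (n_standalone_lifestyle > length(standalone_pool))
    standalone_pool <- c(standalone_pool,
                         sprintf("lifestyle_extra%02d",
                                 seq_len(n_standalone_lifestyle -
                                           length(standalone_pool))))
  standalone <- standalone_pool[seq_len(n_standalone_lifestyle)]
  # intake-like standalone items carry a declared reporting period
  intake_items <- intersect(standalone,
                            c("meat_intake", "fresh_fish_seafood_intake",
                              "sugar_soft_drinks", "sugar_free_soft_drinks",
                              "fruit_intake", "nuts_intake"))
  periods <- ifelse(standalone %in% intake_items, "month", NA_character_)

  inv <- list(row(standalone, "ENV", "lifestyle", "standalone",
                  period = periods))
  inv[[length(inv) + 1L]] <-
    row("current_smoker", "ENV", "lifestyle", "standalone")
  inv[[length(inv) + 1L]] <-
    row(c("years_smoked", "cigarettes_per_day"), "ENV", "lifestyle",
        "smoking_raw")
  period_cycle <- c("month", "week", "day")
  for (g in names(group_sizes)) {
    k <- group_sizes[[g]]
    nm <- sprintf("%s_item%02d", g, seq_len(k))
    wg <- rep(FALSE, k)
    if (g == "carbohydrate_rich_intake") wg[seq_len(ceiling(k / 2))] <- TRUE
    inv[[length(inv) + 1L]] <-
      row(nm, "ENV", "lifestyle", "group_source", group = g,
          period = period_cycle[(seq_len(k) - 1L) %% 3L + 1L],
          whole_grain = wg)
  }
  inv[[length(inv) + 1L]] <- row(
    c("age", "sex", "height_cm", "weight_kg", "bmi", "waist_cm", "hip_cm"),
    "ENV", "anthropometric", "standalone")
  inv[[length(inv) + 1L]] <- row(
    c("bmi_ge_30", "bmi_le_19", "waist_gt_102", "waist_gt_88"),
    "ENV", "anthropometric", "threshold_flag",
    parent = c("bmi", "bmi", "waist_cm", "waist_cm"))
  disease_pool <- c(
    "hypertension", "n_hypotensive_drugs", "dyslipidemia",
    "statin_treatment", "cardiovascular_disease", "gestational_diabetes",
    "relatives_t2d", "thyroid_disease", "corticosteroid_treatment",
    "kidney_disease", "depression_treatment")
  if (n_disease > length(disease_pool))
    disease_pool <- c(disease_pool,
                      sprintf("disease_extra%02d",
                              seq_len(n_disease - length(disease_pool))))
  inv[[length(inv) + 1L]] <-
    row(disease_pool[seq_len(n_disease)], "ENV", "disease", "standalone")
  clinical_pool <- c(
    "fasting_glucose", "hba1c", "triglycerides", "total_cholesterol",
    "hdl_cholesterol", "ldl_cholesterol", "ggt", "ast", "alt",
    "fasting_insulin", "serum_ferritin", "crp_us", "creatinine",
    "uric_acid", "systolic_bp", "diastolic_bp")
  if (n_clinical > length(clinical_pool))
    clinical_pool <- c(clinical_pool,
                       sprintf("clinical_extra%02d",
                               seq_len(n_clinical - length(clinical_pool))))
  inv[[length(inv) + 1L]] <-
    row(clinical_pool[seq_len(n_clinical)], "CLI", "clinical", "standalone")
  out <- do.call(rbind, inv)
  rownames(out) <- NULL
  out
}

#' Default latent-risk drivers
#'
#' Standardized log-odds coefficients of the latent risk score that
#' determines all T2D labels in the generator. Fasting glucose is the
#' dominant clinical driver, so healthcare-scenario models outperform
#' environmental ones on default cohorts, mirroring the structure the
#' analysis is designed to detect.
#'
#' @return data frame with columns `feature` and `effect`.
#' @export
default_effect_spec <- function() {
  data.frame(
    feature = c("age", "bmi", "waist_cm", "relatives_t2d",
                "fasting_glucose", "hours_of_sleep"),
    effect = c(1.0, 0.8, 0.7, 0.6, 1.6, -0.5),
    stringsAsFactors = FALSE)
}

default_missingness_spec <- function(inventory) {
  ffq <- inventory$name[!is.na(inventory$period) |
                          (!is.na(inventory$group))]
  exercise <- intersect(
    c("physical_activity_workdays", "moderate_met_minutes_week",
      "vigorous_met_minutes_week", "walking_met_minutes_week"),
    inventory$name)
  blocks <- list(food_frequency = list(features = unique(ffq), rate = 0.08))
  if (length(exercise))
    blocks$exercise <- list(features = exercise, rate = 0.05)
  list(mcar_rate = 0.02,
       always_complete = intersect(c("age", "sex"), inventory$name),
       blocks = blocks)
}

#' Generate the synthetic municipality table
#'
#' Draws municipalities on an abstract bounded square with population,
#' income (a configurable fraction missing), a region label, and -- for
#' covered municipalities only -- a 10-year yearly series per pollution
#' metric. Regions are contiguous longitudinal bands, so residents of one
#' region are spatially coherent.
#'
#' @param config a [cohort_config()].
#' @return object of class `municipality_table`: list with elements `table`
#'   (data frame: municipality_id, canonical_name, x, y, population, income,
#'   covered, region_id) and `pollution` (named list of municipality-by-year
#'   matrices, NA rows for uncovered municipalities).
#' @export
generate_municipality_table <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  m <- config$n_municipalities
  if (m <= 0) stop_config("n_municipalities must be positive")
  with_seed(derive_seed(config$seed, "municipalities"), {
    x <- runif(m, 0, 100)
    y <- runif(m, 0, 100)
    population <- round(exp(rnorm(m, mean = 8.5, sd = 1.4))) + 50
    income <- rnorm(m, mean = 16000, sd = 3500)
    miss_income <- sample.int(m, size = round(config$income_missing_rate * m))
    income[miss_income] <- NA_real_
    covered <- rep(FALSE, m)
    covered[sample.int(m, config$n_covered_municipalities)] <- TRUE
    # contiguous longitudinal bands as regions: all non-empty by construction
    ord <- order(x)
    region <- integer(m)
    region[ord] <- as.integer(
      cut(seq_len(m), breaks = config$n_regions, labels = FALSE))
    metrics <- pollution_metric_names(config$n_pollution_metrics)
    ny <- config$n_pollution_years
    pollution <- lapply(seq_along(metrics), function(j) {
      mat <- matrix(NA_real_, nrow = m, ncol = ny)
      idx <- which(covered)
      base <- exp(rnorm(length(idx), mean = log(10 + 5 * j), sd = 0.4))
      for (i in seq_along(idx))
        mat[idx[i], ] <- pmax(0, base[i] * (1 + rnorm(ny, sd = 0.15)))
      mat
    })
    names(pollution) <- metrics
    tab <- data.frame(
      municipality_id = seq_len(m),
      canonical_name = sprintf("municipio %03d", seq_len(m)),
      x = x, y = y,
      population = population,
      income = income,
      covered = covered,
      region_id = region,
      stringsAsFactors = FALSE)
    structure(list(table = tab, pollution = pollution,
                   n_years = ny, metrics = metrics),
              class = "municipality_table")
  })
}

#' @export
print.municipality_table <- function(x, ...) {
  cat(sprintf("municipality_table: %d municipalities (%d covered), %d regions, %d pollution metrics x %d years\n",
              nrow(x$table), sum(x$table$covered),
              length(unique(x$table$region_id)),
              length(x$metrics), x$n_years))
  invisible(x)
}

# Draw the raw feature layer. All features are numeric; nominal features are
# integer-coded. Threshold flags are exact functions of their parents, so the
# redundancy the engineering stage removes is real.
draw_raw_features <- function(config, n) {
  inv <- config$feature_inventory
  vals <- matrix(NA_real_, nrow = n, ncol = nrow(inv),
                 dimnames = list(NULL, inv$name))
  lambda_for_period <- c(day = 0.4, week = 1.6, month = 4.5)
  for (i in seq_len(nrow(inv))) {
    nm <- inv$name[i]
    vals[, i] <- switch(
      nm,
      age = round(pmin(90, pmax(18, rnorm(n, 48.9, 16.7)))),
      sex = rbinom(n, 1, 0.52),
      height_cm = round(rnorm(n, 163.2, 9.4), 1),
      bmi = round(pmin(55, pmax(16, rnorm(n, 27.8, 5.1))), 1),
      hip_cm = round(pmin(150, pmax(75, rnorm(n, 104.4, 9.5))), 1),
      hours_of_sleep = round(pmin(12, pmax(3, rnorm(n, 7.3, 1.3))), 1),
      current_smoker = rbinom(n, 1, 0.26),
      fasting_glucose = round(pmax(55, rnorm(n, 94.0, 19.5)), 1),
      triglycerides = round(pmax(25, exp(rnorm(n, log(100), 0.5))), 1),
      hdl_cholesterol = round(pmax(20, rnorm(n, 52.8, 12.9)), 1),
      ggt = round(pmax(0.05, exp(rnorm(n, log(0.4), 0.6))), 2),
      ast = round(pmax(0.05, exp(rnorm(n, log(0.3), 0.4))), 2),
      moderate_met_minutes_week = round(pmax(0, exp(rnorm(n, 5.0, 1.6)) - 40)),
      vigorous_met_minutes_week = round(pmax(0, exp(rnorm(n, 4.0, 1.9)) - 30)),
      walking_met_minutes_week = round(pmax(0, exp(rnorm(n, 6.3, 1.4)) - 80)),
      relatives_t2d = rpois(n, 0.45),
      n_hypotensive_drugs = rpois(n, 0.3),
      NULL
    ) %||% {
      if (inv$role[i] == "threshold_flag") {
        rep(NA_real_, n) # filled after parents exist
      } else if (!is.na(inv$period[i]) || !is.na(inv$group[i])) {
        per <- inv$period[i]
        if (is.na(per)) per <- "month"
        rpois(n, lambda_for_period[[per]])
      } else if (inv$source[i] == "disease") {
        rbinom(n, 1, runif(1, 0.05, 0.3))
      } else if (inv$source[i] == "clinical") {
        round(pmax(0.01, exp(rnorm(n, runif(1, 1, 5), 0.4))), 1)
      } else {
        # generic standalone lifestyle item: small counts or scores
        if (runif(1) < 0.5) rpois(n, runif(1, 1, 6))
        else round(pmax(0, rnorm(n, runif(1, 2, 8), 2)), 1)
      }
    }
  }
  vals <- as.data.frame(vals)
  # consistent derived anthropometrics
  if (all(c("waist_cm", "hip_cm") %in% inv$name)) {
    whr <- pmin(1.25, pmax(0.6, rnorm(n, 0.9, 0.08)))
    vals$waist_cm <- round(whr * vals$hip_cm, 1)
  }
  if (all(c("weight_kg", "bmi", "height_cm") %in% inv$name))
    vals$weight_kg <- round(vals$bmi * (vals$height_cm / 100)^2, 1)
  for (i in which(inv$role == "threshold_flag")) {
    p <- vals[[inv$parent[i]]]
    vals[[inv$name[i]]] <- switch(inv$name[i],
      bmi_ge_30 = as.numeric(p >= 30),
      bmi_le_19 = as.numeric(p <= 19),
      waist_gt_102 = as.numeric(p > 102),
      waist_gt_88 = as.numeric(p > 88),
      as.numeric(p >= stats::median(p)))
  }
  # smoking: never-smokers have zero pack-year inputs
  if ("years_smoked" %in% inv$name) {
    ever <- rbinom(n, 1, 0.40)
    vals$years_smoked <- ifelse(ever == 1, round(runif(n, 1, 40)), 0)
    vals$cigarettes_per_day <- ifelse(ever == 1, rpois(n, 12) + 1, 0)
    if ("current_smoker" %in% inv$name)
      vals$current_smoker <- ifelse(ever == 1, rbinom(n, 1, 0.6), 0)
  }
  vals
}

# Rank a latent score with seed-stable jitter tie-breaking and return the
# indices of the top k.
top_k <- function(score, k, eligible = seq_along(score)) {
  if (k == 0L) return(integer(0))
  s <- score[eligible]
  eligible[order(s, decreasing = TRUE)][seq_len(k)]
}

#' Generate a synthetic cohort
#'
#' Emits the raw (pre-engineering) feature layer plus labels. A latent linear
#' risk score over the configured drivers (standardized, plus logistic noise)
#' determines every label; label counts are matched exactly to the configured
#' counts by thresholding the latent score at the appropriate empirical
#' quantile, with ties broken by a seed-stable jitter.
#'
#' @param config a [cohort_config()].
#' @param municipalities optional pre-built [generate_municipality_table()]
#'   output (rebuilt from `config` when omitted).
#' @return object of class `cohort_bundle`: list with `values` (data frame),
#'   `mask` (logical matrix, TRUE = observed), `metadata` (feature
#'   inventory), `municipality_id`, `labels` (data frame) and `config`.
#' @export
generate_cohort <- function(config, municipalities = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  muni <- municipalities %||% generate_municipality_table(config)
  n <- config$n_individuals
  with_seed(derive_seed(config$seed, "cohort"), {
    vals <- draw_raw_features(config, n)

    # municipality assignment: exact uncovered-resident count
    tab <- muni$table
    cov_ids <- tab$municipality_id[tab$covered]
    unc_ids <- tab$municipality_id[!tab$covered]
    n_unc <- min(config$n_uncovered_individuals, n)
    pick <- function(ids, k) {
      if (k == 0L) return(integer(0))
      if (length(ids) == 0L)
        stop_config("no municipalities available for assignment")
      w <- tab$population[match(ids, tab$municipality_id)]
      ids[sample.int(length(ids), size = k, replace = TRUE, prob = w)]
    }
    municipality_id <- integer(n)
    unc_slots <- if (n_unc > 0) sample.int(n, n_unc) else integer(0)
    municipality_id[unc_slots] <- pick(unc_ids, n_unc)
    cov_slots <- setdiff(seq_len(n), unc_slots)
    municipality_id[cov_slots] <- pick(cov_ids, length(cov_slots))

    # latent risk: standardized drivers on the log-odds scale
    eff <- config$effect_spec
    latent <- numeric(n)
    for (i in seq_len(nrow(eff))) {
      v <- vals[[eff$feature[i]]]
      s <- stats::sd(v)
      if (s > 0) latent <- latent + eff$effect[i] * (v - mean(v)) / s
    }
    latent <- latent + stats::rlogis(n)
    jitter <- stats::runif(n, 0, 1e-9) # seed-stable tie-break
    latent <- latent + jitter

    known <- logical(n)
    known_rank <- latent + stats::rlogis(n) # long-standing cases: noisier link
    known[top_k(known_rank, config$n_known_t2d)] <- TRUE

    at_risk <- which(!known)
    newdx <- logical(n)
    newdx[top_k(latent, config$n_new_diagnosis, at_risk)] <- TRUE

    in_followup <- logical(n)
    in_followup[at_risk[sample.int(length(at_risk), config$n_followup)]] <- TRUE
    fu_newdx <- which(in_followup & newdx)
    fu_clean <- which(in_followup & !newdx)
    n_incomplete <- length(fu_clean) - config$n_followup_eligible
    if (n_incomplete < 0)
      stop_config("configured counts leave too few follow-up individuals after baseline diagnoses; lower n_followup_eligible")
    followup_complete <- logical(n)
    followup_complete[in_followup] <- TRUE
    if (n_incomplete > 0)
      followup_complete[fu_clean[sample.int(length(fu_clean),
                                            n_incomplete)]] <- FALSE
    eligible <- which(in_followup & followup_complete & !newdx)
    incident <- logical(n)
    incident[top_k(latent, config$n_incident, eligible)] <- TRUE

    followup_years <- ifelse(
      in_followup,
      round(stats::rnorm(n, config$followup_years_mean,
                         config$followup_years_sd), 2),
      NA_real_)

    labels <- data.frame(
      known_t2d = known,
      baseline_new_diagnosis = newdx,
      in_followup = in_followup,
      followup_complete = in_followup & followup_complete,
      incident_t2d = incident,
      followup_years = followup_years)

    mask <- !is.na(as.matrix(vals))
    structure(list(values = vals, mask = mask,
                   metadata = config$feature_inventory,
                   municipality_id = municipality_id,
                   labels = labels, config = config,
                   municipalities = muni),
              class = "cohort_bundle")
  })
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf(
    "cohort_bundle: %d individuals x %d features (%d ENV, %d CLI)\n",
    nrow(x$values), ncol(x$values),
    sum(x$metadata$domain == "ENV"), sum(x$metadata$domain == "CLI")))
  cat(sprintf(
    "  labels: %d known T2D, %d baseline new diagnoses, %d in follow-up, %d incident\n",
    sum(x$labels$known_t2d), sum(x$labels$baseline_new_diagnosis),
    sum(x$labels$in_followup), sum(x$labels$incident_t2d)))
  cat(sprintf("  observed entries: %.1f%%\n", 100 * mean(x$mask)))
  invisible(x)
}

#' Inject structured missingness into a cohort
#'
#' Applies (a) feature-wise completely-at-random missingness, (b)
#' block-monotone missingness where an individual-level nonresponse
#' indicator wipes an entire feature block (e.g. the food-frequency
#' questionnaire), leaving the mask consistent with the values. Geospatial
#' missingness is not injected here: it is a deterministic function of
#' municipality pollution coverage and is realized (and immediately imputed)
#' during geospatial augmentation.
#'
#' @param cohort a [generate_cohort()] bundle.
#' @param config optional override of the bundle's configuration.
#' @return the bundle with `values` holding NA at masked positions.
#' @export
inject_missingness <- function(cohort, config = NULL) {
  stopifnot(inherits(cohort, "cohort_bundle"))
  config <- config %||% cohort$config
  spec <- config$missingness_spec
  bad <- unlist(lapply(spec$blocks,
                       function(b) setdiff(b$features, colnames(cohort$values))))
  if (length(bad))
    stop_config("missingness block references unknown features: %s",
                paste(unique(bad), collapse = ", "))
  n <- nrow(cohort$values)
  with_seed(derive_seed(config$seed, "missingness"), {
    mask <- cohort$mask
    mcar_cols <- setdiff(colnames(cohort$values), spec$always_complete)
    if (spec$mcar_rate > 0) {
      for (cl in mcar_cols) {
        drop <- stats::runif(n) < spec$mcar_rate
        mask[drop, cl] <- FALSE
      }
    }
    for (b in spec$blocks) {
      if (b$rate <= 0) next
      nonresp <- stats::runif(n) < b$rate
      mask[nonresp, b$features] <- FALSE
    }
    vals <- cohort$values
    for (cl in colnames(vals)) vals[[cl]][!mask[, cl]] <- NA_real_
    cohort$values <- vals
    cohort$mask <- mask
    cohort
  })
}

#' Fraction of individuals without direct pollution records
#'
#' Residents of municipalities absent from the pollution registry have no
#' directly assignable pollution values; this fraction is a deterministic
#' function of the municipality coverage flags.
#'
#' @param cohort a cohort bundle with municipality links.
#' @return fraction in `[0, 1]`.
#' @export
uncovered_fraction <- function(cohort) {
  tab <- cohort$municipalities$table
  cov <- tab$covered[match(cohort$municipality_id, tab$municipality_id)]
  mean(!cov)
}
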