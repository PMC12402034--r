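# Shared fixtures, generated in code at test time.

# Flat inventory of standalone features for planted-driver experiments.
flat_inventory <- function(env_names, cli_names = character(0)) {
  mk <- function(nm, domain, source) {
    if (length(nm) == 0L) return(NULL)
    data.frame(name = nm, domain = domain, source = source,
               role = "standalone", group = NA_character_,
               period = NA_character_, whole_grain = FALSE,
               parent = NA_character_, stringsAsFactors = FALSE)
  }
  out <- rbind(mk(env_names, "ENV", "lifestyle"),
               mk(cli_names, "CLI", "clinical"))
  rownames(out) <- NULL
  out
}

no_missingness_spec <- function() {
  list(mcar_rate = 0, always_complete = character(0), blocks = list())
}

# Cohort with three strong planted drivers and pure-noise companions;
# complete data, high enough prevalence for stable importance estimates.
driver_cohort_config <- function(seed, n_noise = 7L) {
  inv <- flat_inventory(c("age", "bmi", sprintf("noise_%02d", seq_len(n_noise))),
                        "fasting_glucose")
  cohort_config(
    n_individuals = 500L, n_known_t2d = 30L, n_new_diagnosis = 80L,
    n_followup = 150L, n_followup_eligible = 100L, n_incident = 10L,
    n_municipalities = 20L, n_covered_municipalities = 8L,
    n_uncovered_individuals = 250L, n_regions = 16L,
    feature_inventory = inv,
    effect_spec = data.frame(feature = c("age", "bmi", "fasting_glucose"),
                             effect = c(1.5, 1.2, 1.0)),
    missingness_spec = no_missingness_spec(),
    seed = seed)
}

# No-signal cohort at the study's own scale: labels independent of every
# feature. Cohort size matters here: the split-repetition CI is conditional
# on the realized dataset, so at small n realization-level spurious
# correlations dominate the gate.
null_cohort_config <- function(seed, n_features = 6L) {
  inv <- flat_inventory(c("age", sprintf("noise_%02d", seq_len(n_features - 1L))))
  cohort_config(
    n_individuals = 4617L, n_known_t2d = 417L, n_new_diagnosis = 227L,
    n_followup = 1850L, n_followup_eligible = 1608L, n_incident = 125L,
    n_municipalities = 100L, n_covered_municipalities = 40L,
    n_uncovered_individuals = 2327L, n_regions = 30L,
    feature_inventory = inv,
    effect_spec = data.frame(feature = "age", effect = 0),
    missingness_spec = no_missingness_spec(),
    seed = seed)
}

diagnosis_xy <- function(config) {
  cohort <- generate_cohort(config)
  build_task_sample(cohort, task_spec("diagnosis", "HEA"))
}

# brute-force pairwise AUROC oracle (ties count one half)
auroc_oracle <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}

# pairwise-difference Gini oracle
gini_oracle <- function(v) {
  n <- length(v); m <- mean(v)
  if (m == 0) return(0)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) s <- s + abs(v[i] - v[j])
  s / (2 * n^2 * m)
}

# tiny fitted-model stand-ins for partial-dependence contracts
constant_model <- function(value) {
  structure(list(value = value), class = "constant_model")
}
identity_model <- function(feature) {
  structure(list(feature = feature), class = "identity_model")
}
additive_model <- function(f1, f2) {
  structure(list(f1 = f1, f2 = f2), class = "additive_model")
}
registerS3method("predict", "constant_model",
                 function(object, newdata, ...) rep(object$value, nrow(newdata)))
registerS3method("predict", "identity_model",
                 function(object, newdata, ...) newdata[[object$feature]])
registerS3method("predict", "additive_model",
                 function(object, newdata, ...)
                   newdata[[object$f1]] + 2 * newdata[[object$f2]])
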