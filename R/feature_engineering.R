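#' Convert a reported frequency to the canonical period
#'
#' Questionnaire intake items are reported as daily, weekly or monthly
#' counts; all are standardized to a single canonical period before
#' aggregation. The default canonical period is the month with a 30-day
#' month and 7-day week convention, so e.g. 2/day becomes 60/month and
#' 7/week becomes 30/month.
#'
#' @param value nonnegative count (NA passes through).
#' @param declared_period one of `"day"`, `"week"`, `"month"`.
#' @param canonical target period, default `"month"`.
#' @param days_per_month,days_per_week conversion constants.
#' @return count per canonical period.
#' @export
normalize_frequency <- function(value, declared_period, canonical = "month",
                                days_per_month = 30, days_per_week = 7) {
  days <- c(day = 1, week = days_per_week, month = days_per_month)
  if (!declared_period %in% names(days))
    stop_config("unknown declared period '%s'", declared_period)
  if (!canonical %in% names(days))
    stop_config("unknown canonical period '%s'", canonical)
  if (any(value < 0, na.rm = TRUE)) stop_config("frequencies must be >= 0")
  value * days[[canonical]] / days[[declared_period]]
}

#' Smoking pack-years
#'
#' Cumulative smoking exposure: years smoked times packs (of `pack_size`
#' cigarettes) per day. Missing inputs propagate to a missing result.
#'
#' @param years_smoked years the individual smoked.
#' @param cigarettes_per_day average daily cigarette count.
#' @param pack_size cigarettes per pack (standard 20).
#' @return pack-years.
#' @export
smoking_pack_years <- function(years_smoked, cigarettes_per_day,
                               pack_size = 20) {
  if (any(years_smoked < 0, na.rm = TRUE) ||
      any(cigarettes_per_day < 0, na.rm = TRUE))
    stop_config("smoking inputs must be >= 0")
  years_smoked * (cigarettes_per_day / pack_size)
}

#' Waist-to-hip ratio
#'
#' @param waist,hip circumferences in cm; `hip` must be positive.
#' @return dimensionless ratio; missing inputs propagate.
#' @export
waist_hip_ratio <- function(waist, hip) {
  if (any(hip <= 0, na.rm = TRUE)) stop_config("hip circumference must be > 0")
  waist / hip
}

#' Grouping map derived from feature metadata
#'
#' Builds the semantic grouping map the engineering stage applies: one
#' sum-group per questionnaire group in the metadata, plus a whole-grain
#' fraction over the carbohydrate sources when whole-grain flags are
#' present.
#'
#' @param metadata feature metadata data frame (inventory columns).
#' @return list of group descriptors
#'   (`name`, `mode` = "sum"/"fraction", `sources`, `subset`).
#' @export
default_grouping_map <- function(metadata) {
  groups <- unique(stats::na.omit(metadata$group))
  map <- lapply(groups, function(g) {
    src <- metadata$name[!is.na(metadata$group) & metadata$group == g]
    list(name = g, mode = "sum", sources = src, subset = NULL)
  })
  carb <- metadata$name[!is.na(metadata$group) &
                          metadata$group == "carbohydrate_rich_intake"]
  wg <- metadata$name[metadata$whole_grain %in% TRUE]
  if (length(carb) && length(wg))
    map[[length(map) + 1L]] <- list(name = "pct_whole_grain",
                                    mode = "fraction", sources = carb,
                                    subset = intersect(wg, carb))
  map
}

# monthly-normalized source matrix for one group
normalized_sources <- function(cohort, sources, canonical = "month") {
  meta <- cohort$metadata
  out <- sapply(sources, function(s) {
    per <- meta$period[meta$name == s]
    per <- if (length(per) == 0L || is.na(per[1L])) canonical else per[1L]
    normalize_frequency(cohort$values[[s]], per, canonical)
  })
  matrix(out, nrow = nrow(cohort$values),
         dimnames = list(NULL, sources))
}

#' Aggregate questionnaire groups into representative features
#'
#' Sum-groups create one feature as the sum of their period-normalized
#' sources; fraction groups create a ratio in `[0, 1]` (subset sum over
#' total sum). A group value is missing iff all of its sources are missing;
#' otherwise missing sources contribute 0, so questionnaire block
#' missingness propagates to groups without silently shrinking sums. Source
#' features are removed after aggregation.
#'
#' @param cohort a cohort bundle.
#' @param map grouping map as returned by [default_grouping_map()].
#' @return the bundle with group features added and sources removed.
#' @export
aggregate_groups <- function(cohort, map = default_grouping_map(cohort$metadata)) {
  for (g in map) {
    if (length(g$sources) == 0L) stop_config("empty group '%s'", g$name)
    missing_src <- setdiff(g$sources, colnames(cohort$values))
    if (length(missing_src))
      stop_config("group '%s' references absent features: %s", g$name,
                  paste(missing_src, collapse = ", "))
  }
  vals <- cohort$values
  new_cols <- list()
  drop <- character(0)
  for (g in map) {
    src <- normalized_sources(cohort, g$sources)
    all_missing <- rowSums(!is.na(src)) == 0L
    if (g$mode == "sum") {
      v <- rowSums(src, na.rm = TRUE)
      v[all_missing] <- NA_real_
    } else if (g$mode == "fraction") {
      num <- rowSums(src[, g$subset, drop = FALSE], na.rm = TRUE)
      den <- rowSums(src, na.rm = TRUE)
      v <- ifelse(den > 0, num / den, NA_real_)
      v[all_missing] <- NA_real_
    } else stop_config("unknown group mode '%s'", g$mode)
    new_cols[[g$name]] <- v
    if (g$mode == "sum") drop <- c(drop, g$sources)
  }
  # fraction-group sources are dropped by their sum-group; drop any leftover
  drop <- unique(c(drop, unlist(lapply(map, function(g)
    if (g$mode == "fraction") g$sources else character(0)))))
  if (length(new_cols) == 0L) return(cohort)
  keep <- setdiff(colnames(vals), drop)
  vals <- vals[, keep, drop = FALSE]
  for (nm in names(new_cols)) vals[[nm]] <- new_cols[[nm]]
  cohort$values <- vals
  cohort$mask <- !is.na(as.matrix(vals))
  meta <- cohort$metadata[cohort$metadata$name %in% keep, , drop = FALSE]
  meta <- rbind(meta, data.frame(
    name = names(new_cols), domain = "ENV", source = "lifestyle",
    role = "engineered", group = NA_character_, period = "month",
    whole_grain = FALSE, parent = NA_character_, stringsAsFactors = FALSE))
  rownames(meta) <- NULL
  cohort$metadata <- meta
  cohort
}

#' Remove threshold-derived features
#'
#' Drops every feature tagged as derived by thresholding another feature
#' (obesity-style flags), retaining the raw parent measurements, which carry
#' strictly more information.
#'
#' @param cohort a cohort bundle.
#' @return the bundle without threshold-flag columns.
#' @export
drop_derived_thresholds <- function(cohort) {
  flags <- cohort$metadata$name[cohort$metadata$role == "threshold_flag"]
  if (length(flags) == 0L) return(cohort)
  keep <- setdiff(colnames(cohort$values), flags)
  cohort$values <- cohort$values[, keep, drop = FALSE]
  cohort$mask <- cohort$mask[, keep, drop = FALSE]
  cohort$metadata <- cohort$metadata[cohort$metadata$name %in% keep, ,
                                     drop = FALSE]
  rownames(cohort$metadata) <- NULL
  cohort
}

#' Run the full feature-engineering stage
#'
#' Applies, in order: smoking pack-years derivation (dropping the raw
#' year/cigarette inputs, retaining `current_smoker`), waist-to-hip ratio,
#' questionnaire group aggregation (sources removed) and removal of
#' threshold-derived flags. Row count is never altered; the stage is
#' idempotent, so re-running it on an engineered bundle is a no-op.
#'
#' @param cohort a cohort bundle.
#' @param map optional grouping-map override.
#' @param pack_size cigarettes per pack for pack-years.
#' @return the engineered bundle.
#' @export
engineer_features <- function(cohort, map = NULL, pack_size = 20) {
  stopifnot(inherits(cohort, "cohort_bundle"))
  meta <- cohort$metadata
  vals <- cohort$values

  if (all(c("years_smoked", "cigarettes_per_day") %in% colnames(vals))) {
    vals$smoking_pack_years <- smoking_pack_years(
      vals$years_smoked, vals$cigarettes_per_day, pack_size)
    keep <- setdiff(colnames(vals), c("years_smoked", "cigarettes_per_day"))
    vals <- vals[, keep, drop = FALSE]
    meta <- meta[meta$name %in% keep, , drop = FALSE]
    meta <- rbind(meta, data.frame(
      name = "smoking_pack_years", domain = "ENV", source = "lifestyle",
      role = "engineered", group = NA_character_, period = NA_character_,
      whole_grain = FALSE, parent = NA_character_, stringsAsFactors = FALSE))
  }
  if (all(c("waist_cm", "hip_cm") %in% colnames(vals)) &&
      !"waist_hip_ratio" %in% colnames(vals)) {
    vals$waist_hip_ratio <- waist_hip_ratio(vals$waist_cm, vals$hip_cm)
    meta <- rbind(meta, data.frame(
      name = "waist_hip_ratio", domain = "ENV", source = "anthropometric",
      role = "engineered", group = NA_character_, period = NA_character_,
      whole_grain = FALSE, parent = NA_character_, stringsAsFactors = FALSE))
  }
  cohort$values <- vals
  cohort$mask <- !is.na(as.matrix(vals))
  rownames(meta) <- NULL
  cohort$metadata <- meta

  cohort <- aggregate_groups(cohort, map %||% default_grouping_map(cohort$metadata))
  cohort <- drop_derived_thresholds(cohort)
  cohort
}

#' Per-domain feature counts
#'
#' @param cohort a cohort bundle.
#' @return named integer vector with `ENV`, `CLI` and `HEA` (= ENV + CLI)
#'   feature counts.
#' @export
scenario_feature_counts <- function(cohort) {
  env <- sum(cohort$metadata$domain == "ENV")
  cli <- sum(cohort$metadata$domain == "CLI")
  c(ENV = env, CLI = cli, HEA = env + cli)
}
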