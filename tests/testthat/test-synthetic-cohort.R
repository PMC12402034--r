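test_that("configuration validation rejects inconsistent counts", {
  expect_error(cohort_config(n_individuals = 100, n_known_t2d = 80,
                             n_new_diagnosis = 30),
               "exceeds n_individuals")
  expect_error(cohort_config(n_covered_municipalities = 500),
               "exceeds n_municipalities")
  expect_error(cohort_config(n_followup_eligible = 99999),
               "n_followup_eligible exceeds")
  expect_error(
    cohort_config(effect_spec = data.frame(feature = "not_a_feature",
                                           effect = 1)),
    "absent features")
  inv <- default_feature_inventory()
  expect_error(
    cohort_config(missingness_spec = list(
      mcar_rate = 0, always_complete = character(0),
      blocks = list(b = list(features = "ghost", rate = 0.5)))),
    "unknown features")
})

test_that("municipality table matches configured coverage and is deterministic", {
  cfg <- small_cohort_config(seed = 11)
  tab <- generate_municipality_table(cfg)
  expect_equal(nrow(tab$table), cfg$n_municipalities)
  expect_equal(sum(tab$table$covered), cfg$n_covered_municipalities)
  expect_equal(length(unique(tab$table$region_id)), cfg$n_regions)
  # covered rows carry complete series; uncovered rows none
  for (m in tab$metrics) {
    expect_false(anyNA(tab$pollution[[m]][tab$table$covered, ]))
    expect_true(all(is.na(tab$pollution[[m]][!tab$table$covered, ])))
  }
  expect_identical(tab, generate_municipality_table(cfg))
  # boundary: full coverage
  cfg2 <- small_cohort_config(seed = 11)
  cfg2$n_covered_municipalities <- cfg2$n_municipalities
  cfg2$n_uncovered_individuals <- 0L
  expect_true(all(generate_municipality_table(cfg2)$table$covered))
})

test_that("cohort generation is deterministic and label counts are exact", {
  cfg <- small_cohort_config(seed = 5)
  co <- generate_cohort(cfg)
  expect_identical(co$values, generate_cohort(cfg)$values)
  expect_identical(co$labels, generate_cohort(cfg)$labels)
  lb <- co$labels
  expect_equal(sum(lb$known_t2d), cfg$n_known_t2d)
  expect_equal(sum(lb$baseline_new_diagnosis), cfg$n_new_diagnosis)
  expect_equal(sum(lb$in_followup), cfg$n_followup)
  expect_equal(sum(lb$in_followup & lb$followup_complete &
                     !lb$baseline_new_diagnosis), cfg$n_followup_eligible)
  expect_equal(sum(lb$incident_t2d), cfg$n_incident)
  # label consistency: incident implies eligible
  expect_true(all(!lb$incident_t2d |
                    (lb$in_followup & lb$followup_complete &
                       !lb$baseline_new_diagnosis & !lb$known_t2d)))
  # every individual has a resolvable municipality
  expect_true(all(co$municipality_id %in%
                    co$municipalities$table$municipality_id))
  # follow-up duration stored for follow-up members only
  expect_true(all(is.na(lb$followup_years[!lb$in_followup])))
  expect_true(all(!is.na(lb$followup_years[lb$in_followup])))
})

test_that("a dominant driver has the highest discriminative univariate AUROC", {
  cfg <- driver_cohort_config(seed = 21)
  cfg$effect_spec <- data.frame(feature = "fasting_glucose", effect = 3)
  sample <- diagnosis_xy(cfg)
  scan <- vapply(sample$X, function(v) abs(auroc(v, sample$y) - 0.5),
                 numeric(1))
  expect_equal(names(which.max(scan)), "fasting_glucose")
})

test_that("planted drivers rank in the top decile of univariate AUROC", {
  hits <- vapply(1:10, function(s) {
    cfg <- cohort_config(seed = 100 + s)
    sample <- diagnosis_xy(cfg)
    scan <- vapply(sample$X, function(v) abs(auroc(v, sample$y) - 0.5),
                   numeric(1))
    drivers <- intersect(cfg$effect_spec$feature, names(scan))
    cutoff <- ceiling(length(scan) / 10)
    all(rank(-scan)[drivers] <= max(cutoff, length(drivers)))
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("missingness injection follows the configured structure", {
  cfg <- small_cohort_config(seed = 9)
  co <- generate_cohort(cfg)

  # all rates zero leave the mask unchanged
  cfg0 <- cfg
  cfg0$missingness_spec <- no_missingness_spec()
  expect_identical(inject_missingness(co, cfg0)$mask, co$mask)

  # block rate 1 wipes every block feature with one shared pattern
  cfg1 <- cfg
  cfg1$missingness_spec$mcar_rate <- 0
  cfg1$missingness_spec$blocks <- list(
    ffq = list(features = cfg1$missingness_spec$blocks$food_frequency$features,
               rate = 1.0))
  m1 <- inject_missingness(co, cfg1)$mask
  blk <- cfg1$missingness_spec$blocks$ffq$features
  expect_true(all(!m1[, blk]))
  other <- setdiff(colnames(m1), blk)
  expect_identical(m1[, other], co$mask[, other])

  # default injection: values NA exactly where mask is FALSE
  mi <- inject_missingness(co)
  expect_identical(unname(is.na(as.matrix(mi$values))), unname(!mi$mask))
  expect_false(anyNA(mi$values[, cfg$missingness_spec$always_complete]))

  # unknown block feature is rejected
  cfgbad <- cfg
  cfgbad$missingness_spec$blocks <- list(
    b = list(features = "ghost", rate = 0.1))
  expect_error(inject_missingness(co, cfgbad), "unknown features")
})

test_that("pollution non-coverage fraction is fixed by municipality assignment", {
  cfg <- cohort_config(seed = 4)
  co <- generate_cohort(cfg)
  expect_equal(round(100 * uncovered_fraction(co), 1), 50.4)
  # deterministic function of coverage: recomputation agrees
  tab <- co$municipalities$table
  cov <- tab$covered[match(co$municipality_id, tab$municipality_id)]
  expect_equal(uncovered_fraction(co), mean(!cov))
})

test_that("cohort round-trips to plain-text files", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(small_cohort_config(seed = 2))
  write_cohort(co, dir)
  back <- utils::read.csv(file.path(dir, "cohort.csv"))
  expect_equal(nrow(back), nrow(co$values))
  expect_true(all(colnames(co$values) %in% colnames(back)))
  meta <- jsonlite::read_json(file.path(dir, "cohort_metadata.json"))
  expect_equal(meta$n_individuals, nrow(co$values))
  muni <- utils::read.csv(file.path(dir, "municipalities.csv"))
  expect_equal(nrow(muni), nrow(co$municipalities$table))
})
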