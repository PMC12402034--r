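test_that("weighted moving average matches hand-evaluated cases", {
  expect_equal(weighted_moving_average(rep(3.7, 10)), 3.7)
  expect_equal(weighted_moving_average(1:10), 385 / 55) # sum i^2 / w = 7
  expect_equal(weighted_moving_average(c(rep(0, 9), 1)), 10 / 55)
  expect_equal(weighted_moving_average(5), 5) # n = 1 boundary
  expect_error(weighted_moving_average(numeric(0)), "non-empty")
  expect_error(weighted_moving_average(c(1, NA, 3)), "missing")
  # output bounded by the series range
  for (s in 1:20) {
    v <- with_seed(s, stats::runif(10, -5, 5))
    w <- weighted_moving_average(v)
    expect_gte(w, min(v)); expect_lte(w, max(v))
  }
})

test_that("IDW imputation reproduces worked examples and conventions", {
  expect_equal(
    idw_impute(c(0, 0), rbind(c(1, 0), c(2, 0)), c(0, 3),
               idw_config(beta = 2, k = 2)),
    0.6) # (0*1 + 3*0.25) / 1.25
  # k = 1 degenerates to nearest neighbor
  expect_equal(idw_impute(c(0, 0), rbind(c(1, 0), c(5, 0)), c(10, 99),
                          idw_config(k = 1)), 10)
  # convex combination: equal values pass through
  expect_equal(idw_impute(c(0, 0), rbind(c(1, 1), c(3, 7), c(-2, 4)),
                          rep(4.2, 3), idw_config()), 4.2)
  # zero-distance convention
  expect_equal(idw_impute(c(3, 7), rbind(c(1, 1), c(3, 7)), c(1, 2),
                          idw_config()), 2)
  expect_error(idw_impute(c(0, 0), matrix(numeric(0), ncol = 2), numeric(0)),
               "no neighbors")
  expect_error(idw_config(beta = -1), "beta")
  expect_error(idw_config(k = 0), "k must")
})

test_that("IDW output is bounded, scale-invariant and tends to nearest neighbor", {
  for (s in 1:10) {
    coords <- with_seed(s, matrix(stats::runif(24, 0, 10), ncol = 2))
    vals <- with_seed(s + 100, stats::runif(12, -3, 8))
    q <- c(5, 5)
    est <- idw_impute(q, coords, vals, idw_config(beta = 2, k = 5))
    d <- sqrt(rowSums(sweep(coords, 2, q)^2))
    used <- vals[order(d)[1:5]]
    expect_gte(est, min(used)); expect_lte(est, max(used))
    # uniform rescaling of all coordinates about the query leaves it unchanged
    est2 <- idw_impute(q, sweep(sweep(coords, 2, q), 1, 3, "*") +
                         rep(q, each = 12), vals, idw_config(beta = 2, k = 5))
    expect_equal(est, est2)
  }
  # beta -> infinity converges to the nearest neighbor on a fixed fixture
  # with well-separated distances (1, 1.5, 2, 3)
  coords <- rbind(c(1, 0), c(0, 1.5), c(-2, 0), c(0, -3))
  vals <- c(8.25, -1, 4, 6)
  expect_equal(idw_impute(c(0, 0), coords, vals, idw_config(beta = 50, k = 4)),
               8.25, tolerance = 1e-6)
})

test_that("geospatial augmentation adds 14 complete features without touching the rest", {
  cfg <- small_cohort_config(seed = 3)
  co <- inject_missingness(generate_cohort(cfg))
  before <- co$values
  aug <- augment_cohort_geospatial(co)
  geo_cols <- setdiff(colnames(aug$values), colnames(before))
  expect_length(geo_cols, 14L)
  expect_false(anyNA(aug$values[, geo_cols]))
  expect_identical(aug$values[, colnames(before)], before)
  expect_true(all(aug$metadata$domain[aug$metadata$name %in% geo_cols] == "ENV"))
  expect_true(all(aug$metadata$source[aug$metadata$name %in% geo_cols] ==
                    "geospatial"))

  # covered municipalities receive their own temporal aggregates
  tab <- co$municipalities$table
  cov_muni <- intersect(tab$municipality_id[tab$covered],
                        co$municipality_id)[1]
  resident <- which(co$municipality_id == cov_muni)[1]
  m1 <- co$municipalities$metrics[1]
  own <- weighted_moving_average(
    co$municipalities$pollution[[m1]][cov_muni, ])
  expect_equal(aug$values[resident, paste0("pollution_", m1)], own)

  # population is always assigned directly
  expect_equal(aug$values$population,
               tab$population[match(co$municipality_id, tab$municipality_id)])
})

test_that("an uncovered municipality equidistant from two covered ones averages them", {
  co <- generate_cohort(small_cohort_config(seed = 6))
  muni <- co$municipalities
  muni$table <- muni$table[1:3, ]
  muni$table$covered <- c(TRUE, TRUE, FALSE)
  muni$table$x <- c(0, 2, 1); muni$table$y <- c(0, 0, 0)
  muni$table$income <- c(10, 20, 30)
  for (m in muni$metrics) {
    muni$pollution[[m]] <- muni$pollution[[m]][1:3, , drop = FALSE]
    muni$pollution[[m]][1, ] <- 2; muni$pollution[[m]][2, ] <- 4
    muni$pollution[[m]][3, ] <- NA
  }
  co$municipality_id <- rep(3L, nrow(co$values))
  aug <- augment_cohort_geospatial(co, muni)
  expect_true(all(aug$values$pollution_no2 == 3)) # equal weights -> mean(2, 4)
})

test_that("region groups map residents through municipalities", {
  cfg <- small_cohort_config(seed = 8)
  co <- generate_cohort(cfg)
  g <- region_groups(co)
  expect_length(g, nrow(co$values))
  expect_equal(sort(unique(g)), seq_len(cfg$n_regions))
  # residents of one municipality share a region
  tab <- co$municipalities$table
  expect_equal(g, tab$region_id[match(co$municipality_id,
                                      tab$municipality_id)])
  # each municipality its own region: labels become municipality ids
  muni2 <- co$municipalities
  muni2$table$region_id <- muni2$table$municipality_id
  expect_equal(region_groups(co, muni2), co$municipality_id)
})

test_that("municipality names standardize to joinable keys", {
  expect_equal(standardize_municipality_name("  Málaga "), "malaga")
  expect_equal(standardize_municipality_name("MADRID"), "madrid")
  expect_equal(standardize_municipality_name("castellón   de la plana"),
               "castellon de la plana")
  once <- standardize_municipality_name("Alcalá de Henares")
  expect_equal(standardize_municipality_name(once), once) # idempotent
})
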