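test_that("feature typing follows the minimum-frequency rule", {
  expect_equal(classify_feature_type(rep(c(0, 1), each = 100)), "nominal")
  expect_equal(classify_feature_type(c(rep(1, 50), rep(2, 3))),
               "quantitative") # a level below 5 appearances
  expect_equal(classify_feature_type(stats::runif(200)), "quantitative")
  expect_equal(classify_feature_type(rep(1:20, each = 10)),
               "quantitative") # too many levels
  expect_error(classify_feature_type(numeric(0)), "at least one")
})

test_that("quality score matches its formula and bounds", {
  expect_equal(quality_score(1, 0), 1)
  expect_equal(quality_score(0, 1), 1)
  expect_equal(quality_score(0.6, 0.5), 0.8)
  expect_error(quality_score(1.2, 0), "gamma")
  expect_error(quality_score(0.5, -0.1), "mu")
  # monotone nondecreasing in both arguments, bounded by [gamma, 1]
  g <- seq(0, 1, by = 0.1)
  for (mu in c(0, 0.3, 0.9)) {
    qs <- quality_score(g, rep(mu, length(g)))
    expect_true(all(diff(qs) >= 0))
    expect_true(all(qs >= g - 1e-12 & qs <= 1 + 1e-12))
  }
  m <- seq(0, 1, by = 0.1)
  expect_true(all(diff(quality_score(rep(0.4, length(m)), m)) >= 0))
})

make_imputation_data <- function(n = 300, seed = 1) {
  with_seed(seed, {
    z <- stats::rnorm(n)
    data.frame(
      anchor = z,
      copy = z, # exact copy of a predictor
      noise = stats::rnorm(n),
      cat = rbinom(n, 1, 0.5))
  })
}

test_that("imputer assessment short-circuits complete features and scores copies high", {
  df <- make_imputation_data()
  a <- assess_imputer(df$anchor, df[c("noise", "cat")], "mean", seed = 1)
  expect_equal(a$imputer, "none")
  expect_equal(a$qs, 1)
  expect_equal(a$gamma, 1)

  # feature equal to a predictor: multivariate imputers recover it near-perfectly
  x <- df$copy
  x[with_seed(2, sample(nrow(df), 60))] <- NA
  a_rf <- assess_imputer(x, df[c("anchor", "noise")], "iterative_rf", seed = 3)
  expect_gte(a_rf$mu, 0.9)
  expect_gte(a_rf$qs, 0.9)
  a_knn <- assess_imputer(x, df[c("anchor", "noise")], "knn_k5", seed = 3)
  expect_gte(a_knn$mu, 0.9)

  # pure noise with a mean imputer: mu clipped near zero, QS ~ gamma
  y <- df$noise
  y[with_seed(4, sample(nrow(df), 60))] <- NA
  a_mean <- assess_imputer(y, df[c("anchor", "cat")], "mean", seed = 5)
  expect_lte(a_mean$mu, 0.15)
  expect_equal(a_mean$qs, quality_score(a_mean$gamma, a_mean$mu))

  expect_error(assess_imputer(c(1, 2, NA, rep(NA, 40)), df[1:43, 1:2], "mean"),
               "at least")
})

test_that("the distribution-preserving imputer converges to the observed distribution", {
  x <- with_seed(10, stats::rexp(4000))
  ks <- vapply(c(200, 2000), function(n) {
    obs <- x[seq_len(n)]
    imp <- with_seed(11, sample(obs, 5000, replace = TRUE))
    suppressWarnings(stats::ks.test(imp, x)$statistic)
  }, numeric(1))
  expect_lt(ks[2], ks[1]) # KS statistic shrinks with sample size
  expect_lt(ks[2], 0.05)
})

test_that("imputer selection retains complete and imputable features, drops hopeless ones", {
  n <- 400
  df <- with_seed(20, {
    z <- stats::rnorm(n)
    data.frame(anchor = z,
               derived = z + stats::rnorm(n, sd = 0.1),
               hopeless = stats::rnorm(n))
  })
  df$derived[with_seed(21, sample(n, 100))] <- NA    # gamma 0.75, imputable
  df$hopeless[with_seed(22, sample(n, 240))] <- NA   # gamma 0.4, pure noise
  plan <- select_imputers(df, seed = 7)
  expect_s3_class(plan, "imputation_plan")
  p <- function(f, col) plan[plan$feature == f, col]
  expect_equal(p("anchor", "imputer"), "none")
  expect_true(p("anchor", "retained"))
  expect_true(p("derived", "retained")) # QS = 0.75 + 0.25 * high mu
  expect_gte(p("derived", "qs"), 0.9)
  expect_false(p("hopeless", "retained")) # QS ~ 0.4 + 0.6 * ~0 < 0.7
  expect_equal(plan$qs, quality_score(plan$gamma,
                                      ifelse(is.na(plan$mu), 0, plan$mu)),
               tolerance = 1e-12)
})

test_that("imputation application is leakage-safe and completes retained columns", {
  n <- 300
  mk <- function(seed) with_seed(seed, {
    z <- stats::rnorm(n)
    d <- data.frame(anchor = z, friend = z + stats::rnorm(n, sd = 0.2),
                    plain = stats::rnorm(n))
    d$friend[sample(n, 60)] <- NA
    d$plain[sample(n, 60)] <- NA
    d
  })
  train <- mk(30); test <- mk(31)
  plan <- select_imputers(train, seed = 8)
  out <- apply_imputation(plan, train, test, seed = 8)
  keep <- plan$feature[plan$retained]
  expect_setequal(colnames(out$train), keep)
  expect_false(anyNA(out$train))
  expect_false(anyNA(out$test[, keep]))

  # no missing values anywhere: tables unchanged
  full <- data.frame(a = stats::rnorm(50), b = stats::rnorm(50))
  plan_full <- select_imputers(full, seed = 9)
  out_full <- apply_imputation(plan_full, full, full, seed = 9)
  expect_identical(out_full$train, full)

  # median imputer: test-set holes receive the TRAIN median
  tr <- data.frame(x = c(stats::rnorm(100), rep(NA, 40)),
                   y = stats::rnorm(140))
  te <- data.frame(x = c(stats::rnorm(30), rep(NA, 10)),
                   y = stats::rnorm(40))
  plan2 <- select_imputers(tr, seed = 10)
  plan2$imputer[plan2$feature == "x"] <- "median"
  filled <- apply_imputation(plan2, tr, te, seed = 10)
  expect_true(all(filled$test$x[31:40] == stats::median(tr$x, na.rm = TRUE)))

  # perturbing the test set never changes the imputed training values
  te_perturbed <- te
  te_perturbed$x <- te_perturbed$x + 100
  te_perturbed$y <- te_perturbed$y * -3
  a <- apply_imputation(plan2, tr, te, seed = 10)
  b <- apply_imputation(plan2, tr, te_perturbed, seed = 10)
  expect_identical(a$train, b$train)
})

test_that("one-hot encoding emits exactly one indicator per observed nominal value", {
  df <- data.frame(nom = rep(c(1, 2, 7), each = 20),
                   other = stats::rnorm(60))
  enc <- t2drisk:::build_predictor_encoder(df, list(nom = "nominal",
                                                    other = "quantitative"))
  M <- t2drisk:::encode_predictors(df, enc)
  ind <- M[, grep("^nom=", colnames(M)), drop = FALSE]
  expect_equal(ncol(ind), 3L)
  expect_true(all(rowSums(ind) == 1))
})
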