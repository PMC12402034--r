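test_that("auroc equals the brute-force pairwise oracle on exhaustive small inputs", {
  expect_equal(auroc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auroc(rep(0.5, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_equal(auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(auroc(1:4, c(1, 1, 1, 1)), "both classes")
  for (s in 1:50) {
    n <- with_seed(s, sample(2:12, 1))
    labels <- with_seed(s + 100, c(0, 1, rbinom(n - 2, 1, 0.5)))
    scores <- with_seed(s + 200, sample(seq(0, 1, by = 0.25), n,
                                        replace = TRUE)) # ties likely
    expect_equal(auroc(scores, labels), auroc_oracle(scores, labels))
  }
})

test_that("gradient-boosted fits are deterministic and predictive on separable data", {
  n <- 200
  X <- with_seed(1, data.frame(a = stats::rnorm(n), b = stats::rnorm(n)))
  y <- as.integer(X$a > 0)
  f1 <- fit_gbt(X, y, seed = 5)
  f2 <- fit_gbt(X, y, seed = 5)
  expect_identical(predict(f1, X), predict(f2, X))
  expect_gt(auroc(predict(f1, X), y), 0.99)
})

test_that("grouped folds partition individuals and keep regions whole", {
  groups <- rep(1:12, times = sample(5:15, 12, replace = TRUE))
  folds <- grouped_folds(groups, 4, seed = 3)
  expect_length(folds, length(groups))
  expect_setequal(unique(folds), 1:4)
  for (g in unique(groups))
    expect_length(unique(folds[groups == g]), 1L)
  expect_error(grouped_folds(rep(1, 10), 2), "distinct groups")
})

test_that("tuning honours the space, is seed-deterministic and never beats itself", {
  n <- 240
  X <- with_seed(7, data.frame(a = stats::rnorm(n), b = stats::rnorm(n)))
  y <- as.integer(X$a + with_seed(8, stats::rnorm(n, sd = 0.7)) > 0)
  groups <- rep(1:12, each = 20)
  point <- list(max_depth = list(type = "int", lower = 3, upper = 3),
                eta = list(type = "float", lower = 0.2, upper = 0.2),
                nrounds = list(type = "int", lower = 30, upper = 30))
  tp <- tune_hyperparameters(X, y, groups, point, n_folds = 3, n_trials = 3,
                             seed = 1)
  expect_equal(tp$params$max_depth, 3L)
  expect_equal(tp$params$eta, 0.2)
  expect_equal(tp$params$nrounds, 30L)

  space <- default_search_space(max_scale_pos_weight = 3)
  t1 <- tune_hyperparameters(X, y, groups, space, n_folds = 3, n_trials = 6,
                             seed = 9)
  t2 <- tune_hyperparameters(X, y, groups, space, n_folds = 3, n_trials = 6,
                             seed = 9)
  expect_identical(t1$params, t2$params)
  expect_identical(t1$trials, t2$trials)
  # argmax over trials includes the clipped-default trial 1
  expect_gte(t1$score, t1$trials$score[1])
  expect_equal(t1$score, max(t1$trials$score))
  bad <- space; bad$eta$lower <- 1; bad$eta$upper <- 0.5
  expect_error(tune_hyperparameters(X, y, groups, bad, n_folds = 3,
                                    n_trials = 2, seed = 1), "infeasible")
})

test_that("cross-validated evaluation partitions rows and brackets chance and perfection", {
  n <- 300
  groups <- rep(1:20, each = 15)
  X <- with_seed(11, data.frame(a = stats::rnorm(n), b = stats::rnorm(n)))
  # perfectly separable by construction
  y_sep <- as.integer(X$a > 0)
  ev <- crossval_evaluate(X, y_sep, groups, k = 5, seed = 2)
  tab <- table(ev$folds)
  expect_equal(sum(tab), n) # every individual in exactly one test fold
  expect_length(tab, 5L)
  expect_equal(ev$mean_auroc, 1, tolerance = 0.015)
  for (g in unique(groups)) # group-disjoint folds
    expect_length(unique(ev$folds[groups == g]), 1L)

  # label-permuted data sits at chance
  y_null <- with_seed(12, sample(y_sep))
  ev0 <- crossval_evaluate(X, y_null, groups, k = 10, seed = 3)
  expect_lt(abs(ev0$mean_auroc - 0.5), 0.1)
  expect_true(all(ev0$roc$fpr == seq(0, 1, length.out = 101)))
})

test_that("youden metrics maximize J with exact identities at every threshold", {
  # hand-checkable separation
  ym <- youden_metrics(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(ym$TPR, 1); expect_equal(ym$TNR, 1); expect_equal(ym$J, 1)

  scores <- with_seed(21, stats::runif(200))
  labels <- with_seed(22, rbinom(200, 1, plogis(3 * (scores - 0.5))))
  ym2 <- youden_metrics(scores, labels)
  expect_equal(ym2$J, ym2$TPR + ym2$TNR - 1)
  expect_equal(ym2$F1, 2 * ym2$TPR * ym2$PPV / (ym2$TPR + ym2$PPV))
  # the scan truly maximizes J over all distinct-score cutoffs
  js <- vapply(sort(unique(scores)), function(t) {
    mean(scores[labels == 1] >= t) + mean(scores[labels == 0] < t) - 1
  }, numeric(1))
  expect_equal(ym2$J, max(js))
  # tie-break prefers the lowest qualifying threshold
  ym3 <- youden_metrics(c(1, 2, 3, 4), c(0, 1, 1, 1))
  expect_equal(ym3$threshold, 2)
  expect_error(youden_metrics(1:3, c(1, 1, 1)), "both classes")
})

test_that("partial dependence reproduces constant, identity and additive responses", {
  X <- with_seed(31, data.frame(u = stats::runif(100), v = stats::runif(100)))
  flat <- partial_dependence(constant_model(0.3), X, "u",
                             grid = seq(0.1, 0.9, length.out = 9))
  expect_true(all(flat$response == 0.3))

  ident <- partial_dependence(identity_model("u"), X, "u",
                              grid = seq(0, 1, by = 0.25))
  expect_equal(ident$response, seq(0, 1, by = 0.25))

  # additive model: the curve recovers u's component up to a constant
  add <- partial_dependence(additive_model("u", "v"), X, "u",
                            grid = seq(0, 1, by = 0.1))
  expect_equal(diff(add$response), rep(0.1, 10), tolerance = 1e-12)

  # grouped curves: one per level
  grp <- partial_dependence(identity_model("u"), X, "u",
                            grid = c(0.2, 0.8), by = rep(c("a", "b"), 50))
  expect_equal(nrow(grp), 4L)
  expect_error(partial_dependence(constant_model(1), X, "zz"), "unknown feature")

  # default grid spans the 5th-95th percentile band
  auto <- partial_dependence(constant_model(1), X, "u")
  q <- stats::quantile(X$u, c(0.05, 0.95), names = FALSE)
  expect_equal(range(auto$grid), q)
  expect_equal(nrow(auto), 50L)
})

test_that("a monotone single-feature model yields a monotone curve", {
  n <- 400
  X <- with_seed(41, data.frame(x = stats::runif(n)))
  y <- as.integer(with_seed(42, stats::runif(n)) < plogis(6 * (X$x - 0.5)))
  fit <- fit_gbt(X, y, default_gbt_params(), seed = 1)
  pd <- partial_dependence(fit, X, "x", grid = seq(0.1, 0.9, length.out = 20))
  # strong upward trend: endpoints clearly ordered
  expect_gt(pd$response[20] - pd$response[1], 0.2)
  expect_gt(stats::cor(pd$grid, pd$response), 0.9)
})
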