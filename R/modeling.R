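#' Area under the ROC curve
#'
#' Probability that a uniformly drawn positive outscores a uniformly drawn
#' negative, with ties counted one half. Computed from midranks
#' (Wilcoxon-Mann-Whitney identity), which agrees exactly with the
#' brute-force pairwise definition.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1 or logical).
#' @return value in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop_config("both classes must be present to compute AUROC")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fit a gradient-boosted-tree classifier
#'
#' Thin wrapper around xgboost for binary classification. Single-threaded
#' and seeded so identical inputs produce identical models.
#'
#' @param X data frame or numeric matrix of features.
#' @param y binary labels.
#' @param params named list of hyperparameters; recognised entries are
#'   `max_depth`, `eta`, `nrounds`, `subsample`, `colsample_bytree`,
#'   `min_child_weight`, `lambda`, `scale_pos_weight`.
#' @param seed RNG seed.
#' @return object of class `gbt_model` with a [predict()] method returning
#'   positive-class probabilities.
#' @export
fit_gbt <- function(X, y, params = default_gbt_params(), seed = 1L) {
  y <- as.integer(as.logical(y))
  M <- as.matrix(X)
  storage.mode(M) <- "double"
  nrounds <- params$nrounds %||% 50L
  xgb_par <- list(
    objective = "binary:logistic",
    max_depth = as.integer(params$max_depth %||% 3L),
    eta = params$eta %||% 0.1,
    subsample = params$subsample %||% 0.8,
    colsample_bytree = params$colsample_bytree %||% 0.8,
    min_child_weight = params$min_child_weight %||% 1,
    lambda = params$lambda %||% 1,
    scale_pos_weight = params$scale_pos_weight %||% 1,
    nthread = 1,
    seed = as.integer(seed))
  booster <- with_seed(seed, xgboost::xgb.train(
    params = xgb_par,
    data = xgboost::xgb.DMatrix(M, label = y, nthread = 1),
    nrounds = as.integer(nrounds),
    verbose = 0))
  structure(list(booster = booster, features = colnames(M),
                 params = params, seed = seed),
            class = "gbt_model")
}

#' @export
predict.gbt_model <- function(object, newdata, ...) {
  M <- as.matrix(newdata[, object$features, drop = FALSE])
  storage.mode(M) <- "double"
  stats::predict(object$booster, xgboost::xgb.DMatrix(M, nthread = 1))
}

#' Default gradient-boosted-tree hyperparameters
#'
#' @param scale_pos_weight positive-class weight multiplier.
#' @return named list of hyperparameters.
#' @export
default_gbt_params <- function(scale_pos_weight = 1) {
  list(max_depth = 3L, eta = 0.1, nrounds = 50L, subsample = 0.8,
       colsample_bytree = 0.8, min_child_weight = 1, lambda = 1,
       scale_pos_weight = scale_pos_weight)
}

#' Default hyperparameter search space
#'
#' Box constraints for the tuner; each entry is
#' `list(type = "int"|"float"|"logfloat", lower, upper)`.
#'
#' @param max_scale_pos_weight upper bound for the positive-class weight
#'   (typically the negative/positive ratio).
#' @return named list describing the space.
#' @export
default_search_space <- function(max_scale_pos_weight = 20) {
  list(
    max_depth = list(type = "int", lower = 2, upper = 8),
    eta = list(type = "logfloat", lower = 0.01, upper = 0.3),
    nrounds = list(type = "int", lower = 20, upper = 200),
    subsample = list(type = "float", lower = 0.5, upper = 1),
    colsample_bytree = list(type = "float", lower = 0.5, upper = 1),
    min_child_weight = list(type = "float", lower = 1, upper = 10),
    lambda = list(type = "logfloat", lower = 0.01, upper = 10),
    scale_pos_weight = list(type = "float", lower = 1,
                            upper = max(1, max_scale_pos_weight)))
}

space_sample <- function(space) {
  lapply(space, function(s) {
    v <- switch(s$type,
                int = stats::runif(1, s$lower, s$upper + 1 - 1e-9),
                float = stats::runif(1, s$lower, s$upper),
                logfloat = exp(stats::runif(1, log(s$lower), log(s$upper))),
                stop_config("unknown space type '%s'", s$type))
    if (s$type == "int") as.integer(floor(v)) else v
  })
}

# Weighted Gaussian KDE density at points q given observations x.
kde_density <- function(q, x, lower, upper) {
  if (length(x) == 1L) x <- c(x, x)
  bw <- max(stats::sd(x), (upper - lower) / 20, 1e-9)
  vapply(q, function(qi) mean(stats::dnorm(qi, mean = x, sd = bw)),
         numeric(1)) + 1e-12
}

# One TPE proposal: split past trials into good/bad by score quantile,
# sample candidates from the good-density per dimension and keep the
# candidate maximizing the good/bad density ratio.
tpe_propose <- function(space, trials, scores, gamma = 0.25,
                        n_candidates = 24L) {
  n_good <- max(1L, ceiling(gamma * length(scores)))
  ord <- order(scores, decreasing = TRUE)
  good <- trials[ord[seq_len(n_good)]]
  bad <- trials[ord[-seq_len(n_good)]]
  if (length(bad) == 0L) bad <- trials
  out <- list()
  for (nm in names(space)) {
    s <- space[[nm]]
    tr <- function(v) if (s$type == "logfloat") log(v) else v
    inv <- function(v) if (s$type == "logfloat") exp(v) else v
    g <- tr(vapply(good, function(t) as.numeric(t[[nm]]), numeric(1)))
    b <- tr(vapply(bad, function(t) as.numeric(t[[nm]]), numeric(1)))
    lo <- tr(s$lower); hi <- tr(if (s$type == "int") s$upper + 1 else s$upper)
    cand <- pmin(pmax(stats::rnorm(n_candidates,
                                   mean = sample(g, n_candidates, replace = TRUE),
                                   sd = max(stats::sd(g), (hi - lo) / 20, 1e-9)),
                      lo), hi)
    ratio <- kde_density(cand, g, lo, hi) / kde_density(cand, b, lo, hi)
    v <- inv(cand[which.max(ratio)])
    out[[nm]] <- if (s$type == "int")
      as.integer(min(s$upper, max(s$lower, floor(v)))) else v
  }
  out
}

#' Assign whole groups to k folds
#'
#' Groups are shuffled (seeded) and greedily assigned, largest first, to the
#' currently smallest fold, so folds are balanced and no group straddles two
#' folds. When labels are supplied, assignment instead balances the
#' positive-class count across folds (groups with the most positives placed
#' first, each into the fold with the fewest positives so far), which keeps
#' both classes in every fold whenever the positives span at least k groups.
#'
#' @param groups per-individual group labels.
#' @param k number of folds.
#' @param seed RNG seed.
#' @param y optional binary labels for stratified-by-group assignment.
#' @return integer fold id per individual.
#' @export
grouped_folds <- function(groups, k, seed = 1L, y = NULL) {
  ug <- unique(groups)
  if (length(ug) < k)
    stop_config("need at least k distinct groups for k folds")
  sizes <- as.numeric(table(groups)[as.character(ug)])
  pos <- if (is.null(y)) rep(0, length(ug))
         else vapply(ug, function(g) sum(y[groups == g] == 1), numeric(1))
  with_seed(derive_seed(seed, "folds"), {
    ord <- sample(seq_along(ug))
    ug <- ug[ord]; sizes <- sizes[ord]; pos <- pos[ord]
    ord2 <- order(pos, sizes, decreasing = TRUE)
    ug <- ug[ord2]; sizes <- sizes[ord2]; pos <- pos[ord2]
    fold_of <- integer(length(ug))
    load <- numeric(k)
    pos_load <- numeric(k)
    for (i in seq_along(ug)) {
      f <- if (is.null(y)) which.min(load)
           else order(pos_load, load)[1L]
      fold_of[i] <- f
      load[f] <- load[f] + sizes[i]
      pos_load[f] <- pos_load[f] + pos[i]
    }
    fold_of[match(groups, ug)]
  })
}

#' Tune hyperparameters with a tree-structured Parzen estimator
#'
#' Sequential model-based optimization of the mean group-disjoint
#' cross-validated AUROC over a box-constrained space. The first quarter of
#' trials (at least 5) is random; subsequent trials split past results into
#' good and bad by score, model each parameter's good and bad values with
#' Gaussian kernel densities, and propose the candidate maximizing the
#' density ratio. Deterministic given the seed. The returned configuration
#' is the argmax over all evaluated trials (a default-parameter trial is
#' always included, so the tuned score never falls below the default's).
#'
#' @param X,y,groups training features, binary labels, split-group labels.
#' @param space search space as in [default_search_space()]; entries fixed
#'   to a single value (`lower == upper`) are honoured.
#' @param n_folds folds of the inner cross-validation (default 20).
#' @param n_trials number of configurations evaluated (default 100).
#' @param seed master seed.
#' @return list of class `model_params`: `params` (best configuration),
#'   `score` (its mean CV AUROC), `trials` (data frame of all trials).
#' @export
tune_hyperparameters <- function(X, y, groups, space = default_search_space(),
                                 n_folds = 20L, n_trials = 100L, seed = 1L) {
  for (s in space)
    if (s$lower > s$upper) stop_config("infeasible search space")
  cv_score <- function(params) {
    folds <- grouped_folds(groups, n_folds, seed = derive_seed(seed, "tunecv"))
    aucs <- vapply(seq_len(n_folds), function(f) {
      tr <- folds != f; te <- !tr
      if (length(unique(y[te])) < 2L || length(unique(y[tr])) < 2L)
        return(NA_real_)
      fit <- fit_gbt(X[tr, , drop = FALSE], y[tr], params,
                     seed = derive_seed(seed, paste0("tunefit", f)))
      auroc(predict(fit, X[te, , drop = FALSE]), y[te])
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }
  clip_to <- function(v, s) {
    v <- min(s$upper, max(s$lower, v))
    if (s$type == "int") as.integer(round(v)) else v
  }
  with_seed(derive_seed(seed, "tpe"), {
    # trial 1: default parameters clipped into the space, so the argmax can
    # never fall below the default configuration's score
    defaults <- default_gbt_params(
      scale_pos_weight = max(1, sum(y == 0) / max(1, sum(y == 1))))
    first <- space_sample(space)
    for (nm in names(space))
      if (!is.null(defaults[[nm]]))
        first[[nm]] <- clip_to(defaults[[nm]], space[[nm]])
    trials <- list(first)
    scores <- cv_score(trials[[1]])
    n_startup <- max(5L, ceiling(n_trials / 4))
    while (length(trials) < n_trials) {
      cand <- if (length(trials) < n_startup) space_sample(space)
              else tpe_propose(space, trials, scores)
      trials[[length(trials) + 1L]] <- cand
      scores <- c(scores, cv_score(cand))
    }
    best <- which.max(scores)
    tr_df <- do.call(rbind, lapply(seq_along(trials), function(i)
      data.frame(trial = i, score = scores[i],
                 as.data.frame(trials[[i]]))))
    structure(list(params = trials[[best]], score = scores[best],
                   trials = tr_df),
              class = "model_params")
  })
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("model_params: best mean CV AUROC %.4f over %d trials\n",
              x$score, nrow(x$trials)))
  utils::str(x$params, give.attr = FALSE)
  invisible(x)
}

# Vertical ROC averaging support: empirical TPR at fixed FPR grid.
roc_curve_at <- function(scores, labels, fpr_grid) {
  labels <- as.logical(labels)
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(th, function(t) mean(scores[labels] >= t), numeric(1)))
  fpr <- c(0, vapply(th, function(t) mean(scores[!labels] >= t), numeric(1)))
  vapply(fpr_grid, function(f) max(tpr[fpr <= f]), numeric(1))
}

#' Group-disjoint cross-validated evaluation
#'
#' Fits one model per fold (folds are group-disjoint), scores each held-out
#' fold, and aggregates per-fold AUROC into a mean with a Student-t 95%
#' confidence interval. ROC curves are averaged vertically on a fixed
#' 101-point FPR grid. Per-fold Youden-threshold metrics are collected so
#' operating-point metrics can be reported as fold means. A fold missing a
#' class triggers a reshuffled refold (logged via warning).
#'
#' @param X,y,groups features, binary labels, split-group labels.
#' @param params hyperparameter list (e.g. from [tune_hyperparameters()]).
#' @param k number of folds (default 10).
#' @param seed master seed.
#' @return object of class `model_evaluation`: per-fold AUROC, mean AUROC
#'   with CI, averaged ROC curve, per-fold and mean Youden metrics.
#' @export
crossval_evaluate <- function(X, y, groups, params = default_gbt_params(),
                              k = 10L, seed = 1L) {
  y <- as.integer(as.logical(y))
  degenerate <- function(f) any(vapply(seq_len(k), function(i)
    length(unique(y[f == i])) < 2L, logical(1)))
  folds <- grouped_folds(groups, k, seed = seed)
  if (degenerate(folds)) {
    # stratified-by-group refold, logged
    folds <- grouped_folds(groups, k, seed = seed, y = y)
    message("refolded with positive-count stratification to keep both classes in every fold")
  }
  fpr_grid <- seq(0, 1, length.out = 101L)
  fold_auc <- numeric(k)
  fold_tpr <- matrix(NA_real_, nrow = k, ncol = length(fpr_grid))
  fold_youden <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    fit <- fit_gbt(X[tr, , drop = FALSE], y[tr], params,
                   seed = derive_seed(seed, paste0("fold", f)))
    sc <- predict(fit, X[te, , drop = FALSE])
    fold_auc[f] <- auroc(sc, y[te])
    fold_tpr[f, ] <- roc_curve_at(sc, y[te], fpr_grid)
    fold_youden[[f]] <- youden_metrics(sc, y[te])
  }
  ci <- t_ci(fold_auc)
  ym <- do.call(rbind, lapply(fold_youden, as.data.frame))
  structure(list(
    fold_auroc = fold_auc,
    mean_auroc = mean(fold_auc),
    ci = ci,
    roc = data.frame(fpr = fpr_grid,
                     tpr = colMeans(fold_tpr),
                     tpr_lo = apply(fold_tpr, 2, function(v) t_ci(v)[1]),
                     tpr_hi = apply(fold_tpr, 2, function(v) t_ci(v)[2])),
    youden_folds = ym,
    youden_mean = colMeans(ym),
    youden_sd = apply(ym, 2, stats::sd),
    k = k, folds = folds),
    class = "model_evaluation")
}

t_ci <- function(v, level = 0.95) {
  v <- v[is.finite(v)]
  n <- length(v)
  if (n < 2L || stats::sd(v) == 0) return(c(mean(v), mean(v)))
  half <- stats::qt(1 - (1 - level) / 2, df = n - 1) * stats::sd(v) / sqrt(n)
  c(mean(v) - half, mean(v) + half)
}

#' @export
print.model_evaluation <- function(x, ...) {
  cat(sprintf("model_evaluation: %d-fold mean AUROC %.3f (95%% CI %.3f-%.3f)\n",
              x$k, x$mean_auroc, x$ci[1], x$ci[2]))
  cat("Youden-threshold metrics (fold mean +/- sd):\n")
  m <- x$youden_mean; s <- x$youden_sd
  for (nm in c("TPR", "TNR", "PPV", "F1", "J"))
    cat(sprintf("  %-4s %.2f +/- %.2f\n", nm, m[[nm]], s[[nm]]))
  invisible(x)
}

#' Metrics at the Youden-optimal threshold
#'
#' Scans every distinct score as a candidate cutoff (prediction positive
#' when score >= cutoff), selects the one maximizing Youden's index
#' J = TPR + TNR - 1, breaking ties toward the lowest (most sensitive)
#' threshold, and reports TPR, TNR, PPV, F1 and J there. The identities
#' J = TPR + TNR - 1 and F1 = 2 TPR PPV / (TPR + PPV) hold exactly at
#' every threshold.
#'
#' @param scores prediction scores.
#' @param labels binary labels.
#' @return list of class `threshold_metrics` with elements `threshold`,
#'   `TPR`, `TNR`, `PPV`, `F1`, `J`.
#' @export
youden_metrics <- function(scores, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels))
    stop_config("both classes must be present")
  th <- sort(unique(scores))
  tpr <- vapply(th, function(t) mean(scores[labels] >= t), numeric(1))
  tnr <- vapply(th, function(t) mean(scores[!labels] < t), numeric(1))
  j <- tpr + tnr - 1
  best <- which(j == max(j))[1L] # th sorted ascending: first max = lowest cutoff
  tp <- sum(scores[labels] >= th[best])
  fp <- sum(scores[!labels] >= th[best])
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(ppv) && tpr[best] + ppv > 0)
    2 * tpr[best] * ppv / (tpr[best] + ppv) else NA_real_
  structure(list(threshold = th[best], TPR = tpr[best], TNR = tnr[best],
                 PPV = ppv, F1 = f1, J = j[best]),
            class = "threshold_metrics")
}

#' @export
as.data.frame.threshold_metrics <- function(x, ...) {
  data.frame(threshold = x$threshold, TPR = x$TPR, TNR = x$TNR,
             PPV = x$PPV, F1 = x$F1, J = x$J)
}

#' Partial dependence of a model on one feature
#'
#' For each grid value, sets the feature to that value for all rows
#' (optionally within a label-defined subgroup) and averages the predicted
#' probability, tracing the model's marginal response to the feature.
#'
#' @param model a fitted model with a `predict` method returning
#'   probabilities (e.g. [fit_gbt()]).
#' @param table data frame of observations.
#' @param feature feature name.
#' @param grid grid values; default 50 points between the 5th and 95th
#'   percentiles of the observed feature.
#' @param by optional factor splitting rows into subgroups (e.g. diagnosed
#'   status), producing one curve per level.
#' @return data frame of class `pdp_curve` with columns `feature`, `grid`,
#'   `response` and optionally `group`.
#' @export
partial_dependence <- function(model, table, feature, grid = NULL,
                               by = NULL) {
  if (!feature %in% colnames(table))
    stop_config("unknown feature '%s'", feature)
  v <- table[[feature]]
  if (is.null(grid)) {
    q <- stats::quantile(v, c(0.05, 0.95), na.rm = TRUE, names = FALSE)
    grid <- seq(q[1], q[2], length.out = 50L)
  }
  grid <- sort(unique(grid))
  one_curve <- function(rows) {
    vapply(grid, function(g) {
      tb <- table[rows, , drop = FALSE]
      tb[[feature]] <- g
      mean(predict(model, tb))
    }, numeric(1))
  }
  if (is.null(by)) {
    out <- data.frame(feature = feature, grid = grid,
                      response = one_curve(seq_len(nrow(table))))
  } else {
    out <- do.call(rbind, lapply(unique(by), function(lv) {
      data.frame(feature = feature, grid = grid,
                 response = one_curve(which(by == lv)), group = lv)
    }))
  }
  class(out) <- c("pdp_curve", "data.frame")
  out
}
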