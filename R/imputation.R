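#' Classify a feature as nominal or quantitative
#'
#' A feature is treated as nominal only when every distinct observed value
#' occurs at least `min_freq` times (the usual adequacy requirement for a
#' chi-squared test) and the number of distinct values is small. Anything
#' else is treated as quantitative.
#'
#' @param values observed vector (missing entries are ignored).
#' @param min_freq minimum appearance count per distinct value (default 5).
#' @param max_levels maximum number of distinct values for a nominal
#'   feature (default 15).
#' @return `"nominal"` or `"quantitative"`.
#' @export
classify_feature_type <- function(values, min_freq = 5L, max_levels = 15L) {
  v <- values[!is.na(values)]
  if (length(v) == 0L) stop_config("need at least one observed value")
  if (!is.numeric(v)) stop_config("feature values must be numeric")
  tab <- table(v)
  if (length(tab) <= max_levels && all(tab >= min_freq)) "nominal"
  else "quantitative"
}

#' Imputation quality score
#'
#' Combines a feature's completeness with its imputability:
#' \eqn{QS = \gamma + (1 - \gamma)\,\mu}. A fully observed feature scores 1
#' regardless of \eqn{\mu}, as does an incomplete feature whose missing
#' entries can be imputed without error. QS is monotone nondecreasing in
#' both arguments and bounded by \eqn{[\gamma, 1]}.
#'
#' @param gamma completeness fraction in `[0, 1]`.
#' @param mu imputation score in `[0, 1]`.
#' @return quality score in `[0, 1]`.
#' @export
quality_score <- function(gamma, mu) {
  check_fraction(gamma, "gamma")
  check_fraction(mu, "mu")
  gamma + (1 - gamma) * mu
}

imputer_menu <- function(type) {
  if (type == "nominal")
    c("most_frequent", "distribution_preserving_random", "knn_k5",
      "iterative_rf")
  else
    c("median", "mean", "distribution_preserving_random", "knn_k5",
      "iterative_rf")
}

stat_mode <- function(x) {
  tab <- table(x)
  as.numeric(names(tab)[which.max(tab)])
}

# One-hot encode nominal predictor columns and median-fill missing entries,
# using statistics/levels from the training rows only.
build_predictor_encoder <- function(train_df, types) {
  cols <- colnames(train_df)
  spec <- lapply(cols, function(cl) {
    v <- train_df[[cl]]
    obs <- v[!is.na(v)]
    if (length(obs) == 0L) return(NULL)
    if (types[[cl]] == "nominal" && length(unique(obs)) > 2L) {
      list(col = cl, kind = "onehot", levels = sort(unique(obs)),
           fill = stat_mode(obs))
    } else {
      list(col = cl, kind = "numeric", fill = stats::median(obs))
    }
  })
  spec[!vapply(spec, is.null, logical(1))]
}

encode_predictors <- function(df, encoder) {
  pieces <- lapply(encoder, function(e) {
    v <- df[[e$col]]
    v[is.na(v)] <- e$fill
    if (e$kind == "onehot") {
      out <- sapply(e$levels, function(l) as.numeric(v == l))
      out <- matrix(out, nrow = nrow(df))
      colnames(out) <- paste0(e$col, "=", e$levels)
      out
    } else {
      matrix(v, ncol = 1, dimnames = list(NULL, e$col))
    }
  })
  do.call(cbind, pieces)
}

# Fit imputer on (y_obs, pred_obs) and predict at pred_query rows.
impute_predict <- function(imputer_id, y_obs, pred_obs, pred_query, type,
                           seed = 1L) {
  nq <- nrow(pred_query) %||% length(pred_query)
  switch(imputer_id,
    median = rep(stats::median(y_obs), nq),
    mean = rep(mean(y_obs), nq),
    most_frequent = rep(stat_mode(y_obs), nq),
    distribution_preserving_random = with_seed(seed,
      sample(y_obs, nq, replace = TRUE)),
    knn_k5 = {
      mu <- colMeans(pred_obs)
      sdv <- pmax(apply(pred_obs, 2, stats::sd), 1e-9)
      tr <- sweep(sweep(pred_obs, 2, mu), 2, sdv, "/")
      qu <- sweep(sweep(pred_query, 2, mu), 2, sdv, "/")
      k <- min(5L, nrow(tr))
      apply(qu, 1, function(q) {
        d <- sqrt(colSums((t(tr) - q)^2))
        nb <- y_obs[order(d)[seq_len(k)]]
        if (type == "nominal") stat_mode(nb) else mean(nb)
      })
    },
    iterative_rf = {
      y <- if (type == "nominal") factor(y_obs) else y_obs
      dtr <- data.frame(pred_obs, check.names = FALSE)
      fit <- ranger::ranger(
        x = dtr, y = y, num.trees = 100, seed = seed, num.threads = 1,
        respect.unordered.factors = TRUE)
      p <- stats::predict(fit, data.frame(pred_query, check.names = FALSE),
                          num.threads = 1)$predictions
      if (type == "nominal") as.numeric(as.character(p)) else p
    },
    stop_config("unknown imputer '%s'", imputer_id))
}

balanced_accuracy <- function(truth, pred) {
  classes <- unique(truth)
  mean(vapply(classes, function(cl) mean(pred[truth == cl] == cl),
              numeric(1)))
}

# Two-sample discernibility check: pass iff the test does NOT reject that
# imputed and observed held-out values share a distribution (alpha 0.05).
discernibility_pass <- function(imputed, observed, type, alpha = 0.05) {
  p <- tryCatch({
    if (type == "nominal") {
      lev <- sort(unique(c(imputed, observed)))
      tab <- rbind(table(factor(imputed, levels = lev)),
                   table(factor(observed, levels = lev)))
      suppressWarnings(stats::chisq.test(tab)$p.value)
    } else {
      suppressWarnings(stats::ks.test(imputed, observed)$p.value)
    }
  }, error = function(e) NA_real_)
  is.na(p) || p >= alpha # a degenerate test cannot reject
}

#' Assess one imputer on one feature
#'
#' Hides a held-out fraction of the feature's observed entries, fits the
#' imputer on the remainder (multivariate imputers also see the one-hot
#' encoded predictor columns), and predicts the hidden entries. The
#' imputation score mu is an R-squared-type score (clipped at 0) for
#' quantitative features and balanced accuracy for nominal ones. The
#' discernibility flag records whether a two-sample test
#' (Kolmogorov-Smirnov / chi-squared at alpha = 0.05) fails to distinguish
#' imputed from observed held-out values. A fully observed feature
#' short-circuits to gamma = 1, QS = 1, imputer `"none"`. A fit failure is
#' recorded as mu = 0 with a failed discernibility flag.
#'
#' @param x feature vector (with NAs at missing entries).
#' @param predictors data frame of candidate predictor columns.
#' @param imputer_id one of `median`, `mean`, `most_frequent`,
#'   `distribution_preserving_random`, `knn_k5`, `iterative_rf`.
#' @param seed seed for the held-out mask and stochastic imputers.
#' @param holdout_fraction fraction of observed entries hidden (default 0.2).
#' @param min_obs minimum observed-value count required (default 30).
#' @param type feature type; inferred via [classify_feature_type()] when
#'   NULL.
#' @param predictor_types named list/vector of predictor types (inferred
#'   when NULL).
#' @return list of class `imputer_assessment`: feature stats `gamma`, `mu`,
#'   `discernibility_pass`, `qs`, `imputer`, `type`.
#' @export
assess_imputer <- function(x, predictors, imputer_id, seed = 1L,
                           holdout_fraction = 0.2, min_obs = 30L,
                           type = NULL, predictor_types = NULL) {
  obs_idx <- which(!is.na(x))
  gamma <- length(obs_idx) / length(x)
  if (gamma == 1) {
    return(structure(list(imputer = "none", gamma = 1, mu = NA_real_,
                          discernibility_pass = TRUE, qs = 1,
                          type = type %||% classify_feature_type(x)),
                     class = "imputer_assessment"))
  }
  if (length(obs_idx) < min_obs)
    stop_config("need at least %d observed values (got %d)", min_obs,
                length(obs_idx))
  type <- type %||% classify_feature_type(x)
  ptypes <- predictor_types %||%
    lapply(predictors, classify_feature_type)
  enc <- build_predictor_encoder(predictors, ptypes)
  P <- encode_predictors(predictors, enc)

  n_hold <- max(2L, round(holdout_fraction * length(obs_idx)))
  hold <- with_seed(derive_seed(seed, "holdout"),
                    sample(obs_idx, n_hold))
  fit_idx <- setdiff(obs_idx, hold)
  truth <- x[hold]

  result <- tryCatch({
    pred <- impute_predict(imputer_id, x[fit_idx],
                           P[fit_idx, , drop = FALSE],
                           P[hold, , drop = FALSE], type, seed = seed)
    mu <- if (type == "nominal") {
      balanced_accuracy(truth, pred)
    } else {
      ss_tot <- sum((truth - mean(x[fit_idx]))^2)
      ss_res <- sum((truth - pred)^2)
      if (ss_tot == 0) as.numeric(ss_res == 0)
      else max(0, min(1, 1 - ss_res / ss_tot))
    }
    list(mu = mu, pass = discernibility_pass(pred, truth, type))
  }, error = function(e) list(mu = 0, pass = FALSE))

  structure(list(imputer = imputer_id, gamma = gamma, mu = result$mu,
                 discernibility_pass = result$pass,
                 qs = quality_score(gamma, result$mu), type = type),
            class = "imputer_assessment")
}

#' Select an imputer per feature by quality score
#'
#' For every incomplete feature, assesses the applicable imputer menu
#' (classifier variants for nominal features, regressor variants for
#' quantitative), discards assessments whose imputed values are
#' statistically discernible from observed ones, and keeps the surviving
#' imputer with the highest imputation score. A feature is retained iff its
#' quality score reaches `qs_threshold` (default 0.7). When every imputer
#' is rejected, QS falls back to the completeness fraction alone and, if the
#' feature is still retained, its missing values are filled by the
#' distribution-preserving random imputer (the least distribution-distorting
#' fallback).
#'
#' @param train data frame of training values (NAs at missing entries).
#' @param qs_threshold retention threshold on QS.
#' @param seed master seed.
#' @param min_obs,holdout_fraction passed to [assess_imputer()].
#' @return object of class `imputation_plan`: data frame with one row per
#'   feature (`feature`, `type`, `imputer`, `gamma`, `mu`, `qs`,
#'   `retained`).
#' @export
select_imputers <- function(train, qs_threshold = 0.7, seed = 1L,
                            min_obs = 30L, holdout_fraction = 0.2) {
  stopifnot(is.data.frame(train))
  types <- lapply(train, classify_feature_type)
  rows <- lapply(colnames(train), function(cl) {
    x <- train[[cl]]
    gamma <- mean(!is.na(x))
    if (gamma == 1) {
      return(data.frame(feature = cl, type = types[[cl]], imputer = "none",
                        gamma = 1, mu = NA_real_, qs = 1, retained = TRUE,
                        stringsAsFactors = FALSE))
    }
    predictors <- train[, setdiff(colnames(train), cl), drop = FALSE]
    menu <- imputer_menu(types[[cl]])
    assessments <- lapply(menu, function(im)
      assess_imputer(x, predictors, im, seed = derive_seed(seed, paste0(cl, im)),
                     holdout_fraction = holdout_fraction, min_obs = min_obs,
                     type = types[[cl]],
                     predictor_types = types[setdiff(names(types), cl)]))
    pass <- vapply(assessments, function(a) a$discernibility_pass, logical(1))
    if (any(pass)) {
      surv <- assessments[pass]
      best <- surv[[which.max(vapply(surv, function(a) a$mu, numeric(1)))]]
      data.frame(feature = cl, type = types[[cl]], imputer = best$imputer,
                 gamma = gamma, mu = best$mu, qs = best$qs,
                 retained = best$qs >= qs_threshold, stringsAsFactors = FALSE)
    } else {
      retained <- gamma >= qs_threshold
      data.frame(feature = cl, type = types[[cl]],
                 imputer = if (retained) "distribution_preserving_random"
                           else NA_character_,
                 gamma = gamma, mu = NA_real_, qs = gamma,
                 retained = retained, stringsAsFactors = FALSE)
    }
  })
  plan <- do.call(rbind, rows)
  attr(plan, "qs_threshold") <- qs_threshold
  attr(plan, "seed") <- seed
  class(plan) <- c("imputation_plan", "data.frame")
  plan
}

#' Apply an imputation plan, train-fitted only
#'
#' Completes every retained feature in the training table and, if supplied,
#' the test table, using imputers fitted exclusively on training rows:
#' univariate statistics, sampling pools, neighbor sets, predictor
#' encodings and random-forest fits all derive from the training table, so
#' test values never influence any fitted parameter. Dropped features are
#' removed from both tables.
#'
#' @param plan an [select_imputers()] plan built on `train`.
#' @param train,test data frames; `test` may be NULL.
#' @param seed seed for stochastic imputers.
#' @return list with completed `train` and `test` (NULL if not supplied).
#' @export
apply_imputation <- function(plan, train, test = NULL, seed = 1L) {
  stopifnot(inherits(plan, "imputation_plan"))
  if (!setequal(plan$feature, colnames(train)))
    stop_config("plan features do not match the training table")
  keep <- plan$feature[plan$retained]
  train <- train[, keep, drop = FALSE]
  if (!is.null(test)) {
    if (!all(keep %in% colnames(test)))
      stop_config("test table lacks features named in the plan")
    test <- test[, keep, drop = FALSE]
  }
  types <- stats::setNames(as.list(plan$type), plan$feature)
  train_raw <- train # imputers always fit on the original observed entries
  for (cl in keep) {
    row <- plan[plan$feature == cl, ]
    if (row$imputer == "none" && !anyNA(train[[cl]]) &&
        (is.null(test) || !anyNA(test[[cl]]))) next
    imputer <- if (row$imputer == "none")
      if (row$type == "nominal") "most_frequent" else "median"
    else row$imputer
    obs_idx <- which(!is.na(train_raw[[cl]]))
    predictors <- train_raw[, setdiff(keep, cl), drop = FALSE]
    enc <- build_predictor_encoder(predictors, types[setdiff(keep, cl)])
    P_train <- encode_predictors(predictors, enc)
    y_obs <- train_raw[[cl]][obs_idx]
    s <- derive_seed(seed, paste0("apply", cl))
    fill <- function(tbl, P) {
      miss <- which(is.na(tbl[[cl]]))
      if (length(miss)) {
        tbl[[cl]][miss] <- impute_predict(
          imputer, y_obs, P_train[obs_idx, , drop = FALSE],
          P[miss, , drop = FALSE], row$type, seed = s)
      }
      tbl
    }
    train <- fill(train, P_train)
    if (!is.null(test)) {
      P_test <- encode_predictors(test[, setdiff(keep, cl), drop = FALSE], enc)
      test <- fill(test, P_test)
    }
  }
  list(train = train, test = test)
}

#' @export
print.imputation_plan <- function(x, ...) {
  cat(sprintf("imputation_plan: %d features, %d retained (QS >= %.2f)\n",
              nrow(x), sum(x$retained), attr(x, "qs_threshold")))
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Serialize an imputation plan to JSON
#'
#' @param plan an imputation plan.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_imputation_plan <- function(plan, path) {
  jsonlite::write_json(as.data.frame(plan), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
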