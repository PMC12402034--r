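#' Group-respecting train/test split
#'
#' Assigns whole groups to exactly one side so no group straddles the
#' split. Groups are shuffled (seeded) and the prefix whose cumulative size
#' is closest to the target test fraction becomes the test side.
#'
#' @param groups per-individual group labels (>= 2 distinct).
#' @param test_fraction target fraction of individuals in the test side.
#' @param seed RNG seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
grouped_split <- function(groups, test_fraction = 0.3, seed = 1L) {
  ug <- unique(groups)
  if (length(ug) < 2L) stop_config("need at least 2 groups to split")
  check_fraction(test_fraction, "test_fraction")
  with_seed(derive_seed(seed, "split"), {
    ug <- sample(ug)
    sizes <- as.numeric(table(groups)[as.character(ug)])
    cum <- cumsum(sizes)
    target <- test_fraction * length(groups)
    kbest <- which.min(abs(cum - target))
    kbest <- min(kbest, length(ug) - 1L) # both sides non-empty
    test_groups <- ug[seq_len(kbest)]
    test <- which(groups %in% test_groups)
    list(train = setdiff(seq_along(groups), test), test = test)
  })
}

#' Repeated-split permutation importance
#'
#' Estimates each feature's contribution as the AUROC drop after permuting
#' its values in held-out data. Per repetition: a group-respecting
#' train/test split (default 70/30), one gradient-boosted-tree fit with the
#' supplied hyperparameters, the test AUROC, and then for each feature the
#' AUROC recomputed after a seeded permutation of its test-side column.
#' Across repetitions the mean drop and its 95% Student-t confidence
#' interval are aggregated; a feature is flagged significant iff the lower
#' CI bound is strictly positive. A Spearman rank correlation with the
#' target annotates each feature's direction. A split that leaves a single
#' class on either side is resampled with a fresh seed (logged).
#'
#' @param X data frame of complete features.
#' @param y binary labels.
#' @param groups split-group labels.
#' @param params hyperparameters for the fitted classifier.
#' @param n_reps number of repetitions (production default 100; reduce for
#'   quick runs).
#' @param test_fraction held-out fraction per split.
#' @param seed master seed.
#' @return object of class `pi_results`: matrix of drops (repetitions x
#'   features) plus per-feature summary data frame (`mean_drop`, `ci_lo`,
#'   `ci_hi`, `significant`, `spearman_r`, `spearman_p`).
#' @export
permutation_importance <- function(X, y, groups, params = default_gbt_params(),
                                   n_reps = 100L, test_fraction = 0.3,
                                   seed = 1L) {
  y <- as.integer(as.logical(y))
  p <- ncol(X)
  drops <- matrix(NA_real_, nrow = n_reps, ncol = p,
                  dimnames = list(NULL, colnames(X)))
  resampled <- 0L
  for (r in seq_len(n_reps)) {
    sp <- NULL
    for (try in 0:24) {
      cand <- grouped_split(groups, test_fraction,
                            seed = derive_seed(seed, paste0("pi", r, "_", try)))
      if (length(unique(y[cand$train])) == 2L &&
          length(unique(y[cand$test])) == 2L) { sp <- cand; break }
      resampled <- resampled + 1L
    }
    if (is.null(sp)) stop_config("could not find a split with both classes")
    fit <- fit_gbt(X[sp$train, , drop = FALSE], y[sp$train], params,
                   seed = derive_seed(seed, paste0("pifit", r)))
    Xte <- X[sp$test, , drop = FALSE]
    base <- auroc(predict(fit, Xte), y[sp$test])
    perm <- with_seed(derive_seed(seed, paste0("piperm", r)),
                      lapply(seq_len(p), function(j) sample(nrow(Xte))))
    for (j in seq_len(p)) {
      Xp <- Xte
      Xp[[j]] <- Xp[[j]][perm[[j]]]
      drops[r, j] <- base - auroc(predict(fit, Xp), y[sp$test])
    }
  }
  if (resampled > 0L)
    message(sprintf("resampled %d degenerate single-class split(s)", resampled))
  summary <- do.call(rbind, lapply(seq_len(p), function(j) {
    ci <- t_ci(drops[, j])
    sp_test <- spearman_sign(X[[j]], y)
    data.frame(feature = colnames(X)[j], mean_drop = mean(drops[, j]),
               ci_lo = ci[1], ci_hi = ci[2], significant = ci[1] > 0,
               spearman_r = sp_test$r, spearman_p = sp_test$p,
               stringsAsFactors = FALSE)
  }))
  structure(list(drops = drops, summary = summary, n_reps = n_reps,
                 test_fraction = test_fraction, seed = seed),
            class = "pi_results")
}

#' @export
print.pi_results <- function(x, ...) {
  cat(sprintf("pi_results: %d features over %d repetitions, %d significant\n",
              ncol(x$drops), x$n_reps, sum(x$summary$significant)))
  s <- x$summary[order(-x$summary$mean_drop), ]
  print(utils::head(s, 15), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Significant features from permutation importance
#'
#' Features whose 95% CI of the mean AUROC drop lies strictly in the
#' positive reals, ordered by decreasing mean drop. A CI touching zero is
#' excluded.
#'
#' @param results a [permutation_importance()] result.
#' @return character vector of feature names.
#' @export
significant_features <- function(results) {
  stopifnot(inherits(results, "pi_results"))
  s <- results$summary[results$summary$significant, , drop = FALSE]
  s$feature[order(-s$mean_drop)]
}

#' Spearman correlation with the target
#'
#' Rank correlation between a feature and the (binary) target with its
#' two-sided p-value; used downstream to annotate the direction of each
#' important feature's association.
#'
#' @param feature numeric vector.
#' @param target binary or numeric vector.
#' @return list with `r` and `p` (both NA for constant input).
#' @export
spearman_sign <- function(feature, target) {
  ok <- !is.na(feature) & !is.na(target)
  if (sum(ok) < 3L) stop_config("need at least 3 paired observations")
  if (stats::sd(feature[ok]) == 0 || stats::sd(target[ok]) == 0)
    return(list(r = NA_real_, p = NA_real_))
  ct <- suppressWarnings(stats::cor.test(feature[ok], as.numeric(target[ok]),
                                         method = "spearman", exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Backward sequential feature selection
#'
#' Starting from the significant-feature set, removes one feature per step:
#' every candidate removal is scored by the mean test AUROC over a fixed
#' battery of seeded group-respecting splits (the battery is shared across
#' candidates and steps, so comparisons are paired), and the candidate whose
#' removal yields the best mean score is eliminated (ties broken by feature
#' name order). The search continues down to a single feature; the selected
#' subset is the step (including the untouched start set) with the highest
#' mean score, with ties resolved toward the earlier (larger) subset.
#'
#' @param X,y,groups complete features, binary labels, split-group labels.
#' @param start_features character vector of starting features (>= 2),
#'   typically [significant_features()] output.
#' @param params classifier hyperparameters.
#' @param n_reps splits per evaluation (production default 100).
#' @param test_fraction held-out fraction per split.
#' @param seed master seed.
#' @return object of class `sfs_trace`: data frame `trace` (step, removed
#'   feature, mean score after removal, step-0 row included), `selected`
#'   (character vector), `best_score`.
#' @export
backward_sfs <- function(X, y, groups, start_features,
                         params = default_gbt_params(), n_reps = 100L,
                         test_fraction = 0.3, seed = 1L) {
  if (length(start_features) < 2L)
    stop_config("need at least 2 starting features")
  missing <- setdiff(start_features, colnames(X))
  if (length(missing))
    stop_config("start features absent from X: %s",
                paste(missing, collapse = ", "))
  y <- as.integer(as.logical(y))
  # fixed battery of splits shared by all candidate evaluations
  splits <- lapply(seq_len(n_reps), function(r) {
    for (try in 0:24) {
      sp <- grouped_split(groups, test_fraction,
                          seed = derive_seed(seed, paste0("sfs", r, "_", try)))
      if (length(unique(y[sp$train])) == 2L &&
          length(unique(y[sp$test])) == 2L) return(sp)
    }
    stop_config("could not find a split with both classes")
  })
  score_set <- function(features) {
    mean(vapply(seq_along(splits), function(r) {
      sp <- splits[[r]]
      fit <- fit_gbt(X[sp$train, features, drop = FALSE], y[sp$train],
                     params, seed = derive_seed(seed, paste0("sfsfit", r)))
      auroc(predict(fit, X[sp$test, features, drop = FALSE]), y[sp$test])
    }, numeric(1)))
  }
  current <- sort(start_features)
  trace <- data.frame(step = 0L, removed = NA_character_,
                      mean_score = score_set(current), n_features = length(current),
                      stringsAsFactors = FALSE)
  subsets <- list(current)
  step <- 0L
  while (length(current) > 1L) {
    step <- step + 1L
    cand_scores <- vapply(current, function(f)
      score_set(setdiff(current, f)), numeric(1))
    best <- which(cand_scores == max(cand_scores))
    removed <- current[best[order(current[best])[1L]]] # name-order tie-break
    current <- setdiff(current, removed)
    trace <- rbind(trace, data.frame(
      step = step, removed = removed,
      mean_score = max(cand_scores), n_features = length(current),
      stringsAsFactors = FALSE))
    subsets[[step + 1L]] <- current
  }
  best_step <- which.max(trace$mean_score) # first max: earlier/larger subset
  structure(list(trace = trace, selected = subsets[[best_step]],
                 best_score = trace$mean_score[best_step],
                 start_features = sort(start_features), seed = seed),
            class = "sfs_trace")
}

#' @export
print.sfs_trace <- function(x, ...) {
  cat(sprintf("sfs_trace: %d -> %d features, best mean AUROC %.4f\n",
              length(x$start_features), length(x$selected), x$best_score))
  print(x$trace, row.names = FALSE, digits = 4)
  invisible(x)
}
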