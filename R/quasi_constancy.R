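#' L-transform of a feature vector
#'
#' Relates the standard deviation to each observation instead of the mean
#' (as the classical coefficient of variation does). The input is
#' standardized, shifted so its minimum equals 1 (keeping all values in the
#' strictly positive domain and bounding the ratios), and each shifted value
#' \eqn{x_i} is mapped to \eqn{s\,\sigma/x_i}, where \eqn{\sigma} is the
#' standard deviation of the shifted vector and
#' \eqn{s = \mathrm{sign}(\bar x - \tilde x)} of the original input flips
#' negatively skewed distributions to positive (with `s = +1` when mean and
#' median coincide). A constant input returns the all-zeros vector.
#'
#' @param x numeric vector, length >= 2, no missing values.
#' @param shift_min value the minimum is anchored to after standardization.
#' @return dimensionless vector the same length as `x`.
#' @export
l_transform <- function(x, shift_min = 1) {
  if (length(x) < 2L || anyNA(x))
    stop_config("x must have length >= 2 with no missing values")
  sdev <- stats::sd(x)
  if (sdev == 0) return(rep(0, length(x)))
  z <- (x - mean(x)) / sdev
  shifted <- z - min(z) + shift_min
  s <- sign(mean(x) - stats::median(x))
  if (s == 0) s <- 1
  s * stats::sd(shifted) / shifted
}

#' Gini coefficient of a nonnegative vector
#'
#' Mean absolute difference between all pairs, normalized by twice the mean:
#' \eqn{\mathcal{G} = \sum_i \sum_j |x_i - x_j| / (2 n^2 \bar x)}; 0 for a
#' constant vector, approaching 1 when a single observation carries all the
#' mass. Returns 0 when the mean is 0. Computed via the sorted-rank identity
#' (O(n log n)).
#'
#' @param values nonnegative numeric vector, length >= 2.
#' @return coefficient in `[0, 1]`.
#' @export
gini <- function(values) {
  if (length(values) < 2L || anyNA(values))
    stop_config("values must have length >= 2 with no missing values")
  if (any(values < 0)) stop_config("values must be nonnegative")
  n <- length(values)
  m <- mean(values)
  if (m == 0) return(0)
  x <- sort(values)
  (2 * sum(seq_len(n) * x) / (n * sum(x))) - (n + 1) / n
}

#' Quasi-constancy index
#'
#' Gini coefficient of the absolute values of the L-transform:
#' \eqn{\mathcal{G}(|\mathcal{L}(x)|)}. Tends to 0 for (near-)constant
#' features and grows with variability; invariant under positive affine
#' transformations of `x` because standardization absorbs location and
#' scale. Absolute values are taken before the Gini step so negatively
#' skewed features (s = -1) remain in the coefficient's nonnegative domain.
#'
#' @param x numeric vector, length >= 2 (missing entries are dropped).
#' @return index in `[0, 1]`.
#' @export
quasi_constancy_index <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) stop_config("need >= 2 observed values")
  gini(abs(l_transform(x)))
}

#' Filter quasi-constant features
#'
#' Computes the quasi-constancy index of every column of a complete table
#' and retains those with index >= `threshold` (default 0.05).
#'
#' @param table complete (post-imputation) data frame of numeric columns.
#' @param threshold retention threshold on the index.
#' @return list with `retained` (character vector of surviving feature
#'   names) and `results` (data frame: feature, index, retained).
#' @export
filter_quasi_constant <- function(table, threshold = 0.05) {
  idx <- vapply(table, quasi_constancy_index, numeric(1))
  res <- data.frame(feature = names(idx), index = unname(idx),
                    retained = unname(idx) >= threshold,
                    stringsAsFactors = FALSE)
  list(retained = res$feature[res$retained], results = res)
}
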