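#' Recency-weighted moving average of a yearly series
#'
#' Aggregates an n-year series into one scalar with linearly increasing
#' weights, so recent years dominate and single-year peaks are smoothed:
#' \eqn{\bar x_w = \sum_{i=1}^{n} i \, x_i / w}, \eqn{w = n(n+1)/2}, with
#' \eqn{x_1} the oldest year and \eqn{x_n} the most recent.
#'
#' @param series numeric vector ordered oldest to newest, no missing entries.
#' @return scalar weighted average, always within `range(series)`.
#' @export
weighted_moving_average <- function(series) {
  if (length(series) < 1L || anyNA(series))
    stop_config("series must be non-empty with no missing entries")
  n <- length(series)
  sum(seq_len(n) * series) / (n * (n + 1) / 2)
}

#' Inverse-distance-weighted configuration
#'
#' @param beta distance exponent (> 0); 2 penalizes distance quadratically.
#' @param k number of nearest neighbors used per imputation.
#' @return object of class `idw_config`.
#' @export
idw_config <- function(beta = 2.0, k = 10L) {
  if (!is.numeric(beta) || beta <= 0) stop_config("beta must be > 0")
  if (!is.numeric(k) || k < 1) stop_config("k must be >= 1")
  structure(list(beta = beta, k = as.integer(k)), class = "idw_config")
}

#' Inverse-distance-weighted spatial imputation
#'
#' Estimates a value at `query` from the `k` nearest neighbors by Euclidean
#' distance, each weighted by \eqn{1/d^\beta}. An exact coordinate match
#' returns the matched neighbor's value directly (documented zero-distance
#' convention). The result always lies within the range of the neighbor
#' values used.
#'
#' @param query length-2 numeric coordinate.
#' @param neighbor_coords matrix (rows = neighbors) of coordinates.
#' @param neighbor_values numeric vector of neighbor values.
#' @param cfg an [idw_config()].
#' @return scalar estimate.
#' @export
idw_impute <- function(query, neighbor_coords, neighbor_values,
                       cfg = idw_config()) {
  neighbor_coords <- matrix(as.numeric(neighbor_coords), ncol = 2)
  keep <- is.finite(neighbor_values)
  neighbor_coords <- neighbor_coords[keep, , drop = FALSE]
  neighbor_values <- neighbor_values[keep]
  if (length(neighbor_values) == 0L)
    stop_config("no neighbors with finite values")
  d <- sqrt((neighbor_coords[, 1] - query[1])^2 +
              (neighbor_coords[, 2] - query[2])^2)
  if (any(d == 0)) return(neighbor_values[which(d == 0)[1L]])
  sel <- order(d)[seq_len(min(cfg$k, length(d)))]
  w <- 1 / d[sel]^cfg$beta
  sum(w * neighbor_values[sel]) / sum(w)
}

#' Augment a cohort with geospatial features
#'
#' Adds one feature block of 12 pollution aggregates plus population and
#' income (14 geospatial features) to every individual via their
#' municipality link. Pollution series are first collapsed in time with
#' [weighted_moving_average()]; covered municipalities contribute their own
#' aggregates, while uncovered ones receive inverse-distance-weighted
#' estimates from covered municipalities only (a municipality never imputes
#' from a pool including itself). Missing municipal income is IDW-imputed
#' from municipalities with recorded income. Population is always direct.
#' Non-geospatial columns are never altered.
#'
#' @param cohort a cohort bundle.
#' @param municipalities a [generate_municipality_table()] output (defaults
#'   to the table embedded in the bundle).
#' @param cfg an [idw_config()].
#' @return the bundle with 14 additional completely observed columns tagged
#'   `domain = "ENV"`, `source = "geospatial"`.
#' @export
augment_cohort_geospatial <- function(cohort, municipalities = NULL,
                                      cfg = idw_config()) {
  stopifnot(inherits(cohort, "cohort_bundle"))
  muni <- municipalities %||% cohort$municipalities
  tab <- muni$table
  idx <- match(cohort$municipality_id, tab$municipality_id)
  if (anyNA(idx)) stop_config("unknown municipality_id in cohort")

  m <- nrow(tab)
  covered <- tab$covered
  coords <- cbind(tab$x, tab$y)

  # per-municipality scalar per metric: own aggregate if covered, IDW
  # estimate from covered aggregates otherwise
  muni_vals <- matrix(NA_real_, nrow = m, ncol = length(muni$metrics),
                      dimnames = list(NULL, paste0("pollution_", muni$metrics)))
  for (j in seq_along(muni$metrics)) {
    series <- muni$pollution[[j]]
    agg <- rep(NA_real_, m)
    for (i in which(covered)) agg[i] <- weighted_moving_average(series[i, ])
    for (i in which(!covered))
      agg[i] <- idw_impute(coords[i, ], coords[covered, , drop = FALSE],
                           agg[covered], cfg)
    muni_vals[, j] <- agg
  }
  income <- tab$income
  has_inc <- is.finite(income)
  for (i in which(!has_inc))
    income[i] <- idw_impute(coords[i, ], coords[has_inc, , drop = FALSE],
                            tab$income[has_inc], cfg)

  geo <- as.data.frame(muni_vals[idx, , drop = FALSE])
  geo$population <- tab$population[idx]
  geo$income <- income[idx]
  rownames(geo) <- NULL

  cohort$values <- cbind(cohort$values, geo)
  add_mask <- matrix(TRUE, nrow = nrow(geo), ncol = ncol(geo),
                     dimnames = list(NULL, colnames(geo)))
  cohort$mask <- cbind(cohort$mask, add_mask)
  cohort$metadata <- rbind(
    cohort$metadata,
    data.frame(name = colnames(geo), domain = "ENV", source = "geospatial",
               role = "standalone", group = NA_character_,
               period = NA_character_, whole_grain = FALSE,
               parent = NA_character_, stringsAsFactors = FALSE))
  cohort
}

#' Region labels for leakage-safe splits
#'
#' Maps each individual to the region of their municipality. Regions are the
#' unit of every downstream train/test split, so localized geospatial
#' anomalies cannot leak across split sides.
#'
#' @param cohort a cohort bundle.
#' @param municipalities municipality table (defaults to the embedded one).
#' @return integer vector of per-individual region labels.
#' @export
region_groups <- function(cohort, municipalities = NULL) {
  muni <- municipalities %||% cohort$municipalities
  tab <- muni$table
  idx <- match(cohort$municipality_id, tab$municipality_id)
  if (anyNA(idx)) stop_config("unknown municipality_id in cohort")
  tab$region_id[idx]
}

#' Canonical municipality-name key
#'
#' Lowercases, strips accents and collapses whitespace so free-text
#' municipality names can be joined reliably. Idempotent.
#'
#' @param raw character vector.
#' @return character vector of canonical keys.
#' @export
standardize_municipality_name <- function(raw) {
  x <- tolower(trimws(raw))
  x <- iconv(x, from = "UTF-8", to = "ASCII//TRANSLIT")
  x <- gsub("['`^~\"]", "", x)
  gsub("\\s+", " ", x)
}
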