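#' Aggregate daily values to calendar-month means
#'
#' @param dates vector of `Date`s.
#' @param values numeric vector of the same length (daily minima, NDVI, ...).
#' @return data frame with `month` (first-of-month Date) and `value`
#'   (arithmetic mean of that month's values); calendar months inside the
#'   spanned range with no data get `NA`, not zero.
#' @export
aggregate_monthly <- function(dates, values) {
  stopifnot(length(dates) == length(values))
  dates <- as.Date(dates)
  month <- as.Date(format(dates, "%Y-%m-01"))
  agg <- tapply(values, month, mean)
  months_all <- seq(min(month), max(month), by = "month")
  out <- data.frame(month = months_all,
                    value = as.numeric(agg[as.character(months_all)]))
  rownames(out) <- NULL
  out
}

#' Trailing moving average
#'
#' `out[t] = mean(x[(t - window + 1):t])`, inclusive of the current value;
#' undefined (NA) for the first `window - 1` positions.
#'
#' @param x numeric series.
#' @param window window length in months (default 12).
#' @export
moving_average <- function(x, window = 12) {
  stopifnot(window >= 1)
  if (window > length(x)) stop("window longer than series")
  as.numeric(stats::filter(x, rep(1 / window, window), sides = 1))
}

#' Z-score a series using the moments of a reference window
#'
#' Centering and scaling use only the reference (training) window so that
#' held-out values are standardized without information leakage. The sample
#' (n - 1) standard deviation is used.
#'
#' @param x numeric series.
#' @param ref integer indices of the reference window (default: all).
#' @export
zscore <- function(x, ref = seq_along(x)) {
  m <- mean(x[ref], na.rm = TRUE)
  s <- sd(x[ref], na.rm = TRUE)
  if (!is.finite(s) || s == 0) stop("reference window has zero variance")
  (x - m) / s
}

#' Filter species by presence across observed sessions
#'
#' Retains species whose proportion of observed sessions with a nonzero
#' count is at least `min_presence` (exclusion is strictly below the
#' threshold, so a species at exactly the threshold is kept). Order is
#' preserved.
#'
#' @param x a `community_ts`.
#' @param min_presence minimum presence proportion (default 0.10).
#' @export
filter_species <- function(x, min_presence = 0.10) {
  n_obs <- rowSums(x$mask)
  n_pos <- rowSums(x$mask & !is.na(x$counts) & x$counts > 0)
  keep <- (n_pos / pmax(n_obs, 1)) >= min_presence
  if (!any(keep)) stop("all species fall below the presence threshold")
  community_ts(x$counts[keep, , drop = FALSE], x$mask[keep, , drop = FALSE],
               x$species[keep], start_date = x$dates[1])
}

#' Build a distributed-lag design from a covariate series
#'
#' For each modelled timepoint `t` (positions `start:length(x)` of the
#' supplied series, which must include at least `max_lag` months of lead-in),
#' the value matrix row is `(x[t], x[t-1], ..., x[t-max_lag])` and the
#' companion lag matrix row is `(0, 1, ..., max_lag)`.
#'
#' @param x numeric covariate series including lead-in.
#' @param max_lag maximum lag in months (default 6).
#' @param start 1-based index of the first modelled timepoint
#'   (default `max_lag + 1`, i.e. the whole series after the lead-in).
#' @return list with `value_matrix` and `lag_matrix`, both T x (max_lag + 1).
#' @export
build_lag_design <- function(x, max_lag = 6, start = max_lag + 1) {
  if (start <= max_lag)
    stop(sprintf("need %d months of lead-in before the count window", max_lag))
  ts <- start:length(x)
  value_matrix <- matrix(0, length(ts), max_lag + 1)
  for (l in 0:max_lag) value_matrix[, l + 1] <- x[ts - l]
  lag_matrix <- matrix(0:max_lag, nrow = length(ts), ncol = max_lag + 1,
                       byrow = TRUE)
  list(value_matrix = value_matrix, lag_matrix = lag_matrix)
}

#' Derive model-ready covariate columns
#'
#' Adds the 12-month trailing moving average of NDVI (z-scored) and z-scored
#' minimum temperature to a raw covariate table. The first `lead_in` rows are
#' covariate lead-in: derived columns are defined for every count timepoint,
#' and z-scoring moments come from the training rows only.
#'
#' @param covars data frame with columns `time_index`, `mintemp`, `ndvi`;
#'   rows with `time_index <= 0` (or the first `lead_in` rows) are lead-in.
#' @param lead_in number of lead-in months before the count window (12).
#' @param train_end last count timepoint used for standardization moments
#'   (default: all count timepoints).
#' @export
prepare_covariates <- function(covars, lead_in = 12, train_end = NULL) {
  T_all <- nrow(covars)
  if (T_all < lead_in + 12)
    stop("need at least 12 lead-in months plus a count window")
  count_rows <- (lead_in + 1):T_all
  if (is.null(train_end)) train_end <- length(count_rows)
  train_rows <- count_rows[seq_len(train_end)]
  ma <- moving_average(covars$ndvi, 12)
  m <- mean(ma[train_rows]); s <- sd(ma[train_rows])
  covars$ndvi_ma12 <- (ma - m) / s
  mt <- mean(covars$mintemp[train_rows]); st <- sd(covars$mintemp[train_rows])
  covars$mintemp_z <- (covars$mintemp - mt) / st
  attr(covars, "lead_in") <- lead_in
  attr(covars, "mintemp_moments") <- c(mean = mt, sd = st)
  attr(covars, "ndvi_ma12_moments") <- c(mean = m, sd = s)
  covars
}
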