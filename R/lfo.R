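#' Exact leave-future-out cross-validation over expanding windows
#'
#' For each origin, every requested model variant is refit on observations
#' 1..origin and posterior-predictive count ensembles are drawn for the next
#' `horizon` timepoints; each *observed* test timepoint is scored with the
#' energy score, the variogram score and their even combination. Masked
#' test timepoints are skipped and flagged.
#'
#' @param data a `community_ts`.
#' @param covars raw covariate table with lead-in.
#' @param variants character vector of model variants to compare.
#' @param origins training-window endpoints (expanding window folds).
#' @param horizon forecast steps scored per fold (default 12).
#' @param chains,warmup,sampling,seed passed to [fit_model()].
#' @param p variogram exponent.
#' @param species_subset deviation-smooth subset passed to [build_model()].
#' @param ... further arguments to [fit_model()].
#' @return a `score_report`: long data frame (model, fold, origin, horizon,
#'   score_type, value, observed) plus per-model mean combined scores.
#' @export
leave_future_out_cv <- function(data, covars,
                                variants = c("GAM-VAR", "AR"),
                                origins = c(75, 115, 154, 194, 233, 273),
                                horizon = 12, chains = 2, warmup = 300,
                                sampling = 300, seed = 1, p = 0.5,
                                species_subset = NULL, ...) {
  T_full <- ncol(data$counts)
  if (any(origins + horizon > T_full))
    stop("origin + horizon exceeds the available timepoints")
  rows <- list()
  for (fold in seq_along(origins)) {
    origin <- origins[fold]
    for (vr in variants) {
      model <- build_model(data, covars, variant = vr, train_end = origin,
                           species_subset = species_subset)
      ft <- fit_model(model, chains = chains, warmup = warmup,
                      sampling = sampling, seed = seed + fold, ...)
      fc <- forecast(ft, horizon = horizon, seed = seed + fold)
      for (h in seq_len(horizon)) {
        t_idx <- origin + h
        observed <- all(data$mask[, t_idx])
        if (!observed) {
          rows[[length(rows) + 1]] <- data.frame(
            model = vr, fold = fold, origin = origin, horizon = h,
            score_type = "combined", value = NA_real_, observed = FALSE)
          next
        }
        y <- data$counts[, t_idx]
        ens <- fc$counts[, h, ]
        es <- energy_score(ens, y)
        vs <- variogram_score(ens, y, p = p)
        rows[[length(rows) + 1]] <- data.frame(
          model = vr, fold = fold, origin = origin, horizon = h,
          score_type = c("energy", "variogram", "combined"),
          value = c(es, vs, 0.5 * (es + vs)), observed = TRUE)
      }
    }
  }
  report <- do.call(rbind, rows)
  agg <- stats::aggregate(value ~ model,
                          data = report[report$score_type == "combined" &
                                          report$observed, ],
                          FUN = mean)
  names(agg)[2] <- "mean_combined"
  structure(list(scores = report, summary = agg[order(agg$mean_combined), ],
                 origins = origins, horizon = horizon),
            class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("<score_report> %d folds x %d-step horizon\n",
              length(x$origins), x$horizon))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write a score report as delimited text
#'
#' @param x a `score_report`.
#' @param path output file.
#' @export
write_score_report <- function(x, path) {
  write.csv(x$scores, path, row.names = FALSE)
  invisible(path)
}
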