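#' Community count time-series container
#'
#' Bundles a species-by-time matrix of non-negative integer counts on a
#' regular monthly grid with an observation mask. Missing trapping sessions
#' are masked (mask = FALSE), never dropped, so the time index always
#' advances in unit steps.
#'
#' @param counts integer matrix, species x time. `NA` allowed where masked.
#' @param mask logical matrix, same shape; `TRUE` marks an observed session.
#'   Defaults to `!is.na(counts)`.
#' @param species character vector of species labels (rownames used if NULL).
#' @param start_date first-of-month `Date` of the first column.
#' @return an object of class `community_ts`.
#' @export
community_ts <- function(counts, mask = NULL, species = NULL,
                         start_date = as.Date("2000-01-01")) {
  counts <- as.matrix(counts)
  if (is.null(mask)) mask <- !is.na(counts)
  mask <- as.matrix(mask)
  stopifnot(identical(dim(counts), dim(mask)))
  if (is.null(species)) {
    species <- rownames(counts)
    if (is.null(species)) species <- paste0("sp", seq_len(nrow(counts)))
  }
  obs <- counts[mask]
  if (any(!is.finite(obs)) || any(obs < 0))
    stop("observed counts must be finite and non-negative")
  if (any(obs != round(obs))) stop("counts must be integers")
  rownames(counts) <- rownames(mask) <- species
  structure(list(
    counts = counts, mask = mask, species = species,
    time_index = seq_len(ncol(counts)),
    dates = seq(start_date, by = "month", length.out = ncol(counts))
  ), class = "community_ts")
}

#' @export
print.community_ts <- function(x, ...) {
  cat(sprintf("<community_ts> %d species x %d months (%s to %s), %.1f%% sessions missing\n",
              nrow(x$counts), ncol(x$counts),
              format(x$dates[1]), format(x$dates[length(x$dates)]),
              100 * mean(!x$mask[1, ])))
  invisible(x)
}

#' @export
dim.community_ts <- function(x) dim(x$counts)

#' Write / read community counts as long-format delimited text
#'
#' Columns are `time_index`, `date`, `species`, `count`; a missing session
#' is written with an empty count field. Round-trips exactly.
#'
#' @param x a `community_ts`.
#' @param path file path.
#' @rdname community_io
#' @export
write_community <- function(x, path) {
  n <- nrow(x$counts); T <- ncol(x$counts)
  df <- data.frame(
    time_index = rep(x$time_index, each = n),
    date = rep(format(x$dates), each = n),
    species = rep(x$species, times = T),
    count = ifelse(as.vector(x$mask), as.vector(x$counts), NA_integer_)
  )
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname community_io
#' @export
read_community <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  species <- unique(df$species)
  times <- sort(unique(df$time_index))
  if (!all(diff(times) == 1)) stop("time_index must be consecutive")
  n <- length(species); T <- length(times)
  counts <- matrix(NA_integer_, n, T, dimnames = list(species, NULL))
  idx <- cbind(match(df$species, species), match(df$time_index, times))
  counts[idx] <- df$count
  mask <- !is.na(counts)
  start <- as.Date(df$date[df$time_index == times[1]][1])
  community_ts(counts, mask, species, start_date = start)
}

#' Write / read monthly covariate tables
#'
#' Columns `time_index`, `date`, `mintemp`, `ndvi` plus any derived columns
#' present (e.g. `ndvi_ma12`, `mintemp_z`).
#'
#' @param covars a data frame as produced by [simulate_covariates()] or
#'   [prepare_covariates()].
#' @param path file path.
#' @rdname covariate_io
#' @export
write_covariates <- function(covars, path) {
  write.csv(covars, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname covariate_io
#' @export
read_covariates <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$date <- as.Date(df$date)
  df
}
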