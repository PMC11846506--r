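test_that("monthly aggregation averages within calendar months and keeps gaps", {
  d <- seq(as.Date("2001-01-01"), as.Date("2001-01-31"), by = "day")
  out <- aggregate_monthly(d, 1:31)
  expect_equal(out$value, 16)

  d2 <- as.Date(c("2001-01-10", "2001-01-20", "2001-03-05"))
  out2 <- aggregate_monthly(d2, c(4, 4, 9))
  expect_equal(out2$value, c(4, NA, 9))   # empty February is missing, not 0

  d3 <- rep(seq(as.Date("2002-06-01"), by = "day", length.out = 30), 1)
  expect_equal(aggregate_monthly(d3, rep(4, 30))$value, 4)
})

test_that("trailing moving average matches a brute-force oracle", {
  expect_equal(moving_average(1:12, 12)[12], 6.5)
  expect_equal(moving_average(rep(3.3, 20), 7)[7:20], rep(3.3, 14))
  expect_equal(moving_average(c(5, 1, 9), 1), c(5, 1, 9))
  expect_error(moving_average(1:5, 10), "window")

  set.seed(1)
  for (rep in 1:25) {
    x <- rnorm(sample(20:80, 1))
    w <- sample(1:12, 1)
    got <- moving_average(x, w)
    ora <- sapply(seq_along(x), function(t)
      if (t < w) NA_real_ else mean(x[(t - w + 1):t]))
    expect_equal(got, ora)
  }
})

test_that("z-scoring uses reference-window moments only (no leakage)", {
  x <- c(1, 5, 3, 100, 200)
  z <- zscore(x, ref = 1:3)
  expect_equal(z[1:3], (c(1, 5, 3) - 3) / 2)
  expect_equal(z[4], (100 - 3) / 2)                 # training moments reused
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1), tolerance = 1e-12)
  expect_equal(sd(c(1, 2, 3)), 1)                   # sample sd convention
  expect_error(zscore(rep(2, 5)), "variance")
})

test_that("species filtering keeps presence >= threshold, strictly-below dropped", {
  counts <- rbind(a = c(1, 0, 0, 0, 0, 0, 0, 0, 0, 0),   # 1/10 sessions
                  b = rep(0, 10),                         # 0/10
                  c = c(2, 3, 0, 1, 0, 4, 0, 0, 1, 0))    # 4/10
  ct <- community_ts(counts)
  kept <- filter_species(ct, 0.10)
  expect_equal(kept$species, c("a", "c"))   # boundary species retained
  expect_error(filter_species(community_ts(matrix(0, 2, 10)), 0.10))

  # 20 species, 11 engineered below a 10% presence threshold -> 9 retained
  set.seed(3)
  T <- 50
  pres <- c(rep(0.3, 9), rep(0.04, 11))
  counts2 <- t(sapply(pres, function(p) rbinom(T, 5, p)))
  # force exact presence counts to avoid binomial noise at the boundary
  for (i in seq_along(pres)) {
    tgt <- if (pres[i] > 0.1) 15 else 2
    row <- rep(0, T); row[seq_len(tgt)] <- 1 + rpois(tgt, 2)
    counts2[i, ] <- row
  }
  ct2 <- community_ts(counts2)
  expect_equal(nrow(filter_species(ct2, 0.10)$counts), 9)
})

test_that("lag design rows are (x_t, x_{t-1}, ..., x_{t-L})", {
  x <- c(10, 20, 30, 40, 50, 60, 70, 80)
  ld <- build_lag_design(x, max_lag = 6, start = 8)
  expect_equal(ld$value_matrix[1, ], c(80, 70, 60, 50, 40, 30, 20))
  expect_equal(ld$lag_matrix[1, ], 0:6)
  expect_error(build_lag_design(x, max_lag = 6, start = 5), "lead-in")

  ld0 <- build_lag_design(x, max_lag = 0, start = 1)
  expect_equal(as.vector(ld0$value_matrix), x)
  ldc <- build_lag_design(rep(2.5, 30), max_lag = 6)
  expect_true(all(ldc$value_matrix == 2.5))

  set.seed(2)
  x2 <- rnorm(60)
  ld2 <- build_lag_design(x2, max_lag = 6, start = 10)
  for (t in seq_len(nrow(ld2$value_matrix)))
    for (l in 0:6)
      expect_identical(ld2$value_matrix[t, l + 1], x2[9 + t - l])
})

test_that("community tables round-trip through delimited text exactly", {
  fx <- small_sim(n_species = 4, n_months = 40, seed = 11)
  path <- tempfile(fileext = ".csv")
  write_community(fx$data, path)
  back <- read_community(path)
  expect_identical(back$counts, fx$data$counts)
  expect_identical(back$mask, fx$data$mask)
  expect_identical(back$species, fx$data$species)
  expect_equal(back$dates, fx$data$dates)

  cpath <- tempfile(fileext = ".csv")
  write_covariates(fx$covars, cpath)
  cov2 <- read_covariates(cpath)
  expect_equal(cov2$mintemp, fx$covars$mintemp)
  expect_equal(cov2$ndvi, fx$covars$ndvi)
})

test_that("prepared covariates define the NDVI moving average at every count timepoint", {
  fx <- small_sim(n_species = 3, n_months = 60, seed = 5)
  pc <- prepare_covariates(fx$covars, lead_in = 12)
  count_rows <- pc$time_index >= 1
  expect_false(any(is.na(pc$ndvi_ma12[count_rows])))
  expect_equal(mean(pc$ndvi_ma12[count_rows]), 0, tolerance = 1e-10)
  expect_equal(sd(pc$ndvi_ma12[count_rows]), 1, tolerance = 1e-10)
})
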