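test_that("PSIS tail size and flat-ratio behaviour follow the definitions", {
  set.seed(1)
  ps <- psis_smooth(rnorm(1000))
  expect_equal(ps$n_tail, 94)           # floor(min(200, 3 sqrt(1000)))
  expect_equal(sum(exp(ps$log_weights)), 1, tolerance = 1e-10)

  flat <- psis_smooth(rep(0.7, 100))
  expect_equal(exp(flat$log_weights), rep(1 / 100, 100), tolerance = 1e-12)
  expect_error(psis_smooth(rnorm(10)), "25")
})

test_that("tail shape is benign for well-specified importance ratios", {
  set.seed(2)
  ks <- replicate(200, psis_smooth(-dnorm(rnorm(400), log = TRUE))$pareto_k)
  expect_gte(mean(ks < 0.7), 0.95)
})

test_that("ELPD-LOO: definition, dataset doubling, and comparison conventions", {
  set.seed(3)
  ll <- matrix(rnorm(200 * 150, -2, 0.3), 200, 150)
  r <- elpd_loo(ll)
  expect_length(r$pointwise, 150)
  expect_gte(r$se, 0)
  # single point with uniform weights reduces to log mean exp
  ll1 <- matrix(rep(-1.7, 100), 100, 1)
  r1 <- elpd_loo(ll1)
  expect_equal(r1$elpd, log(mean(exp(ll1[, 1]))), tolerance = 1e-10)

  # duplicating the dataset doubles the ELPD; the SE scales by sqrt(2)
  # (up to the n-1 vs n sample-variance factor, negligible at this n)
  rd <- elpd_loo(cbind(ll, ll))
  expect_equal(rd$elpd, 2 * r$elpd, tolerance = 1e-8)
  expect_equal(rd$se, sqrt(2) * r$se, tolerance = 0.01)

  cmp_self <- elpd_compare(list(m1 = r, m2 = r))
  expect_equal(cmp_self$elpd_diff, c(0, 0))
  expect_equal(cmp_self$se_diff, c(0, 0))

  r_shift <- r; r_shift$pointwise <- r$pointwise - 0.3
  r_shift$elpd <- sum(r_shift$pointwise)
  cmp <- elpd_compare(list(best = r, worse = r_shift))
  expect_equal(cmp$elpd_diff, c(0, -0.3 * 150), tolerance = 1e-10)
  expect_equal(cmp$se_diff, c(0, 0), tolerance = 1e-10)   # constant diffs
  expect_equal(cmp$model[1], "best")
})

test_that("PSIS-LOO matches exact leave-one-out refits on a conjugate toy", {
  # y_i ~ Poisson(lambda), lambda ~ Gamma(a, b): both the full posterior and
  # every leave-one-out posterior are Gamma, so exact LOO is available in
  # closed form (negative binomial predictive) as an independent oracle
  set.seed(4)
  n <- 20
  y <- rpois(n, 3)
  a <- 1.5; b <- 0.5
  S <- 4000
  lam_draws <- rgamma(S, a + sum(y), b + n)
  ll <- sapply(y, function(yi) dpois(yi, lam_draws, log = TRUE))
  psis <- elpd_loo(ll)

  exact <- sum(sapply(seq_len(n), function(i) {
    a_i <- a + sum(y[-i]); b_i <- b + (n - 1)
    # predictive: NegBin(size = a_i, prob = b_i / (b_i + 1))
    dnbinom(y[i], size = a_i, prob = b_i / (b_i + 1), log = TRUE)
  }))
  expect_lt(abs(psis$elpd - exact), psis$se)
})
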