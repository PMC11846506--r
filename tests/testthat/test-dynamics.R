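test_that("stationarity map: closed forms and guarantees", {
  # zero maps to zero
  m0 <- map_to_stationary(matrix(0, 3, 3), diag(3))
  expect_equal(m0$A, matrix(0, 3, 3))
  expect_equal(m0$Gamma, diag(3))

  # scalar closed form a = r / sqrt(1 + r^2), for any Sigma
  for (r in c(-5, -0.7, 0.3, 2, 40)) {
    m <- map_to_stationary(matrix(r, 1, 1), matrix(2.7, 1, 1))
    expect_equal(m$A[1, 1], r / sqrt(1 + r^2), tolerance = 1e-12)
    expect_lt(abs(m$A[1, 1]), 1)
  }

  # random matrices all map inside the stationarity region
  set.seed(21)
  for (i in 1:200) {
    n <- 5
    R <- matrix(rnorm(n * n, 0, 2), n, n)
    S <- make_covariance(runif(n, 0.2, 2), rlkj(n))
    expect_lt(spectral_radius(map_to_stationary(R, S)$A), 1)
  }
  expect_error(map_to_stationary(diag(2), matrix(c(1, 2, 2, 1), 2, 2)),
               "positive definite")
})

test_that("covariance assembly validates inputs", {
  expect_equal(make_covariance(c(1, 2), diag(2)), diag(c(1, 4)))
  C <- matrix(c(1, .5, .5, 1), 2, 2)
  expect_equal(make_covariance(c(1, 1), C), C)
  set.seed(2)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    S <- make_covariance(runif(n, 0.1, 3), rlkj(n))
    expect_silent(chol(S))   # positive definite by construction
  }
  expect_error(make_covariance(c(1, -1), diag(2)), "positive")
  expect_error(make_covariance(c(1, 1), matrix(c(2, 0, 0, 1), 2, 2)), "diagonal")
})

test_that("Lyapunov solution satisfies Gamma = A Gamma A' + Sigma", {
  expect_equal(stationary_covariance(matrix(0, 2, 2), diag(2)), diag(2))
  expect_equal(stationary_covariance(diag(0.5, 3), diag(3)),
               diag(3) / 0.75, tolerance = 1e-10)
  set.seed(31)
  worst <- 0
  for (i in 1:100) {
    n <- sample(2:6, 1)
    S <- make_covariance(runif(n, 0.2, 2), rlkj(n))
    A <- map_to_stationary(matrix(rnorm(n * n), n, n), S)$A
    G <- stationary_covariance(A, S)
    worst <- max(worst, max(abs(G - A %*% G %*% t(A) - S)))
  }
  expect_lt(worst, 1e-8)
  expect_error(stationary_covariance(diag(1.2, 2), diag(2)), "stationary")
})

test_that("state simulation: noiseless propagation, mean additivity, stationary spread", {
  A <- matrix(c(0.5, 0.2, -0.1, 0.4), 2, 2)
  v <- c(1, -2)
  st <- simulate_states(A, matrix(0, 2, 2), mu = matrix(0, 2, 10), init = v)
  expected <- v
  for (t in 1:10) {
    expect_equal(st$z[, t], expected, tolerance = 1e-12)
    expected <- as.vector(A %*% expected)
  }

  mu <- matrix(rnorm(20), 2, 10)
  set.seed(1)
  st2 <- simulate_states(A, diag(2) * 0.5, mu = mu)
  expect_equal(st2$X - st2$z, mu)

  # long-run empirical covariance approaches the Lyapunov solution
  set.seed(5)
  n <- 3
  S <- make_covariance(c(0.5, 0.8, 0.3), rlkj(n))
  A3 <- map_to_stationary(matrix(rnorm(9, 0, 0.6), 3, 3), S)$A
  G <- stationary_covariance(A3, S)
  st3 <- simulate_states(A3, S, mu = matrix(0, 3, 50000))
  emp <- cov(t(st3$z))
  expect_lt(max(abs(emp - G)) / max(abs(G)), 0.1)

  # forecast variance converges with horizon (stationarity guarantee)
  varh <- function(A, S, h) {
    V <- matrix(0, nrow(A), nrow(A))
    for (i in seq_len(h)) V <- A %*% V %*% t(A) + S
    V
  }
  vars <- sapply(c(1, 6, 12, 24), function(h) sum(diag(varh(A3, S, h))))
  expect_lt(vars[4] - vars[3], vars[2] - vars[1])
  expect_lt(vars[4], sum(diag(G)) * 1.001 + 1e-8)
})
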