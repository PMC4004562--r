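test_that("fixed-effect pooling is inverse-variance with the hand-computed Q", {
  fits <- make_fits(c(0.10, 0.30), c(0.01, 0.04))
  pf <- pool_fixed(fits)
  expect_equal(pf$beta, 0.14, tolerance = 1e-12)
  expect_equal(pf$cov[1, 1], 0.008, tolerance = 1e-12)
  expect_equal(pf$Q, 100 * 0.04^2 + 25 * 0.16^2, tolerance = 1e-12)  # 0.8

  # Q < df, so the DL moment estimate truncates at zero and random = fixed
  pr <- pool_random(fits)
  expect_identical(pr$tau2, 0)
  expect_equal(pr$beta, pf$beta, tolerance = 1e-15)
  expect_equal(pr$cov, pf$cov, tolerance = 1e-15)

  expect_error(pool_fixed(fits[1]), "at least 2")
})

test_that("identical studies pool to themselves with zero heterogeneity", {
  fits <- make_fits(rep(0.05, 4), rep(4e-4, 4))
  pf <- pool_fixed(fits)
  expect_equal(pf$beta, 0.05)
  expect_equal(pf$Q, 0, tolerance = 1e-20)
  expect_identical(pf$I2, 0)
})

test_that("pooling is invariant to study order", {
  set.seed(41)
  fits <- make_fits(rnorm(5, 0.03, 0.02), runif(5, 1e-4, 1e-3))
  perm <- sample(5)
  for (pool in list(pool_fixed, pool_random)) {
    a <- pool(fits); b <- pool(fits[perm])
    expect_equal(a$beta, b$beta, tolerance = 1e-12)
    expect_equal(a$Q, b$Q, tolerance = 1e-12)
    expect_equal(a$tau2, b$tau2, tolerance = 1e-12)
  }
})

test_that("DerSimonian-Laird matches the moment formula and metafor", {
  skip_if_not_installed("metafor")
  set.seed(43)
  for (rep in 1:5) {
    yi <- rnorm(6, 0.03, 0.03)
    vi <- runif(6, 1e-4, 1e-3)
    pr <- pool_random(make_fits(yi, vi))
    m <- metafor::rma(yi, vi, method = "DL")
    expect_equal(pr$tau2, m$tau2, tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(pr$beta, as.numeric(m$beta), tolerance = 1e-10)
    expect_equal(sqrt(pr$cov[1, 1]), as.numeric(m$se), tolerance = 1e-10)
    expect_equal(pr$Q, as.numeric(m$QE), tolerance = 1e-10)
  }
})

test_that("an outlying study strictly inflates the between-study variance", {
  yi <- c(0.02, 0.025, 0.03, 0.028)
  vi <- rep(2e-5, 4)
  base <- pool_random(make_fits(yi, vi))$tau2
  for (shift in c(0.05, 0.1, 0.2)) {
    t2 <- pool_random(make_fits(c(yi[1:3], yi[4] + shift), vi))$tau2
    expect_gt(t2, base)
    base <- t2
  }
})

test_that("bivariate pooling generalises the univariate moment construction", {
  set.seed(44)
  fits <- lapply(1:5, function(i) {
    A <- matrix(rnorm(4, sd = 0.01), 2)
    trend_fit(paste0("s", i), "all", "spline", rnorm(2, c(0.02, 0.003), 0.01),
              crossprod(A) + diag(2e-4, 2), 6)
  })
  pf <- pool_fixed(fits)
  expect_identical(pf$df, 8L)                      # 2 (k - 1)
  # multivariate Q by direct summation
  Q <- sum(vapply(fits, function(f) {
    r <- f$beta - pf$beta
    drop(t(r) %*% solve(f$cov_beta) %*% r)
  }, numeric(1)))
  expect_equal(pf$Q, Q, tolerance = 1e-10)

  pr <- pool_random(fits)
  expect_gte(pr$tau2, 0)
  if (pr$tau2 > 0) {
    # re-derive the pooled coefficients from the tau2-inflated covariances
    Ws <- lapply(fits, function(f) solve(f$cov_beta + pr$tau2 * diag(2)))
    cov <- solve(Reduce(`+`, Ws))
    beta <- drop(cov %*% Reduce(`+`, Map(function(W, f) W %*% f$beta, Ws, fits)))
    expect_equal(pr$beta, beta, tolerance = 1e-10)
  }
})

test_that("I2 interval reproduces the Higgins test-based construction", {
  # Q at the paper-style operating point: k = 5, p_Q = 0.59
  Q <- qchisq(1 - 0.59, df = 4)
  het <- heterogeneity_ci(Q, 5)
  expect_identical(het$I2, 0)
  expect_equal(het$ci_low, 0)
  expect_equal(round(het$ci_high), 79)

  # boundary: Q = k - 1 gives I2 = 0 exactly
  expect_identical(heterogeneity_ci(4, 5)$I2, 0)

  # monotone nondecreasing in Q for fixed k
  i2 <- vapply(seq(0.5, 40, by = 0.5),
               function(q) heterogeneity_ci(q, 5)$I2, numeric(1))
  expect_true(all(diff(i2) >= 0))

  # Q > k branch: se(lnH) from the large-Q formula
  het2 <- heterogeneity_ci(12, 5)
  se <- 0.5 * (log(12) - log(4)) / (sqrt(24) - sqrt(7))
  H <- sqrt(12 / 4)
  up <- exp(log(H) + qnorm(0.975) * se)
  expect_equal(het2$ci_high, 100 * (up^2 - 1) / up^2, tolerance = 1e-10)

  expect_warning(out <- heterogeneity_ci(1, 2), "undefined")
  expect_true(is.na(out$ci_high))
})

test_that("nonlinearity Wald test hits exact quantile identities", {
  mk <- function(b2, v2) {
    structure(list(model = "spline", beta = c(0.02, b2),
                   cov = matrix(c(1e-4, 0, 0, v2), 2), k = 5),
              class = "pooled_result")
  }
  expect_equal(nonlinearity_test(mk(0, 1e-4)), 1)
  expect_equal(nonlinearity_test(mk(qnorm(0.975) * 0.01, 1e-4)), 0.05,
               tolerance = 1e-10)
  expect_error(nonlinearity_test(mk(0.01, 0)), "degenerate")
  lin <- structure(list(beta = 0.02, cov = matrix(1e-4, 1, 1)),
                   class = "pooled_result")
  expect_error(nonlinearity_test(lin), "2 coefficients")
})

test_that("Q is invariant to rescaling all doses", {
  set.seed(45)
  studies <- lapply(1:4, function(i) {
    rr <- c(1, exp(rnorm(2, c(0.15, 0.3), 0.05)))
    make_study(rr = rr, dose = c(0, 5, 10), cases = c(20, 25, 30),
               total = c(300, 150, 150), study_id = paste0("s", i))
  })
  fit_at_scale <- function(scale) {
    lapply(studies, function(st) {
      st$categories$dose_assigned <- st$categories$dose_assigned * scale
      lrr <- log_rr_vector(st)
      ps <- fit_pseudo_counts(st, lrr$L)
      gls_fit(st, lrr, covariance_matrix(ps, lrr$V), "linear")
    })
  }
  Q1 <- pool_fixed(fit_at_scale(1))$Q
  Q2 <- pool_fixed(fit_at_scale(3.7))$Q
  expect_equal(Q1, Q2, tolerance = 1e-10)
})
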