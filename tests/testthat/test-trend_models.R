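test_that("knots sit at weighted quantiles of the pooled dose distribution", {
  cats <- make_categories(c(1, 1.5, 2, 2.5), c(1, 1.2, 1.5, 1.8),
                          c(1, 1.9, 2.7, 3.5), c(10, 15, 20, 25),
                          rep(1, 4), dose = c(5, 10, 15, 20))
  st <- study_record("s1", "all", "cumulative_incidence", cats)
  spec <- place_knots(list(st))
  expect_equal(spec$knots, c(8.75, 12.5, 16.25))    # type-7 under equal weights

  # duplicating every study rescales weights and leaves knots unchanged
  spec2 <- place_knots(list(st, st))
  expect_equal(spec2$knots, spec$knots)

  all_same <- st
  all_same$categories$dose_assigned <- rep(10, 4)
  expect_error(place_knots(list(all_same)), "egenerate")
})

test_that("restricted cubic spline basis has the stated tail behaviour", {
  k <- c(10, 20, 30)
  expect_equal(rcs_basis(c(2, 5, 10), k)[, "s2"], c(0, 0, 0))  # zero below k1
  expect_equal(rcs_basis(20, k)[, "s2"], 2.5, ignore_attr = TRUE)
  s2 <- rcs_basis(c(30, 35, 40), k)[, "s2"]
  expect_equal(s2[3] - s2[2], s2[2] - s2[1], tolerance = 1e-12) # linear tail
  expect_equal(rcs_basis(c(3, 17, 44), k)[, "s1"], c(3, 17, 44),
               ignore_attr = TRUE)                              # s1 is the dose
})

test_that("GLS reduces to the closed form with one non-reference category", {
  st <- make_study(rr = c(1, exp(0.7)), dose = c(0, 5), cases = c(10, 20),
                   total = c(100, 100))
  fit <- gls_fit(st, list(L = 0.7, ref = 1), matrix(0.04, 1, 1), "linear")
  expect_equal(fit$beta, 0.14, tolerance = 1e-12)               # L / delta-dose
  expect_equal(sqrt(fit$cov_beta[1, 1]), 0.04, tolerance = 1e-12)
})

test_that("GLS recovers an exactly linear signal to machine precision", {
  st <- make_study(rr = c(1, 1.5, 2, 2.5), dose = c(0, 4, 9, 16),
                   cases = c(10, 10, 10, 10), total = rep(100, 4))
  slope <- 0.033
  L <- slope * c(4, 9, 16)
  fit <- gls_fit(st, list(L = L, ref = 1), diag(3), "linear")
  expect_equal(fit$beta, slope, tolerance = 1e-14)
})

test_that("GLS with the reconstructed K=3 covariance matches matrix algebra", {
  st <- make_study(rr = c(1, 1.5, 2), dose = c(0, 5, 10),
                   cases = c(20, 20, 20), total = c(200, 100, 100))
  L <- log(c(1.5, 2))
  ps <- fit_pseudo_counts(st, L)
  C <- covariance_matrix(ps, c(0.04, 0.05))
  fit <- gls_fit(st, list(L = L, ref = 1), C, "linear")
  X <- matrix(c(5, 10), 2, 1)
  Ci <- solve(C)
  beta_o <- solve(t(X) %*% Ci %*% X) %*% t(X) %*% Ci %*% L
  expect_equal(fit$beta, drop(beta_o), tolerance = 1e-10)
  expect_equal(fit$cov_beta[1, 1], solve(t(X) %*% Ci %*% X)[1, 1],
               tolerance = 1e-10)
})

test_that("GLS with diagonal covariance equals 1/V weighted least squares", {
  set.seed(31)
  for (rep in 1:10) {
    d <- sort(runif(4, 1, 40))
    L <- rnorm(4, 0.02 * d, 0.1)
    V <- runif(4, 0.01, 0.1)
    st <- make_study(rr = c(1, exp(L)), dose = c(0, d),
                     cases = rep(10, 5), total = rep(100, 5))
    fit <- gls_fit(st, list(L = L, ref = 1), diag(V), "linear")
    wls <- lm(L ~ 0 + d, weights = 1 / V)
    expect_equal(fit$beta, unname(coef(wls)), tolerance = 1e-10)
  }
})

test_that("spline fits need 3 non-reference categories and nest the linear fit", {
  spec <- structure(list(knots = c(8, 15, 25)), class = "spline_spec")
  st3 <- make_study(rr = c(1, 1.5, 2), dose = c(5, 15, 30))
  lrr <- list(L = log(c(1.5, 2)), ref = 1)
  expect_error(gls_fit(st3, lrr, diag(2), "spline", spec),
               "3 non-reference")

  # with the nonlinear term dropped, the spline design is the linear design
  st4 <- make_study(rr = c(1, 1.3, 1.7, 2.1), dose = c(5, 12, 20, 32),
                    cases = rep(10, 4), total = rep(100, 4))
  L <- log(c(1.3, 1.7, 2.1))
  lin <- gls_fit(st4, list(L = L, ref = 1), diag(3), "linear")
  B <- rcs_basis(st4$categories$dose_assigned, spec)
  expect_equal(B[, "s1"] - B[1, "s1"],
               st4$categories$dose_assigned - 5, ignore_attr = TRUE)
  s1_only <- lm(L ~ 0 + I(st4$categories$dose_assigned[-1] - 5))
  expect_equal(lin$beta, unname(coef(s1_only)), tolerance = 1e-12)
})

test_that("stratum combination is inverse-variance with precision additivity", {
  f1 <- make_fit("s1", 0.02, 1e-4)
  f2 <- make_fit("s1", 0.03, 1e-4)
  comb <- combine_strata(list(f1, f2))
  expect_equal(comb$beta, 0.025, tolerance = 1e-12)
  expect_equal(comb$cov_beta[1, 1], 5e-5, tolerance = 1e-12)

  expect_identical(combine_strata(list(f1)), f1)      # single stratum

  twice <- combine_strata(list(f1, f1))
  expect_equal(twice$beta, f1$beta)
  expect_equal(twice$cov_beta[1, 1], f1$cov_beta[1, 1] / 2)

  # multivariate: block algebra on 2x2 covariances
  g1 <- trend_fit("s1", "m", "spline", c(0.02, 0.001),
                  matrix(c(2e-4, 5e-5, 5e-5, 1e-4), 2), 6)
  g2 <- trend_fit("s1", "f", "spline", c(0.03, -0.002),
                  matrix(c(1e-4, 2e-5, 2e-5, 3e-4), 2), 6)
  comb2 <- combine_strata(list(g1, g2))
  W1 <- solve(g1$cov_beta); W2 <- solve(g2$cov_beta)
  expect_equal(comb2$cov_beta, solve(W1 + W2), tolerance = 1e-12)
  expect_equal(comb2$beta,
               drop(solve(W1 + W2) %*% (W1 %*% g1$beta + W2 %*% g2$beta)),
               tolerance = 1e-12)

  expect_error(combine_strata(list(f1, g1)), "different models")
})

test_that("predicted curve is anchored at the reference and exponentiates the slope", {
  curve <- predict_curve(log(1.14) / 5, matrix(1e-6, 1, 1), 6, c(6, 11, 16))
  expect_equal(curve$rr[1], 1)
  expect_equal(curve$ci_low[1], 1)
  expect_equal(curve$ci_high[1], 1)
  expect_equal(curve$rr[2], 1.14, tolerance = 1e-12)
  expect_equal(curve$rr[3], 1.14^2, tolerance = 1e-12)

  # grid permutation invariance
  g <- c(8, 20, 14, 6)
  c1 <- predict_curve(0.02, matrix(1e-5, 1, 1), 6, g)
  c2 <- predict_curve(0.02, matrix(1e-5, 1, 1), 6, sort(g))
  expect_equal(c1[order(c1$dose), ], c2, ignore_attr = TRUE)
})

test_that("delta-method bands match Monte-Carlo propagation", {
  set.seed(32)
  spec <- structure(list(knots = c(10, 18, 28)), class = "spline_spec")
  beta <- c(0.025, 0.004)
  cov <- matrix(c(4e-5, -1e-5, -1e-5, 2e-5), 2)
  grid <- c(12, 20, 35)
  curve <- predict_curve(beta, cov, 6, grid, spec = spec)

  R <- chol(cov)
  draws <- matrix(rnorm(2e6), ncol = 2) %*% R
  draws <- sweep(draws, 2, beta, `+`)
  X <- rcs_basis(grid, spec) -
    matrix(rcs_basis(6, spec), length(grid), 2, byrow = TRUE)
  lp <- draws %*% t(X)
  mc_low <- exp(colMeans(lp) - qnorm(0.975) * apply(lp, 2, sd))
  mc_high <- exp(colMeans(lp) + qnorm(0.975) * apply(lp, 2, sd))
  expect_equal(curve$ci_low, mc_low, tolerance = 0.005)
  expect_equal(curve$ci_high, mc_high, tolerance = 0.005)
})

test_that("per-increment rescaling follows the exponential convention", {
  expect_equal(per_increment(0, 0), c(rr = 1, ci_low = 1, ci_high = 1))

  beta <- log(1.14) / 5
  se <- log(1.17 / 1.14) / (5 * qnorm(0.975))
  est <- per_increment(beta, se^2)
  expect_equal(est[["rr"]], 1.14, tolerance = 1e-10)
  expect_equal(est[["ci_high"]], 1.17, tolerance = 1e-10)

  est10 <- per_increment(beta, se^2, increment = 10)
  expect_equal(est10[["rr"]], est[["rr"]]^2, tolerance = 1e-12)
})
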