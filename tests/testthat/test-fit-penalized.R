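test_that("symmetric half-effect data give a flat curve at mu = 0.5", {
  d <- dose_response(data.frame(
    agent = "A", dose = rep(10^c(-1, 0, 1), each = 2), response = 0.5),
    response_scale = "fraction")
  for (lam in c(0, 1)) {
    f <- fit_median_effect(d, lambda = lam)[[1]]
    expect_equal(f$beta0, 0, tolerance = 1e-6)
    expect_equal(f$beta1, 0, tolerance = 1e-6)
  }
})

test_that("lambda = 0 PIRLS agrees with a brute-force likelihood maximizer", {
  d <- clean_data(seed = 301)
  f <- fit_median_effect(d, estimator = "mle")[[1]]
  orc <- oracle_fit(d$dose, squeeze_like_package(d$response))
  expect_lt(max(abs(c(f$beta0, f$beta1, f$log_phi) - orc$par)), 1e-4)
  expect_equal(f$loglik, orc$loglik, tolerance = 1e-8)
  expect_true(f$converged)
})

test_that("estimates recover the generating parameters within 3 SEs", {
  # beta0 = 0, beta1 = 1.5, phi = 50, n = 60
  d <- clean_data(seed = 99, m = 1.5, dm = 1, phi = 50, reps = 6,
                  doses = 10^seq(-2, 1.5, length.out = 10))
  f <- fit_median_effect(d, lambda = 0)[[1]]
  se <- sqrt(diag(f$coef_cov))
  expect_lt(abs(f$beta0 - 0), 3 * se[1])
  expect_lt(abs(f$beta1 - 1.5), 3 * se[2])
})

test_that("dose rescaling shifts the intercept by -beta1 * log10(c) only", {
  d <- clean_data(seed = 17)
  f <- fit_median_effect(d, lambda = 0, control = me_control(tol = 1e-10))[[1]]
  for (c_scale in c(1000, 0.02)) {
    d2 <- dose_response(data.frame(agent = d$agent, dose = d$dose * c_scale,
                                   response = d$response),
                        response_scale = "fraction")
    f2 <- fit_median_effect(d2, lambda = 0,
                            control = me_control(tol = 1e-10))[[1]]
    expect_equal(f2$beta1, f$beta1, tolerance = 1e-8)
    expect_equal(f2$beta0, f$beta0 - f$beta1 * log10(c_scale),
                 tolerance = 1e-8)
  }
})

test_that("complementing the response negates both coefficients", {
  d <- clean_data(seed = 23)
  f <- fit_median_effect(d, lambda = 0, control = me_control(tol = 1e-10))[[1]]
  d2 <- dose_response(data.frame(agent = d$agent, dose = d$dose,
                                 response = 1 - d$response),
                      response_scale = "fraction")
  f2 <- fit_median_effect(d2, lambda = 0,
                          control = me_control(tol = 1e-10))[[1]]
  expect_equal(f2$beta0, -f$beta0, tolerance = 1e-6)
  expect_equal(f2$beta1, -f$beta1, tolerance = 1e-6)
})

test_that("|beta1| shrinks monotonically in lambda and vanishes in the limit", {
  d <- clean_data(seed = 41)
  grid <- c(0, 0.5, 2, 10, 100, 1e4)
  slopes <- vapply(grid, function(l) {
    fit_median_effect(d, lambda = l)[[1]]$beta1
  }, numeric(1))
  expect_true(all(diff(abs(slopes)) <= 1e-10))

  # lambda -> large: slope 0, intercept-only beta MLE for the remaining pars
  f_inf <- fit_median_effect(d, lambda = 1e10)[[1]]
  expect_lt(abs(f_inf$beta1), 1e-4)
  nll0 <- function(p) {
    y <- squeeze_like_package(d$response)
    -sum(dbeta(y, plogis(p[1]) * exp(p[2]), (1 - plogis(p[1])) * exp(p[2]),
               log = TRUE))
  }
  o <- optim(c(0, log(5)), nll0, control = list(reltol = 1e-14, maxit = 5000))
  expect_equal(f_inf$beta0, o$par[1], tolerance = 1e-3)
  expect_equal(f_inf$log_phi, o$par[2], tolerance = 1e-3)
})

test_that("coefficient covariance matches the inverse numerical Hessian", {
  d <- clean_data(seed = 57)
  for (lam in c(0, 2)) {
    f <- fit_median_effect(d, lambda = lam)[[1]]
    y <- squeeze_like_package(d$response)
    negpen <- function(p) {
      mu <- plogis(p[1] + p[2] * log10(d$dose))
      -(sum(dbeta(y, mu * exp(p[3]), (1 - mu) * exp(p[3]), log = TRUE)) -
          lam / 2 * p[2]^2)
    }
    H <- fd_hessian(negpen, c(f$beta0, f$beta1, f$log_phi))
    ref <- solve(H)[1:2, 1:2]
    expect_lt(max(abs(f$coef_cov - ref)) / max(abs(ref)), 0.05)
    expect_true(all(diag(f$coef_cov) >= 0))
    expect_equal(f$coef_cov[1, 2], f$coef_cov[2, 1])
  }
})

test_that("boundary responses are squeezed and counted", {
  dose <- rep(10^c(-2, -1, 0, 1), each = 2)
  y <- c(0, 0.05, 0.2, 0.35, 0.6, 0.75, 0.95, 1)
  d <- dose_response(data.frame(agent = "A", dose = dose, response = y),
                     response_scale = "fraction")
  f <- fit_median_effect(d, lambda = 0)[[1]]
  expect_identical(f$boundary_adjusted, 2L)
  n <- length(y)
  expect_equal(f$data$response_adj[y == 0], 0.5 / n)
  expect_equal(f$data$response_adj[y == 1], (n - 0.5) / n)
  expect_equal(f$data$response_adj[y == 0.2], 0.2)
})

test_that("constant extreme responses yield a flagged, finite fit", {
  d <- dose_response(data.frame(agent = "A", dose = 10^c(-1, 0, 1),
                                response = c(0.9, 0.9, 0.9)),
                     response_scale = "fraction")
  f <- fit_median_effect(d, lambda = 0)[[1]]
  expect_true(is.finite(f$beta1))
  expect_lt(abs(f$beta1), 1e-6)
  expect_error(estimate_potency(f), "degenerate",
               class = "betadose_parameter_error")
})
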