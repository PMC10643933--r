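# A deterministic fit-like object with chosen coefficients, for closed-form
# checks that do not depend on the estimation path.
fake_fit <- function(agent = "A", beta0 = 0, beta1 = 1,
                     cov = diag(c(0.01, 0.01))) {
  structure(list(agent = agent, beta0 = beta0, beta1 = beta1,
                 log_phi = log(30), lambda = 0, coef_cov = cov,
                 loglik = 0, n_obs = 24L, converged = TRUE, n_iter = 1L,
                 boundary_adjusted = 0L, estimator = "penalized",
                 alpha = NA_real_,
                 data = tibble::tibble(dose = 10^c(-1, 0, 1),
                                       log10_dose = c(-1, 0, 1),
                                       response = c(0.2, 0.5, 0.8),
                                       response_adj = c(0.2, 0.5, 0.8))),
            class = "me_fit")
}

test_that("potency closed forms hold at x = 50 and x = 90", {
  f <- fake_fit(beta0 = 0, beta1 = 1)
  p50 <- estimate_potency(f, 50)
  expect_equal(p50$log10_dose, 0)
  expect_equal(p50$dose, 1)
  p90 <- estimate_potency(f, 90)
  expect_equal(p90$log10_dose, log(9))  # logit(0.9) = ln 9 ~ 2.1972
  expect_equal(p90$dose, 10^log(9))

  # general identity at several levels, non-trivial coefficients
  f2 <- fake_fit(beta0 = -0.7, beta1 = 2.2)
  for (x in c(10, 50, 90)) {
    expect_equal(estimate_potency(f2, x)$log10_dose,
                 (qlogis(x / 100) - (-0.7)) / 2.2)
  }
})

test_that("predict_effect is the exact inverse of estimate_potency", {
  d <- clean_data(seed = 121)
  f <- fit_median_effect(d)[[1]]
  for (x in c(1, 5, 10, 50, 90, 95, 99)) {
    p <- estimate_potency(f, x)
    expect_equal(predict_effect(f, p$dose)$estimate, x / 100,
                 tolerance = 1e-10)
  }
  # the fitted D50 produces exactly half-effect
  expect_equal(predict_effect(f, estimate_potency(f, 50)$dose)$estimate, 0.5,
               tolerance = 1e-12)
})

test_that("potency is strictly increasing in x for an increasing curve", {
  f <- fit_median_effect(clean_data(seed = 122))[[1]]
  ld <- estimate_potency(f, c(1, 5, 10, 50, 90, 95, 99))$log10_dose
  expect_true(all(diff(ld) > 0))
})

test_that("prediction bands stay strictly inside the unit interval", {
  f <- fit_median_effect(clean_data(seed = 123))[[1]]
  pr <- predict_effect(f, 10^seq(-6, 6, length.out = 100))
  expect_true(all(pr$conf.low > 0 & pr$conf.high < 1))
  expect_true(all(pr$conf.low <= pr$estimate & pr$estimate <= pr$conf.high))
})

test_that("delta-method SE propagates the coefficient covariance correctly", {
  f <- fit_median_effect(clean_data(seed = 124))[[1]]
  p <- estimate_potency(f, 80)
  # parametric bootstrap from the reported covariance as the oracle
  withr::with_seed(2024, {
    L <- chol(f$coef_cov)
    draws <- matrix(rnorm(2 * 4000), ncol = 2) %*% L
    b0 <- f$beta0 + draws[, 1]
    b1 <- f$beta1 + draws[, 2]
    boot <- (qlogis(0.8) - b0) / b1
  })
  expect_equal(p$se_log10_dose, sd(boot), tolerance = 0.1)
  # CI is symmetric on the log scale, hence asymmetric on the dose scale
  expect_equal(log10(p$ci_low) + log10(p$ci_high), 2 * p$log10_dose)
  expect_true(p$ci_low <= p$dose && p$dose <= p$ci_high)
})

test_that("potency comparison reduces to known normal-tail values", {
  f <- fake_fit()
  same <- compare_potency(f, fake_fit(agent = "B"))
  expect_equal(same$difference, 0)
  expect_equal(same$p_value, 1)

  # difference 1.0 with se_a = se_b = sqrt(0.5): z = 1, p = 2 * (1 - pnorm(1))
  fa <- fake_fit(agent = "A", beta0 = 0, beta1 = 1,
                 cov = diag(c(0.5, 0)))
  fb <- fake_fit(agent = "B", beta0 = 1, beta1 = 1,
                 cov = diag(c(0.5, 0)))
  cmp <- compare_potency(fa, fb, 50)
  expect_equal(cmp$difference, 1)
  expect_equal(cmp$z, 1)
  expect_equal(cmp$p_value, 2 * pnorm(-1))
  expect_equal(cmp$p_value, 0.3173, tolerance = 1e-4)
})

test_that("hill comparison reduces to known normal-tail values", {
  fa <- fake_fit(agent = "A", beta1 = 2, cov = diag(c(0.01, 0.25)))
  fb <- fake_fit(agent = "B", beta1 = 1, cov = diag(c(0.01, 0.25)))
  cmp <- compare_hill(fa, fb)
  expect_equal(cmp$difference, 1)
  expect_equal(cmp$z, 1 / sqrt(0.5))
  expect_equal(cmp$p_value, 2 * pnorm(-1 / sqrt(0.5)))
  expect_equal(cmp$p_value, 0.1573, tolerance = 1e-4)

  ident <- compare_hill(fa, fake_fit(agent = "B", beta1 = 2,
                                     cov = diag(c(0.01, 0.25))))
  expect_equal(ident$p_value, 1)
})

test_that("comparisons are antisymmetric in the agent order", {
  fa <- fit_median_effect(clean_data(seed = 131))[[1]]
  db <- clean_data(seed = 132, m = 1.0, dm = 3)
  db <- dose_response(data.frame(agent = "B", dose = db$dose,
                                 response = db$response),
                      response_scale = "fraction")
  fb <- fit_median_effect(db)[[1]]
  for (cmp in list(list(compare_potency(fa, fb, 70),
                        compare_potency(fb, fa, 70)),
                   list(compare_hill(fa, fb), compare_hill(fb, fa)))) {
    expect_equal(cmp[[1]]$difference, -cmp[[2]]$difference)
    expect_equal(cmp[[1]]$z, -cmp[[2]]$z)
    expect_equal(cmp[[1]]$p_value, cmp[[2]]$p_value)
  }
})

test_that("pairwise comparisons enumerate pairs and adjust with Holm", {
  specs <- list(
    simulation_spec(m = 1.5, dm = 0.5, phi = 30, doses = std_doses(),
                    reps = 3, seed = 141, agent = "A"),
    simulation_spec(m = 1.2, dm = 1, phi = 30, doses = std_doses(),
                    reps = 3, seed = 142, agent = "B"),
    simulation_spec(m = 0.8, dm = 3, phi = 30, doses = std_doses(),
                    reps = 3, seed = 143, agent = "C"))
  fits <- fit_median_effect(simulate_dose_response(specs))

  pot_only <- pairwise_compare(fits, quantities = "potency")
  expect_equal(nrow(pot_only), 3)  # C(3, 2)
  expect_equal(pot_only$p_adjusted, pot_only$p_value)
  expect_identical(pot_only$agent_a, c("A", "A", "B"))

  both <- pairwise_compare(fits, quantities = c("potency", "hill"),
                           adjustment = "holm")
  expect_equal(nrow(both), 6)
  # Holm step-down, hand-computed within each quantity family
  for (q in c("potency", "hill")) {
    rows <- both[both$quantity == q, ]
    p <- rows$p_value
    o <- order(p)
    hand <- p
    running <- 0
    for (k in seq_along(p)) {
      running <- max(running, (length(p) - k + 1) * p[o[k]])
      hand[o[k]] <- min(1, running)
    }
    expect_equal(rows$p_adjusted, hand)
    expect_true(all(rows$p_adjusted >= rows$p_value))
  }

  expect_error(pairwise_compare(fits[[1]]), "at least 2",
               class = "betadose_parameter_error")
})

test_that("holm adjustment matches the hand-computed step-down on (.01,.02,.04)", {
  # three agents engineered so the wiring, not p.adjust, is exercised
  hand <- c(0.03, 0.04, 0.04)
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), "holm"), hand)
})

test_that("degenerate and invalid potency requests fail loudly", {
  f <- fake_fit(beta1 = 0)
  expect_error(estimate_potency(f, 50), "degenerate",
               class = "betadose_parameter_error")
  f2 <- fake_fit()
  expect_error(estimate_potency(f2, 0), class = "betadose_parameter_error")
  expect_error(estimate_potency(f2, 100), class = "betadose_parameter_error")
  expect_error(predict_effect(f2, c(1, -1)), class = "betadose_parameter_error")
})

test_that("increasing replication increases power to separate Hill slopes", {
  # slope contrast 1.0 vs 1.4 keeps power off the ceiling in both designs,
  # so the ordering is informative
  n_rep <- 500
  detect <- function(reps, seed_base) {
    vapply(1:n_rep, function(s) {
      da <- clean_data(seed = seed_base + 2 * s, m = 1.0, phi = 30,
                       reps = reps)
      db <- clean_data(seed = seed_base + 2 * s + 1, m = 1.4, phi = 30,
                       reps = reps)
      db <- dose_response(data.frame(agent = "B", dose = db$dose,
                                     response = db$response),
                          response_scale = "fraction")
      fa <- fit_median_effect(da, estimator = "mle")[[1]]
      fb <- fit_median_effect(db, estimator = "mle")[[1]]
      compare_hill(fa, fb)$p_value < 0.05
    }, logical(1))
  }
  power3 <- mean(detect(3, 30000))
  power1 <- mean(detect(1, 60000))
  expect_gt(power3, power1)
})
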