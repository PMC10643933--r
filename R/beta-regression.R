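#' Convergence control for the penalized fitter
#'
#' @param tol Convergence tolerance: the fit stops when the maximum absolute
#'   change in (beta0, beta1, log phi) between outer iterations falls below
#'   `tol`.
#' @param max_iter Maximum number of outer iterations. Non-convergence is
#'   flagged on the returned fit (a warning, not an error), so batch screens
#'   do not abort.
#' @return A list of class `"me_control"`.
#' @export
me_control <- function(tol = 1e-8, max_iter = 100L) {
  if (tol <= 0) stop_parameter("`tol` must be positive.")
  if (max_iter < 1) stop_parameter("`max_iter` must be at least 1.")
  structure(list(tol = tol, max_iter = as.integer(max_iter)),
            class = "me_control")
}

#' Default ridge tuning-parameter grid
#'
#' Log-spaced grid used when `lambda = "auto"`; includes a near-zero value so
#' that clean, well-separated data can select an essentially unpenalized fit.
#' @return A sorted numeric vector.
#' @export
default_lambda_grid <- function() {
  c(1e-6, 1e-4, 1e-3, 1e-2, 0.1, 1, 10, 100)
}

# Boundary squeeze: beta support is open, but in vitro screens routinely
# report exact 0%/100% responses. Only boundary values are compressed,
# y' = (y * (n - 1) + 0.5) / n with n the per-agent observation count.
squeeze_boundary <- function(y) {
  n <- length(y)
  at_boundary <- y == 0 | y == 1
  y[at_boundary] <- (y[at_boundary] * (n - 1) + 0.5) / n
  list(y = y, n_adjusted = sum(at_boundary))
}

#' Beta log-likelihood of a median-effect curve
#'
#' Evaluates the log-likelihood of single-agent dose-response data under the
#' beta law in the mean-precision parameterization, with the logit of the
#' mean linear in log10(dose): `logit(mu_i) = beta0 + beta1 * log10(D_i)` and
#' `y_i ~ Beta(mu_i * phi, (1 - mu_i) * phi)`.
#'
#' @param data A `"dose_response"` dataset containing exactly one agent, with
#'   all responses strictly inside (0, 1) (apply the boundary squeeze first;
#'   responses at exactly 0 or 1 are a contract violation).
#' @param beta0,beta1 Intercept and slope (Hill coefficient) on the
#'   logit-log10 scale.
#' @param log_phi Log of the beta precision parameter.
#' @return The scalar log-likelihood.
#' @export
beta_loglik <- function(data, beta0, beta1, log_phi) {
  one <- check_one_agent(data)
  y <- one$response
  if (any(y <= 0 | y >= 1)) {
    stop_parameter(
      "Responses must lie strictly inside (0, 1); squeeze boundary values first.")
  }
  mu <- plogis(beta0 + beta1 * log10(one$dose))
  beta_loglik_vec(y, mu, exp(log_phi))
}

beta_loglik_vec <- function(y, mu, phi) {
  a <- mu * phi
  b <- (1 - mu) * phi
  sum(lgamma(phi) - lgamma(a) - lgamma(b) +
        (a - 1) * log(y) + (b - 1) * log1p(-y))
}

check_one_agent <- function(data) {
  if (!inherits(data, "dose_response")) {
    data <- dose_response(data)
  }
  agents <- unique(data$agent)
  if (length(agents) != 1) {
    stop_parameter(sprintf(
      "Expected data for exactly one agent, found %d.", length(agents)))
  }
  data
}

# Penalized log-likelihood: the ridge penalty applies to the slope only.
penalized_loglik <- function(x, y, beta0, beta1, log_phi, lambda) {
  mu <- plogis(beta0 + beta1 * x)
  beta_loglik_vec(y, mu, exp(log_phi)) - lambda / 2 * beta1^2
}

# Core engine: alternate (a) one penalized Fisher-scoring (PIRLS) update of
# (beta0, beta1) at fixed phi with lambda added to the slope entry of the
# normal-equations matrix, and (b) a safeguarded Newton maximization over
# log phi at fixed slope/intercept. Both steps are step-halved against the
# penalized log-likelihood, so the objective never decreases.
me_engine <- function(x, y, lambda, control = me_control()) {
  ystar <- qlogis(y)
  n <- length(y)

  # Starting values: OLS of logit(y) on log10(dose); method-of-moments phi.
  vx <- var(x)
  b1 <- if (vx > 0) cov(x, ystar) / vx else 0
  b0 <- mean(ystar) - b1 * mean(x)
  mu0 <- plogis(b0 + b1 * x)
  s2 <- mean((y - mu0)^2)
  phi0 <- if (s2 > 0) max(mean(mu0 * (1 - mu0)) / s2 - 1, 1) else 100
  th <- min(max(log(phi0), -5), 25)

  pll <- penalized_loglik(x, y, b0, b1, th, lambda)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(control$max_iter)) {
    old <- c(b0, b1, th)

    # (a) penalized scoring step for (beta0, beta1)
    phi <- exp(th)
    mu <- plogis(b0 + b1 * x)
    a <- mu * phi
    bb <- (1 - mu) * phi
    mustar <- digamma(a) - digamma(bb)
    d <- mu * (1 - mu)
    r <- d * (ystar - mustar)
    U0 <- phi * sum(r)
    U1 <- phi * sum(r * x) - lambda * b1
    w <- phi^2 * (trigamma(a) + trigamma(bb)) * d^2
    K00 <- sum(w)
    K01 <- sum(w * x)
    K11 <- sum(w * x^2) + lambda
    det <- K00 * K11 - K01^2
    if (is.finite(det) && det > 0) {
      db0 <- (K11 * U0 - K01 * U1) / det
      db1 <- (-K01 * U0 + K00 * U1) / det
      step <- 1
      repeat {
        cand <- penalized_loglik(x, y, b0 + step * db0, b1 + step * db1,
                                 th, lambda)
        if (is.finite(cand) && cand >= pll - 1e-12) {
          b0 <- b0 + step * db0
          b1 <- b1 + step * db1
          pll <- cand
          break
        }
        step <- step / 2
        if (step < 1e-10) break
      }
    }

    # (b) Newton maximization over log phi at fixed (beta0, beta1)
    mu <- plogis(b0 + b1 * x)
    for (inner in 1:50) {
      phi <- exp(th)
      a <- mu * phi
      bb <- (1 - mu) * phi
      dldphi <- sum(digamma(phi) - mu * digamma(a) - (1 - mu) * digamma(bb) +
                      mu * log(y) + (1 - mu) * log1p(-y))
      d2 <- sum(trigamma(phi) - mu^2 * trigamma(a) - (1 - mu)^2 * trigamma(bb))
      g <- phi * dldphi
      h <- phi^2 * d2 + phi * dldphi
      if (!is.finite(g) || !is.finite(h) || h >= 0) {
        opt <- optimize(function(t) penalized_loglik(x, y, b0, b1, t, lambda),
                        interval = c(-10, 30), maximum = TRUE, tol = 1e-10)
        th <- opt$maximum
        break
      }
      dth <- -g / h
      if (abs(dth) > 5) dth <- sign(dth) * 5
      step <- 1
      repeat {
        cand <- penalized_loglik(x, y, b0, b1, th + step * dth, lambda)
        if (is.finite(cand) && cand >= pll - 1e-12) {
          th <- th + step * dth
          pll <- cand
          break
        }
        step <- step / 2
        if (step < 1e-10) break
      }
      if (abs(step * dth) < control$tol / 10 || step < 1e-10) break
    }
    pll <- penalized_loglik(x, y, b0, b1, th, lambda)

    if (max(abs(c(b0, b1, th) - old)) < control$tol) {
      converged <- TRUE
      break
    }
  }

  info <- observed_information(x, y, b0, b1, th, lambda)
  cov3 <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, 3, 3)
  })
  coef_cov <- (cov3[1:2, 1:2] + t(cov3[1:2, 1:2])) / 2

  list(beta0 = b0, beta1 = b1, log_phi = th,
       coef_cov = coef_cov,
       loglik = beta_loglik_vec(y, plogis(b0 + b1 * x), exp(th)),
       converged = converged, n_iter = iter)
}

# Observed information (negative Hessian) of the penalized log-likelihood in
# (beta0, beta1, log phi), evaluated analytically.
observed_information <- function(x, y, b0, b1, th, lambda) {
  phi <- exp(th)
  ystar <- qlogis(y)
  mu <- plogis(b0 + b1 * x)
  a <- mu * phi
  b <- (1 - mu) * phi
  mustar <- digamma(a) - digamma(b)
  d <- mu * (1 - mu)

  dl_dmu <- phi * (ystar - mustar)
  d2l_dmu2 <- -phi^2 * (trigamma(a) + trigamma(b))
  d2l_dmudphi <- ystar - mustar - phi * (mu * trigamma(a) - (1 - mu) * trigamma(b))
  dl_dphi <- digamma(phi) - mu * digamma(a) - (1 - mu) * digamma(b) +
    mu * log(y) + (1 - mu) * log1p(-y)
  d2l_dphi2 <- trigamma(phi) - mu^2 * trigamma(a) - (1 - mu)^2 * trigamma(b)

  # chain rule to eta = b0 + b1 x and theta = log phi
  l_ee <- d2l_dmu2 * d^2 + dl_dmu * d * (1 - 2 * mu)
  l_et <- phi * d2l_dmudphi * d
  l_tt <- phi^2 * sum(d2l_dphi2) + phi * sum(dl_dphi)

  H <- matrix(0, 3, 3)
  H[1, 1] <- sum(l_ee)
  H[1, 2] <- H[2, 1] <- sum(l_ee * x)
  H[2, 2] <- sum(l_ee * x^2) - lambda
  H[1, 3] <- H[3, 1] <- sum(l_et)
  H[2, 3] <- H[3, 2] <- sum(l_et * x)
  H[3, 3] <- l_tt
  -H
}

new_me_fit <- function(agent, eng, lambda, estimator, alpha, n_obs,
                       boundary_adjusted, x, y, dose, response) {
  structure(
    list(agent = agent,
         beta0 = eng$beta0, beta1 = eng$beta1, log_phi = eng$log_phi,
         lambda = lambda, coef_cov = eng$coef_cov,
         loglik = eng$loglik, n_obs = n_obs,
         converged = eng$converged, n_iter = eng$n_iter,
         boundary_adjusted = boundary_adjusted,
         estimator = estimator, alpha = alpha,
         data = tibble::tibble(dose = dose, log10_dose = x,
                               response = response, response_adj = y)),
    class = "me_fit"
  )
}

#' Fit median-effect dose-response curves by (penalized) beta regression
#'
#' Fits, independently for each agent, the model
#' `y ~ Beta(mu * phi, (1 - mu) * phi)` with
#' `logit(mu) = beta0 + beta1 * log10(dose)` — the median-effect equation in
#' regression form, where `beta1` is the Hill coefficient m and the
#' median-effect dose is `Dm = 10^(-beta0 / beta1)`. Estimation maximizes the
#' log-likelihood minus a ridge penalty `lambda / 2 * beta1^2` on the slope
#' by penalized iteratively re-weighted least squares, alternating with a
#' one-dimensional Newton update of `log(phi)`.
#'
#' @param data A `"dose_response"` dataset (any number of agents) or a data
#'   frame accepted by [dose_response()].
#' @param estimator `"penalized"` (ridge, the default), `"mle"`
#'   (equivalently `lambda = 0`), or `"mdpd"` (robust minimum density power
#'   divergence, see [fit_mdpd()]).
#' @param lambda Non-negative ridge tuning parameter, or `"auto"` to select
#'   it per agent by stratified K-fold out-of-fold likelihood
#'   (see [select_lambda()]).
#' @param alpha MDPD tuning parameter in `[0, 1]`; used when
#'   `estimator = "mdpd"`.
#' @param lambda_grid Candidate grid for `lambda = "auto"`.
#' @param k_folds Number of cross-validation folds for `lambda = "auto"`.
#' @param fold_seed Seed controlling fold assignment (selection is
#'   deterministic given this seed).
#' @param control An [me_control()] list.
#'
#' @return An object of class `"me_fit_list"`: a named list with one
#'   `"me_fit"` per agent (first-appearance order). Each fit carries the
#'   coefficient estimates, the 2x2 covariance of (beta0, beta1) from the
#'   inverse penalized observed information, the unpenalized log-likelihood,
#'   convergence diagnostics and the count of boundary-adjusted responses.
#'   Use [tidy()] / [glance()] for tabular summaries.
#'
#' @examples
#' spec <- simulation_spec(m = 1.5, dm = 1, phi = 30,
#'                         doses = 10^seq(-2, 1.5, by = 0.5), reps = 3,
#'                         seed = 7)
#' fits <- fit_median_effect(simulate_dose_response(spec))
#' tidy(fits)
#' @export
fit_median_effect <- function(data,
                              estimator = c("penalized", "mle", "mdpd"),
                              lambda = "auto",
                              alpha = 0.5,
                              lambda_grid = default_lambda_grid(),
                              k_folds = 5L,
                              fold_seed = 1L,
                              control = me_control()) {
  estimator <- match.arg(estimator)
  if (!inherits(data, "dose_response")) data <- dose_response(data)
  agents <- attr(data, "agents")

  fits <- lapply(agents, function(a) {
    one <- agent_subset(data, a)
    fit_one_agent(one, estimator, lambda, alpha, lambda_grid,
                  k_folds, fold_seed, control)
  })
  names(fits) <- agents
  structure(fits, agents = agents, class = "me_fit_list")
}

fit_one_agent <- function(one, estimator, lambda, alpha, lambda_grid,
                          k_folds, fold_seed, control) {
  agent <- one$agent[1]
  x <- log10(one$dose)
  sq <- squeeze_boundary(one$response)
  y <- sq$y

  lam <- if (estimator == "mle") {
    0
  } else if (identical(lambda, "auto")) {
    select_lambda_one(x, y, grid = lambda_grid, k = k_folds,
                      fold_seed = fold_seed, control = control)
  } else {
    if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0) {
      stop_parameter("`lambda` must be a single non-negative number or \"auto\".")
    }
    lambda
  }

  eng <- me_engine(x, y, lam, control)
  if (!eng$converged) {
    warn(sprintf("Fit for agent '%s' did not converge in %d iterations.",
                 agent, control$max_iter))
  }
  fit <- new_me_fit(agent, eng, lam,
                    estimator = if (estimator == "mle") "mle" else "penalized",
                    alpha = NA_real_, n_obs = length(y),
                    boundary_adjusted = sq$n_adjusted,
                    x = x, y = y, dose = one$dose, response = one$response)
  if (estimator == "mdpd") {
    fit <- mdpd_refit(fit, alpha = alpha)
  }
  fit
}

#' Select the ridge tuning parameter by out-of-fold likelihood
#'
#' For each agent, evaluates each candidate `lambda` by stratified K-fold
#' cross-validation: folds are formed within each dose level (so every
#' training set spans the dose design), the model is fitted on the training
#' folds and the held-out beta log-likelihood is accumulated. The grid value
#' maximizing the out-of-fold log-likelihood is returned, with ties broken
#' toward the larger (more stabilizing) `lambda`.
#'
#' @inheritParams fit_median_effect
#' @param grid Candidate values, non-negative, ascending; should include a
#'   near-zero value.
#' @return A tibble with columns `agent` and `lambda`.
#' @export
select_lambda <- function(data, grid = default_lambda_grid(), k_folds = 5L,
                          fold_seed = 1L, control = me_control()) {
  if (!inherits(data, "dose_response")) data <- dose_response(data)
  if (length(grid) == 0 || any(!is.finite(grid)) || any(grid < 0)) {
    stop_parameter("`grid` must be a non-empty vector of non-negative values.")
  }
  agents <- attr(data, "agents")
  lam <- vapply(agents, function(a) {
    one <- agent_subset(data, a)
    sq <- squeeze_boundary(one$response)
    select_lambda_one(log10(one$dose), sq$y, grid = grid, k = k_folds,
                      fold_seed = fold_seed, control = control)
  }, numeric(1))
  tibble::tibble(agent = agents, lambda = unname(lam))
}

select_lambda_one <- function(x, y, grid, k, fold_seed, control) {
  grid <- sort(grid)
  if (length(grid) == 1) return(grid)
  n <- length(y)
  if (n < 4) {
    warn("Too few observations for cross-validation; using the smallest lambda.")
    return(grid[1])
  }

  folds <- make_folds(x, k, fold_seed)
  # Every training set must keep >= 3 distinct doses; otherwise retry
  # leave-one-out, and give up to the smallest grid value if even that fails.
  ok <- all(vapply(seq_len(max(folds)), function(f) {
    length(unique(x[folds != f])) >= 3
  }, logical(1)))
  if (!ok) {
    folds <- seq_len(n)
    ok <- all(vapply(seq_len(n), function(f) {
      length(unique(x[folds != f])) >= 3
    }, logical(1)))
    if (!ok) {
      warn("Dose design too sparse for cross-validation; using the smallest lambda.")
      return(grid[1])
    }
  }

  oof <- vapply(grid, function(lam) {
    total <- 0
    for (f in seq_len(max(folds))) {
      test <- folds == f
      eng <- me_engine(x[!test], y[!test], lam, control)
      mu <- plogis(eng$beta0 + eng$beta1 * x[test])
      total <- total + beta_loglik_vec(y[test], mu, exp(eng$log_phi))
    }
    total
  }, numeric(1))

  best <- max(oof)
  max(grid[oof >= best - 1e-9 * max(1, abs(best))])
}

# Stratified fold assignment: within each dose level, observations are
# shuffled (seeded) and dealt round-robin, with a rotating offset so fold
# sizes stay balanced across dose levels. Falls back to leave-one-out when
# n < 2 * k.
make_folds <- function(x, k, fold_seed) {
  n <- length(x)
  if (n < 2 * k) return(seq_len(n))
  folds <- integer(n)
  offset <- 0L
  local_seed(fold_seed, {
    for (lev in unique(x)) {
      idx <- which(x == lev)
      idx <- if (length(idx) > 1) sample(idx) else idx
      folds[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
      offset <- offset + length(idx)
    }
  })
  folds
}
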