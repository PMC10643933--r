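# Shared fixtures and independent oracles. Fixtures are generated in code;
# oracles deliberately avoid the package's fitting path.

std_doses <- function() 10^seq(-2, 1.5, by = 0.5)

# A clean simulated single-agent dataset at the reference study conditions.
clean_data <- function(seed, m = 1.5, dm = 1, phi = 30, reps = 3,
                       doses = std_doses()) {
  simulate_dose_response(simulation_spec(
    m = m, dm = dm, phi = phi, doses = doses, reps = reps, seed = seed))
}

# Independent oracle: brute-force maximization of the beta log-likelihood
# (built directly on stats::dbeta) over (beta0, beta1, log phi) by
# Nelder-Mead with restarts. Never touches the package's PIRLS engine.
oracle_fit <- function(dose, y, lambda = 0) {
  nll <- function(p) {
    mu <- plogis(p[1] + p[2] * log10(dose))
    val <- sum(dbeta(y, mu * exp(p[3]), (1 - mu) * exp(p[3]), log = TRUE)) -
      lambda / 2 * p[2]^2
    if (!is.finite(val)) return(1e10)
    -val
  }
  # data-driven start (OLS on the logit scale) plus fixed fallbacks
  x <- log10(dose)
  z <- qlogis(y)
  b1 <- cov(x, z) / var(x)
  b0 <- mean(z) - b1 * mean(x)
  mu0 <- plogis(b0 + b1 * x)
  s2 <- max(mean((y - mu0)^2), 1e-12)
  start_data <- c(b0, b1, log(max(mean(mu0 * (1 - mu0)) / s2 - 1, 1)))
  best <- NULL
  for (start in list(start_data, c(0, 1, log(10)), c(0.5, 2, log(30)),
                     c(-0.5, 0.5, log(5)))) {
    o <- optim(start, nll, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
    o <- optim(o$par, nll, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  list(par = best$par, loglik = -best$value)
}

# Squeeze exactly as the package defines it, for building oracle inputs.
squeeze_like_package <- function(y) {
  n <- length(y)
  at <- y == 0 | y == 1
  y[at] <- (y[at] * (n - 1) + 0.5) / n
  y
}

# Choose which responses to corrupt in outlier-robustness checks.
local_flip_idx <- function(seed, n, k = 3) {
  withr::with_seed(10000 + seed, sample(n, k))
}

# Central finite-difference Hessian of a scalar function (for covariance
# cross-checks).
fd_hessian <- function(f, par, eps = 1e-4) {
  k <- length(par)
  H <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in i:k) {
      pp <- function(si, sj) {
        p <- par
        p[i] <- p[i] + si * eps
        p[j] <- p[j] + sj * eps
        f(p)
      }
      H[i, j] <- H[j, i] <-
        (pp(1, 1) - pp(1, -1) - pp(-1, 1) + pp(-1, -1)) / (4 * eps^2)
    }
  }
  H
}
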