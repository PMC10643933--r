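#' @export
print.me_fit <- function(x, ...) {
  cat(sprintf("<me_fit: agent '%s' (%s)>\n", x$agent, x$estimator))
  cat(sprintf("  logit(fa) = %.4g + %.4g * log10(D)   [m = %.4g, Dm = %.4g]\n",
              x$beta0, x$beta1, x$beta1,
              if (abs(x$beta1) > 1e-8) 10^(-x$beta0 / x$beta1) else NA))
  cat(sprintf("  phi = %.4g, lambda = %.4g, logLik = %.4g, n = %d%s\n",
              exp(x$log_phi), x$lambda, x$loglik, x$n_obs,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' @export
print.me_fit_list <- function(x, ...) {
  cat(sprintf("<me_fit_list: %d agent(s)>\n", length(x)))
  for (f in x) print(f)
  invisible(x)
}

#' @export
coef.me_fit <- function(object, ...) {
  c(beta0 = object$beta0, beta1 = object$beta1, log_phi = object$log_phi)
}

#' @export
vcov.me_fit <- function(object, ...) {
  v <- object$coef_cov
  dimnames(v) <- list(c("beta0", "beta1"), c("beta0", "beta1"))
  v
}

#' @export
logLik.me_fit <- function(object, ...) {
  structure(object$loglik, df = 3L, nobs = object$n_obs, class = "logLik")
}

#' Tidy median-effect fits into a coefficient table
#'
#' @param x An `"me_fit"` or `"me_fit_list"` object.
#' @param conf.level Confidence level for the Wald intervals.
#' @param ... Unused.
#' @return A tibble with one row per agent and term (`beta0`, `beta1`,
#'   `log_phi`), with estimates, standard errors (delta-method, `NA` for
#'   `log_phi` which is profiled out of the reported covariance), z
#'   statistics and confidence bounds.
#' @method tidy me_fit
#' @export
tidy.me_fit <- function(x, conf.level = 0.95, ...) {
  se <- sqrt(pmax(diag(x$coef_cov), 0))
  z <- qnorm(1 - (1 - conf.level) / 2)
  est <- c(x$beta0, x$beta1, x$log_phi)
  ses <- c(se, NA_real_)
  tibble::tibble(
    agent = x$agent,
    term = c("beta0", "beta1", "log_phi"),
    estimate = est,
    std.error = ses,
    statistic = est / ses,
    conf.low = est - z * ses,
    conf.high = est + z * ses
  )
}

#' @rdname tidy.me_fit
#' @method tidy me_fit_list
#' @export
tidy.me_fit_list <- function(x, conf.level = 0.95, ...) {
  purrr::list_rbind(purrr::map(unclass(x), tidy, conf.level = conf.level))
}

#' One-row-per-agent fit summaries
#'
#' @param x An `"me_fit"` or `"me_fit_list"` object.
#' @param ... Unused.
#' @return A tibble with the Hill coefficient, median-effect dose `Dm`,
#'   precision, tuning parameter, log-likelihood and diagnostics per agent.
#' @method glance me_fit
#' @export
glance.me_fit <- function(x, ...) {
  tibble::tibble(
    agent = x$agent,
    estimator = x$estimator,
    hill = x$beta1,
    dm = if (abs(x$beta1) > 1e-8) 10^(-x$beta0 / x$beta1) else NA_real_,
    phi = exp(x$log_phi),
    lambda = x$lambda,
    logLik = x$loglik,
    n_obs = x$n_obs,
    n_iter = x$n_iter,
    converged = x$converged,
    boundary_adjusted = x$boundary_adjusted
  )
}

#' @rdname glance.me_fit
#' @method glance me_fit_list
#' @export
glance.me_fit_list <- function(x, ...) {
  purrr::list_rbind(purrr::map(unclass(x), glance))
}

# Coerce either fit class to a plain list of per-agent me_fit objects.
as_fit_list <- function(fit) {
  if (inherits(fit, "me_fit")) {
    out <- list(fit)
    names(out) <- fit$agent
    out
  } else if (inherits(fit, "me_fit_list")) {
    unclass(fit)
  } else {
    stop_parameter("Expected an 'me_fit' or 'me_fit_list' object.")
  }
}
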