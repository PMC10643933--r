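#' Estimate potency (ICx/ECx) at user-specified effect levels
#'
#' Inverts the fitted median-effect curve at each requested effect level x:
#' the dose giving a fraction-affected of x/100 is
#' `log10(Dx) = (logit(x/100) - beta0) / beta1`. The standard error of
#' `log10(Dx)` follows by the delta method with gradient
#' `(-1/beta1, -(logit(x/100) - beta0)/beta1^2)` applied to the coefficient
#' covariance; the confidence interval is formed on the log10-dose scale and
#' exponentiated, so it is asymmetric on the concentration scale. At x = 50
#' the estimate is the median-effect dose Dm (IC50/EC50).
#'
#' @param fit An `"me_fit"` or `"me_fit_list"` object.
#' @param x_percent Effect level(s), strictly between 0 and 100. May be a
#'   vector; one row is returned per agent and level.
#' @param level Confidence level in (0, 1).
#' @return A tibble with columns `agent`, `x_percent`, `log10_dose`, `dose`,
#'   `se_log10_dose`, `ci_low`, `ci_high` (dose scale) and `level`.
#' @examples
#' spec <- simulation_spec(m = 1.5, dm = 1, phi = 30,
#'                         doses = 10^seq(-2, 1.5, by = 0.5), reps = 3,
#'                         seed = 7)
#' fits <- fit_median_effect(simulate_dose_response(spec))
#' estimate_potency(fits, x_percent = c(50, 90))
#' @export
estimate_potency <- function(fit, x_percent = 50, level = 0.95) {
  fits <- as_fit_list(fit)
  check_level(level)
  if (any(!is.finite(x_percent) | x_percent <= 0 | x_percent >= 100)) {
    stop_parameter("`x_percent` values must lie strictly between 0 and 100.")
  }
  rows <- purrr::map(fits, function(f) {
    purrr::map(x_percent, function(x) potency_one(f, x, level))
  })
  purrr::list_rbind(purrr::map(rows, purrr::list_rbind))
}

potency_one <- function(f, x, level) {
  check_slope(f)
  lx <- qlogis(x / 100)
  ld <- (lx - f$beta0) / f$beta1
  g <- c(-1 / f$beta1, -(lx - f$beta0) / f$beta1^2)
  se <- sqrt(max(drop(t(g) %*% f$coef_cov %*% g), 0))
  z <- qnorm(1 - (1 - level) / 2)
  tibble::tibble(
    agent = f$agent,
    x_percent = x,
    log10_dose = ld,
    dose = 10^ld,
    se_log10_dose = se,
    ci_low = 10^(ld - z * se),
    ci_high = 10^(ld + z * se),
    level = level
  )
}

check_slope <- function(f) {
  if (!is.finite(f$beta1) || abs(f$beta1) < 1e-8) {
    stop_parameter(sprintf(
      "Slope for agent '%s' is degenerate (|beta1| < 1e-8); potency is undefined for a flat curve.",
      f$agent))
  }
  invisible(f)
}

check_level <- function(level) {
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    stop_parameter("`level` must be a single value in (0, 1).")
  }
  invisible(level)
}

#' Predicted effect along the dose axis
#'
#' Evaluates the fitted mean curve `mu = invlogit(beta0 + beta1 * log10(D))`
#' at the requested doses, with pointwise confidence bands computed on the
#' logit scale by the delta method and back-transformed — so the bounds
#' always lie strictly inside (0, 1).
#'
#' @param fit An `"me_fit"` or `"me_fit_list"` object.
#' @param doses Positive doses at which to predict.
#' @param level Confidence level in (0, 1).
#' @return A tibble with columns `agent`, `dose`, `estimate`, `conf.low`,
#'   `conf.high`.
#' @export
predict_effect <- function(fit, doses, level = 0.95) {
  fits <- as_fit_list(fit)
  check_level(level)
  if (any(!is.finite(doses) | doses <= 0)) {
    stop_parameter("`doses` must be strictly positive.")
  }
  z <- qnorm(1 - (1 - level) / 2)
  purrr::list_rbind(purrr::map(fits, function(f) {
    x <- log10(doses)
    eta <- f$beta0 + f$beta1 * x
    se_eta <- sqrt(pmax(
      f$coef_cov[1, 1] + 2 * x * f$coef_cov[1, 2] + x^2 * f$coef_cov[2, 2], 0))
    tibble::tibble(
      agent = f$agent,
      dose = doses,
      estimate = plogis(eta),
      conf.low = plogis(eta - z * se_eta),
      conf.high = plogis(eta + z * se_eta)
    )
  }))
}

#' Wald test of equal potency between two agents
#'
#' Tests whether two agents reach the same x% effect at the same
#' concentration. The difference is taken on the log10-dose scale,
#' `log10(Dx_a) - log10(Dx_b)`; since agents are fitted independently the
#' standard error of the difference is `sqrt(se_a^2 + se_b^2)`, and the
#' two-sided p-value comes from the standard normal reference.
#'
#' @param fit_a,fit_b Single-agent `"me_fit"` objects (or one-agent
#'   `"me_fit_list"`s).
#' @param x_percent Effect level, strictly between 0 and 100.
#' @return A one-row tibble with columns `agent_a`, `agent_b`, `quantity`,
#'   `x_percent`, `difference`, `se_difference`, `z`, `p_value`,
#'   `p_adjusted` (equal to `p_value`; adjustment happens in
#'   [pairwise_compare()]).
#' @export
compare_potency <- function(fit_a, fit_b, x_percent = 50) {
  a <- single_fit(fit_a)
  b <- single_fit(fit_b)
  pa <- potency_one(a, x_percent, 0.95)
  pb <- potency_one(b, x_percent, 0.95)
  wald_row(a$agent, b$agent, "potency", x_percent,
           pa$log10_dose - pb$log10_dose,
           sqrt(pa$se_log10_dose^2 + pb$se_log10_dose^2))
}

#' Wald test of equal Hill coefficients between two agents
#'
#' Compares the slopes (Hill coefficients m) of two independently fitted
#' agents: `difference = beta1_a - beta1_b`, with variance the sum of the
#' slope variances, against the standard normal.
#'
#' @inheritParams compare_potency
#' @return A one-row tibble in the same layout as [compare_potency()], with
#'   `quantity = "hill"` and `x_percent = NA`.
#' @export
compare_hill <- function(fit_a, fit_b) {
  a <- single_fit(fit_a)
  b <- single_fit(fit_b)
  wald_row(a$agent, b$agent, "hill", NA_real_,
           a$beta1 - b$beta1,
           sqrt(max(a$coef_cov[2, 2], 0) + max(b$coef_cov[2, 2], 0)))
}

wald_row <- function(agent_a, agent_b, quantity, x_percent, diff, se) {
  z <- if (se > 0) diff / se else if (diff == 0) 0 else sign(diff) * Inf
  p <- 2 * pnorm(-abs(z))
  tibble::tibble(
    agent_a = agent_a, agent_b = agent_b,
    quantity = quantity, x_percent = x_percent,
    difference = diff, se_difference = se,
    z = z, p_value = p, p_adjusted = p
  )
}

single_fit <- function(fit) {
  fits <- as_fit_list(fit)
  if (length(fits) != 1) {
    stop_parameter("Expected a fit for exactly one agent.")
  }
  f <- fits[[1]]
  if (!isTRUE(f$converged)) {
    warn(sprintf("Fit for agent '%s' did not converge; comparison may be unreliable.",
                 f$agent))
  }
  f
}

#' All pairwise potency and Hill-coefficient comparisons
#'
#' Runs [compare_potency()] and/or [compare_hill()] for every unordered pair
#' of agents (in first-appearance order) and optionally applies the Holm
#' step-down adjustment within each quantity family.
#'
#' @param fit An `"me_fit_list"` with at least two agents.
#' @param x_percent Effect level for the potency comparisons.
#' @param quantities Character subset of `c("potency", "hill")`.
#' @param adjustment `"none"` (then `p_adjusted == p_value`) or `"holm"`.
#' @return A tibble with one row per pair and quantity.
#' @export
pairwise_compare <- function(fit, x_percent = 50,
                             quantities = c("potency", "hill"),
                             adjustment = c("none", "holm")) {
  adjustment <- match.arg(adjustment)
  quantities <- match.arg(quantities, several.ok = TRUE)
  fits <- as_fit_list(fit)
  if (length(fits) < 2) {
    stop_parameter("Pairwise comparison requires at least 2 fitted agents.")
  }
  pairs <- utils::combn(seq_along(fits), 2)
  rows <- purrr::list_rbind(purrr::map(seq_len(ncol(pairs)), function(j) {
    a <- fits[[pairs[1, j]]]
    b <- fits[[pairs[2, j]]]
    out <- list()
    if ("potency" %in% quantities) {
      out <- c(out, list(compare_potency(a, b, x_percent = x_percent)))
    }
    if ("hill" %in% quantities) {
      out <- c(out, list(compare_hill(a, b)))
    }
    purrr::list_rbind(out)
  }))
  if (adjustment == "holm") {
    rows <- rows |>
      dplyr::group_by(.data$quantity) |>
      dplyr::mutate(p_adjusted = p.adjust(.data$p_value, method = "holm")) |>
      dplyr::ungroup()
  }
  rows
}
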