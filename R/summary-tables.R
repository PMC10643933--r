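#' Write analysis summary tables
#'
#' Writes the standard report of one analysis run to `out_dir`: four
#' human-readable CSV tables (4 significant digits) and one full-precision
#' structured JSON file.
#'
#' \describe{
#'   \item{`equations.csv`}{the fitted median-effect equation per agent, as
#'     text `logit(fa) = b0 + b1*log10(D)` plus the numeric coefficients.}
#'   \item{`hill.csv`}{Hill coefficient `m = beta1` with SE and Wald CI.}
#'   \item{`potency.csv`}{agent, effect level x, dose `Dx`,
#'     `SE(log10 Dx)` and the dose-scale CI.}
#'   \item{`comparisons.csv`}{pair, quantity, difference, SE, z, p and
#'     adjusted p (header-only when no comparisons were run).}
#'   \item{`results.json`}{all of the above at full double precision;
#'     re-reading it reproduces the coefficients bit-identically.}
#' }
#'
#' @param fits An `"me_fit_list"` (or single `"me_fit"`).
#' @param potencies Tibble from [estimate_potency()] (may be empty).
#' @param comparisons Tibble from [pairwise_compare()] or `NULL`.
#' @param out_dir Output directory; created if missing.
#' @param ci_level Level used for the reported Wald intervals.
#' @return (Invisibly) a tibble manifest of the written files.
#' @export
write_summary_tables <- function(fits, potencies = NULL, comparisons = NULL,
                                 out_dir, ci_level = 0.95) {
  fit_list <- as_fit_list(fits)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("Cannot create output directory '%s'.", out_dir),
                   class = "betadose_io_error")
  }
  if (file.access(out_dir, mode = 2) != 0) {
    abort(sprintf("Output directory '%s' is not writable.", out_dir),
          class = "betadose_io_error")
  }
  z <- qnorm(1 - (1 - ci_level) / 2)

  equations <- purrr::list_rbind(purrr::map(fit_list, function(f) {
    tibble::tibble(
      agent = f$agent,
      equation = sprintf("logit(fa) = %s + %s*log10(D)",
                         signif(f$beta0, 4), signif(f$beta1, 4)),
      beta0 = f$beta0, beta1 = f$beta1, phi = exp(f$log_phi),
      lambda = f$lambda, converged = f$converged
    )
  }))
  hill <- purrr::list_rbind(purrr::map(fit_list, function(f) {
    se <- sqrt(max(f$coef_cov[2, 2], 0))
    tibble::tibble(
      agent = f$agent, hill = f$beta1, se = se,
      ci_low = f$beta1 - z * se, ci_high = f$beta1 + z * se
    )
  }))
  if (is.null(potencies)) {
    potencies <- estimate_potency(fits, 50, ci_level)[0, ]
  }
  if (is.null(comparisons)) {
    comparisons <- wald_row("a", "b", "potency", 50, 0, 1)[0, ]
  }

  write4 <- function(df, path) {
    out <- dplyr::mutate(df, dplyr::across(
      dplyr::where(is.numeric), ~ signif(.x, 4)))
    readr::write_csv(out, path, progress = FALSE)
    path
  }
  paths <- c(
    equations = write4(equations, file.path(out_dir, "equations.csv")),
    hill = write4(hill, file.path(out_dir, "hill.csv")),
    potency = write4(potencies, file.path(out_dir, "potency.csv")),
    comparisons = write4(comparisons, file.path(out_dir, "comparisons.csv"))
  )

  results <- list(
    equations = equations,
    hill = hill,
    potency = potencies,
    comparisons = comparisons,
    fits = purrr::map(fit_list, function(f) {
      list(agent = f$agent, beta0 = f$beta0, beta1 = f$beta1,
           log_phi = f$log_phi, lambda = f$lambda,
           coef_cov = f$coef_cov, loglik = f$loglik, n_obs = f$n_obs,
           converged = f$converged, n_iter = f$n_iter,
           boundary_adjusted = f$boundary_adjusted,
           estimator = f$estimator)
    })
  )
  json_path <- file.path(out_dir, "results.json")
  # I(17) significant digits guarantee an exact double round-trip
  jsonlite::write_json(results, json_path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  paths <- c(paths, results = json_path)

  invisible(tibble::tibble(table = names(paths), path = unname(paths)))
}
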