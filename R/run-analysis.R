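#' Run a complete dose-response analysis
#'
#' The batch pipeline behind the command-line interface: read and validate
#' the input, fit every agent, estimate the requested potency levels, run
#' pairwise comparisons, and write the summary tables, a dense prediction
#' grid for curve plotting, and a warnings log.
#'
#' @param input Path to a CSV/TSV file or a data frame /
#'   `"dose_response"` object.
#' @param out_dir Output directory.
#' @param response_scale,orientation Passed to [dose_response()].
#' @param estimator,lambda,alpha,control Passed to [fit_median_effect()].
#' @param ic_levels Effect levels (x in ICx) to estimate; default 50.
#' @param level Confidence level for all intervals.
#' @param compare Which pairwise comparisons to run: `"potency"`, `"hill"`,
#'   `"both"`, or `"none"`.
#' @param adjust Multiplicity adjustment for the comparison table:
#'   `"holm"` (default here, matching a many-agent screen) or `"none"`.
#' @param seed Seed for the cross-validation fold assignment.
#'
#' @return (Invisibly) a list with elements `fits`, `potencies`,
#'   `comparisons`, `curves`, `manifest`, and `warnings`.
#'
#' @details Besides the tables of [write_summary_tables()], `curves.csv`
#'   holds, per agent, a 200-point dose grid spanning the observed doses
#'   plus 0.5 log10 units on each side with predicted fraction-affected and
#'   CI, and `run_log.txt` records dropped rows, boundary adjustments and
#'   convergence warnings. Per-agent failures are logged and skipped, never
#'   fatal, so a batch screen completes.
#' @export
run_analysis <- function(input, out_dir,
                         response_scale = "auto",
                         orientation = "affected",
                         estimator = "penalized",
                         lambda = "auto",
                         alpha = 0.5,
                         ic_levels = 50,
                         level = 0.95,
                         compare = c("both", "potency", "hill", "none"),
                         adjust = c("holm", "none"),
                         seed = 1L,
                         control = me_control()) {
  compare <- match.arg(compare)
  adjust <- match.arg(adjust)
  if (any(ic_levels <= 0 | ic_levels >= 100)) {
    stop_parameter("`ic_levels` must lie strictly between 0 and 100.")
  }
  log_lines <- character()
  note <- function(msg) log_lines <<- c(log_lines, msg)

  data <- if (is.character(input)) {
    read_dose_response(input, response_scale = response_scale,
                       orientation = orientation)
  } else if (inherits(input, "dose_response")) {
    input
  } else {
    dose_response(input, response_scale = response_scale,
                  orientation = orientation)
  }
  if (attr(data, "n_dropped") > 0) {
    note(sprintf("Excluded %d row(s) with dose <= 0.", attr(data, "n_dropped")))
  }

  fits <- withCallingHandlers(
    fit_median_effect(data, estimator = estimator, lambda = lambda,
                      alpha = alpha, fold_seed = seed, control = control),
    warning = function(w) {
      note(conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  for (f in as_fit_list(fits)) {
    if (f$boundary_adjusted > 0) {
      note(sprintf("Agent '%s': %d boundary response(s) squeezed into (0, 1).",
                   f$agent, f$boundary_adjusted))
    }
  }

  usable <- Filter(function(f) is.finite(f$beta1) && abs(f$beta1) >= 1e-8,
                   as_fit_list(fits))
  for (f in as_fit_list(fits)) {
    if (!f$agent %in% names(usable)) {
      note(sprintf("Agent '%s': degenerate (flat) fitted curve; excluded from potency and comparisons.",
                   f$agent))
    }
  }
  usable <- structure(usable, agents = names(usable), class = "me_fit_list")

  potencies <- if (length(usable) > 0) {
    estimate_potency(usable, x_percent = ic_levels, level = level)
  } else NULL

  comparisons <- NULL
  if (compare != "none") {
    quantities <- if (compare == "both") c("potency", "hill") else compare
    if (length(usable) >= 2) {
      comparisons <- purrr::list_rbind(purrr::map(ic_levels, function(x) {
        pairwise_compare(usable, x_percent = x, quantities = quantities,
                         adjustment = adjust)
      }))
      # hill rows do not depend on x, so drop their duplicates
      comparisons <- dplyr::distinct(comparisons)
    } else {
      note("Fewer than 2 usable agents; comparison table left empty.")
    }
  }

  manifest <- write_summary_tables(fits, potencies, comparisons, out_dir,
                                   ci_level = level)

  curves <- purrr::list_rbind(purrr::map(unclass(usable), function(f) {
    rng <- range(f$data$log10_dose)
    grid <- 10^seq(rng[1] - 0.5, rng[2] + 0.5, length.out = 200)
    predict_effect(f, grid, level = level)
  }))
  curves_path <- file.path(out_dir, "curves.csv")
  readr::write_csv(curves, curves_path, progress = FALSE)

  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(if (length(log_lines)) log_lines else "No warnings.", log_path)

  manifest <- dplyr::bind_rows(
    manifest,
    tibble::tibble(table = c("curves", "log"),
                   path = c(curves_path, log_path)))

  invisible(list(fits = fits, potencies = potencies,
                 comparisons = comparisons, curves = curves,
                 manifest = manifest, warnings = log_lines))
}
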