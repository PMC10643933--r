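#' Build a validated dose-response dataset
#'
#' Validates long-format dose-response observations (one row per well) and
#' returns a tibble in the package's canonical form: `agent` (label), `dose`
#' (positive concentration), `response` (fraction affected in `[0, 1]`) and,
#' when supplied, `replicate`. Percent responses are rescaled to fractions,
#' unaffected-fraction data are complemented so the stored response is always
#' the fraction affected, and rows with non-positive dose (e.g. vehicle
#' controls) are dropped and counted.
#'
#' @param data A data frame with one row per observation.
#' @param agent,dose,response,replicate Column names (strings) holding the
#'   agent label, dose, response, and optional replicate label.
#' @param response_scale `"fraction"`, `"percent"`, or `"auto"`. Under
#'   `"auto"` the input is treated as percent iff any response exceeds 1.5;
#'   fractional values in `(1, 1.5]` are rejected rather than silently
#'   rescaled.
#' @param orientation `"affected"` if the response is the fraction affected,
#'   `"unaffected"` if it is the surviving fraction (then `1 - response` is
#'   stored).
#'
#' @return A tibble of class `"dose_response"` with attributes
#'   `response_scale` (the resolved input dialect), `agents` (first-appearance
#'   agent order) and `n_dropped` (rows removed for `dose <= 0`).
#'
#' @details Every agent must retain at least 3 distinct dose levels after
#'   filtering: the mean curve has 2 parameters, so fewer doses leave no
#'   residual information. Doses at 0 cannot enter the model, whose predictor
#'   is log10(dose); they are surfaced via `attr(x, "n_dropped")` so that
#'   unnormalized input is noticed.
#'
#' @examples
#' df <- data.frame(agent = "A", dose = c(0.1, 1, 10),
#'                  response = c(20, 50, 80))
#' dr <- dose_response(df, response_scale = "percent")
#' dr$response
#' @export
dose_response <- function(data,
                          agent = "agent",
                          dose = "dose",
                          response = "response",
                          replicate = NULL,
                          response_scale = c("auto", "fraction", "percent"),
                          orientation = c("affected", "unaffected")) {
  response_scale <- match.arg(response_scale)
  orientation <- match.arg(orientation)
  if (!is.data.frame(data)) {
    stop_input("`data` must be a data frame.")
  }
  for (col in c(agent, dose, response)) {
    if (!col %in% names(data)) {
      stop_input(sprintf("Input is missing required column '%s'.", col))
    }
  }
  out <- tibble::tibble(
    agent = as.character(data[[agent]]),
    dose = as.numeric(data[[dose]]),
    response = as.numeric(data[[response]]),
    .row = seq_len(nrow(data))
  )
  if (!is.null(replicate)) {
    if (!replicate %in% names(data)) {
      stop_input(sprintf("Input is missing required column '%s'.", replicate))
    }
    out$replicate <- as.character(data[[replicate]])
  }
  if (anyNA(out$agent) || anyNA(out$response)) {
    bad <- out$.row[is.na(out$agent) | is.na(out$response)][1]
    stop_validation(sprintf("Missing agent or response value at row %d.", bad))
  }

  keep <- !is.na(out$dose) & out$dose > 0
  n_dropped <- sum(!keep)
  out <- out[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    stop_validation("No rows remain after removing non-positive doses.")
  }

  if (response_scale == "auto") {
    response_scale <- if (any(out$response > 1.5)) "percent" else "fraction"
  }
  if (response_scale == "percent") {
    out$response <- out$response / 100
  }
  bad <- which(out$response < 0 | out$response > 1)
  if (length(bad) > 0) {
    stop_validation(sprintf(
      "Response outside [0, 1] after normalization at row %d (value %.4g).",
      out$.row[bad[1]], out$response[bad[1]]
    ))
  }
  if (orientation == "unaffected") {
    out$response <- 1 - out$response
  }

  agents <- unique(out$agent)  # first-appearance order, never sorted
  for (a in agents) {
    n_doses <- length(unique(out$dose[out$agent == a]))
    if (n_doses < 3) {
      stop_validation(sprintf(
        "Agent '%s' has only %d distinct dose level(s); at least 3 are required.",
        a, n_doses
      ))
    }
  }

  out$.row <- NULL
  new_dose_response(out, response_scale = response_scale,
                    agents = agents, n_dropped = n_dropped)
}

new_dose_response <- function(x, response_scale, agents, n_dropped) {
  structure(
    x,
    response_scale = response_scale,
    agents = agents,
    n_dropped = n_dropped,
    class = c("dose_response", class(tibble::tibble()))
  )
}

#' Read a dose-response table from a delimited file
#'
#' Reads a CSV/TSV export (header row required; delimiter sniffed from the
#' file extension, then from the header line) and validates it with
#' [dose_response()].
#'
#' @param path Path to a delimited text file.
#' @inheritParams dose_response
#' @return A `"dose_response"` tibble; see [dose_response()].
#' @export
read_dose_response <- function(path,
                               agent = "agent",
                               dose = "dose",
                               response = "response",
                               replicate = NULL,
                               response_scale = c("auto", "fraction", "percent"),
                               orientation = c("affected", "unaffected")) {
  if (!file.exists(path)) {
    stop_input(sprintf("Input file '%s' does not exist.", path))
  }
  delim <- sniff_delim(path)
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, trim_ws = TRUE)
  dose_response(raw, agent = agent, dose = dose, response = response,
                replicate = replicate, response_scale = response_scale,
                orientation = orientation)
}

sniff_delim <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") return(",")
  if (ext %in% c("tsv", "tab")) return("\t")
  header <- readLines(path, n = 1L)
  if (lengths(regmatches(header, gregexpr("\t", header))) >=
      lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
}

#' @export
print.dose_response <- function(x, ...) {
  agents <- attr(x, "agents")
  cat(sprintf("<dose_response: %d observations, %d agent%s (%s)>\n",
              nrow(x), length(agents), if (length(agents) == 1) "" else "s",
              paste(agents, collapse = ", ")))
  if (attr(x, "n_dropped") > 0) {
    cat(sprintf("  %d row(s) with dose <= 0 were excluded\n",
                attr(x, "n_dropped")))
  }
  NextMethod()
}

# Extract the observations of a single agent, preserving attributes.
agent_subset <- function(data, agent) {
  stopifnot(inherits(data, "dose_response"))
  if (!agent %in% attr(data, "agents")) {
    stop_parameter(sprintf("Agent '%s' not present in the dataset.", agent))
  }
  new_dose_response(
    tibble::as_tibble(data)[data$agent == agent, , drop = FALSE],
    response_scale = attr(data, "response_scale"),
    agents = agent,
    n_dropped = 0L
  )
}
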