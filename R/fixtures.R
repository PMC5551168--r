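# Ingestion of the packaged published coefficient table and of published
# reference prevalence estimates.

#' Load the packaged published coefficient table
#'
#' @param path path to a coefficient-table JSON; defaults to the packaged
#'   transcription.
#' @return the parsed fixture (list) of class `coefficient_table`.
#' @export
load_coefficient_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "published_coefficients.json", package = "tractrisk",
                        mustWork = TRUE)
  fx <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  for (m in names(fx$models)) {
    fam <- fx$models[[m]]$family
    if (!(fam %in% c("logistic", "linear")))
      stop_config("fixture model '%s' has unknown family '%s'", m, fam)
  }
  class(fx) <- "coefficient_table"
  fx
}

#' Build a model from the published coefficient table
#'
#' Assembles a [fitted_model()] from the transcribed coefficients of one
#' outcome. Variables the published table marks NS (dropped during the
#' original backward selection) or N/A (not considered, given the chain
#' order) are absent from the term blocks. The published table prints no
#' intercepts, so the returned model is flagged uncalibrated and must be
#' passed through [calibrate_intercept()] before prediction; no standard
#' errors are available either, so coefficient-draw Monte Carlo cannot use
#' these models.
#'
#' @param outcome one of "exercise", "fruitveg", "bmi", "diabetes".
#' @param fixture a parsed table from [load_coefficient_table()].
#' @return an (uncalibrated) [fitted_model()].
#' @export
model_from_table <- function(outcome, fixture = load_coefficient_table()) {
  entry <- fixture$models[[outcome]]
  if (is.null(entry))
    stop_config("unknown outcome '%s'; fixture provides: %s", outcome,
                paste(names(fixture$models), collapse = ", "))
  terms <- entry$terms
  vars <- vapply(terms, `[[`, character(1), "variable")
  blocks <- lapply(unique(vars), function(v) {
    ts <- terms[vars == v]
    type <- ts[[1]]$type
    est <- vapply(ts, `[[`, numeric(1), "estimate")
    if (type == "categorical") {
      term_block(v, "categorical",
                 categories = vapply(ts, `[[`, character(1), "category"),
                 reference = fixture$references[[v]],
                 estimate = est)
    } else {
      term_block(v, type, estimate = est)
    }
  })
  dropped <- stats::setNames(rep(NA_real_, length(entry$ns_variables)),
                             unlist(entry$ns_variables))
  fitted_model(fixture$outcome_columns[[outcome]], entry$family,
               intercept = NA_real_, blocks = blocks,
               dropped = dropped, calibrated = FALSE)
}

#' A published reference prevalence estimate
#'
#' @param label source label.
#' @param outcome outcome name.
#' @param prevalence point prevalence (percent).
#' @param ci_lower,ci_upper 95% interval bounds (percent).
#' @return object of class `reference_estimate`.
#' @export
reference_estimate <- function(label, outcome, prevalence, ci_lower, ci_upper) {
  if (!is.finite(ci_lower) || !is.finite(ci_upper) || ci_lower > ci_upper)
    stop_config("malformed interval [%s, %s]", format(ci_lower), format(ci_upper))
  if (prevalence < ci_lower || prevalence > ci_upper)
    stop_config("prevalence %s outside its interval [%s, %s]",
                format(prevalence), format(ci_lower), format(ci_upper))
  structure(list(label = label, outcome = outcome, prevalence = prevalence,
                 ci_lower = ci_lower, ci_upper = ci_upper),
            class = "reference_estimate")
}

#' Load packaged published reference prevalences
#'
#' City and state behavioral-surveillance prevalence estimates (percent,
#' with 95% confidence intervals) for exercise, fruit/vegetable consumption,
#' and diabetes among adults 21 and older, alongside the published
#' synthetic-microdata estimates, used for consistency evaluation by
#' confidence-interval overlap.
#'
#' @param path CSV path; defaults to the packaged file.
#' @return data frame with label, outcome, prevalence, ci_lower, ci_upper.
#' @export
load_reference_estimates <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "reference_prevalence.csv", package = "tractrisk",
                        mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
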