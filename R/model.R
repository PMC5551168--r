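#' Construct a term block for an outcome model
#'
#' A block is the unit at which variables enter and leave a model: the full
#' set of non-reference indicator coefficients for a categorical variable, a
#' single 0/1 indicator, or a single continuous slope. Blocks are tested and
#' removed as a unit during backward selection, mirroring how published
#' coefficient tables annotate whole variables as non-significant.
#'
#' @param variable column name in the data the block reads.
#' @param type one of "categorical", "binary", "continuous".
#' @param categories for categorical blocks, the non-reference category
#'   labels in model column order.
#' @param reference for categorical blocks, the reference category (implicit
#'   coefficient 0); for binary blocks the implicit reference is 0.
#' @param estimate,se,p optional numeric vectors aligned with `categories`
#'   (length 1 for binary/continuous) carrying known coefficients.
#' @return an object of class `term_block`.
#' @export
term_block <- function(variable, type = c("categorical", "binary", "continuous"),
                       categories = NULL, reference = NULL,
                       estimate = NULL, se = NULL, p = NULL) {
  type <- match.arg(type)
  if (type == "categorical") {
    if (is.null(categories) || length(categories) < 1L)
      stop_config("categorical block '%s' needs at least one non-reference category", variable)
    if (is.null(reference))
      stop_config("categorical block '%s' needs a reference category", variable)
    if (reference %in% categories)
      stop_config("reference category '%s' of block '%s' must not appear among its categories",
                  reference, variable)
    k <- length(categories)
  } else {
    categories <- variable
    reference <- NULL
    k <- 1L
  }
  blk <- list(
    variable = variable, type = type,
    categories = as.character(categories), reference = reference,
    estimate = if (is.null(estimate)) rep(NA_real_, k) else as.numeric(estimate),
    se = if (is.null(se)) rep(NA_real_, k) else as.numeric(se),
    p = if (is.null(p)) rep(NA_real_, k) else as.numeric(p)
  )
  if (length(blk$estimate) != k || length(blk$se) != k || length(blk$p) != k)
    stop_config("block '%s': estimate/se/p must have length %d", variable, k)
  class(blk) <- "term_block"
  blk
}

#' Construct a fitted (or known-truth) outcome model
#'
#' The container used for models fitted from survey data, for the generating
#' models of the synthetic-data module, and for models ingested from published
#' coefficient tables. Reference categories carry an implicit coefficient of
#' zero. An `NA` intercept marks a model ingested from a published table that
#' prints no intercept; such a model must be calibrated (see
#' [calibrate_intercept()]) before it can produce predictions.
#'
#' @param outcome name of the outcome column the model predicts.
#' @param family "logistic" or "linear".
#' @param intercept numeric intercept (NA for uncalibrated ingested models).
#' @param blocks list of [term_block()] objects.
#' @param intercept_se standard error of the intercept, if known.
#' @param sigma residual standard deviation (linear models only).
#' @param block_p named numeric vector of block-level Wald p-values.
#' @param n_used number of observations used in fitting.
#' @param dropped named character vector describing removed blocks.
#' @param vcov covariance matrix of (intercept, coefficients), if available.
#' @param calibrated logical; FALSE marks an uncalibrated ingested intercept.
#' @return an object of class `fitted_model`.
#' @export
fitted_model <- function(outcome, family = c("logistic", "linear"), intercept,
                         blocks, intercept_se = NA_real_, sigma = NA_real_,
                         block_p = NULL, n_used = NA_integer_,
                         dropped = character(), vcov = NULL,
                         calibrated = !is.na(intercept)) {
  family <- match.arg(family)
  stopifnot(is.list(blocks))
  for (b in blocks) {
    if (!inherits(b, "term_block")) stop_config("blocks must be term_block objects")
    if (identical(b$variable, outcome))
      stop_config("outcome '%s' cannot appear among its own predictors", outcome)
  }
  names(blocks) <- vapply(blocks, `[[`, character(1), "variable")
  m <- list(
    outcome = outcome, family = family,
    intercept = as.numeric(intercept), intercept_se = as.numeric(intercept_se),
    sigma = as.numeric(sigma), blocks = blocks, block_p = block_p,
    n_used = n_used, dropped = dropped, vcov = vcov,
    calibrated = isTRUE(calibrated)
  )
  class(m) <- "fitted_model"
  m
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf("<fitted_model> outcome=%s family=%s intercept=%s%s\n",
              x$outcome, x$family,
              if (is.na(x$intercept)) "uncalibrated" else format(x$intercept, digits = 4),
              if (is.na(x$n_used)) "" else sprintf(" n=%d", x$n_used)))
  for (b in x$blocks) {
    lab <- if (b$type == "categorical")
      paste0(b$variable, " [ref ", b$reference, "]: ",
             paste(sprintf("%s=%.3g", b$categories, b$estimate), collapse = ", "))
    else sprintf("%s (%s): %.3g", b$variable, b$type, b$estimate)
    cat(" ", lab, "\n")
  }
  if (length(x$dropped))
    cat("  dropped:", paste(names(x$dropped), collapse = ", "), "\n")
  invisible(x)
}

# Flat coefficient vector (excluding intercept), named by column label.
model_coefficients <- function(model) {
  out <- numeric(0)
  for (b in model$blocks) {
    est <- b$estimate
    names(est) <- if (b$type == "categorical")
      paste(b$variable, b$categories, sep = ".") else b$variable
    out <- c(out, est)
  }
  out
}

#' Serialize a fitted model to JSON
#'
#' @param model a [fitted_model()].
#' @param path file path; if NULL the JSON string is returned.
#' @return the path (invisibly) or a JSON string.
#' @export
model_to_json <- function(model, path = NULL) {
  obj <- list(
    outcome = model$outcome, family = model$family,
    intercept = model$intercept, intercept_se = model$intercept_se,
    sigma = model$sigma, calibrated = model$calibrated,
    n_used = model$n_used, dropped = as.list(model$dropped),
    block_p = as.list(model$block_p),
    blocks = lapply(unname(model$blocks), function(b) {
      list(variable = b$variable, type = b$type,
           categories = b$categories, reference = b$reference,
           estimate = b$estimate, se = b$se, p = b$p)
    })
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Deserialize a fitted model from JSON
#'
#' @param path file path or JSON string produced by [model_to_json()].
#' @return a [fitted_model()].
#' @export
model_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  blocks <- lapply(obj$blocks, function(b) {
    term_block(b$variable, b$type,
               categories = if (b$type == "categorical") unlist(b$categories) else NULL,
               reference = b$reference,
               estimate = unlist(b$estimate), se = unlist(b$se), p = unlist(b$p))
  })
  fitted_model(obj$outcome, obj$family, intercept = obj$intercept %||% NA_real_,
               blocks = blocks, intercept_se = obj$intercept_se %||% NA_real_,
               sigma = obj$sigma %||% NA_real_,
               block_p = unlist(obj$block_p),
               n_used = obj$n_used %||% NA_integer_,
               dropped = unlist(obj$dropped) %||% character(),
               calibrated = isTRUE(obj$calibrated))
}
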