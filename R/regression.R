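# Multivariable logistic and linear outcome models fitted from survey data
# with block-wise backward selection: whole categorical variables (blocks)
# are the unit of removal, tested with Wald chi-square statistics, and a
# block is dropped when its block-level p-value exceeds 0.05.

#' Candidate model specification
#'
#' @param outcome outcome column name.
#' @param family "logistic" or "linear".
#' @param blocks ordered list of candidate [term_block()]s.
#' @param stage chain stage index (1-based).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(outcome, family = c("logistic", "linear"), blocks, stage = NA_integer_) {
  family <- match.arg(family)
  for (b in blocks) {
    if (!inherits(b, "term_block")) stop_config("blocks must be term_block objects")
    if (identical(b$variable, outcome))
      stop_config("outcome '%s' cannot be one of its own predictors", outcome)
  }
  if (length(blocks) < 1L) stop_config("a model spec needs at least one candidate block")
  names(blocks) <- vapply(blocks, `[[`, character(1), "variable")
  structure(list(outcome = outcome, family = family, blocks = blocks,
                 stage = as.integer(stage)),
            class = "model_spec")
}

#' Encode a design matrix from survey data
#'
#' Reference-cell dummy coding in deterministic column order (block order,
#' then category order). Rows with missing values in any used column are
#' dropped and counted.
#'
#' @param data survey data frame.
#' @param spec a [model_spec()].
#' @return object of class `design`: `X` (no intercept column), `response`,
#'   `blocks`, `col_block` (column-to-block map), `outcome`, `family`,
#'   `n_dropped`.
#' @export
encode_design <- function(data, spec) {
  used <- c(spec$outcome, vapply(spec$blocks, `[[`, character(1), "variable"))
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols))
    stop_config("data lacks column(s): %s", paste(missing_cols, collapse = ", "))
  cc <- stats::complete.cases(data[used])
  n_dropped <- sum(!cc)
  d <- data[cc, used, drop = FALSE]

  cols <- list()
  col_block <- integer(0)
  for (bi in seq_along(spec$blocks)) {
    b <- spec$blocks[[bi]]
    v <- d[[b$variable]]
    if (b$type == "categorical") {
      ok <- v %in% c(b$categories, b$reference)
      if (!all(ok))
        stop_config("variable '%s' has value '%s' outside the declared categories",
                    b$variable, v[which(!ok)[1]])
      for (cat in b$categories) {
        col <- as.numeric(v == cat)
        if (sum(col) == 0L)
          stop_config("category '%s' of variable '%s' has no observations after filtering",
                      cat, b$variable)
        cols[[paste(b$variable, cat, sep = ".")]] <- col
        col_block <- c(col_block, bi)
      }
    } else {
      cols[[b$variable]] <- as.numeric(v)
      col_block <- c(col_block, bi)
    }
  }
  X <- do.call(cbind, cols)
  structure(list(X = X, response = d[[spec$outcome]], blocks = spec$blocks,
                 col_block = col_block, outcome = spec$outcome,
                 family = spec$family, n_dropped = n_dropped),
            class = "design")
}

# Assemble a fitted_model from a coefficient fit on a design.
build_fitted <- function(design, est, se, p, vcov, n, sigma = NA_real_,
                         dropped = character()) {
  blocks <- design$blocks
  k <- 1L
  for (bi in seq_along(blocks)) {
    nb <- length(blocks[[bi]]$estimate)
    idx <- k:(k + nb - 1L)
    blocks[[bi]]$estimate <- unname(est[idx + 1L])  # +1 skips intercept
    blocks[[bi]]$se <- unname(se[idx + 1L])
    blocks[[bi]]$p <- unname(p[idx + 1L])
    k <- k + nb
  }
  m <- fitted_model(design$outcome,
                    family = design$family,
                    intercept = unname(est[1L]), intercept_se = unname(se[1L]),
                    sigma = sigma, blocks = blocks, n_used = n,
                    dropped = dropped, vcov = vcov)
  bp <- vapply(names(m$blocks), function(v) block_p_value(m, v), numeric(1))
  m$block_p <- bp
  m
}

#' Fit a logistic model on an encoded design
#'
#' Maximum likelihood by iteratively reweighted least squares (tolerance
#' 1e-8, at most 100 iterations); Wald standard errors from the observed
#' information. Complete separation and degenerate responses raise
#' diagnostic errors.
#'
#' @param design a `design` from [encode_design()].
#' @param response optional response override (defaults to the design's).
#' @return a [fitted_model()].
#' @export
fit_logistic <- function(design, response = design$response) {
  y <- as.numeric(response)
  if (!all(y %in% c(0, 1))) stop_config("logistic response must be binary 0/1")
  if (length(unique(y)) < 2L)
    stop_config("degenerate response: all observations are %d (complete separation)", y[1])
  Xi <- cbind(`(Intercept)` = 1, design$X)
  fit <- suppressWarnings(stats::glm.fit(Xi, y, family = stats::binomial(),
                                         control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  if (!fit$converged)
    stop_config("logistic fit for '%s' did not converge within 100 iterations", design$outcome)
  mu <- fit$fitted.values
  if (max(abs(fit$coefficients), na.rm = TRUE) > 15 && all(pmin(mu, 1 - mu) < 1e-6))
    stop_config("complete separation detected in the fit for '%s'", design$outcome)
  if (anyNA(fit$coefficients)) {
    bad <- colnames(Xi)[is.na(fit$coefficients)]
    stop_config("rank-deficient design for '%s'; collinear column(s): %s",
                design$outcome, paste(bad, collapse = ", "))
  }
  p <- ncol(Xi)
  R <- qr.R(fit$qr)[seq_len(p), seq_len(p), drop = FALSE]
  piv <- fit$qr$pivot
  vcov <- matrix(NA_real_, p, p)
  vcov[piv, piv] <- chol2inv(R)
  dimnames(vcov) <- list(colnames(Xi), colnames(Xi))
  se <- sqrt(diag(vcov))
  z <- fit$coefficients / se
  pval <- 2 * stats::pnorm(-abs(z))
  build_fitted(design, fit$coefficients, se, pval, vcov, n = length(y))
}

#' Fit a linear model on an encoded design
#'
#' Ordinary least squares; standard errors from the residual variance.
#'
#' @inheritParams fit_logistic
#' @return a [fitted_model()].
#' @export
fit_linear <- function(design, response = design$response) {
  y <- as.numeric(response)
  if (any(!is.finite(y))) stop_config("linear response must be finite")
  Xi <- cbind(`(Intercept)` = 1, design$X)
  fit <- stats::lm.fit(Xi, y)
  p <- ncol(Xi)
  if (fit$rank < p) {
    bad <- colnames(Xi)[fit$qr$pivot[(fit$rank + 1L):p]]
    stop_config("rank-deficient design for '%s'; collinear column(s): %s",
                design$outcome, paste(bad, collapse = ", "))
  }
  rss <- sum(fit$residuals^2)
  df <- length(y) - p
  sigma2 <- if (df > 0) rss / df else 0
  R <- qr.R(fit$qr)[seq_len(p), seq_len(p), drop = FALSE]
  # undo pivoting
  piv <- fit$qr$pivot
  xtxinv <- chol2inv(R)
  vcov <- matrix(NA_real_, p, p)
  vcov[piv, piv] <- sigma2 * xtxinv
  dimnames(vcov) <- list(colnames(Xi), colnames(Xi))
  se <- sqrt(diag(vcov))
  tt <- fit$coefficients / se
  pval <- if (df > 0) 2 * stats::pt(-abs(tt), df) else rep(NA_real_, p)
  build_fitted(design, fit$coefficients, se, pval, vcov, n = length(y),
               sigma = sqrt(sigma2))
}

block_colnames <- function(b) {
  if (b$type == "categorical") paste(b$variable, b$categories, sep = ".") else b$variable
}

#' Block-level Wald p-value
#'
#' Wald chi-square test that all coefficients of the block are
#' simultaneously zero; degrees of freedom equal the number of non-reference
#' categories (1 for binary/continuous blocks).
#'
#' @param model a [fitted_model()] with a covariance matrix.
#' @param variable name of a retained block.
#' @return p-value in \[0, 1\].
#' @export
block_p_value <- function(model, variable) {
  b <- model$blocks[[variable]]
  if (is.null(b)) stop_config("variable '%s' is not retained in the model", variable)
  if (is.null(model$vcov)) stop_config("model carries no covariance matrix")
  cols <- block_colnames(b)
  V <- model$vcov[cols, cols, drop = FALSE]
  beta <- b$estimate
  stat <- drop(t(beta) %*% solve(V, beta))
  stats::pchisq(stat, df = length(beta), lower.tail = FALSE)
}

fit_design <- function(design) {
  if (design$family == "logistic") fit_logistic(design) else fit_linear(design)
}

#' Backward selection over candidate blocks
#'
#' Iteratively fits the model, finds the retained block with the largest
#' block-level Wald p-value, and removes the whole block when that p-value
#' exceeds `alpha`, refitting until every retained block is significant at
#' `alpha` or no block remains. Ties are broken by earliest block order.
#'
#' @param data survey data frame.
#' @param spec a [model_spec()].
#' @param alpha drop criterion: a block is removed when its p-value is
#'   greater than `alpha` (default 0.05).
#' @return a [fitted_model()] whose `dropped` field records the removal
#'   history (removal-order p-values, named by variable).
#' @export
backward_select <- function(data, spec, alpha = 0.05) {
  # complete cases over the full candidate set, so every refit sees the same
  # observations
  used <- c(spec$outcome, vapply(spec$blocks, `[[`, character(1), "variable"))
  used <- intersect(used, names(data))
  data <- data[stats::complete.cases(data[used]), , drop = FALSE]

  current <- spec
  removed <- numeric(0)
  repeat {
    if (length(current$blocks) == 0L) {
      warning(sprintf("all candidate blocks removed for '%s'; returning an intercept-only model",
                      spec$outcome))
      return(fit_intercept_only(data, spec, removed))
    }
    model <- fit_design(encode_design(data, current))
    bp <- model$block_p
    worst <- which.max(bp)  # first index on ties = earliest block order
    if (bp[worst] > alpha) {
      removed <- c(removed, stats::setNames(bp[worst], names(bp)[worst]))
      current$blocks[[names(bp)[worst]]] <- NULL
    } else {
      model$dropped <- removed
      return(model)
    }
  }
}

fit_intercept_only <- function(data, spec, removed) {
  y <- as.numeric(data[[spec$outcome]])
  if (spec$family == "logistic") {
    phat <- mean(y)
    fitted_model(spec$outcome, "logistic", intercept = logit(phat),
                 blocks = list(), n_used = length(y), dropped = removed,
                 intercept_se = 1 / sqrt(length(y) * phat * (1 - phat)))
  } else {
    fitted_model(spec$outcome, "linear", intercept = mean(y),
                 blocks = list(), n_used = length(y), dropped = removed,
                 intercept_se = stats::sd(y) / sqrt(length(y)),
                 sigma = stats::sd(y))
  }
}

# ---- chain fitting ----------------------------------------------------------

#' Default candidate specifications for the outcome chain
#'
#' Each stage considers the demographic variables (sex, age band,
#' race/ethnicity, income band, education), smoking and alcohol status, and
#' every earlier-stage outcome, matching the order in which the models are
#' built: exercise, fruit/vegetable consumption, BMI (linear), diabetes
#' (with BMI entering as its category).
#'
#' @return named list of [model_spec()]s in chain order.
#' @export
default_model_specs <- function() {
  cats <- default_categories()
  demo <- function() list(
    term_block("sex", "categorical", categories = "male", reference = "female"),
    term_block("age_band", "categorical",
               categories = setdiff(ADULT_AGE_BANDS, "80-99"), reference = "80-99"),
    term_block("race_ethnicity", "categorical",
               categories = c("black_nh", "hispanic", "other"), reference = "white_nh"),
    term_block("income_band", "categorical",
               categories = c("lt25k", "25-35k"), reference = "gte35k"),
    term_block("education", "categorical",
               categories = c("lt_hs", "hs"), reference = "gt_hs"),
    term_block("smoking", "categorical",
               categories = c("current", "former"), reference = "never"),
    term_block("alcohol_any_30d", "binary")
  )
  list(
    exercise = model_spec("exercise_any_30d", "logistic", demo(), stage = 1L),
    fruitveg = model_spec("fruitveg_5plus", "logistic",
                          c(demo(), list(term_block("exercise_any_30d", "binary"))),
                          stage = 2L),
    bmi = model_spec("bmi_value", "linear",
                     c(demo(), list(term_block("exercise_any_30d", "binary"),
                                    term_block("fruitveg_5plus", "binary"))),
                     stage = 3L),
    diabetes = model_spec("diabetes", "logistic",
                          c(demo(), list(
                            term_block("exercise_any_30d", "binary"),
                            term_block("fruitveg_5plus", "binary"),
                            term_block("bmi_category", "categorical",
                                       categories = c("normal", "overweight", "obese"),
                                       reference = "underweight"))),
                          stage = 4L)
  )
}

chain_base_vars <- c("sex", "age_band", "race_ethnicity", "education",
                     "income_band", "employment", "ancestry",
                     "smoking", "alcohol_any_30d")

chain_spec_provides <- function(outcome) {
  switch(outcome,
         exercise_any_30d = "exercise_any_30d",
         fruitveg_5plus = "fruitveg_5plus",
         bmi_value = c("bmi_value", "bmi_category"),
         diabetes = "diabetes",
         outcome)
}

#' Fit the full outcome chain with backward selection
#'
#' Fits the specs in order; each stage's candidate predictors may only be
#' demographics, smoking/alcohol, or outcomes of earlier stages (observed
#' survey values, not predictions, are used as predictors during fitting). A
#' spec that references a later-stage outcome is a configuration error.
#'
#' @param data survey data frame.
#' @param specs ordered list of [model_spec()]s (default
#'   [default_model_specs()]).
#' @param alpha block-drop criterion.
#' @return named list of [fitted_model()]s.
#' @export
fit_chain <- function(data, specs = default_model_specs(), alpha = 0.05) {
  available <- chain_base_vars
  out <- vector("list", length(specs))
  names(out) <- names(specs)
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    used <- vapply(spec$blocks, `[[`, character(1), "variable")
    bad <- setdiff(used, available)
    if (length(bad))
      stop_config("spec for '%s' uses predictor(s) not available at its chain stage: %s",
                  spec$outcome, paste(bad, collapse = ", "))
    out[[i]] <- backward_select(data, spec, alpha = alpha)
    available <- c(available, chain_spec_provides(spec$outcome))
  }
  out
}
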