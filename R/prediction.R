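# Application of the outcome-model chain to the synthetic population and
# Monte Carlo propagation of uncertainty to tract-level prevalences.

#' Restrict a population to prediction-eligible individuals
#'
#' The behavioral models include alcohol consumption, so prediction is
#' restricted to individuals of legal drinking age: 21 and older (inclusive)
#' by default.
#'
#' @param pop a `population`, `microdata`, synthetic population, or plain
#'   data frame of individuals with an `age_years` column.
#' @param min_age eligibility threshold in years.
#' @param quiet suppress the message reporting how many were removed.
#' @return the same structure with only eligible individuals. Idempotent.
#' @export
eligible_population <- function(pop, min_age = 21, quiet = FALSE) {
  filter_df <- function(df) {
    keep <- df$age_years >= min_age
    if (!quiet) message(sprintf("eligible_population: removed %d of %d individuals under age %s",
                                sum(!keep), length(keep), format(min_age)))
    if (!any(keep) && !quiet) warning("no individuals remain after the age filter")
    df[keep, , drop = FALSE]
  }
  if (is.data.frame(pop)) return(filter_df(pop))
  if (is.list(pop) && !is.null(pop$individuals)) {
    pop$individuals <- filter_df(pop$individuals)
    return(pop)
  }
  stop_config("eligible_population: unsupported input")
}

require_calibrated <- function(model) {
  if (is.na(model$intercept) || !isTRUE(model$calibrated))
    stop_config("model for '%s' has an uncalibrated intercept; run calibrate_intercept() first",
                model$outcome)
  invisible(model)
}

block_contribution <- function(b, v) {
  if (is.null(v))
    stop_config("variable '%s' required by the model is not present in the data", b$variable)
  if (b$type == "categorical") {
    idx <- match(v, b$categories)
    unseen <- is.na(idx) & v != b$reference
    if (any(unseen))
      stop_config("category '%s' of variable '%s' is not known to the model",
                  v[which(unseen)[1]], b$variable)
    c(0, b$estimate)[ifelse(is.na(idx), 0L, idx) + 1L]
  } else {
    b$estimate * as.numeric(v)
  }
}

#' Linear predictor of a model over a data frame
#'
#' Intercept plus the sum of matched-category coefficients; reference
#' categories contribute zero. Errors on categories the model has never
#' seen and on uncalibrated intercepts.
#'
#' @param model a [fitted_model()] with a calibrated or fitted intercept.
#' @param data data frame with one row per individual.
#' @return numeric vector of linear predictors.
#' @export
linear_predictor <- function(model, data) {
  require_calibrated(model)
  lp <- rep(model$intercept, nrow(data))
  for (b in model$blocks) lp <- lp + block_contribution(b, data[[b$variable]])
  lp
}

# Linear predictor without the intercept (used by calibration).
lp_terms <- function(model, data) {
  lp <- numeric(nrow(data))
  for (b in model$blocks) lp <- lp + block_contribution(b, data[[b$variable]])
  lp
}

#' Predicted probability from a logistic model
#'
#' @inheritParams linear_predictor
#' @return probabilities in \[0, 1\].
#' @export
predict_probability <- function(model, data) {
  if (model$family != "logistic")
    stop_config("predict_probability() requires a logistic model; '%s' is %s (use predict_value)",
                model$outcome, model$family)
  inv_logit(linear_predictor(model, data))
}

#' Predicted value from a linear model
#'
#' @inheritParams linear_predictor
#' @return numeric predictions on the model's outcome scale.
#' @export
predict_value <- function(model, data) {
  if (model$family != "linear")
    stop_config("predict_value() requires a linear model; '%s' is %s", model$outcome, model$family)
  linear_predictor(model, data)
}

BMI_CATEGORIES <- c("underweight", "normal", "overweight", "obese")

#' Categorize BMI values
#'
#' Standard adult cutpoints: obese at BMI >= 30, overweight at 25 <= BMI <
#' 30, normal weight at 18.5 <= BMI < 25, underweight below 18.5.
#'
#' @param value numeric BMI in kg/m^2.
#' @return character vector of categories.
#' @export
categorize_bmi <- function(value) {
  if (any(!is.finite(value))) stop_config("categorize_bmi: non-finite BMI value")
  BMI_CATEGORIES[findInterval(value, c(18.5, 25, 30)) + 1L]
}

#' Calibrate a logistic model's intercept to a target mean prevalence
#'
#' Published coefficient tables print no intercepts, so a model ingested from
#' one cannot produce probabilities until its intercept is chosen. This sets
#' the intercept so the mean predicted probability over the supplied
#' population equals the target prevalence, by bisection: the mean predicted
#' probability is strictly increasing in the intercept, so the solution is
#' unique.
#'
#' @param model a logistic [fitted_model()] (intercept may be NA).
#' @param data the population the mean is taken over.
#' @param target_prevalence target mean predicted probability in (0, 1).
#' @param tol convergence tolerance on the mean probability.
#' @return the model with a calibrated intercept.
#' @export
calibrate_intercept <- function(model, data, target_prevalence, tol = 1e-6) {
  if (model$family != "logistic") stop_config("calibrate_intercept() requires a logistic model")
  if (!is.finite(target_prevalence) || target_prevalence <= 0 || target_prevalence >= 1)
    stop_config("target prevalence must lie strictly inside (0, 1)")
  if (nrow(data) == 0L) stop_config("cannot calibrate against an empty population")
  off <- lp_terms(model, data)
  f <- function(a) mean(inv_logit(a + off)) - target_prevalence
  lo <- -50; hi <- 50
  if (f(lo) > 0 || f(hi) < 0) stop_config("calibration target not bracketed")
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < tol) break
    if (fm < 0) lo <- mid else hi <- mid
  }
  model$intercept <- mid
  model$calibrated <- TRUE
  model
}

#' Calibrate an ingested model chain against target prevalences
#'
#' Calibrates intercepts stage by stage: the exercise intercept is set
#' against its target; exercise status is then drawn once so the
#' fruit/vegetable model can be calibrated conditional on realized exercise,
#' and so on through BMI (whose intercept is set so the mean predicted BMI
#' equals the target mean) and diabetes. Pipelines refuse uncalibrated
#' ingested models, so this step is mandatory when predicting from a
#' published coefficient table.
#'
#' @param models named list with `exercise`, `fruitveg`, `bmi`, `diabetes`
#'   models (e.g. from [model_from_table()]).
#' @param data eligible individuals the targets refer to.
#' @param targets named list/vector: target prevalences in (0,1) for
#'   `exercise`, `fruitveg`, `diabetes`, and a target mean for `bmi`.
#' @param seed RNG seed for the upstream draws used during calibration.
#' @return the models with calibrated intercepts.
#' @export
calibrate_chain <- function(models, data, targets, seed = 1L) {
  set.seed(derive_seed(seed, "calibrate_chain"))
  n <- nrow(data)
  models$exercise <- calibrate_intercept(models$exercise, data, targets[["exercise"]])
  data$exercise_any_30d <- as.integer(stats::runif(n) < predict_probability(models$exercise, data))
  if (!is.null(models$fruitveg)) {
    models$fruitveg <- calibrate_intercept(models$fruitveg, data, targets[["fruitveg"]])
    data$fruitveg_5plus <- as.integer(stats::runif(n) < predict_probability(models$fruitveg, data))
  }
  if (!is.null(models$bmi)) {
    if (is.na(models$bmi$intercept)) {
      off <- lp_terms(models$bmi, data)
      models$bmi$intercept <- targets[["bmi"]] - mean(off)
      models$bmi$calibrated <- TRUE
    }
    data$bmi_category <- categorize_bmi(linear_predictor(models$bmi, data))
  }
  if (!is.null(models$diabetes))
    models$diabetes <- calibrate_intercept(models$diabetes, data, targets[["diabetes"]])
  models
}

# ---- chain engine -----------------------------------------------------------
# Precompiled per-individual structure for fast repeated evaluation. Static
# blocks (demographics and carried behaviors) are resolved to index vectors
# once; dynamic blocks (fields drawn within a replicate) are looked up per
# replicate.

compile_model <- function(model, data, dynamic = character()) {
  require_calibrated(model)
  static <- rep(model$intercept, nrow(data))
  terms <- list()
  dyn <- list()
  for (b in model$blocks) {
    if (b$variable %in% dynamic) {
      dyn[[b$variable]] <- b
      next
    }
    static <- static + block_contribution(b, data[[b$variable]])
  }
  list(static = static, dyn = dyn, model = model)
}

# Coefficient of a dynamic binary block (0 when the block was dropped).
dyn_bin_coef <- function(cm, variable) {
  b <- cm$dyn[[variable]]
  if (is.null(b)) 0 else b$estimate
}

# BMI-category coefficients by category code (underweight..obese), 0 for the
# reference and for a dropped block.
dyn_bmi_coefs <- function(cm) {
  b <- cm$dyn[["bmi_category"]]
  out <- stats::setNames(numeric(4), BMI_CATEGORIES)
  if (!is.null(b)) out[b$categories] <- b$estimate
  out
}

chain_models <- c("exercise", "fruitveg", "bmi", "diabetes")

# One stochastic pass through the chain. Draws use the current RNG state.
chain_realize <- function(eng, n) {
  out <- list()
  p_ex <- inv_logit(eng$exercise$static)
  ex <- as.integer(stats::runif(n) < p_ex)
  out$p_exercise <- p_ex; out$exercise <- ex

  if (!is.null(eng$fruitveg)) {
    p_fv <- inv_logit(eng$fruitveg$static + dyn_bin_coef(eng$fruitveg, "exercise_any_30d") * ex)
    fv <- as.integer(stats::runif(n) < p_fv)
    out$p_fruitveg <- p_fv; out$fruitveg <- fv
  }
  if (!is.null(eng$bmi)) {
    bmi <- eng$bmi$static +
      dyn_bin_coef(eng$bmi, "exercise_any_30d") * ex +
      (if (!is.null(eng$fruitveg)) dyn_bin_coef(eng$bmi, "fruitveg_5plus") * out$fruitveg else 0)
    code <- findInterval(bmi, c(18.5, 25, 30)) + 1L
    out$bmi_value <- bmi; out$bmi_code <- code
  }
  if (!is.null(eng$diabetes)) {
    lp <- eng$diabetes$static +
      dyn_bin_coef(eng$diabetes, "exercise_any_30d") * ex +
      (if (!is.null(eng$fruitveg)) dyn_bin_coef(eng$diabetes, "fruitveg_5plus") * out$fruitveg else 0) +
      (if (!is.null(eng$bmi)) dyn_bmi_coefs(eng$diabetes)[out$bmi_code] else 0)
    p_dia <- inv_logit(lp)
    out$p_diabetes <- p_dia
    out$diabetes <- as.integer(stats::runif(n) < p_dia)
  }
  out
}

build_chain_engine <- function(models, data) {
  if (is.null(models$exercise)) stop_config("the model chain requires at least an exercise model")
  if (!is.null(models$diabetes) && "bmi_category" %in% names(models$diabetes$blocks) &&
      is.null(models$bmi))
    stop_config("the diabetes model uses BMI category but no BMI model was supplied")
  eng <- list()
  eng$exercise <- compile_model(models$exercise, data)
  if (!is.null(models$fruitveg))
    eng$fruitveg <- compile_model(models$fruitveg, data, dynamic = "exercise_any_30d")
  if (!is.null(models$bmi))
    eng$bmi <- compile_model(models$bmi, data,
                             dynamic = c("exercise_any_30d", "fruitveg_5plus"))
  if (!is.null(models$diabetes))
    eng$diabetes <- compile_model(models$diabetes, data,
                                  dynamic = c("exercise_any_30d", "fruitveg_5plus", "bmi_category"))
  eng
}

#' Apply the model chain to a population
#'
#' In chain order, per individual: compute the exercise probability and draw
#' exercise; compute the fruit/vegetable probability conditional on the drawn
#' exercise status and draw it; compute BMI deterministically from the linear
#' model (no residual draw — BMI uncertainty is not propagated) and
#' categorize it; compute the diabetes probability conditional on the drawn
#' behaviors and the BMI category, and draw diabetes status. Smoking and
#' alcohol are read from the population (they are carried on the synthetic
#' microdata); all models must have fitted or calibrated intercepts.
#'
#' @param models named list of [fitted_model()]s with elements `exercise`,
#'   `fruitveg`, `bmi`, `diabetes` (later stages optional).
#' @param data data frame of eligible individuals (see
#'   [eligible_population()]).
#' @param seed RNG seed; the realization is reproducible from it.
#' @return data frame of per-individual probabilities, drawn statuses, BMI
#'   value and category.
#' @export
chain_predict <- function(models, data, seed = 1L) {
  eng <- build_chain_engine(models, data)
  set.seed(derive_seed(seed, "chain_predict"))
  r <- chain_realize(eng, nrow(data))
  out <- data.frame(individual_id = data$individual_id,
                    tract_id = data$tract_id %||% NA_character_,
                    p_exercise = r$p_exercise, exercise_draw = r$exercise,
                    stringsAsFactors = FALSE)
  if (!is.null(r$p_fruitveg)) {
    out$p_fruitveg <- r$p_fruitveg; out$fruitveg_draw <- r$fruitveg
  }
  if (!is.null(r$bmi_value)) {
    out$bmi_value <- r$bmi_value
    out$bmi_category <- BMI_CATEGORIES[r$bmi_code]
  }
  if (!is.null(r$p_diabetes)) {
    out$p_diabetes <- r$p_diabetes; out$diabetes_draw <- r$diabetes
  }
  out
}

mc_outcome_cols <- c(exercise = "exercise", fruitveg = "fruitveg", diabetes = "diabetes")

#' Monte Carlo simulation of tract-level prevalences
#'
#' Propagates model uncertainty to tract prevalence estimates over `n_reps`
#' replicates (1000 by default). Two modes:
#' \describe{
#'   \item{outcome}{(default) every replicate re-draws each individual's
#'     binary outcomes through the chain and records each tract's realized
#'     prevalence per outcome.}
#'   \item{coefficient}{every replicate perturbs each model's intercept and
#'     coefficients by independent normal draws at their standard errors,
#'     recomputes probabilities (holding one fixed chain realization of the
#'     upstream drawn fields), and records the tract mean probability.
#'     Requires models with standard errors, i.e. fitted models.}
#' }
#'
#' @param models named list of chain models (see [chain_predict()]).
#' @param data eligible individuals with a `tract_id` column.
#' @param n_reps number of replicates (>= 2).
#' @param mode "outcome" or "coefficient".
#' @param seed RNG seed.
#' @return object of class `mc_result`: data frame (outcome, tract_id, rep,
#'   prevalence) with the run settings in attributes.
#' @export
monte_carlo <- function(models, data, n_reps = 1000L, mode = c("outcome", "coefficient"),
                        seed = 1L) {
  mode <- match.arg(mode)
  if (n_reps < 2) stop_config("n_reps must be at least 2")
  if (is.null(data$tract_id)) stop_config("data must carry a tract_id column")
  n <- nrow(data)
  tract <- factor(data$tract_id)
  tracts <- levels(tract)
  present <- intersect(names(mc_outcome_cols), names(models))

  prev <- vector("list", n_reps)
  if (mode == "outcome") {
    eng <- build_chain_engine(models, data)
    for (r in seq_len(n_reps)) {
      set.seed(derive_seed(seed, "mc_outcome", r))
      real <- chain_realize(eng, n)
      prev[[r]] <- lapply(present, function(o) tapply(real[[mc_outcome_cols[o]]], tract, mean))
    }
  } else {
    set.seed(derive_seed(seed, "mc_coef_base"))
    base_eng <- build_chain_engine(models, data)
    base_real <- chain_realize(base_eng, n)
    for (m in models[present]) {
      if (any(!is.finite(c(m$intercept_se, unlist(lapply(m$blocks, `[[`, "se"))))))
        stop_config("coefficient-draw mode requires standard errors on every coefficient of '%s'",
                    m$outcome)
    }
    for (r in seq_len(n_reps)) {
      set.seed(derive_seed(seed, "mc_coef", r))
      pm <- lapply(models, perturb_model)
      eng <- build_chain_engine(pm, data)
      pr <- list(
        exercise = inv_logit(eng$exercise$static),
        fruitveg = if (!is.null(eng$fruitveg))
          inv_logit(eng$fruitveg$static +
                      dyn_bin_coef(eng$fruitveg, "exercise_any_30d") * base_real$exercise),
        diabetes = if (!is.null(eng$diabetes))
          inv_logit(eng$diabetes$static +
                      dyn_bin_coef(eng$diabetes, "exercise_any_30d") * base_real$exercise +
                      (if (!is.null(base_real$fruitveg))
                        dyn_bin_coef(eng$diabetes, "fruitveg_5plus") * base_real$fruitveg else 0) +
                      (if (!is.null(base_real$bmi_code))
                        dyn_bmi_coefs(eng$diabetes)[base_real$bmi_code] else 0))
      )
      prev[[r]] <- lapply(present, function(o) tapply(pr[[o]], tract, mean))
    }
  }

  rows <- do.call(rbind, lapply(seq_len(n_reps), function(r) {
    do.call(rbind, lapply(seq_along(present), function(i) {
      data.frame(outcome = present[i], tract_id = tracts, rep = r,
                 prevalence = as.numeric(prev[[r]][[i]]), stringsAsFactors = FALSE)
    }))
  }))
  rownames(rows) <- NULL
  attr(rows, "mode") <- mode
  attr(rows, "seed") <- seed
  attr(rows, "n_reps") <- as.integer(n_reps)
  attr(rows, "n_individuals") <- as.integer(table(tract))
  names(attr(rows, "n_individuals")) <- tracts
  class(rows) <- c("mc_result", "data.frame")
  rows
}

# Perturb every coefficient (and the intercept) by an independent normal
# draw at its standard error. Linear-model sigma is left untouched.
perturb_model <- function(model) {
  model$intercept <- model$intercept + stats::rnorm(1, sd = model$intercept_se)
  model$blocks <- lapply(model$blocks, function(b) {
    b$estimate <- b$estimate + stats::rnorm(length(b$estimate), sd = b$se)
    b
  })
  names(model$blocks) <- vapply(model$blocks, `[[`, character(1), "variable")
  model
}
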