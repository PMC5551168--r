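# Known-truth generating models for the synthetic city. The chain order is
# the one the outcome models are built and applied in:
#   smoking -> alcohol -> exercise -> fruit/veg -> BMI -> diabetes
# with each stage consuming only demographics and earlier-stage fields.
# Smoking is generated as two nested binaries (ever-smoker, then
# current-vs-former among ever-smokers) to stay within the binary-model
# machinery; the three-level smoking status used downstream is reassembled
# from the two draws.

cat_block <- function(variable, est, reference) {
  term_block(variable, "categorical", categories = names(est),
             reference = reference, estimate = unname(est))
}
bin_block <- function(variable, est) {
  term_block(variable, "binary", estimate = est)
}

adult_age_block <- function(est) {
  cat_block("age_band", est, reference = "80-99")
}

#' Default generating models of the synthetic survey
#'
#' Coefficient vectors on the logit scale (kg/m^2 for the linear BMI model)
#' with the reference groups used throughout: female sex, age 80-99, non-
#' Hispanic white, income at or above $35k, above-high-school education,
#' never smoker, no alcohol in the past 30 days, no exercise in the past 30
#' days, under five daily servings of fruit/vegetables, underweight BMI.
#' Effect directions follow the epidemiological literature (lower income and
#' education reduce health-promoting behaviors and raise BMI and diabetes
#' risk; age raises diabetes risk); magnitudes are chosen to give clearly
#' separated tract-level prevalences in the synthetic city.
#'
#' @param bmi_sd residual standard deviation of the generated BMI values.
#' @return object of class `true_model_set`.
#' @export
true_model_set <- function(bmi_sd = 4.5) {
  models <- list(
    smoking_ever = fitted_model(
      "smoking_ever", "logistic", intercept = -0.3,
      blocks = list(
        cat_block("sex", c(male = 0.3), "female"),
        adult_age_block(c("18-29" = -0.6, "30-39" = -0.3, "40-49" = -0.1,
                          "50-59" = 0.2, "60-69" = 0.3, "70-79" = 0.2)),
        cat_block("education", c(lt_hs = 0.5, hs = 0.3), "gt_hs"),
        cat_block("income_band", c(lt25k = 0.3, "25-35k" = 0.1), "gte35k")
      )),
    smoking_current = fitted_model(
      "smoking_current", "logistic", intercept = -0.4,
      blocks = list(
        adult_age_block(c("18-29" = 0.8, "30-39" = 0.6, "40-49" = 0.5,
                          "50-59" = 0.2, "60-69" = -0.3, "70-79" = -0.8)),
        cat_block("education", c(lt_hs = 0.5, hs = 0.3), "gt_hs"),
        cat_block("income_band", c(lt25k = 0.4, "25-35k" = 0.15), "gte35k")
      )),
    alcohol = fitted_model(
      "alcohol_any_30d", "logistic", intercept = -0.2,
      blocks = list(
        cat_block("sex", c(male = 0.4), "female"),
        adult_age_block(c("18-29" = 0.6, "30-39" = 0.5, "40-49" = 0.4,
                          "50-59" = 0.3, "60-69" = 0.1, "70-79" = -0.1)),
        cat_block("education", c(lt_hs = -0.5, hs = -0.25), "gt_hs"),
        cat_block("income_band", c(lt25k = -0.5, "25-35k" = -0.2), "gte35k")
      )),
    exercise = fitted_model(
      "exercise_any_30d", "logistic", intercept = 0.9,
      blocks = list(
        cat_block("sex", c(male = 0.15), "female"),
        adult_age_block(c("18-29" = 0.8, "30-39" = 0.5, "40-49" = 0.35,
                          "50-59" = 0.15, "60-69" = 0.0, "70-79" = -0.2)),
        cat_block("race_ethnicity",
                  c(black_nh = -0.05, hispanic = -0.5, other = 0.2), "white_nh"),
        cat_block("income_band", c(lt25k = -0.6, "25-35k" = -0.2), "gte35k"),
        cat_block("education", c(lt_hs = -0.7, hs = -0.3), "gt_hs"),
        cat_block("smoking", c(current = -0.5, former = 0.1), "never"),
        bin_block("alcohol_any_30d", 0.35)
      )),
    fruitveg = fitted_model(
      "fruitveg_5plus", "logistic", intercept = -1.0,
      blocks = list(
        cat_block("sex", c(male = -0.5), "female"),
        adult_age_block(c("18-29" = -0.3, "30-39" = -0.4, "40-49" = -0.2,
                          "50-59" = 0.05, "60-69" = 0.1, "70-79" = 0.15)),
        cat_block("education", c(lt_hs = -0.5, hs = -0.25), "gt_hs"),
        cat_block("income_band", c(lt25k = -0.3, "25-35k" = -0.15), "gte35k"),
        cat_block("smoking", c(current = -0.45, former = 0.05), "never"),
        bin_block("exercise_any_30d", 0.6)
      )),
    bmi = fitted_model(
      "bmi_value", "linear", intercept = 26.5, sigma = bmi_sd,
      blocks = list(
        cat_block("sex", c(male = 0.6), "female"),
        adult_age_block(c("18-29" = -1.8, "30-39" = -0.8, "40-49" = -0.2,
                          "50-59" = 0.3, "60-69" = 0.4, "70-79" = 0.2)),
        cat_block("income_band", c(lt25k = 0.7, "25-35k" = 0.3), "gte35k"),
        cat_block("education", c(lt_hs = 0.8, hs = 0.4), "gt_hs"),
        cat_block("smoking", c(current = -0.8, former = 0.2), "never"),
        bin_block("alcohol_any_30d", -0.3),
        bin_block("exercise_any_30d", -1.0),
        bin_block("fruitveg_5plus", -0.5)
      )),
    diabetes = fitted_model(
      "diabetes", "logistic", intercept = -2.6,
      blocks = list(
        cat_block("sex", c(male = 0.25), "female"),
        adult_age_block(c("18-29" = -2.2, "30-39" = -1.4, "40-49" = -0.7,
                          "50-59" = -0.1, "60-69" = 0.35, "70-79" = 0.55)),
        cat_block("income_band", c(lt25k = 0.4, "25-35k" = 0.1), "gte35k"),
        cat_block("smoking", c(current = -0.1, former = 0.2), "never"),
        bin_block("alcohol_any_30d", -0.35),
        bin_block("exercise_any_30d", -0.25),
        cat_block("bmi_category",
                  c(obese = 1.3, overweight = 0.3, normal = -0.4), "underweight")
      ))
  )
  ts <- list(models = models,
             chain = c("smoking_ever", "smoking_current", "alcohol",
                       "exercise", "fruitveg", "bmi", "diabetes"),
             bmi_sd = bmi_sd)
  class(ts) <- "true_model_set"
  validate_truth_chain(ts)
  ts
}

DEMOGRAPHIC_VARS <- c("sex", "age_band", "race_ethnicity", "education",
                      "income_band", "employment", "ancestry")

# The fields each chain stage makes available to later stages.
stage_provides <- c(
  smoking_ever = "smoking_ever", smoking_current = "smoking",
  alcohol = "alcohol_any_30d", exercise = "exercise_any_30d",
  fruitveg = "fruitveg_5plus", bmi = "bmi_category", diabetes = "diabetes"
)

validate_truth_chain <- function(truth) {
  available <- DEMOGRAPHIC_VARS
  for (stage in truth$chain) {
    m <- truth$models[[stage]]
    if (is.null(m)) stop_config("chain stage '%s' has no model", stage)
    used <- vapply(m$blocks, `[[`, character(1), "variable")
    bad <- setdiff(used, available)
    if (length(bad))
      stop_config("chain stage '%s' uses field(s) not yet generated: %s",
                  stage, paste(bad, collapse = ", "))
    available <- c(available, stage_provides[[stage]])
  }
  invisible(truth)
}

# Draw all behavioral/outcome fields for a data frame of adults, in chain
# order, from the truth models. Pure function of (data, truth, seed).
draw_chain_fields <- function(data, truth, seed) {
  set.seed(derive_seed(seed, "draw_chain_fields"))
  n <- nrow(data)
  m <- truth$models

  p_ever <- predict_probability(m$smoking_ever, data)
  ever <- as.integer(stats::runif(n) < p_ever)
  p_cur <- predict_probability(m$smoking_current, data)
  cur <- as.integer(stats::runif(n) < p_cur)
  data$smoking <- ifelse(ever == 0L, "never", ifelse(cur == 1L, "current", "former"))

  data$alcohol_any_30d <- as.integer(stats::runif(n) < predict_probability(m$alcohol, data))
  data$exercise_any_30d <- as.integer(stats::runif(n) < predict_probability(m$exercise, data))
  data$fruitveg_5plus <- as.integer(stats::runif(n) < predict_probability(m$fruitveg, data))

  bmi_mu <- linear_predictor(m$bmi, data)
  data$bmi_value <- bmi_mu + stats::rnorm(n, sd = m$bmi$sigma)
  data$bmi_category <- categorize_bmi(data$bmi_value)

  data$diabetes <- as.integer(stats::runif(n) < predict_probability(m$diabetes, data))
  data
}

#' Attach simulated behaviors and outcomes to a ground-truth population
#'
#' Draws the full behavioral/outcome chain for every adult (18+) in the
#' population; minors receive NA in every simulated field. The result is the
#' ground truth against which pipeline predictions are validated, and the
#' source of the smoking/alcohol fields the microdata carries.
#'
#' @param pop a `population`.
#' @param truth a [true_model_set()].
#' @param seed RNG seed.
#' @return the population with simulated fields on `individuals`.
#' @export
simulate_outcomes <- function(pop, truth, seed = 1L) {
  ind <- pop$individuals
  adult <- ind$age_years >= 18
  drawn <- draw_chain_fields(ind[adult, , drop = FALSE], truth, seed)
  for (col in c("smoking", "alcohol_any_30d", "exercise_any_30d",
                "fruitveg_5plus", "bmi_value", "bmi_category", "diabetes")) {
    ind[[col]] <- drawn[[col]][match(ind$individual_id, drawn$individual_id)]
  }
  pop$individuals <- ind
  pop
}

#' Simulate a BRFSS-like survey from the ground truth
#'
#' Samples `n` adults (18+) without replacement and draws their behavioral
#' and outcome fields sequentially in chain order from the truth models:
#' binary fields as Bernoulli draws at the inverse-logit of the generating
#' linear predictor, BMI as the linear predictor plus Gaussian noise, and
#' diabetes using the categorized BMI.
#'
#' @param pop a `population`.
#' @param truth a [true_model_set()].
#' @param n number of respondents (at most the adult population size).
#' @param seed RNG seed.
#' @return data frame of survey records (class `survey_data`).
#' @export
simulate_survey <- function(pop, truth, n, seed = 1L) {
  adults <- pop$individuals[pop$individuals$age_years >= 18, , drop = FALSE]
  if (n > nrow(adults))
    stop_config("survey size n = %d exceeds adult population size %d", n, nrow(adults))
  set.seed(derive_seed(seed, "simulate_survey_sample"))
  take <- sample.int(nrow(adults), n)
  svy <- draw_chain_fields(adults[take, , drop = FALSE], truth,
                           derive_seed(seed, "simulate_survey_fields"))
  rownames(svy) <- NULL
  class(svy) <- c("survey_data", "data.frame")
  svy
}

#' Ground-truth tract prevalences of the binary outcomes
#'
#' Two notions of truth are available. `"realized"` is the empirical rate of
#' the drawn 0/1 outcomes in the ground-truth population — one stochastic
#' realization, whose tract rates carry binomial noise of order
#' sqrt(p(1-p)/n_tract). `"expected"` evaluates the generating models'
#' probabilities on each eligible individual (conditional on their realized
#' upstream behaviors) and averages per tract — the underlying spatial
#' pattern the pipeline is trying to recover, free of the final Bernoulli
#' draw.
#'
#' @param pop a population with simulated outcomes.
#' @param min_age eligibility age threshold (default 21).
#' @param type "realized" or "expected".
#' @param truth the [true_model_set()] (required for `type = "expected"`).
#' @return data frame tract_id x outcome with tract prevalences.
#' @export
tract_truth_prevalence <- function(pop, min_age = 21, type = c("realized", "expected"),
                                   truth = NULL) {
  type <- match.arg(type)
  ind <- pop$individuals
  if (!"exercise_any_30d" %in% names(ind))
    stop_config("population carries no simulated outcomes; run simulate_outcomes() first")
  el <- ind[ind$age_years >= min_age, , drop = FALSE]
  if (type == "realized") {
    out <- lapply(c(exercise = "exercise_any_30d", fruitveg = "fruitveg_5plus",
                    diabetes = "diabetes"), function(col) {
      tapply(el[[col]], el$tract_id, mean)
    })
  } else {
    if (is.null(truth)) stop_config("type = 'expected' needs the true_model_set")
    out <- lapply(c(exercise = "exercise", fruitveg = "fruitveg",
                    diabetes = "diabetes"), function(mname) {
      tapply(predict_probability(truth$models[[mname]], el), el$tract_id, mean)
    })
  }
  tracts <- sort(unique(el$tract_id))
  data.frame(tract_id = tracts,
             exercise = as.numeric(out$exercise[tracts]),
             fruitveg = as.numeric(out$fruitveg[tracts]),
             diabetes = as.numeric(out$diabetes[tracts]),
             stringsAsFactors = FALSE)
}
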