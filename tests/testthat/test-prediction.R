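ref_individual <- function(n = 1) {
  data.frame(individual_id = paste0("I", seq_len(n)), tract_id = "T01",
             sex = "female", age_band = "80-99", race_ethnicity = "white_nh",
             income_band = "gte35k", education = "gt_hs", smoking = "never",
             alcohol_any_30d = 0, exercise_any_30d = 0, fruitveg_5plus = 0,
             bmi_category = "underweight", stringsAsFactors = FALSE)
}

test_that("eligibility filter is inclusive at 21 and idempotent", {
  d <- data.frame(individual_id = 1:3, age_years = c(20, 21, 35))
  out <- eligible_quiet(d)
  expect_identical(out$age_years, c(21, 35))
  expect_identical(eligible_quiet(out), out)
  d2 <- data.frame(individual_id = 1:2, age_years = c(5, 12))
  expect_warning(out2 <- suppressMessages(eligible_population(d2)), "no individuals")
  expect_identical(nrow(out2), 0L)
})

test_that("linear predictor sums matched coefficients over reference zero", {
  dia <- model_from_table("diabetes")
  dia$intercept <- 0
  dia$calibrated <- TRUE
  # all-reference profile scores exactly the intercept
  expect_identical(linear_predictor(dia, ref_individual()), 0)
  # male + obese, otherwise reference: 0.21 + 0.91
  prof <- ref_individual()
  prof$sex <- "male"; prof$bmi_category <- "obese"
  expect_equal(linear_predictor(dia, prof), 1.12, tolerance = 1e-12)
  expect_equal(predict_probability(dia, prof), 1 / (1 + exp(-1.12)), tolerance = 1e-9)
  # two individuals differing only in exercise differ by exactly -0.083
  a <- ref_individual(); b <- ref_individual(); b$exercise_any_30d <- 1
  expect_equal(linear_predictor(dia, b) - linear_predictor(dia, a), -0.083)
  # unseen categories are named in the error
  bad <- ref_individual(); bad$smoking <- "vaper"
  expect_error(linear_predictor(dia, bad), "vaper")
  # uncalibrated models refuse to predict
  expect_error(predict_probability(model_from_table("diabetes"), ref_individual()),
               "uncalibrated")
  # linear models refuse predict_probability
  bmi <- model_from_table("bmi"); bmi$intercept <- 25; bmi$calibrated <- TRUE
  expect_error(predict_probability(bmi, ref_individual()), "logistic")
})

test_that("BMI categorization follows the standard cutpoints", {
  expect_identical(categorize_bmi(c(30, 18.5, 24.999, 17, 29.999, 25)),
                   c("obese", "normal", "normal", "underweight", "overweight",
                     "overweight"))
  expect_error(categorize_bmi(NaN), "non-finite")
})

test_that("intercept calibration solves the mean-probability equation", {
  m <- fitted_model("y", "logistic", intercept = NA_real_,
                    blocks = list(term_block("x", "continuous", estimate = 1)),
                    calibrated = FALSE)
  d <- data.frame(x = rep(0, 50))
  cal <- calibrate_intercept(m, d, 0.3)
  expect_equal(cal$intercept, logit(0.3), tolerance = 1e-4)
  # three-individual toy against a fine grid-search oracle
  d3 <- data.frame(x = c(-1, 0, 1))
  cal3 <- calibrate_intercept(m, d3, 0.6)
  grid <- seq(-5, 5, by = 1e-4)
  obj <- vapply(grid, function(a) abs(mean(inv_logit(a + d3$x)) - 0.6), numeric(1))
  expect_equal(cal3$intercept, grid[which.min(obj)], tolerance = 1e-4)
  expect_equal(mean(predict_probability(cal3, d3)), 0.6, tolerance = 1e-6)
  expect_error(calibrate_intercept(m, d, 1.2), "inside")
})

test_that("calibrated fixture chain is runnable and seed-reproducible", {
  city <- tiny_city(2, 120)
  el <- eligible_quiet(city$pop$individuals)
  models <- lapply(stats::setNames(nm = c("exercise", "fruitveg", "bmi", "diabetes")),
                   model_from_table)
  models <- calibrate_chain(models, el,
                            c(exercise = 0.649, fruitveg = 0.179, bmi = 27, diabetes = 0.111),
                            seed = 5)
  pr1 <- chain_predict(models, el, seed = 9)
  pr2 <- chain_predict(models, el, seed = 9)
  expect_identical(pr1, pr2)
  expect_true(all(pr1$p_exercise >= 0 & pr1$p_exercise <= 1))
  expect_identical(pr1$bmi_category, categorize_bmi(pr1$bmi_value))
  expect_equal(mean(pr1$p_exercise), 0.649, tolerance = 1e-4)
})

test_that("high-risk profiles score higher diabetes risk than reference profiles", {
  models <- lapply(stats::setNames(nm = c("exercise", "fruitveg", "bmi", "diabetes")),
                   model_from_table)
  for (nm in names(models)) {
    models[[nm]]$intercept <- if (nm == "bmi") 27 else 0
    models[[nm]]$calibrated <- TRUE
  }
  risk <- ref_individual(200)
  risk$sex <- "male"; risk$age_band <- "70-79"; risk$income_band <- "lt25k"
  base <- ref_individual(200)
  pr_risk <- chain_predict(models, risk, seed = 2)
  pr_base <- chain_predict(models, base, seed = 2)
  expect_gt(mean(pr_risk$p_diabetes), mean(pr_base$p_diabetes))
})

test_that("all-zero-slope chain returns the intercept probability everywhere", {
  m <- function(outcome, p0) fitted_model(outcome, "logistic", intercept = logit(p0),
                                          blocks = list())
  models <- list(exercise = m("exercise_any_30d", 0.4),
                 fruitveg = m("fruitveg_5plus", 0.2),
                 bmi = fitted_model("bmi_value", "linear", intercept = 26, blocks = list()),
                 diabetes = m("diabetes", 0.1))
  d <- ref_individual(50)
  pr <- chain_predict(models, d, seed = 1)
  expect_equal(pr$p_exercise, rep(0.4, 50), tolerance = 1e-12)
  expect_equal(pr$p_fruitveg, rep(0.2, 50), tolerance = 1e-12)
  expect_equal(pr$p_diabetes, rep(0.1, 50), tolerance = 1e-12)
  expect_equal(pr$bmi_value, rep(26, 50), tolerance = 1e-12)
})

test_that("Monte Carlo outcome draws match binomial expectations", {
  # 1000 individuals, all probability one half, single tract
  m <- fitted_model("exercise_any_30d", "logistic", intercept = 0, blocks = list())
  d <- data.frame(individual_id = paste0("I", 1:1000), tract_id = "T01")
  mc <- monte_carlo(list(exercise = m), d, n_reps = 1000, seed = 3)
  expect_identical(nrow(mc), 1000L)
  expect_lt(abs(mean(mc$prevalence) - 0.5), 3 * (sqrt(0.25 / 1000) / sqrt(1000)))
  # rep variance approximates the Poisson-binomial formula
  expect_lt(abs(stats::var(mc$prevalence) / (0.25 / 1000) - 1), 0.2)
  # degenerate probability 0 gives all-zero prevalence
  m0 <- fitted_model("exercise_any_30d", "logistic", intercept = -60, blocks = list())
  mc0 <- monte_carlo(list(exercise = m0), d, n_reps = 10, seed = 3)
  expect_true(all(mc0$prevalence == 0))
  expect_error(monte_carlo(list(exercise = m), d, n_reps = 1, seed = 1), "at least 2")
})

test_that("Monte Carlo mean converges to the mean individual probability", {
  set.seed(42)
  lp <- rnorm(800, 0, 1.2)
  m <- fitted_model("exercise_any_30d", "logistic", intercept = 0,
                    blocks = list(term_block("offset_x", "continuous", estimate = 1)))
  d <- data.frame(individual_id = paste0("I", 1:800), tract_id = "T01", offset_x = lp)
  p <- inv_logit(lp)
  mc <- monte_carlo(list(exercise = m), d, n_reps = 1000, seed = 7)
  analytic_se <- sqrt(sum(p * (1 - p)) / 800^2) / sqrt(1000)
  expect_lt(abs(mean(mc$prevalence) - mean(p)), 3 * analytic_se)
  expect_lt(abs(stats::var(mc$prevalence) / (sum(p * (1 - p)) / 800^2) - 1), 0.2)
})

test_that("chain marginal prevalence obeys the law of total probability", {
  # two-state toy: downstream probability depends only on drawn exercise
  m_ex <- fitted_model("exercise_any_30d", "logistic", intercept = logit(0.3),
                       blocks = list())
  m_fv <- fitted_model("fruitveg_5plus", "logistic", intercept = logit(0.1),
                       blocks = list(term_block("exercise_any_30d", "binary",
                                                estimate = logit(0.6) - logit(0.1))))
  d <- data.frame(individual_id = paste0("I", 1:500), tract_id = "T01")
  mc <- monte_carlo(list(exercise = m_ex, fruitveg = m_fv), d, n_reps = 2000, seed = 11)
  fv <- mc$prevalence[mc$outcome == "fruitveg"]
  exact <- 0.3 * 0.6 + 0.7 * 0.1  # total-probability mix over the two states
  se <- sqrt(exact * (1 - exact) / 500) / sqrt(2000)
  expect_lt(abs(mean(fv) - exact), 4 * se)
})

test_that("coefficient-draw mode perturbs at the fitted standard errors", {
  set.seed(21)
  d <- data.frame(x = rbinom(2000, 1, 0.5))
  d$y <- rbinom(2000, 1, inv_logit(-0.2 + 0.6 * d$x))
  fit <- fit_logistic(encode_design(d, model_spec("y", "logistic",
                                                  list(term_block("x", "binary")))))
  fit$outcome <- "exercise_any_30d"
  pd <- data.frame(individual_id = paste0("I", 1:200), tract_id = "T01",
                   x = rbinom(200, 1, 0.5))
  mc <- monte_carlo(list(exercise = fit), pd, n_reps = 400, mode = "coefficient", seed = 5)
  # spread across reps reflects coefficient uncertainty, not Bernoulli noise
  expect_gt(stats::sd(mc$prevalence), 0)
  base <- mean(predict_probability(fit, pd))
  expect_lt(abs(mean(mc$prevalence) - base), 0.05)
  # truth models carry no SEs: coefficient mode must refuse them
  m_nose <- fitted_model("exercise_any_30d", "logistic", intercept = 0,
                         blocks = list(term_block("x", "binary", estimate = 1)))
  expect_error(monte_carlo(list(exercise = m_nose), pd, n_reps = 10,
                           mode = "coefficient", seed = 1), "standard errors")
})

test_that("Monte Carlo results are a pure function of the seed", {
  city <- tiny_city(3, 200)
  el <- eligible_quiet(city$pop$individuals)
  models <- fit_chain(simulate_survey(city$pop, true_model_set(), 800, seed = 2))
  mc1 <- monte_carlo(models, el, n_reps = 50, seed = 13)
  mc2 <- monte_carlo(models, el, n_reps = 50, seed = 13)
  expect_identical(mc1, mc2)
  mc3 <- monte_carlo(models, el, n_reps = 50, seed = 14)
  expect_false(identical(mc1$prevalence, mc3$prevalence))
})
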