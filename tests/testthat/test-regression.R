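test_that("design encoding uses reference-cell dummy coding in block order", {
  d <- data.frame(y = c(0, 1, 0, 1),
                  sex = c("female", "male", "female", "male"),
                  edu = c("gt_hs", "lt_hs", "hs", "gt_hs"),
                  stringsAsFactors = FALSE)
  spec <- model_spec("y", "logistic", list(
    term_block("sex", "categorical", categories = "male", reference = "female"),
    term_block("edu", "categorical", categories = c("lt_hs", "hs"), reference = "gt_hs")
  ))
  des <- encode_design(d, spec)
  expect_identical(colnames(des$X), c("sex.male", "edu.lt_hs", "edu.hs"))
  # an all-reference individual encodes to an all-zero row
  expect_identical(unname(des$X[1, ]), c(0, 0, 0))
  expect_identical(unname(des$X[2, ]), c(1, 1, 0))
  # a 3-level variable yields exactly 2 indicator columns
  expect_identical(sum(des$col_block == 2L), 2L)
  # unseen category errors by name
  d2 <- d; d2$edu[1] <- "phd"
  expect_error(encode_design(d2, spec), "phd")
  # empty declared category errors by name
  d3 <- d; d3$edu <- "gt_hs"
  expect_error(encode_design(d3, spec), "lt_hs")
})

test_that("missing rows are dropped and counted", {
  d <- data.frame(y = c(0, 1, NA, 1), x = c(0, 1, 1, NA))
  spec <- model_spec("y", "logistic", list(term_block("x", "binary")))
  des <- encode_design(d, spec)
  expect_identical(des$n_dropped, 2L)
  expect_identical(nrow(des$X), 2L)
})

test_that("logistic fit reproduces the closed-form 2x2 log odds ratio", {
  d <- data.frame(exposed = rep(c(1, 0), each = 100),
                  y = c(rep(1, 40), rep(0, 60), rep(1, 25), rep(0, 75)))
  spec <- model_spec("y", "logistic", list(term_block("exposed", "binary")))
  fit <- fit_logistic(encode_design(d, spec))
  expect_equal(fit$blocks$exposed$estimate, log((40 * 75) / (60 * 25)),
               tolerance = 1e-6)
  # intercept is the unexposed log odds
  expect_equal(fit$intercept, log(25 / 75), tolerance = 1e-6)
  # cross-check SEs against the 2x2 closed form sqrt(sum of 1/cell)
  expect_equal(fit$blocks$exposed$se,
               sqrt(1 / 40 + 1 / 60 + 1 / 25 + 1 / 75), tolerance = 1e-5)
})

test_that("degenerate and separated responses raise diagnostic errors", {
  d <- data.frame(y = rep(1, 50), x = rnorm(50))
  spec <- model_spec("y", "logistic", list(term_block("x", "continuous")))
  expect_error(fit_logistic(encode_design(d, spec)), "separation|degenerate")
  d2 <- data.frame(y = rep(c(0, 1), each = 25), x = rep(c(0, 1), each = 25))
  spec2 <- model_spec("y", "logistic", list(term_block("x", "continuous")))
  expect_error(fit_logistic(encode_design(d2, spec2)), "separation")
})

test_that("linear fit is exact on noiseless data and errors on collinearity", {
  d <- data.frame(x = 1:20, y = 2 * (1:20) + 3)
  fit <- fit_linear(encode_design(d, model_spec("y", "linear",
                                                list(term_block("x", "continuous")))))
  expect_equal(fit$blocks$x$estimate, 2, tolerance = 1e-10)
  expect_equal(fit$intercept, 3, tolerance = 1e-10)
  expect_lt(fit$sigma, 1e-8)

  d2 <- data.frame(y = rnorm(20), x = 1:20, x2 = 2 * (1:20))
  spec2 <- model_spec("y", "linear", list(term_block("x", "continuous"),
                                          term_block("x2", "continuous")))
  expect_error(fit_linear(encode_design(d2, spec2)), "x2")
})

test_that("linear fit matches the pseudo-inverse oracle on random designs", {
  set.seed(404)
  n <- 200
  d <- data.frame(a = rnorm(n), b = rnorm(n),
                  g = sample(c("u", "v", "w"), n, replace = TRUE),
                  stringsAsFactors = FALSE)
  d$y <- 1.5 + 0.7 * d$a - 0.3 * d$b + (d$g == "v") * 0.5 + rnorm(n)
  spec <- model_spec("y", "linear", list(
    term_block("a", "continuous"), term_block("b", "continuous"),
    term_block("g", "categorical", categories = c("v", "w"), reference = "u")
  ))
  des <- encode_design(d, spec)
  fit <- fit_linear(des)
  Xi <- cbind(1, des$X)
  oracle <- solve(t(Xi) %*% Xi, t(Xi) %*% des$response)
  got <- c(fit$intercept, model_coefs <- c(fit$blocks$a$estimate, fit$blocks$b$estimate,
                                           fit$blocks$g$estimate))
  expect_equal(got, as.numeric(oracle), tolerance = 1e-8)
})

test_that("one-category block p equals the coefficient's own Wald p", {
  set.seed(77)
  d <- data.frame(x = rbinom(400, 1, 0.5))
  d$y <- rbinom(400, 1, inv_logit(-0.3 + 0.8 * d$x))
  fit <- fit_logistic(encode_design(d, model_spec("y", "logistic",
                                                  list(term_block("x", "binary")))))
  expect_equal(block_p_value(fit, "x"), fit$blocks$x$p, tolerance = 1e-10)
  expect_error(block_p_value(fit, "nope"), "not retained")
})

test_that("block p-values are uniform under the null and tiny under strong effects", {
  set.seed(501)
  pvals <- replicate(300, {
    d <- data.frame(y = rbinom(250, 1, 0.4),
                    g = sample(c("a", "b", "c"), 250, replace = TRUE),
                    stringsAsFactors = FALSE)
    fit <- fit_logistic(encode_design(d, model_spec("y", "logistic", list(
      term_block("g", "categorical", categories = c("b", "c"), reference = "a")))))
    block_p_value(fit, "g")
  })
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)

  set.seed(502)
  d <- data.frame(x = rbinom(5000, 1, 0.5))
  d$y <- rbinom(5000, 1, inv_logit(-2 + 3 * d$x))
  fit <- fit_logistic(encode_design(d, model_spec("y", "logistic",
                                                  list(term_block("x", "binary")))))
  expect_lt(block_p_value(fit, "x"), 1e-10)
})

test_that("backward selection drops the largest-p block first and is idempotent", {
  set.seed(99)
  n <- 3000
  d <- data.frame(x = rbinom(n, 1, 0.5),
                  noise1 = sample(c("a", "b"), n, replace = TRUE),
                  noise2 = sample(c("p", "q", "r"), n, replace = TRUE),
                  stringsAsFactors = FALSE)
  d$y <- rbinom(n, 1, inv_logit(-0.5 + 1.2 * d$x))
  spec <- model_spec("y", "logistic", list(
    term_block("x", "binary"),
    term_block("noise1", "categorical", categories = "b", reference = "a"),
    term_block("noise2", "categorical", categories = c("q", "r"), reference = "p")
  ))
  fit <- backward_select(d, spec)
  expect_true("x" %in% names(fit$blocks))
  expect_false(any(c("noise1", "noise2") %in% names(fit$blocks)))
  # removal history: blocks removed in decreasing order of their p at removal
  expect_identical(sort(names(fit$dropped)), c("noise1", "noise2"))
  # the first removed block had the larger p in the full fit
  full <- fit_logistic(encode_design(d, spec))
  worst <- names(which.max(full$block_p))
  expect_identical(names(fit$dropped)[1], worst)
  # idempotence: re-selecting from the retained spec changes nothing
  spec2 <- model_spec("y", "logistic", fit$blocks)
  fit2 <- backward_select(d, spec2)
  expect_equal(fit2$blocks$x$estimate, fit$blocks$x$estimate, tolerance = 1e-12)
  expect_length(fit2$dropped, 0L)
})

test_that("a model whose blocks are all noise collapses to intercept-only", {
  set.seed(15)
  d <- data.frame(y = rbinom(500, 1, 0.3),
                  g = sample(c("a", "b"), 500, replace = TRUE),
                  stringsAsFactors = FALSE)
  spec <- model_spec("y", "logistic", list(
    term_block("g", "categorical", categories = "b", reference = "a")))
  expect_warning(fit <- backward_select(d, spec), "intercept-only")
  expect_length(fit$blocks, 0L)
  expect_equal(inv_logit(fit$intercept), mean(d$y), tolerance = 1e-9)
})

test_that("parameter recovery: fits fall within 2 SE of the generating truth", {
  city <- tiny_city(6, 700, seed = 42, with_outcomes = FALSE)
  truth <- true_model_set()
  true_coefs <- model_coefficients(truth$models$exercise)
  spec <- default_model_specs()$exercise
  set.seed(303)
  cover <- c()
  for (rep in 1:5) {
    svy <- simulate_survey(city$pop, truth, 6000, seed = 1000 + rep)
    fit <- fit_logistic(encode_design(svy, spec))
    est <- model_coefficients(fit)
    se <- model_ses(fit)
    cover <- c(cover, abs(est[names(true_coefs)] - true_coefs) <=
                 2 * se[names(true_coefs)])
  }
  expect_gt(mean(cover), 0.9)
})

test_that("chain fitting enforces the stage ordering", {
  city <- tiny_city(3, 150, seed = 5)
  svy <- simulate_survey(city$pop, true_model_set(), 500, seed = 6)
  bad <- default_model_specs()
  # exercise spec illegally using the later fruit/veg outcome
  bad$exercise$blocks <- c(bad$exercise$blocks,
                           list(fruitveg_5plus = term_block("fruitveg_5plus", "binary")))
  expect_error(fit_chain(svy, bad), "chain stage")
})

test_that("ingested published models carry the transcribed coefficients", {
  dia <- model_from_table("diabetes")
  expect_identical(dia$family, "logistic")
  expect_false(dia$calibrated)
  expect_identical(dia$blocks$sex$estimate, 0.21)
  expect_identical(dia$blocks$bmi_category$estimate[
    dia$blocks$bmi_category$categories == "obese"], 0.91)
  expect_identical(dia$blocks$exercise_any_30d$estimate, -0.083)
  # NS variables are absent from the published final models
  bmi <- model_from_table("bmi")
  expect_identical(bmi$family, "linear")
  expect_false("race_ethnicity" %in% names(bmi$blocks))
  ex <- model_from_table("exercise")
  expect_false(any(c("exercise_any_30d", "fruitveg_5plus", "bmi_category")
                   %in% names(ex$blocks)))
  expect_identical(ex$blocks$race_ethnicity$estimate[
    ex$blocks$race_ethnicity$categories == "hispanic"], -0.35)
  expect_error(model_from_table("nope"), "unknown outcome")
})

test_that("fitted models round-trip through JSON", {
  set.seed(8)
  d <- data.frame(x = rbinom(300, 1, 0.5))
  d$y <- rbinom(300, 1, inv_logit(0.5 * d$x))
  fit <- fit_logistic(encode_design(d, model_spec("y", "logistic",
                                                  list(term_block("x", "binary")))))
  path <- tempfile(fileext = ".json")
  model_to_json(fit, path)
  back <- model_from_json(path)
  expect_equal(back$intercept, fit$intercept, tolerance = 1e-12)
  expect_equal(back$blocks$x$estimate, fit$blocks$x$estimate, tolerance = 1e-12)
  expect_identical(back$family, "logistic")
})
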