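test_that("population generation echoes parameters and is deterministic", {
  p <- gen_params(n_tracts = 4, households_per_tract = 30)
  pop <- generate_ground_truth(p, seed = 11)
  expect_length(unique(pop$households$tract_id), 4L)
  expect_setequal(unique(pop$individuals$tract_id), unique(pop$households$tract_id))

  pop2 <- generate_ground_truth(p, seed = 11)
  expect_identical(pop, pop2)
  pop3 <- generate_ground_truth(p, seed = 12)
  expect_false(identical(pop$individuals, pop3$individuals))
})

test_that("every individual belongs to one household, every household to one tract", {
  city <- tiny_city(3, 40, with_outcomes = FALSE)
  ind <- city$pop$individuals
  hh <- city$pop$households
  expect_true(all(ind$household_id %in% hh$household_id))
  expect_identical(anyDuplicated(hh$household_id), 0L)
  expect_identical(anyDuplicated(ind$individual_id), 0L)
  # member tract always equals the household's tract
  expect_identical(ind$tract_id, hh$tract_id[match(ind$household_id, hh$household_id)])
  # age band is the deterministic image of age
  expect_identical(ind$age_band, age_to_band(ind$age_years))
  # head is the oldest member
  oldest <- tapply(ind$age_years, ind$household_id, max)
  expect_identical(unname(age_to_band(as.integer(oldest[hh$household_id]))),
                   hh$head_age_band)
})

test_that("realized category frequencies converge to the tract profile", {
  p <- gen_params(n_tracts = 2, households_per_tract = 2000)
  p$profiles$sex_female[1] <- 0.9
  pop <- generate_ground_truth(p, seed = 5)
  t1 <- pop$individuals[pop$individuals$tract_id == "T01", ]
  n <- nrow(t1)
  share <- mean(t1$sex == "female")
  expect_lt(abs(share - 0.9), 3 * sqrt(0.9 * 0.1 / n))
})

test_that("invalid probability profiles are rejected with the variable named", {
  p <- gen_params(n_tracts = 2, households_per_tract = 10)
  p$profiles$sex_female[2] <- 1.4
  expect_error(generate_ground_truth(p, seed = 1), "sex")
})

test_that("constraint tables partition and marginalize consistently", {
  city <- tiny_city(3, 25)
  tab <- city$tables
  ind <- city$pop$individuals
  for (tr in unique(ind$tract_id)) {
    sx <- tab[tab$tract_id == tr & tab$table_name == "sex", ]
    expect_identical(sum(sx$count), sum(ind$tract_id == tr))
    # sex x age summed over age reproduces the sex table cell by cell
    sa <- tab[tab$tract_id == tr & tab$table_name == "sex_age", ]
    sex_of <- vapply(strsplit(sa$category_key, "|", fixed = TRUE), `[[`, "", 1)
    marg <- tapply(sa$count, sex_of, sum)
    expect_identical(as.integer(marg[sx$category_key]), sx$count)
    # three-way table marginalizes to the sex x education table
    sae <- tab[tab$tract_id == tr & tab$table_name == "sex_age_education", ]
    parts <- strsplit(sae$category_key, "|", fixed = TRUE)
    key2 <- vapply(parts, function(x) paste(x[c(1, 3)], collapse = "|"), "")
    se <- tab[tab$tract_id == tr & tab$table_name == "sex_education", ]
    marg2 <- tapply(sae$count, key2, sum)
    expect_identical(as.integer(marg2[se$category_key]), se$count)
  }
  expect_identical(length(unique(tab$table_name)), 13L)
})

test_that("a hand-built 4-person tract tabulates exactly", {
  pop <- structure(list(
    households = data.frame(household_id = c("Ha", "Hb"), tract_id = "X",
                            stringsAsFactors = FALSE),
    individuals = data.frame(
      individual_id = paste0("i", 1:4),
      household_id = c("Ha", "Ha", "Hb", "Hb"), tract_id = "X",
      sex = c("male", "male", "female", "female"),
      age_band = c("18-29", "30-39", "18-29", "18-29"),
      stringsAsFactors = FALSE)
  ), class = "population")
  attr(pop, "categories") <- default_categories()
  defs <- list(list(name = "sex_age", variables = c("sex", "age_band"),
                    level = "individual"))
  tab <- tabulate_constraints(pop, defs)
  get <- function(key) tab$count[tab$category_key == key]
  expect_identical(get("male|18-29"), 1L)
  expect_identical(get("male|30-39"), 1L)
  expect_identical(get("female|18-29"), 2L)
  expect_identical(sum(tab$count), 4L)
})

test_that("microdata sampling keeps households whole and strips geography", {
  city <- tiny_city(3, 30)
  md <- sample_microdata(city$pop, 1.0, seed = 3)
  expect_null(md$individuals$tract_id)
  expect_null(md$households$tract_id)
  expect_identical(nrow(md$households), nrow(city$pop$households))
  # member multisets identical to the source households
  src <- city$pop$individuals
  for (h in md$households$household_id[1:5]) {
    got <- sort(md$individuals$individual_id[md$individuals$household_id == h])
    want <- sort(src$individual_id[src$household_id == h])
    expect_identical(got, want)
  }
  # downstream outcome fields are not carried, behaviors are
  expect_false("diabetes" %in% names(md$individuals))
  expect_true(all(c("smoking", "alcohol_any_30d") %in% names(md$individuals)))
})

test_that("fractional microdata sampling is binomial in the household count", {
  p <- gen_params(n_tracts = 5, households_per_tract = 2000)
  pop <- generate_ground_truth(p, seed = 2)
  md <- sample_microdata(pop, 0.25, seed = 9)
  n <- nrow(pop$households)
  expect_lt(abs(nrow(md$households) - 0.25 * n), 3 * sqrt(n * 0.25 * 0.75))
  expect_error(sample_microdata(pop, 1e-9, seed = 1), "empty")
})

test_that("survey simulation respects known generating models", {
  city <- tiny_city(6, 1200, with_outcomes = FALSE)
  # all slopes zero, diabetes intercept = logit(0.25)
  flat <- true_model_set()
  for (nm in names(flat$models)) {
    flat$models[[nm]]$blocks <- lapply(flat$models[[nm]]$blocks, function(b) {
      b$estimate[] <- 0
      b
    })
    names(flat$models[[nm]]$blocks) <-
      vapply(flat$models[[nm]]$blocks, `[[`, character(1), "variable")
  }
  flat$models$diabetes$intercept <- logit(0.25)
  svy <- simulate_survey(city$pop, flat, 10000, seed = 4)
  expect_lt(abs(mean(svy$diabetes) - 0.25), 3 * sqrt(0.25 * 0.75 / 10000))

  # identical under the same seed
  svy2 <- simulate_survey(city$pop, flat, 10000, seed = 4)
  expect_identical(svy, svy2)

  # a huge exercise -> fruit/veg slope shows up as a monotone effect
  strong <- true_model_set()
  strong$models$fruitveg$blocks$exercise_any_30d$estimate <- 5
  svy3 <- simulate_survey(city$pop, strong, 10000, seed = 5)
  p_ex <- mean(svy3$fruitveg_5plus[svy3$exercise_any_30d == 1])
  p_no <- mean(svy3$fruitveg_5plus[svy3$exercise_any_30d == 0])
  expect_gt(p_ex, p_no)
})

test_that("changing a downstream generator leaves upstream draws untouched", {
  city <- tiny_city(2, 120, with_outcomes = FALSE)
  t1 <- true_model_set()
  t2 <- true_model_set()
  t2$models$diabetes$intercept <- 3  # downstream-most stage perturbed
  s1 <- simulate_survey(city$pop, t1, 400, seed = 8)
  s2 <- simulate_survey(city$pop, t2, 400, seed = 8)
  for (col in c("smoking", "alcohol_any_30d", "exercise_any_30d",
                "fruitveg_5plus", "bmi_value"))
    expect_identical(s1[[col]], s2[[col]])
  expect_false(identical(s1$diabetes, s2$diabetes))
})

test_that("oversized survey requests error", {
  city <- tiny_city(2, 10, with_outcomes = FALSE)
  expect_error(simulate_survey(city$pop, true_model_set(), 10000, seed = 1),
               "exceeds")
})
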