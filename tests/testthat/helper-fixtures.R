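# Shared in-code fixtures: a tiny fully-known city, and hand-built
# single-table annealing instances.

tiny_city <- function(n_tracts = 4, households_per_tract = 12, seed = 7,
                      with_outcomes = TRUE) {
  p <- gen_params(n_tracts = n_tracts, households_per_tract = households_per_tract)
  pop <- generate_ground_truth(p, seed = seed)
  if (with_outcomes) pop <- simulate_outcomes(pop, true_model_set(), seed = seed + 1)
  tables <- tabulate_constraints(pop)
  micro <- sample_microdata(pop, 1.0, seed = seed + 2)
  list(params = p, pop = pop, tables = tables, micro = micro)
}

# Microdata of single-person households with given sexes.
one_person_microdata <- function(sexes) {
  n <- length(sexes)
  structure(list(
    households = data.frame(household_id = paste0("H", seq_len(n)), hh_size = 1L,
                            stringsAsFactors = FALSE),
    individuals = data.frame(individual_id = paste0("I", seq_len(n)),
                             household_id = paste0("H", seq_len(n)),
                             sex = sexes, stringsAsFactors = FALSE)
  ), class = "microdata")
}

sex_table <- function(tract, female, male) {
  data.frame(tract_id = tract, table_name = "sex", level = "individual",
             variables = "sex", category_key = c("female", "male"),
             count = c(female, male), stringsAsFactors = FALSE)
}

# Exhaustive minimum TAE over all k-element multisets of single-person
# households against a sex table (brute-force oracle).
enumerate_min_tae <- function(sexes, k, female, male) {
  combos <- utils::combn(length(sexes) + k - 1, k)
  best <- Inf
  for (i in seq_len(ncol(combos))) {
    ms <- combos[, i] - seq_len(k) + 1
    tab <- table(factor(sexes[ms], levels = c("female", "male")))
    best <- min(best, sum(abs(tab - c(female, male))))
  }
  best
}

eligible_quiet <- function(...) eligible_population(..., quiet = TRUE)

# Flat named vectors of coefficients and standard errors of a fitted_model,
# keyed "variable.category" exactly like model_coefficients().
model_ses <- function(model) {
  out <- numeric(0)
  for (b in model$blocks) {
    s <- b$se
    names(s) <- if (b$type == "categorical")
      paste(b$variable, b$categories, sep = ".") else b$variable
    out <- c(out, s)
  }
  out
}

expect_no_na <- function(x) expect_false(anyNA(x))
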