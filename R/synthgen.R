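# Synthetic-data generator: a multi-tract ground-truth city with correlated
# demographics, household structure, ACS-style constraint tables, a
# PUMS-style coarse microdata sample, and a BRFSS-style survey simulated from
# known coefficient vectors. Every downstream stage is validated against the
# known truth this module produces.

AGE_BANDS <- c("0-17", "18-29", "30-39", "40-49", "50-59", "60-69", "70-79", "80-99")
ADULT_AGE_BANDS <- AGE_BANDS[-1]
INCOME_FINE <- c("lt10k", "10-15k", "15-20k", "20-25k", "25-35k", "35-50k", "50-75k", "gte75k")
INCOME_COLLAPSED <- c("lt25k", "25-35k", "gte35k")
INCOME_COLLAPSE_MAP <- c(
  "lt10k" = "lt25k", "10-15k" = "lt25k", "15-20k" = "lt25k", "20-25k" = "lt25k",
  "25-35k" = "25-35k", "35-50k" = "gte35k", "50-75k" = "gte35k", "gte75k" = "gte35k"
)

#' Default category spaces of the synthetic city
#'
#' @return named list of category vectors for each demographic variable.
#' @export
default_categories <- function() {
  list(
    sex = c("female", "male"),
    age_band = AGE_BANDS,
    head_age_band = ADULT_AGE_BANDS,
    race_ethnicity = c("white_nh", "black_nh", "hispanic", "other"),
    education = c("lt_hs", "hs", "gt_hs"),
    income_band = INCOME_COLLAPSED,
    income_band_fine = INCOME_FINE,
    employment = c("employed", "unemployed", "retired", "other"),
    tenure = c("own", "rent"),
    ancestry = c("portuguese", "cape_verdean", "latino", "other"),
    smoking = c("never", "former", "current")
  )
}

#' Map integer age to its age band
#'
#' Deterministic band map; ages above 99 are folded into the top band.
#'
#' @param age_years integer vector of ages (>= 0).
#' @return character vector of band labels.
#' @export
age_to_band <- function(age_years) {
  stopifnot(all(age_years >= 0))
  idx <- findInterval(pmin(age_years, 99), c(0, 18, 30, 40, 50, 60, 70, 80))
  AGE_BANDS[idx]
}

# Linear tract gradient in [0, 1]; single tract sits at 0.5.
tract_gradient <- function(n_tracts) {
  if (n_tracts == 1L) return(0.5)
  (seq_len(n_tracts) - 1) / (n_tracts - 1)
}

#' Generation parameters for the synthetic city
#'
#' Defaults emulate a mid-sized low-income US city: 31 census tracts
#' averaging roughly 3,000 residents each (about 95,000 in total at the
#' default household size of 2.4). Socioeconomic status varies monotonically
#' across the tract index (a low/mid/high SES mixture from which income,
#' education, tenure, and race/ethnicity are drawn, inducing realistic
#' within-household correlation), while the age structure varies on an
#' independent non-monotone pattern, so age-driven outcomes (diabetes) map
#' differently over the city than SES-driven behaviors.
#'
#' @param n_tracts number of census tracts.
#' @param households_per_tract households per tract; scalar or length
#'   `n_tracts` vector.
#' @param mean_household_size mean persons per household (>= 1).
#' @param p_child probability that a household member beyond the first is a
#'   child (under 18) rather than an additional adult.
#' @param ses_range range of the tract-level probability of low SES, from the
#'   first tract to the last.
#' @return object of class `gen_params`.
#' @export
gen_params <- function(n_tracts = 31L, households_per_tract = 1270L,
                       mean_household_size = 2.4, p_child = 0.4,
                       ses_range = c(0.2, 0.65)) {
  stopifnot(n_tracts >= 1, mean_household_size >= 1,
            p_child >= 0, p_child <= 1)
  hpt <- as.integer(rep_len(households_per_tract, n_tracts))
  if (any(hpt <= 0)) stop_config("households_per_tract must be strictly positive")
  g <- tract_gradient(n_tracts)

  p_low <- ses_range[1] + (ses_range[2] - ses_range[1]) * g
  p_high <- pmax(0.05, 0.35 - 0.30 * g)
  ses <- cbind(low = p_low, mid = 1 - p_low - p_high, high = p_high)

  # Non-monotone age pattern: share of older adults peaks mid-city.
  old_shift <- 0.5 + 0.5 * cos(3 * pi * g)
  young <- c(0.26, 0.20, 0.18, 0.15, 0.10, 0.07, 0.04)
  old <- c(0.12, 0.13, 0.15, 0.17, 0.17, 0.15, 0.11)
  adult_age <- t(vapply(old_shift, function(w) {
    p <- (1 - w) * young + w * old
    p / sum(p)
  }, numeric(7)))
  colnames(adult_age) <- ADULT_AGE_BANDS

  p <- list(
    n_tracts = as.integer(n_tracts),
    households_per_tract = hpt,
    mean_household_size = mean_household_size,
    p_child = p_child,
    categories = default_categories(),
    income_collapse = INCOME_COLLAPSE_MAP,
    bmi_sd = 4.5,
    profiles = list(
      ses = ses,
      sex_female = 0.49 + 0.05 * sin(2 * pi * g),
      adult_age = adult_age,
      education_by_ses = rbind(low = c(lt_hs = 0.45, hs = 0.40, gt_hs = 0.15),
                               mid = c(0.18, 0.45, 0.37),
                               high = c(0.05, 0.23, 0.72)),
      income_by_ses = rbind(low = c(0.22, 0.18, 0.18, 0.17, 0.15, 0.07, 0.02, 0.01),
                            mid = c(0.03, 0.05, 0.08, 0.12, 0.22, 0.25, 0.17, 0.08),
                            high = c(0.01, 0.01, 0.02, 0.04, 0.10, 0.20, 0.30, 0.32)),
      tenure_own_by_ses = c(low = 0.22, mid = 0.50, high = 0.78),
      race_by_ses = rbind(low = c(white_nh = 0.42, black_nh = 0.11, hispanic = 0.32, other = 0.15),
                          mid = c(0.60, 0.08, 0.20, 0.12),
                          high = c(0.74, 0.05, 0.11, 0.10)),
      ancestry_by_race = rbind(white_nh = c(portuguese = 0.45, cape_verdean = 0.04, latino = 0.02, other = 0.49),
                               black_nh = c(0.05, 0.55, 0.05, 0.35),
                               hispanic = c(0.02, 0.05, 0.80, 0.13),
                               other = c(0.10, 0.20, 0.10, 0.60)),
      employment_adult = c(employed = 0.68, unemployed = 0.10, retired = 0.04, other = 0.18),
      employment_senior = c(employed = 0.12, unemployed = 0.02, retired = 0.78, other = 0.08)
    )
  )
  colnames(p$profiles$income_by_ses) <- INCOME_FINE
  class(p) <- "gen_params"
  validate_gen_params(p)
  p
}

validate_gen_params <- function(params) {
  pr <- params$profiles
  for (t in seq_len(params$n_tracts)) {
    assert_prob_profile(pr$ses[t, ], "ses", t)
    assert_prob_profile(c(pr$sex_female[t], 1 - pr$sex_female[t]), "sex", t)
    assert_prob_profile(pr$adult_age[t, ], "adult_age", t)
  }
  for (nm in c("education_by_ses", "income_by_ses", "race_by_ses", "ancestry_by_race")) {
    for (r in rownames(pr[[nm]])) assert_prob_profile(pr[[nm]][r, ], nm, r)
  }
  assert_prob_profile(pr$employment_adult, "employment_adult", "all")
  assert_prob_profile(pr$employment_senior, "employment_senior", "all")
  if (any(lengths(params$categories) == 0)) stop_config("empty category space")
  invisible(params)
}

sample_cat <- function(n, categories, prob) {
  categories[sample.int(length(categories), n, replace = TRUE, prob = prob)]
}

# Uniform integer age within a named band.
age_within_band <- function(bands) {
  lo <- c("18-29" = 18, "30-39" = 30, "40-49" = 40, "50-59" = 50,
          "60-69" = 60, "70-79" = 70, "80-99" = 80)
  hi <- c("18-29" = 29, "30-39" = 39, "40-49" = 49, "50-59" = 59,
          "60-69" = 69, "70-79" = 79, "80-99" = 99)
  l <- lo[bands]; h <- hi[bands]
  as.integer(l + floor(stats::runif(length(bands)) * (h - l + 1)))
}

#' Generate the ground-truth city population
#'
#' Draws households tract by tract: a household size (1 + Poisson, capped at
#' 8), a latent household SES class from the tract profile, household-level
#' income, tenure, race/ethnicity, and ancestry conditional on SES, then
#' members — the first member is always an adult drawn from the tract's adult
#' age profile; further members are children with probability `p_child`,
#' otherwise additional adults. Education and employment are drawn per adult
#' conditional on SES and age. The household head is the oldest member and
#' `head_age_band` is that member's band.
#'
#' @param params a [gen_params()] object.
#' @param seed integer RNG seed; the population is a pure function of
#'   (params, seed).
#' @return object of class `population`: list with `households` and
#'   `individuals` data frames, plus the category spaces as an attribute.
#' @export
generate_ground_truth <- function(params, seed = 1L) {
  validate_gen_params(params)
  pr <- params$profiles
  cats <- params$categories
  set.seed(derive_seed(seed, "generate_ground_truth"))

  hh_list <- vector("list", params$n_tracts)
  ind_list <- vector("list", params$n_tracts)
  hh_offset <- 0L
  ind_offset <- 0L

  for (t in seq_len(params$n_tracts)) {
    tract_id <- sprintf("T%02d", t)
    n_hh <- params$households_per_tract[t]
    sizes <- pmin(1L + stats::rpois(n_hh, params$mean_household_size - 1), 8L)
    n_ind <- sum(sizes)
    hh_id <- sprintf("H%06d", hh_offset + seq_len(n_hh))

    ses <- sample_cat(n_hh, colnames(pr$ses), pr$ses[t, ])
    income_fine <- character(n_hh)
    race <- character(n_hh)
    tenure <- character(n_hh)
    for (s in c("low", "mid", "high")) {
      idx <- which(ses == s)
      if (!length(idx)) next
      income_fine[idx] <- sample_cat(length(idx), INCOME_FINE, pr$income_by_ses[s, ])
      race[idx] <- sample_cat(length(idx), cats$race_ethnicity, pr$race_by_ses[s, ])
      tenure[idx] <- ifelse(stats::runif(length(idx)) < pr$tenure_own_by_ses[s], "own", "rent")
    }
    ancestry <- character(n_hh)
    for (r in cats$race_ethnicity) {
      idx <- which(race == r)
      if (!length(idx)) next
      ancestry[idx] <- sample_cat(length(idx), cats$ancestry, pr$ancestry_by_race[r, ])
    }

    # Members: expand household-level draws to individuals.
    hidx <- rep.int(seq_len(n_hh), sizes)
    member_rank <- sequence(sizes)
    is_adult <- member_rank == 1L | stats::runif(n_ind) >= params$p_child
    age <- integer(n_ind)
    n_ad <- sum(is_adult)
    ad_band <- sample_cat(n_ad, ADULT_AGE_BANDS, pr$adult_age[t, ])
    age[is_adult] <- age_within_band(ad_band)
    age[!is_adult] <- as.integer(floor(stats::runif(n_ind - n_ad) * 18))
    band <- age_to_band(age)

    sex <- ifelse(stats::runif(n_ind) < pr$sex_female[t], "female", "male")
    edu <- rep("lt_hs", n_ind)  # children: below high school by definition
    emp <- rep("other", n_ind)
    ses_i <- ses[hidx]
    for (s in c("low", "mid", "high")) {
      idx <- which(is_adult & ses_i == s)
      if (!length(idx)) next
      edu[idx] <- sample_cat(length(idx), cats$education, pr$education_by_ses[s, ])
    }
    senior <- is_adult & age >= 65
    adult_w <- is_adult & age < 65
    emp[adult_w] <- sample_cat(sum(adult_w), cats$employment, pr$employment_adult)
    emp[senior] <- sample_cat(sum(senior), cats$employment, pr$employment_senior)

    head_age <- vapply(split(age, hidx), max, numeric(1))
    head_band <- age_to_band(as.integer(head_age))

    hh_list[[t]] <- data.frame(
      household_id = hh_id, tract_id = tract_id,
      head_age_band = head_band,
      income_band_fine = income_fine,
      income_band = unname(INCOME_COLLAPSE_MAP[income_fine]),
      tenure = tenure, hh_size = as.integer(sizes),
      stringsAsFactors = FALSE
    )
    ind_list[[t]] <- data.frame(
      individual_id = sprintf("I%07d", ind_offset + seq_len(n_ind)),
      household_id = hh_id[hidx], tract_id = tract_id,
      sex = sex, age_years = age, age_band = band,
      race_ethnicity = race[hidx], education = edu, employment = emp,
      ancestry = ancestry[hidx],
      # household fields repeated on each member row
      income_band = unname(INCOME_COLLAPSE_MAP[income_fine])[hidx],
      tenure = tenure[hidx],
      stringsAsFactors = FALSE
    )
    hh_offset <- hh_offset + n_hh
    ind_offset <- ind_offset + n_ind
  }

  pop <- list(households = do.call(rbind, hh_list),
              individuals = do.call(rbind, ind_list))
  rownames(pop$households) <- NULL
  rownames(pop$individuals) <- NULL
  attr(pop, "categories") <- cats
  class(pop) <- "population"
  pop
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("<population> %d tracts, %d households, %d individuals\n",
              length(unique(x$households$tract_id)),
              nrow(x$households), nrow(x$individuals)))
  invisible(x)
}

#' Default constraint-table definitions
#'
#' The thirteen small-area tables the reweighting targets: eight
#' individual-level (ancestry, sex, age, education, sex by age, sex by
#' education, age by education, sex by age by education) and five
#' household-level (head-of-household age, household income, tenure, tenure
#' by head age, income by head age).
#'
#' @return list of definitions with `name`, `variables`, `level`.
#' @export
default_constraint_defs <- function() {
  ind <- function(name, vars) list(name = name, variables = vars, level = "individual")
  hh <- function(name, vars) list(name = name, variables = vars, level = "household")
  list(
    ind("ancestry", "ancestry"),
    ind("sex", "sex"),
    ind("age", "age_band"),
    ind("education", "education"),
    ind("sex_age", c("sex", "age_band")),
    ind("sex_education", c("sex", "education")),
    ind("age_education", c("age_band", "education")),
    ind("sex_age_education", c("sex", "age_band", "education")),
    hh("head_age", "head_age_band"),
    hh("income", "income_band"),
    hh("tenure", "tenure"),
    hh("tenure_head_age", c("tenure", "head_age_band")),
    hh("income_head_age", c("income_band", "head_age_band"))
  )
}

category_space_for <- function(variable, categories) {
  space <- categories[[variable]]
  if (is.null(space)) stop_config("unknown constraint variable '%s'", variable)
  space
}

# Exhaustive cross-tabulation of `data[, variables]` over the declared
# category spaces (zero cells included), returned as a named count vector
# keyed by categories joined with "|".
tabulate_cells <- function(data, variables, categories) {
  spaces <- lapply(variables, category_space_for, categories = categories)
  facs <- lapply(seq_along(variables), function(i) {
    v <- data[[variables[i]]]
    bad <- !(v %in% spaces[[i]])
    if (any(bad))
      stop_config("value '%s' of variable '%s' outside its category space",
                  v[which(bad)[1]], variables[i])
    factor(v, levels = spaces[[i]])
  })
  tab <- table(facs)
  # as.vector(table) varies the first factor fastest, as does expand.grid
  keys <- do.call(expand.grid, c(spaces, stringsAsFactors = FALSE))
  counts <- as.vector(tab)
  names(counts) <- do.call(paste, c(keys, sep = "|"))
  counts
}

#' Tabulate per-tract constraint tables from a ground-truth population
#'
#' @param pop a `population`.
#' @param defs constraint definitions, as from [default_constraint_defs()].
#' @return long-format data frame of class `constraint_tables` with columns
#'   tract_id, table_name, level, variables, category_key, count. Every cell
#'   of each table's category space appears, including zero cells.
#' @export
tabulate_constraints <- function(pop, defs = default_constraint_defs()) {
  cats <- attr(pop, "categories") %||% default_categories()
  tracts <- sort(unique(pop$households$tract_id))
  out <- vector("list", length(tracts) * length(defs))
  k <- 0L
  for (tr in tracts) {
    ind_t <- pop$individuals[pop$individuals$tract_id == tr, , drop = FALSE]
    hh_t <- pop$households[pop$households$tract_id == tr, , drop = FALSE]
    for (d in defs) {
      data <- if (d$level == "individual") ind_t else hh_t
      counts <- tabulate_cells(data, d$variables, cats)
      k <- k + 1L
      out[[k]] <- data.frame(
        tract_id = tr, table_name = d$name, level = d$level,
        variables = paste(d$variables, collapse = "+"),
        category_key = names(counts), count = as.integer(counts),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("constraint_tables", "data.frame")
  res
}

#' Sample coarse-geography microdata from the ground truth
#'
#' Households are sampled whole (all members travel together) by independent
#' Bernoulli inclusion at the given fraction, and tract labels are stripped —
#' emulating a public-use microdata sample whose geography is coarser than
#' the tract. Behavioral fields attached by [simulate_outcomes()] for smoking
#' and alcohol are retained (the microdata carries them into the synthetic
#' population); downstream outcome fields are dropped.
#'
#' @param pop a `population` (optionally carrying simulated behaviors).
#' @param fraction sampling fraction in (0, 1].
#' @param seed RNG seed.
#' @return object of class `microdata` (households + individuals, no tract).
#' @export
sample_microdata <- function(pop, fraction = 1.0, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  set.seed(derive_seed(seed, "sample_microdata"))
  keep <- stats::runif(nrow(pop$households)) < fraction
  if (!any(keep)) stop_config("microdata sample is empty; increase the sampling fraction")
  hh <- pop$households[keep, , drop = FALSE]
  ind <- pop$individuals[pop$individuals$household_id %in% hh$household_id, , drop = FALSE]
  hh$tract_id <- NULL
  ind$tract_id <- NULL
  drop_cols <- intersect(c("exercise_any_30d", "fruitveg_5plus", "bmi_value",
                           "bmi_category", "diabetes"), names(ind))
  ind[drop_cols] <- NULL
  rownames(hh) <- NULL
  rownames(ind) <- NULL
  md <- list(households = hh, individuals = ind)
  attr(md, "categories") <- attr(pop, "categories")
  class(md) <- "microdata"
  md
}

#' @export
print.microdata <- function(x, ...) {
  cat(sprintf("<microdata> %d households, %d individuals (no tract labels)\n",
              nrow(x$households), nrow(x$individuals)))
  invisible(x)
}
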