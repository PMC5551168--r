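# End-to-end orchestration: simulate-data -> build-population -> fit-models
# (or ingest the published table) -> predict -> summarize -> export, with
# every stage's randomness derived from one master seed and a reproducibility
# manifest written at the end. The package's functions are the interface;
# each stage is also callable on its own with serialized intermediates.

#' Pipeline configuration
#'
#' @param out_dir directory all stage outputs are written to.
#' @param seed master RNG seed; every stage derives its own seed from it.
#' @param gen a [gen_params()] for the synthetic city.
#' @param truth a [true_model_set()] of generating models.
#' @param microdata_fraction fraction of households sampled into the
#'   coarse-geography microdata pool.
#' @param survey_n number of survey respondents simulated for model fitting.
#' @param anneal an [anneal_config()] (its seed field is overridden by a
#'   seed derived from the master seed).
#' @param use_fixture if TRUE, skip model fitting and ingest the packaged
#'   published coefficient table instead (calibrated against
#'   `fixture_targets`).
#' @param fixture_targets named targets for [calibrate_chain()] when
#'   `use_fixture` is TRUE.
#' @param specs candidate [model_spec()]s for [fit_chain()].
#' @param alpha backward-selection drop criterion.
#' @param n_reps Monte Carlo replicates.
#' @param mc_mode "outcome" or "coefficient".
#' @param min_age prediction eligibility age (inclusive).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, gen = gen_params(),
                            truth = true_model_set(),
                            microdata_fraction = 0.4, survey_n = 4000L,
                            anneal = anneal_config(),
                            use_fixture = FALSE,
                            fixture_targets = c(exercise = 0.649, fruitveg = 0.179,
                                                bmi = 27.0, diabetes = 0.111),
                            specs = default_model_specs(), alpha = 0.05,
                            n_reps = 1000L, mc_mode = "outcome", min_age = 21) {
  structure(list(out_dir = out_dir, seed = as.integer(seed), gen = gen, truth = truth,
                 microdata_fraction = microdata_fraction, survey_n = as.integer(survey_n),
                 anneal = anneal, use_fixture = isTRUE(use_fixture),
                 fixture_targets = fixture_targets, specs = specs, alpha = alpha,
                 n_reps = as.integer(n_reps), mc_mode = mc_mode, min_age = min_age),
            class = "pipeline_config")
}

write_csv_ <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Validate pipeline inputs
#'
#' Schema and consistency checks: constraint-table variables must exist at
#' the stated level in the microdata, every microdata category must appear
#' in the matching constraint table's category space, counts must be
#' nonnegative, and the model specs must respect the chain order. Problems
#' are collected and reported together rather than raised one at a time.
#'
#' @param microdata a `microdata` pool.
#' @param tables constraint tables (long format).
#' @param specs model specs in chain order.
#' @return list with `ok` (logical) and `errors` (character vector).
#' @export
validate_inputs <- function(microdata, tables, specs = default_model_specs()) {
  errors <- character(0)
  need <- c("tract_id", "table_name", "level", "variables", "category_key", "count")
  miss <- setdiff(need, names(tables))
  if (length(miss)) {
    errors <- c(errors, sprintf("constraint tables lack column(s): %s",
                                paste(miss, collapse = ", ")))
  } else {
    if (any(tables$count < 0)) errors <- c(errors, "negative constraint counts present")
    combos <- unique(tables[c("table_name", "level", "variables")])
    for (i in seq_len(nrow(combos))) {
      vars <- strsplit(combos$variables[i], "+", fixed = TRUE)[[1]]
      data <- if (combos$level[i] == "household") microdata$households else microdata$individuals
      for (v in vars) {
        if (is.null(data[[v]])) {
          errors <- c(errors, sprintf("table '%s': variable '%s' missing from %s-level microdata",
                                      combos$table_name[i], v, combos$level[i]))
          next
        }
      }
      if (all(vars %in% names(data))) {
        keys <- unique(tables$category_key[tables$table_name == combos$table_name[i]])
        mk <- unique(do.call(paste, c(data[vars], sep = "|")))
        bad <- setdiff(mk, keys)
        if (length(bad))
          errors <- c(errors, sprintf("table '%s': microdata categor%s %s absent from the constraint table",
                                      combos$table_name[i],
                                      if (length(bad) > 1) "ies" else "y",
                                      paste(bad, collapse = ", ")))
      }
    }
  }
  available <- chain_base_vars
  for (spec in specs) {
    used <- vapply(spec$blocks, `[[`, character(1), "variable")
    bad <- setdiff(used, available)
    if (length(bad))
      errors <- c(errors, sprintf("spec '%s' uses predictor(s) out of chain order: %s",
                                  spec$outcome, paste(bad, collapse = ", ")))
    available <- c(available, chain_spec_provides(spec$outcome))
  }
  list(ok = length(errors) == 0L, errors = errors)
}

#' Run the full pipeline
#'
#' Executes simulate-data, build-population, fit-models (or fixture
#' ingestion plus calibration), predict, summarize, and export in order,
#' writing each stage's outputs under `config$out_dir` and returning the
#' in-memory results together with a reproducibility manifest (per-stage
#' seeds, output file digests, package version, timestamps).
#'
#' @param config a [pipeline_config()].
#' @return list with `pop`, `microdata`, `survey`, `synthetic`, `models`,
#'   `mc`, `tract_summary`, `citywide`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  paths <- character(0)
  stage_seeds <- c(
    simulate_data = derive_seed(seed, "simulate-data"),
    simulate_outcomes = derive_seed(seed, "simulate-outcomes"),
    microdata = derive_seed(seed, "microdata"),
    survey = derive_seed(seed, "survey"),
    anneal = derive_seed(seed, "build-population"),
    calibrate = derive_seed(seed, "calibrate"),
    mc = derive_seed(seed, "monte-carlo")
  )

  # -- simulate-data
  pop <- generate_ground_truth(config$gen, seed = stage_seeds[["simulate_data"]])
  pop <- simulate_outcomes(pop, config$truth, seed = stage_seeds[["simulate_outcomes"]])
  tables <- tabulate_constraints(pop)
  micro <- sample_microdata(pop, config$microdata_fraction,
                            seed = stage_seeds[["microdata"]])
  survey <- simulate_survey(pop, config$truth, config$survey_n,
                            seed = stage_seeds[["survey"]])
  paths <- c(paths,
             write_csv_(pop$individuals, file.path(config$out_dir, "population.csv")),
             write_csv_(tables, file.path(config$out_dir, "constraints.csv")),
             write_csv_(micro$individuals, file.path(config$out_dir, "microdata_individuals.csv")),
             write_csv_(micro$households, file.path(config$out_dir, "microdata_households.csv")),
             write_csv_(survey, file.path(config$out_dir, "survey.csv")))

  chk <- validate_inputs(micro, tables, config$specs)
  if (!chk$ok)
    stop_config("input validation failed:\n  %s", paste(chk$errors, collapse = "\n  "))

  # -- build-population
  ac <- config$anneal
  ac$seed <- stage_seeds[["anneal"]]
  synth <- build_population(micro, tables, ac)
  paths <- c(paths,
             write_csv_(synth$individuals, file.path(config$out_dir, "synthetic_population.csv")),
             write_csv_(synth$report, file.path(config$out_dir, "anneal_report.csv")))

  # -- fit-models / ingest fixture
  elig <- eligible_population(synth$individuals, config$min_age, quiet = TRUE)
  if (config$use_fixture) {
    models <- lapply(stats::setNames(nm = c("exercise", "fruitveg", "bmi", "diabetes")),
                     model_from_table)
    models <- calibrate_chain(models, elig, config$fixture_targets,
                              seed = stage_seeds[["calibrate"]])
  } else {
    models <- fit_chain(survey, config$specs, alpha = config$alpha)
  }
  for (nm in names(models))
    paths <- c(paths, model_to_json(models[[nm]],
                                    file.path(config$out_dir, paste0("model_", nm, ".json"))))

  # -- predict
  mc <- monte_carlo(models, elig, n_reps = config$n_reps, mode = config$mc_mode,
                    seed = stage_seeds[["mc"]])
  paths <- c(paths, write_csv_(mc, file.path(config$out_dir, "mc_prevalence.csv")))

  # -- summarize
  ts <- summarize_tracts(mc)
  cw <- citywide_summary(mc)
  paths <- c(paths,
             write_csv_(ts, file.path(config$out_dir, "tract_summary.csv")),
             write_csv_(cw, file.path(config$out_dir, "citywide_summary.csv")))

  # -- export
  geoms <- make_tract_grid_geometries(sort(unique(ts$tract_id)))
  for (o in unique(ts$outcome)) {
    gp <- file.path(config$out_dir, paste0("map_", o, ".geojson"))
    export_geo(ts, geoms, o, gp)
    paths <- c(paths, gp)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("tractrisk")),
    timestamp = format(Sys.time(), tz = "UTC"),
    master_seed = seed,
    stage_seeds = as.list(stage_seeds),
    mc_mode = config$mc_mode, n_reps = config$n_reps, min_age = config$min_age,
    use_fixture = config$use_fixture,
    outputs = as.list(tools::md5sum(paths))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(pop = pop, tables = tables, microdata = micro, survey = survey,
       synthetic = synth, models = models, mc = mc,
       tract_summary = ts, citywide = cw, manifest = manifest)
}
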