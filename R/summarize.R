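# Aggregation of Monte Carlo replicates to tract-level prevalence summaries,
# citywide roll-ups, comparison against published reference estimates by
# confidence-interval overlap, ranking, and map-ready GeoJSON export.

sample_cv <- function(x) {
  m <- mean(x)
  s <- stats::sd(x)
  if (s == 0 || m == 0) 0 else s / m
}

#' Summarize Monte Carlo replicates by tract and outcome
#'
#' Mean prevalence, 2.5/97.5 percentile interval (linear-interpolation
#' quantiles, type 7), and coefficient of variation (sample standard
#' deviation over mean; defined 0 when the mean or the spread is 0) per
#' tract and outcome.
#'
#' @param mc an `mc_result` from [monte_carlo()].
#' @return data frame of class `tract_summary`: tract_id, outcome, mean,
#'   lower, upper, cv, n_reps, n_individuals.
#' @export
summarize_tracts <- function(mc) {
  if (!nrow(mc)) stop_config("empty Monte Carlo result")
  key <- interaction(mc$outcome, mc$tract_id, drop = TRUE)
  if (min(table(key)) < 2) stop_config("need at least 2 replicates per tract and outcome")
  n_ind <- attr(mc, "n_individuals")
  parts <- lapply(split(mc, key), function(d) {
    x <- d$prevalence
    data.frame(tract_id = d$tract_id[1], outcome = d$outcome[1],
               mean = mean(x),
               lower = unname(stats::quantile(x, 0.025, type = 7)),
               upper = unname(stats::quantile(x, 0.975, type = 7)),
               cv = sample_cv(x),
               n_reps = nrow(d),
               n_individuals = if (is.null(n_ind)) NA_integer_ else
                 unname(n_ind[d$tract_id[1]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$outcome, out$tract_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tract_summary", "data.frame")
  out
}

#' Citywide prevalence summary
#'
#' Per replicate, the population-weighted mean of tract prevalences; then
#' mean and 2.5/97.5 percentile interval per outcome — the synthetic-
#' microdata analogue of a published citywide prevalence estimate.
#'
#' @param mc an `mc_result`.
#' @param pop_sizes named numeric vector of tract population sizes (defaults
#'   to the individual counts recorded on the result).
#' @return data frame: outcome, mean, lower, upper, cv.
#' @export
citywide_summary <- function(mc, pop_sizes = attr(mc, "n_individuals")) {
  if (is.null(pop_sizes)) stop_config("tract population sizes are required")
  tracts <- sort(unique(mc$tract_id))
  missing_w <- setdiff(tracts, names(pop_sizes))
  if (length(missing_w))
    stop_config("no population size for tract(s): %s", paste(missing_w, collapse = ", "))
  w <- pop_sizes[tracts] / sum(pop_sizes[tracts])
  parts <- lapply(split(mc, mc$outcome), function(d) {
    per_rep <- vapply(split(d, d$rep), function(r) {
      sum(w[match(r$tract_id, tracts)] * r$prevalence)
    }, numeric(1))
    data.frame(outcome = d$outcome[1], mean = mean(per_rep),
               lower = unname(stats::quantile(per_rep, 0.025, type = 7)),
               upper = unname(stats::quantile(per_rep, 0.975, type = 7)),
               cv = sample_cv(per_rep), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Do two 95% intervals overlap?
#'
#' Closed-interval convention: a shared endpoint counts as overlap. The
#' operation is symmetric and reflexive.
#'
#' @param a,b [reference_estimate()] objects, or anything with `ci_lower`
#'   and `ci_upper` fields.
#' @return TRUE iff the closed intervals intersect.
#' @export
ci_overlap <- function(a, b) {
  for (x in list(a, b)) {
    if (!is.finite(x$ci_lower) || !is.finite(x$ci_upper) || x$ci_lower > x$ci_upper)
      stop_config("malformed interval [%s, %s]", format(x$ci_lower), format(x$ci_upper))
  }
  a$ci_lower <= b$ci_upper && b$ci_lower <= a$ci_upper
}

#' Rank tracts by mean prevalence
#'
#' @param summaries a `tract_summary`.
#' @param outcome outcome to rank on.
#' @param direction "ascending" or "descending".
#' @param priority optional character vector of priority tract ids to flag.
#' @param citywide_mean optional citywide mean used for above/below flags.
#' @return data frame in rank order (ties broken by tract_id) with columns
#'   tract_id, mean, rank, and — when requested — priority and
#'   vs_citywide.
#' @export
rank_tracts <- function(summaries, outcome, direction = c("ascending", "descending"),
                        priority = NULL, citywide_mean = NULL) {
  direction <- match.arg(direction)
  d <- summaries[summaries$outcome == outcome, , drop = FALSE]
  if (!nrow(d)) stop_config("outcome '%s' not present in the summaries", outcome)
  ord <- order(if (direction == "ascending") d$mean else -d$mean, d$tract_id)
  d <- d[ord, c("tract_id", "mean"), drop = FALSE]
  d$rank <- seq_len(nrow(d))
  if (!is.null(priority)) {
    d$priority <- d$tract_id %in% priority
    if (!is.null(citywide_mean))
      d$vs_citywide <- ifelse(d$mean > citywide_mean, "above citywide mean",
                              ifelse(d$mean < citywide_mean, "below citywide mean",
                                     "at citywide mean"))
  }
  rownames(d) <- NULL
  d
}

#' Simple square tract geometries for demonstration maps
#'
#' Lays tract ids out on a grid of unit squares — a stand-in for real tract
#' polygons when exercising the geographic export.
#'
#' @param tract_ids character vector of tract ids.
#' @param ncol grid width.
#' @return named list of polygons (each a list of (lon, lat) rings).
#' @export
make_tract_grid_geometries <- function(tract_ids, ncol = ceiling(sqrt(length(tract_ids)))) {
  out <- lapply(seq_along(tract_ids), function(i) {
    r <- (i - 1) %/% ncol
    c0 <- (i - 1) %% ncol
    ring <- list(c(c0, r), c(c0 + 1, r), c(c0 + 1, r + 1), c(c0, r + 1), c(c0, r))
    list(type = "Polygon", coordinates = list(ring))
  })
  names(out) <- tract_ids
  out
}

#' Export tract summaries as GeoJSON
#'
#' One feature per summarized tract with prevalence, interval bounds, and
#' coefficient of variation as properties. Tracts without a geometry are
#' dropped from the output with a warning listing them.
#'
#' @param summaries a `tract_summary`.
#' @param geometries named list of GeoJSON geometry objects (e.g. from
#'   [make_tract_grid_geometries()] or a parsed GeoJSON file).
#' @param outcome outcome to export.
#' @param path output file path.
#' @return the path, invisibly; attribute `missing_geometries` lists tracts
#'   without polygons.
#' @export
export_geo <- function(summaries, geometries, outcome, path) {
  d <- summaries[summaries$outcome == outcome, , drop = FALSE]
  if (!nrow(d)) stop_config("outcome '%s' not present in the summaries", outcome)
  missing_geo <- setdiff(d$tract_id, names(geometries))
  if (length(missing_geo))
    warning(sprintf("no geometry for tract(s): %s; feature(s) omitted",
                    paste(missing_geo, collapse = ", ")))
  keep <- d[!(d$tract_id %in% missing_geo), , drop = FALSE]
  features <- lapply(seq_len(nrow(keep)), function(i) {
    list(type = "Feature",
         geometry = geometries[[keep$tract_id[i]]],
         properties = list(tract_id = keep$tract_id[i],
                           outcome = outcome,
                           prevalence = keep$mean[i],
                           ci_lower = keep$lower[i],
                           ci_upper = keep$upper[i],
                           cv = keep$cv[i]))
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  out <- invisible(path)
  attr(out, "missing_geometries") <- missing_geo
  out
}

#' Compare pipeline estimates against published references by CI overlap
#'
#' @param citywide data frame from [citywide_summary()] with prevalences on
#'   the proportion scale.
#' @param references data frame as from [load_reference_estimates()]
#'   (percent scale).
#' @param label which reference label to compare against.
#' @return data frame: outcome, estimate/interval (percent), reference
#'   prevalence/interval, overlap verdict.
#' @export
compare_to_reference <- function(citywide, references, label) {
  ref <- references[references$label == label, , drop = FALSE]
  if (!nrow(ref)) stop_config("no reference rows with label '%s'", label)
  rows <- lapply(intersect(citywide$outcome, ref$outcome), function(o) {
    cw <- citywide[citywide$outcome == o, ]
    rf <- ref[ref$outcome == o, ]
    est <- reference_estimate("pipeline", o, 100 * cw$mean, 100 * cw$lower, 100 * cw$upper)
    tgt <- reference_estimate(label, o, rf$prevalence, rf$ci_lower, rf$ci_upper)
    data.frame(outcome = o,
               prevalence = est$prevalence, ci_lower = est$ci_lower, ci_upper = est$ci_upper,
               ref_prevalence = tgt$prevalence, ref_ci_lower = tgt$ci_lower,
               ref_ci_upper = tgt$ci_upper,
               overlap = ci_overlap(est, tgt), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
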