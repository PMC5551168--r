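# Tract-level population reconstruction by combinatorial reweighting:
# select a multiset of microdata households per tract (with replacement)
# minimizing the total absolute error (TAE) against that tract's constraint
# tables, using simulated annealing with a Metropolis acceptance rule and
# geometric cooling. The unit of assignment is the household — members
# travel together, so household-level constraints (tenure, income by head
# age) stay tabulatable; individual-level tables are evaluated over the
# members of the selected households.

#' Annealing configuration
#'
#' @param t0 initial temperature; NULL (default) auto-calibrates it so that
#'   roughly `target_accept` of initially worsening probe moves would be
#'   accepted.
#' @param alpha geometric cooling factor in (0, 1).
#' @param steps_per_temp proposals evaluated at each temperature.
#' @param max_iter maximum number of proposals.
#' @param stall_limit stop after this many proposals without a best-so-far
#'   improvement.
#' @param target_accept initial acceptance rate targeted by the
#'   auto-calibration of `t0`.
#' @param probe_moves number of probe proposals used for auto-calibration.
#' @param p_add,p_remove probabilities of proposing an insertion or a
#'   deletion instead of a replacement. Replacement alone cannot change the
#'   number of selected households, and the household-level tables pin that
#'   number (their cells sum to the tract's household count), so without
#'   insertions and deletions an initial overshoot could never be repaired.
#' @param reheats number of times the temperature is reset to `t0` after a
#'   stall, resuming from the best state found so far.
#' @param weights optional named per-table weights (default 1 for every
#'   table).
#' @param seed master RNG seed; per-tract seeds are derived from it.
#' @return object of class `anneal_config`.
#' @export
anneal_config <- function(t0 = NULL, alpha = 0.99, steps_per_temp = 100L,
                          max_iter = 50000L, stall_limit = 2000L,
                          target_accept = 0.8, probe_moves = 200L,
                          p_add = 0.15, p_remove = 0.15, reheats = 2L,
                          weights = NULL, seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, steps_per_temp >= 1, max_iter >= 1,
            stall_limit >= 1, probe_moves >= 1,
            target_accept > 0, target_accept < 1,
            p_add >= 0, p_remove >= 0, p_add + p_remove < 1, reheats >= 0)
  structure(list(t0 = t0, alpha = alpha, steps_per_temp = as.integer(steps_per_temp),
                 max_iter = as.integer(max_iter), stall_limit = as.integer(stall_limit),
                 target_accept = target_accept, probe_moves = as.integer(probe_moves),
                 p_add = p_add, p_remove = p_remove, reheats = as.integer(reheats),
                 weights = weights, seed = as.integer(seed)),
            class = "anneal_config")
}

#' Metropolis acceptance probability
#'
#' Improving or TAE-neutral moves (delta <= 0) are always accepted — the
#' neutral case keeps the search moving across plateaus of the integer-valued
#' objective. Worsening moves are accepted with probability
#' exp(-delta / temperature).
#'
#' @param delta change in the objective caused by the proposed move.
#' @param temperature current (strictly positive) temperature.
#' @return acceptance probability in \[0, 1\].
#' @export
acceptance_probability <- function(delta, temperature) {
  if (any(temperature <= 0)) stop_config("temperature must be strictly positive")
  ifelse(delta <= 0, 1, exp(-delta / temperature))
}

# ---- tract problem compilation ---------------------------------------------

# Compile one tract's annealing problem: a households x cells contribution
# matrix, the target vector, per-cell weights, and the person target (sum of
# the sex table, in which every person appears exactly once).
build_tract_problem <- function(microdata, tables, weights = NULL) {
  tract <- unique(tables$tract_id)
  if (length(tract) != 1L)
    stop_config("constraint tables span %d tracts; anneal one tract at a time", length(tract))
  hh <- microdata$households
  ind <- microdata$individuals
  n_h <- nrow(hh)
  if (n_h == 0L) stop_config("microdata contains no households")
  hh_row <- match(ind$household_id, hh$household_id)

  tnames <- unique(tables$table_name)
  blocks <- vector("list", length(tnames))
  target <- numeric(0)
  w <- numeric(0)
  contrib_cols <- list()
  for (ti in seq_along(tnames)) {
    tbl <- tables[tables$table_name == tnames[ti], , drop = FALSE]
    vars <- strsplit(tbl$variables[1], "+", fixed = TRUE)[[1]]
    keys <- tbl$category_key
    data <- if (tbl$level[1] == "household") hh else ind
    for (v in vars) {
      if (is.null(data[[v]]))
        stop_config("variable '%s' of table '%s' is missing from the %s-level microdata",
                    v, tnames[ti], tbl$level[1])
    }
    unit_key <- do.call(paste, c(data[vars], sep = "|"))
    ci <- match(unit_key, keys)
    if (anyNA(ci))
      stop_config("table '%s': microdata category '%s' absent from the constraint table",
                  tnames[ti], unit_key[which(is.na(ci))[1]])
    unit_row <- if (tbl$level[1] == "household") seq_len(n_h) else hh_row
    cm <- table(factor(unit_row, levels = seq_len(n_h)),
                factor(ci, levels = seq_along(keys)))
    contrib_cols[[ti]] <- unclass(cm)
    target <- c(target, tbl$count)
    wt <- if (!is.null(weights) && !is.null(weights[[tnames[ti]]])) weights[[tnames[ti]]] else 1
    w <- c(w, rep(wt, length(keys)))
  }
  contrib <- do.call(cbind, contrib_cols)
  dimnames(contrib) <- NULL
  storage.mode(contrib) <- "double"
  sex_tbl <- tables[tables$table_name == "sex", , drop = FALSE]
  person_target <- if (nrow(sex_tbl)) sum(sex_tbl$count) else sum(hh$hh_size) * 0
  list(tract_id = tract, contrib = contrib, target = target, w = w,
       hh_ids = hh$household_id, hh_sizes = hh$hh_size,
       person_target = person_target, target_sum = sum(abs(target) * w))
}

tae_of_counts <- function(counts, prob) sum(prob$w * abs(counts - prob$target))

#' Total absolute error of a tract assignment
#'
#' Sum over all constraint-table cells of the weighted absolute difference
#' between the tabulation of the selected households and the target count;
#' zero exactly when every cell matches.
#'
#' @param assignment list with `tract_id` and `selected` (multiset of
#'   microdata household ids; repeats allowed).
#' @param microdata the `microdata` pool.
#' @param tables the tract's constraint tables (long format).
#' @param weights optional named per-table weights.
#' @return nonnegative numeric TAE.
#' @export
total_absolute_error <- function(assignment, microdata, tables, weights = NULL) {
  prob <- build_tract_problem(microdata, tables, weights)
  rows <- match(assignment$selected, prob$hh_ids)
  if (anyNA(rows))
    stop_config("selected household '%s' is not in the microdata",
                assignment$selected[which(is.na(rows))[1]])
  counts <- if (length(rows)) colSums(prob$contrib[rows, , drop = FALSE]) else
    numeric(ncol(prob$contrib))
  tae_of_counts(counts, prob)
}

# Draw uniformly with replacement until the materialized person count first
# reaches the person target. Operates on the compiled problem.
initial_rows <- function(prob) {
  if (prob$person_target <= 0) {
    warning(sprintf("tract %s has person target 0; empty assignment", prob$tract_id))
    return(integer(0))
  }
  rows <- integer(0)
  persons <- 0
  n_h <- length(prob$hh_ids)
  while (persons < prob$person_target) {
    batch <- sample.int(n_h, max(16L, ceiling((prob$person_target - persons) /
                                                mean(prob$hh_sizes))), replace = TRUE)
    for (j in batch) {
      rows <- c(rows, j)
      persons <- persons + prob$hh_sizes[j]
      if (persons >= prob$person_target) break
    }
  }
  rows
}

#' Initial assignment for one tract
#'
#' Households drawn uniformly with replacement until the materialized person
#' count first reaches the tract's person target (the sum of the sex
#' constraint table, in which every person appears exactly once).
#'
#' @inheritParams total_absolute_error
#' @param seed RNG seed.
#' @return list with `tract_id` and `selected` household ids.
#' @export
initial_assignment <- function(microdata, tables, seed = 1L) {
  prob <- build_tract_problem(microdata, tables)
  set.seed(derive_seed(seed, "initial_assignment", prob$tract_id))
  rows <- initial_rows(prob)
  list(tract_id = prob$tract_id, selected = prob$hh_ids[rows])
}

#' Anneal one tract's household selection
#'
#' Proposal move: replace one uniformly chosen selected household with one
#' uniformly chosen microdata household; Metropolis acceptance at the
#' current temperature; geometric cooling every `steps_per_temp` proposals.
#' Returns the best assignment ever visited together with diagnostics. Fully
#' reproducible from the config seed.
#'
#' @inheritParams total_absolute_error
#' @param config an [anneal_config()].
#' @return list with `assignment` (tract_id, selected), `tae`, and
#'   `diagnostics` (TAE trace, acceptance counts, iterations, temperatures).
#' @export
anneal_tract <- function(microdata, tables, config = anneal_config()) {
  prob <- build_tract_problem(microdata, tables, config$weights)
  set.seed(derive_seed(config$seed, "anneal_tract", prob$tract_id))
  n_h <- length(prob$hh_ids)

  sel <- initial_rows(prob)
  if (length(sel) == 0L) {
    tae0 <- tae_of_counts(numeric(ncol(prob$contrib)), prob)
    return(list(assignment = list(tract_id = prob$tract_id, selected = character(0)),
                tae = tae0,
                diagnostics = list(iterations = 0L, initial_tae = tae0, t0 = NA_real_,
                                   accepted = 0L, trace = tae0,
                                   rel_tae = if (prob$target_sum > 0) tae0 / prob$target_sum else 0)))
  }
  counts <- colSums(prob$contrib[sel, , drop = FALSE])
  cur <- tae_of_counts(counts, prob)
  if (!is.finite(cur)) stop("internal error: non-finite TAE")
  best <- cur
  best_sel <- sel
  initial_tae <- cur

  # Auto-calibrate T0 from the positive deltas of probe moves off the
  # initial state (state not modified).
  t0 <- config$t0
  if (is.null(t0)) {
    pos <- numeric(0)
    for (k in seq_len(config$probe_moves)) {
      i <- sample.int(length(sel), 1L)
      j <- sample.int(n_h, 1L)
      d <- prob$contrib[j, ] - prob$contrib[sel[i], ]
      delta <- tae_of_counts(counts + d, prob) - cur
      if (delta > 0) pos <- c(pos, delta)
    }
    t0 <- if (length(pos)) -mean(pos) / log(config$target_accept) else 1
  }
  temp <- max(t0, 1e-9)

  accepted <- 0L
  stall <- 0L
  trace <- numeric(0)
  iter <- 0L
  reheats_left <- config$reheats
  while (iter < config$max_iter) {
    iter <- iter + 1L
    u <- stats::runif(1)
    if (u < config$p_add) {
      # insertion
      j <- sample.int(n_h, 1L)
      d <- prob$contrib[j, ]
      move <- 1L
    } else if (u < config$p_add + config$p_remove && length(sel) > 1L) {
      # deletion
      i <- sample.int(length(sel), 1L)
      d <- -prob$contrib[sel[i], ]
      move <- 2L
    } else {
      # replacement
      i <- sample.int(length(sel), 1L)
      j <- sample.int(n_h, 1L)
      d <- prob$contrib[j, ] - prob$contrib[sel[i], ]
      move <- 3L
    }
    new_tae <- tae_of_counts(counts + d, prob)
    delta <- new_tae - cur
    if (delta <= 0 || stats::runif(1) < exp(-delta / temp)) {
      if (move == 1L) sel <- c(sel, j)
      else if (move == 2L) sel <- sel[-i]
      else sel[i] <- j
      counts <- counts + d
      cur <- new_tae
      accepted <- accepted + 1L
      if (cur < best) {
        best <- cur
        best_sel <- sel
        stall <- 0L
      } else stall <- stall + 1L
    } else stall <- stall + 1L
    if (iter %% config$steps_per_temp == 0L) {
      temp <- temp * config$alpha
      trace <- c(trace, best)
    }
    if (best == 0) break
    if (stall >= config$stall_limit) {
      if (reheats_left > 0L) {
        # resume from the best state at the initial temperature
        reheats_left <- reheats_left - 1L
        sel <- best_sel
        counts <- colSums(prob$contrib[sel, , drop = FALSE])
        cur <- best
        temp <- max(t0, 1e-9)
        stall <- 0L
      } else break
    }
  }
  if (!is.finite(cur)) stop("internal error: non-finite TAE")

  list(assignment = list(tract_id = prob$tract_id, selected = prob$hh_ids[best_sel]),
       tae = best,
       diagnostics = list(iterations = iter, initial_tae = initial_tae, t0 = t0,
                          accepted = accepted, trace = trace,
                          acceptance_rate = accepted / iter,
                          rel_tae = if (prob$target_sum > 0) best / prob$target_sum else 0,
                          person_target = prob$person_target))
}

#' Build the full synthetic population
#'
#' Runs [anneal_tract()] independently for every tract present in the
#' constraint tables (tract-wise sub-seeds derived from the config seed, so
#' tracts are order-independent) and materializes the selected households
#' into a tract-resolved individual table with fresh synthetic ids.
#'
#' @param microdata the `microdata` pool.
#' @param all_tables constraint tables covering one or more tracts.
#' @param config an [anneal_config()].
#' @return object of class `synthetic_population`: `assignments`,
#'   materialized `individuals`, and a per-tract fit `report` (final TAE,
#'   relative TAE = TAE / sum of targets, iterations).
#' @export
build_population <- function(microdata, all_tables, config = anneal_config()) {
  tracts <- sort(unique(all_tables$tract_id))
  if (!length(tracts)) stop_config("constraint tables cover no tracts")
  fits <- vector("list", length(tracts))
  names(fits) <- tracts
  failed <- character(0)
  for (tr in tracts) {
    res <- tryCatch(
      anneal_tract(microdata, all_tables[all_tables$tract_id == tr, , drop = FALSE], config),
      error = function(e) e
    )
    if (inherits(res, "error")) failed <- c(failed, sprintf("%s (%s)", tr, conditionMessage(res)))
    fits[[tr]] <- res
  }
  if (length(failed))
    stop_config("annealing failed for tract(s): %s", paste(failed, collapse = "; "))

  ind <- microdata$individuals
  idx_by_hh <- split(seq_len(nrow(ind)), ind$household_id)
  mats <- lapply(tracts, function(tr) {
    sel <- fits[[tr]]$assignment$selected
    if (!length(sel)) return(NULL)
    pieces <- ind[unlist(idx_by_hh[sel], use.names = FALSE), , drop = FALSE]
    pieces$tract_id <- tr
    pieces
  })
  individuals <- do.call(rbind, mats)
  if (!is.null(individuals)) {
    individuals$source_individual_id <- individuals$individual_id
    individuals$source_household_id <- individuals$household_id
    individuals$individual_id <- sprintf("S%07d", seq_len(nrow(individuals)))
    rownames(individuals) <- NULL
  }

  report <- data.frame(
    tract_id = tracts,
    tae = vapply(fits, `[[`, numeric(1), "tae"),
    rel_tae = vapply(fits, function(f) f$diagnostics$rel_tae, numeric(1)),
    iterations = vapply(fits, function(f) f$diagnostics$iterations, integer(1)),
    persons = vapply(tracts, function(tr)
      if (is.null(mats[[match(tr, tracts)]])) 0L else nrow(mats[[match(tr, tracts)]]), integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(report) <- NULL
  sp <- list(assignments = lapply(fits, `[[`, "assignment"),
             individuals = individuals,
             report = report,
             diagnostics = lapply(fits, `[[`, "diagnostics"))
  attr(sp, "categories") <- attr(microdata, "categories")
  class(sp) <- "synthetic_population"
  sp
}

#' @export
print.synthetic_population <- function(x, ...) {
  cat(sprintf("<synthetic_population> %d tracts, %d individuals; mean relative TAE %.4f\n",
              nrow(x$report),
              if (is.null(x$individuals)) 0L else nrow(x$individuals),
              mean(x$report$rel_tae)))
  invisible(x)
}
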