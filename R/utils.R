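#' Derive a reproducible sub-seed from a master seed and a label
#'
#' All stochastic stages of the pipeline draw their own seed from the master
#' seed through this function, so that per-tract and per-stage work is
#' order-independent: running stages (or tracts) in a different order, or in
#' isolation, produces identical results. The derivation is a small
#' multiplicative string hash reduced modulo 2^31 - 1, which keeps every
#' derived seed inside R's integer range.
#'
#' @param master_seed integer master seed.
#' @param ... one or more labels (stage name, tract id, rep index) coerced to
#'   character and concatenated into the hash input.
#' @return a positive integer seed, strictly less than 2^31.
#' @export
derive_seed <- function(master_seed, ...) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L, is.finite(master_seed))
  key <- paste(c(format(master_seed, scientific = FALSE), as.character(unlist(list(...)))),
               collapse = "/")
  codes <- utf8ToInt(key)
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- as.numeric(master_seed) %% m
  for (cc in codes) {
    h <- (h * 131 + cc) %% m
  }
  as.integer(h %% (m - 1L) + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

assert_prob_profile <- function(p, variable, tract, tol = 1e-9) {
  if (any(!is.finite(p)) || any(p < 0) || abs(sum(p) - 1) > tol) {
    stop_config("invalid probability profile for variable '%s' in tract '%s': entries must be nonnegative and sum to 1",
                variable, tract)
  }
  invisible(TRUE)
}

#' Logit and inverse logit
#'
#' @param p probability in (0,1) for `logit`; `x` any real for `inv_logit`.
#' @return numeric vector.
#' @export
logit <- function(p) stats::qlogis(p)

#' @rdname logit
#' @param x real-valued linear predictor.
#' @export
inv_logit <- function(x) stats::plogis(x)
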