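# Fixed-step Markov-chain (Euler-type) scheme for Feller sample paths:
#   x_{k+1} = x_k + z_k,   z_k ~ Z_{x_k}(h),
# with the increment law re-resolved at the current position every step. For a
# state-independent family the scheme is exact in law at every grid time; for
# genuinely state-dependent families it converges weakly as h -> 0 provided
# |psi_x(xi)| <= C (1 + xi^2) uniformly in x (see exponent_growth_bound) and
# the process is unique for its restricted generator — uniqueness is an
# assumption the simulator cannot check.

validate_config <- function(x0, horizon, h, n_paths) {
  stopifnot(is.numeric(x0), length(x0) == 1, is.finite(x0))
  if (!(is.numeric(horizon) && length(horizon) == 1 && horizon > 0)) {
    stop("`horizon` must be a single positive number", call. = FALSE)
  }
  if (!(is.numeric(h) && length(h) == 1 && h > 0 && h <= horizon)) {
    stop("`h` must satisfy 0 < h <= horizon", call. = FALSE)
  }
  if (!(is.numeric(n_paths) && length(n_paths) == 1 && n_paths >= 1)) {
    stop("`n_paths` must be >= 1", call. = FALSE)
  }
}

simulate_one <- function(family, x0, horizon, h, path_id) {
  n_steps <- floor(horizon / h + 1e-9) # truncate: no partial final step
  states <- numeric(n_steps + 1)
  states[1] <- x0
  x <- x0
  for (k in seq_len(n_steps)) {
    z <- tryCatch(
      family$sampler(x, h, 1L),
      error = function(e) {
        stop(sprintf("simulation failed at step %d (t = %.6g, x = %.6g): %s",
                     k, (k - 1) * h, x, conditionMessage(e)), call. = FALSE)
      })
    x <- x + z
    states[k + 1] <- x
  }
  data.frame(path_id = path_id, step = 0:n_steps, time = (0:n_steps) * h,
             state = states)
}

new_feller_paths <- function(df, family_label, x0, horizon, h, seed) {
  structure(df,
            class = c("feller_paths", "data.frame"),
            model = family_label, x0 = x0, horizon = horizon, h = h,
            seed = seed)
}

#' Simulate one approximate Feller sample path
#'
#' Runs the fixed-step scheme from `x0` over `floor(horizon/h)` steps of size
#' `h`, drawing each increment from the family's law at the current position.
#' Path `path_id` of an ensemble uses RNG substream `path_id` of `seed`, so
#' the same path is reproduced whether simulated alone or inside
#' [simulate_feller()].
#'
#' @param family A `levy_family`.
#' @param x0 Starting point.
#' @param horizon Time horizon T > 0.
#' @param h Step size in (0, T]. When T is not a multiple of h the path stops
#'   at the last full step.
#' @param seed Integer seed; `NULL` consumes the current RNG state.
#' @param path_id Substream index, default 1.
#' @return A `feller_paths` data frame with columns `path_id`, `step`,
#'   `time`, `state`; the discrete states are read as a right-continuous step
#'   function.
#' @export
simulate_path <- function(family, x0, horizon, h, seed = NULL, path_id = 1L) {
  stopifnot(inherits(family, "levy_family"))
  validate_config(x0, horizon, h, 1)
  df <- with_seed(seed, simulate_one(family, x0, horizon, h, path_id),
                  substream = path_id)
  new_feller_paths(df, family$label, x0, horizon, h, seed)
}

#' Simulate an ensemble of Feller sample paths
#'
#' Generates `n_paths` mutually independent paths; path j uses RNG substream
#' j of `seed` (L'Ecuyer-CMRG), so each path is identical whether or not the
#' others are generated.
#'
#' @inheritParams simulate_path
#' @param n_paths Number of paths.
#' @param seed Integer root seed (required here: ensembles are defined by
#'   their substream layout).
#' @return A `feller_paths` data frame in long format.
#' @examples
#' fam <- named_family("bpc")
#' paths <- simulate_feller(fam, x0 = 0, horizon = 1, h = 0.05,
#'                          n_paths = 3, seed = 42)
#' summary(paths)
#' @export
simulate_feller <- function(family, x0, horizon, h, n_paths = 1L, seed = 1L) {
  stopifnot(inherits(family, "levy_family"))
  validate_config(x0, horizon, h, n_paths)
  state <- rng_state(seed, 0L)
  pieces <- lapply(seq_len(n_paths), function(j) {
    state <<- parallel::nextRNGStream(state)
    tryCatch(
      with_state(state, simulate_one(family, x0, horizon, h, j)),
      error = function(e) {
        stop(sprintf("path %d: %s", j, conditionMessage(e)), call. = FALSE)
      })
  })
  new_feller_paths(do.call(rbind, pieces), family$label, x0, horizon, h, seed)
}

#' @export
print.feller_paths <- function(x, ...) {
  cat(sprintf(
    "<feller_paths> model %s: %d path(s), T = %g, h = %g, x0 = %g, seed = %s\n",
    attr(x, "model"), length(unique(x$path_id)), attr(x, "horizon"),
    attr(x, "h"), attr(x, "x0"),
    if (is.null(attr(x, "seed"))) "<current RNG>" else attr(x, "seed")))
  print(utils::head(as.data.frame(x)))
  if (nrow(x) > 6) cat(sprintf("... %d rows total\n", nrow(x)))
  invisible(x)
}

#' @export
summary.feller_paths <- function(object, ...) {
  terminal <- terminal_values(object)
  out <- list(model = attr(object, "model"),
              n_paths = length(unique(object$path_id)),
              horizon = attr(object, "horizon"), h = attr(object, "h"),
              x0 = attr(object, "x0"),
              terminal = summary(terminal))
  class(out) <- "summary.feller_paths"
  out
}

#' @export
print.summary.feller_paths <- function(x, ...) {
  cat(sprintf("Feller ensemble: model %s, %d path(s), T = %g, h = %g, x0 = %g\n",
              x$model, x$n_paths, x$horizon, x$h, x$x0))
  cat("Terminal values:\n")
  print(x$terminal)
  invisible(x)
}

#' Terminal values of an ensemble
#'
#' @param paths A `feller_paths` object.
#' @return Numeric vector, one terminal state per path (ordered by path id).
#' @export
terminal_values <- function(paths) {
  stopifnot(inherits(paths, "feller_paths"))
  last_step <- max(paths$step)
  paths$state[paths$step == last_step]
}

#' Monte Carlo probe of weak convergence in the step size
#'
#' For each step size in `h_list`, estimates \eqn{E[f(X_T)]} from an ensemble
#' of `n_paths` paths and reports the estimate with its standard error. The
#' output is evidence of Cauchy-sequence behaviour at Monte Carlo resolution,
#' not a convergence verdict; for a weakly convergent scheme successive
#' estimates should agree within a few pooled standard errors.
#'
#' @param family A `levy_family`.
#' @param x0,horizon Start point and horizon.
#' @param h_list Strictly decreasing step sizes, each <= `horizon`.
#' @param f Bounded functional of the terminal value (vectorised).
#' @param n_paths Paths per step size.
#' @param seed Root seed; step size i uses substream block i (offset by
#'   `i * n_paths`), so the rows are mutually independent.
#' @return Data frame with columns `h`, `estimate`, `se`, `n_paths`.
#' @export
weak_convergence_probe <- function(family, x0, horizon, h_list, f,
                                   n_paths = 2000L, seed = 1L) {
  stopifnot(length(h_list) >= 1)
  if (any(diff(h_list) >= 0)) {
    stop("`h_list` must be strictly decreasing", call. = FALSE)
  }
  if (any(h_list > horizon)) {
    stop("every step size must be <= `horizon`", call. = FALSE)
  }
  state <- rng_state(seed, 0L)
  rows <- lapply(seq_along(h_list), function(i) {
    h <- h_list[i]
    pieces <- vapply(seq_len(n_paths), function(j) {
      state <<- parallel::nextRNGStream(state)
      df <- with_state(state, simulate_one(family, x0, horizon, h, j))
      df$state[nrow(df)]
    }, numeric(1))
    vals <- f(pieces)
    data.frame(h = h, estimate = mean(vals),
               se = stats::sd(vals) / sqrt(n_paths), n_paths = n_paths)
  })
  do.call(rbind, rows)
}
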