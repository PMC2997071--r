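# State-indexed families of Levy processes: finite mixtures over separated
# regions and parameter-field families. A family carries a state-indexed
# exponent psi_x(xi) and an exact-in-law increment sampler Z_x(h); the
# simulator and the CF diagnostics only talk to this surface.

new_levy_family <- function(kind, exponent, sampler, label,
                            components = NULL, mixers = NULL,
                            constraints = NULL, value_fn = NULL) {
  structure(
    list(kind = kind, exponent = exponent, sampler = sampler, label = label,
         components = components, mixers = mixers,
         constraints = constraints, value_fn = value_fn),
    class = "levy_family"
  )
}

#' @export
print.levy_family <- function(x, ...) {
  cat(sprintf("<levy_family> %s (%s)\n", x$label, x$kind))
  if (!is.null(x$components)) {
    cat(sprintf("  %d component(s): %s\n", length(x$components),
                paste(vapply(x$components, `[[`, "", "name"), collapse = ", ")))
  }
  invisible(x)
}

#' Finite mixture family of Levy processes
#'
#' Builds the state-indexed family with exponent
#' \eqn{\psi_x(\xi) = \sum_i \phi_i(x)\,\psi_i(\xi)} from components
#' \eqn{\psi_i} and mixing functions \eqn{\phi_i}. Increments are sampled
#' exactly through the equality in distribution
#' \eqn{Z_x(h) = \sum_i L_i(\phi_i(x)\,h)} with independent component draws;
#' components with \eqn{\phi_i(x) h = 0} are skipped (they contribute exactly
#' 0 and consume no randomness). \eqn{\sum_i \phi_i(x) > 0} is required on the
#' verification grid to avoid the pathological frozen case.
#'
#' @param components List of `levy_component`s.
#' @param mixers List of `mixing_function`s, same length.
#' @param label Display name.
#' @return A `levy_family` of kind `"mixture"`.
#' @export
mixture_family <- function(components, mixers, label = "mixture") {
  stopifnot(is.list(components), is.list(mixers))
  if (length(components) != length(mixers) || length(components) < 1) {
    construction_error(
      "`components` and `mixers` must have equal length >= 1 (got %d and %d)",
      length(components), length(mixers))
  }
  ok <- vapply(components, inherits, logical(1), "levy_component")
  if (!all(ok)) construction_error("all `components` must be levy_component objects")
  ok <- vapply(mixers, inherits, logical(1), "mixing_function")
  if (!all(ok)) construction_error("all `mixers` must be mixing_function objects")

  endpoints <- unlist(lapply(mixers, attr, "region"))
  grid <- state_grid(extra = endpoints)
  wsum <- Reduce(`+`, lapply(mixers, function(m) m$fn(grid)))
  if (any(wsum <= 0)) {
    construction_error(
      "mixing functions sum to 0 at x = %.6g; every state needs positive total weight",
      grid[which(wsum <= 0)[1]])
  }

  weights_at <- function(x) vapply(mixers, function(m) m$fn(x), numeric(1))
  exponent <- function(x, xi) {
    w <- weights_at(x)
    out <- complex(length(xi))
    for (i in seq_along(components)) {
      if (w[i] != 0) out <- out + w[i] * components[[i]]$exponent(xi)
    }
    out
  }
  sampler <- function(x, h, n) {
    w <- weights_at(x)
    out <- numeric(n)
    for (i in seq_along(components)) {
      hi <- w[i] * h
      if (hi > 0) out <- out + components[[i]]$sampler(hi, n)
    }
    out
  }
  new_levy_family("mixture", exponent, sampler, label,
                  components = components, mixers = mixers)
}

#' Draw increments of a family at a state
#'
#' Returns `n` independent draws of \eqn{Z_x(h)}, the family's increment over
#' elapsed time `h` at state `x`. With a `seed` the draw is bit-reproducible
#' (and leaves the caller's RNG state untouched); with `seed = NULL` the
#' current RNG state is consumed.
#'
#' @param family A `levy_family` (a `levy_component` is accepted too, ignoring
#'   `x`).
#' @param x State at which the increment law is resolved.
#' @param h Elapsed time, > 0.
#' @param n Number of draws, >= 1.
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n`.
#' @export
sample_increment <- function(family, x, h, n, seed = NULL) {
  stopifnot(is.numeric(h), length(h) == 1)
  if (!(h > 0)) stop("`h` must be positive", call. = FALSE)
  stopifnot(is.numeric(n), length(n) == 1, n >= 1)
  if (inherits(family, "levy_component")) {
    return(with_seed(seed, family$sampler(h, n)))
  }
  stopifnot(inherits(family, "levy_family"))
  with_seed(seed, family$sampler(x, h, n))
}

# --- parameter-field families ---------------------------------------------

as_state_fn <- function(f) {
  if (is.function(f)) f else {
    stopifnot(is.numeric(f), length(f) == 1)
    function(x) rep(f, length(x))
  }
}

field_violation <- function(kind, what, grid, bad) {
  construction_error(
    "%s family constraint violated: %s at x = %.6g", kind, what, grid[bad[1]])
}

#' Parameter-field family of Levy processes
#'
#' Builds a state-indexed family by making the parameters of a named Levy
#' class functions of the state: stable-like (\eqn{\alpha(x)}, scale),
#' NIG-like (\eqn{\alpha, \beta(x), \delta, \mu}) or Meixner-like
#' (\eqn{a(x), b(x), d(x), m(x)}). Admissibility is screened on a dense state
#' grid at construction, never at sampling time: stable-like needs
#' \eqn{\alpha(x)} bounded away from 0 and 2 (within
#' \eqn{[\epsilon_0, 2 - \epsilon_0]}), NIG-like needs
#' \eqn{|\beta(x)| \le \alpha - \epsilon_0}, Meixner-like needs
#' \eqn{a(x) \ge \epsilon_0}, \eqn{|b(x)| \le \pi - \epsilon_0} and
#' \eqn{d(x) \ge \epsilon_0}. A violation raises a construction error naming
#' the offending state.
#'
#' @param kind One of `"stable"`, `"nig"`, `"meixner"`.
#' @param param_fns Named list; each entry a vectorised function of the state
#'   or a constant. Required names — stable: `alpha`, `scale`; nig: `alpha`,
#'   `beta`, `delta`, `mu`; meixner: `a`, `b`, `d`, `m`.
#' @param eps0 Margin bounding the parameter functions away from their
#'   critical values.
#' @param grid Verification grid.
#' @param label Display name.
#' @return A `levy_family` of kind `"parameter-field"`.
#' @export
parameter_field_family <- function(kind = c("stable", "nig", "meixner"),
                                   param_fns, eps0 = 1e-2,
                                   grid = state_grid(), label = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.list(param_fns), eps0 > 0)
  need <- switch(kind,
                 stable = c("alpha", "scale"),
                 nig = c("alpha", "beta", "delta", "mu"),
                 meixner = c("a", "b", "d", "m"))
  missing <- setdiff(need, names(param_fns))
  if (length(missing)) {
    construction_error("missing parameter function(s) for %s family: %s",
                       kind, paste(missing, collapse = ", "))
  }
  fns <- lapply(param_fns[need], as_state_fn)
  names(fns) <- need

  vals <- lapply(fns, function(f) f(grid))
  if (any(!is.finite(unlist(vals)))) {
    construction_error("%s parameter function is non-finite on the grid", kind)
  }
  if (kind == "stable") {
    bad <- which(vals$alpha < eps0 | vals$alpha > 2 - eps0)
    if (length(bad)) field_violation(kind, sprintf(
      "alpha(x) = %.6g outside [%g, %g]", vals$alpha[bad[1]], eps0, 2 - eps0),
      grid, bad)
    bad <- which(vals$scale <= 0)
    if (length(bad)) field_violation(kind, "scale(x) <= 0", grid, bad)
  } else if (kind == "nig") {
    bad <- which(abs(vals$beta) > vals$alpha - eps0)
    if (length(bad)) field_violation(kind, sprintf(
      "|beta(x)| = %.6g > alpha - eps0 = %.6g",
      abs(vals$beta[bad[1]]), vals$alpha[bad[1]] - eps0), grid, bad)
    bad <- which(vals$delta <= 0)
    if (length(bad)) field_violation(kind, "delta(x) <= 0", grid, bad)
  } else {
    bad <- which(vals$a < eps0)
    if (length(bad)) field_violation(kind, sprintf(
      "a(x) = %.6g < eps0 = %g", vals$a[bad[1]], eps0), grid, bad)
    bad <- which(abs(vals$b) > pi - eps0)
    if (length(bad)) field_violation(kind, sprintf(
      "|b(x)| = %.6g > pi - eps0 = %.6g", abs(vals$b[bad[1]]), pi - eps0),
      grid, bad)
    bad <- which(vals$d < eps0)
    if (length(bad)) field_violation(kind, sprintf(
      "d(x) = %.6g < eps0 = %g", vals$d[bad[1]], eps0), grid, bad)
  }

  component_at <- switch(kind,
    stable = function(x) levy_stable(fns$alpha(x), fns$scale(x)),
    nig = function(x) levy_nig(fns$alpha(x), fns$beta(x), fns$delta(x), fns$mu(x)),
    meixner = function(x) levy_meixner(fns$a(x), fns$b(x), fns$d(x), fns$m(x)))

  exponent <- function(x, xi) component_at(x)$exponent(xi)
  sampler <- function(x, h, n) component_at(x)$sampler(h, n)
  if (is.null(label)) label <- paste0(kind, "-field")
  new_levy_family("parameter-field", exponent, sampler, label,
                  constraints = list(kind = kind, eps0 = eps0, param_fns = fns))
}

# --- named examples --------------------------------------------------------

# unit triangle wave, period 2*pi, range [-1, 1]; Lipschitz but not smooth
triangle_wave <- function(x) 2 / pi * asin(sin(x))

#' Preconfigured example families
#'
#' Returns one of the package's built-in Feller families:
#' \describe{
#'   \item{`bpc`}{Brownian--Poisson--Cauchy mixture: standard Brownian motion
#'     on \eqn{(-\infty, -6]}, Poisson(1) on \eqn{[-5, 5]}, Cauchy (stable
#'     \eqn{\alpha = 1}, scale 1) on \eqn{[6, \infty)}, linear ramps of width
#'     1 on the gaps (a partition of unity there).}
#'   \item{`stable_like`}{symmetric stable-like with oscillating index
#'     \eqn{\alpha(x) = 1.5 + 0.49\,\mathrm{tri}(x)} (triangle wave, period
#'     \eqn{2\pi}, range \eqn{[1.01, 1.99]}), scale 1: Cauchy-like near the
#'     troughs, nearly Brownian near the crests.}
#'   \item{`nig_like`}{mean-reverting NIG-like family with \eqn{\alpha = 2},
#'     \eqn{\delta = 1}, \eqn{\mu = 0} and \eqn{\beta(x) = -\tanh(x)}: the
#'     state-dependent skewness, not a drift, pulls the process back toward
#'     0.}
#'   \item{`meixner_like`}{Meixner-like family with \eqn{b = 0}, \eqn{d = 1},
#'     \eqn{m = 0} and \eqn{a(x) = 0.5 + 1.5\,e^{-x^2/8}}: the enlarged
#'     step-scale parameter near the origin slows the exponential decay of
#'     the transition density there, so the process moves with bigger steps
#'     around 0.}
#' }
#'
#' @param name One of `"bpc"`, `"stable_like"`, `"nig_like"`,
#'   `"meixner_like"`.
#' @return A `levy_family`.
#' @examples
#' fam <- named_family("bpc")
#' sample_increment(fam, x = 0, h = 1, n = 5, seed = 1) # Poisson counts
#' @export
named_family <- function(name) {
  stopifnot(is.character(name), length(name) == 1)
  switch(name,
    bpc = {
      mixers <- region_mixers(
        list(c(-Inf, -6), c(-5, 5), c(6, Inf)), epsilon = 1)
      fam <- mixture_family(
        list(levy_brownian(0, 1), levy_poisson(1), levy_stable(1, 1)),
        mixers, label = "bpc")
      fam$value_fn <- function(x) {
        # dominant-component index, for color coding
        w <- vapply(fam$mixers, function(m) m$fn(x), numeric(length(x)))
        if (is.null(dim(w))) w <- matrix(w, nrow = 1)
        apply(w, 1, which.max)
      }
      fam
    },
    stable_like = {
      alpha_fn <- function(x) 1.5 + 0.49 * triangle_wave(x)
      fam <- parameter_field_family(
        "stable", list(alpha = alpha_fn, scale = 1), eps0 = 1e-2,
        label = "stable_like")
      fam$value_fn <- alpha_fn
      fam
    },
    nig_like = {
      fam <- parameter_field_family(
        "nig",
        list(alpha = 2, beta = function(x) -tanh(x), delta = 1, mu = 0),
        eps0 = 0.5, label = "nig_like")
      fam$value_fn <- function(x) -tanh(x)
      fam
    },
    meixner_like = {
      a_fn <- function(x) 0.5 + 1.5 * exp(-x^2 / 8)
      fam <- parameter_field_family(
        "meixner", list(a = a_fn, b = 0, d = 1, m = 0), eps0 = 1e-2,
        label = "meixner_like")
      fam$value_fn <- a_fn
      fam
    },
    stop(sprintf("unknown model '%s'; available models: %s",
                 name, paste(list_models(), collapse = ", ")), call. = FALSE)
  )
}

#' Names of the built-in example families
#'
#' @return Character vector of registry names accepted by [named_family()]
#'   and the command-line interface.
#' @export
list_models <- function() {
  c("bpc", "stable_like", "nig_like", "meixner_like")
}
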