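# Mixing functions: non-negative, bounded, Lipschitz weights on the state
# space. A state-indexed exponent psi_x(xi) = sum_i phi_i(x) psi_i(xi) built
# from such weights always corresponds to an existing Feller process, which is
# what makes the mixture construction safe to simulate from.

# default verification grid: x in [-50, 50], 1e4 points
state_grid <- function(extra = numeric(0)) {
  g <- seq(-50, 50, length.out = 1e4)
  sort(unique(c(g, extra[is.finite(extra)])))
}

construction_error <- function(msg, ...) {
  stop(sprintf(msg, ...), call. = FALSE)
}

#' Declare a mixing function
#'
#' Wraps a state-space weight \eqn{\phi: R \to [0, \infty)} with its declared
#' supremum and Lipschitz constant, and verifies both numerically on a dense
#' grid (non-negativity, boundedness, and a sampled finite-difference
#' Lipschitz bound; violations beyond 1e-8 raise a construction error). The
#' check is constructive validation on the grid, not a proof.
#'
#' @param fn Vectorised function of the state.
#' @param bound Declared supremum of `fn`.
#' @param lipschitz Declared Lipschitz constant.
#' @param grid Verification grid (default: 1e4 points on \eqn{[-50, 50]}).
#' @return A `mixing_function` object (callable via `$fn`).
#' @export
mixing_function <- function(fn, bound, lipschitz, grid = state_grid()) {
  stopifnot(is.function(fn), is.numeric(bound), is.numeric(lipschitz))
  v <- fn(grid)
  tol <- 1e-8
  if (any(!is.finite(v))) {
    construction_error("mixing function is non-finite at x = %.6g",
                       grid[which(!is.finite(v))[1]])
  }
  if (any(v < -tol)) {
    construction_error("mixing function is negative at x = %.6g (value %.3g)",
                       grid[which(v < -tol)[1]], min(v))
  }
  if (any(v > bound + tol)) {
    construction_error(
      "mixing function exceeds its declared bound %g at x = %.6g (value %.6g)",
      bound, grid[which(v > bound + tol)[1]], max(v))
  }
  slopes <- abs(diff(v)) / diff(grid)
  if (any(slopes > lipschitz + tol)) {
    i <- which(slopes > lipschitz + tol)[1]
    construction_error(
      "mixing function violates its Lipschitz constant %g near x = %.6g (observed slope %.6g)",
      lipschitz, grid[i], slopes[i])
  }
  structure(list(fn = fn, bound = bound, lipschitz = lipschitz),
            class = "mixing_function")
}

#' @export
print.mixing_function <- function(x, ...) {
  cat(sprintf("<mixing_function> bound %g, Lipschitz constant %g\n",
              x$bound, x$lipschitz))
  invisible(x)
}

# distance from points x to the closed interval [lo, hi]
interval_distance <- function(x, lo, hi) {
  pmax(lo - x, x - hi, 0)
}

#' Mollified indicators of uniformly separated regions
#'
#' Given disjoint closed intervals separated by at least `epsilon`, returns one
#' mixing function per region: identically 1 on its region, 0 at distance
#' `epsilon` or more, linear ramp in between (bound 1, Lipschitz constant
#' `1/epsilon`). On a gap of width exactly `epsilon` between two adjacent
#' regions the two ramps sum to 1, giving a partition of unity there.
#'
#' @param regions List of length-2 numeric vectors `c(lo, hi)`; `-Inf`/`Inf`
#'   endpoints give half-infinite regions.
#' @param epsilon Uniform separation distance, > 0.
#' @return List of `mixing_function`s, one per region, each carrying its
#'   region as the `region` attribute.
#' @examples
#' mix <- region_mixers(list(c(-1, 1)), epsilon = 1)
#' mix[[1]]$fn(c(0, 1.5, 2)) # 1, 0.5, 0
#' @export
region_mixers <- function(regions, epsilon) {
  stopifnot(is.list(regions), length(regions) >= 1,
            is.numeric(epsilon), length(epsilon) == 1, epsilon > 0)
  iv <- lapply(regions, function(r) {
    stopifnot(is.numeric(r), length(r) == 2)
    if (r[1] > r[2]) construction_error("region has lo > hi: [%g, %g]", r[1], r[2])
    r
  })
  n <- length(iv)
  if (n > 1) {
    ord <- order(vapply(iv, `[`, numeric(1), 1))
    for (k in seq_len(n - 1)) {
      a <- iv[[ord[k]]]
      b <- iv[[ord[k + 1]]]
      gap <- b[1] - a[2]
      if (gap < epsilon) {
        construction_error(
          "regions [%g, %g] and [%g, %g] are at distance %g < epsilon = %g",
          a[1], a[2], b[1], b[2], gap, epsilon)
      }
    }
  }
  endpoints <- unlist(iv)
  grid <- state_grid(extra = c(endpoints, endpoints - epsilon, endpoints + epsilon))
  lapply(iv, function(r) {
    fn <- local({
      lo <- r[1]; hi <- r[2]; eps <- epsilon
      function(x) pmax(0, 1 - interval_distance(x, lo, hi) / eps)
    })
    mf <- mixing_function(fn, bound = 1, lipschitz = 1 / epsilon, grid = grid)
    attr(mf, "region") <- r
    mf
  })
}
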