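# Mixing functions, region mollifiers, mixture and parameter-field families.

test_that("region mixers ramp linearly and are 1 on their own region", {
  mix <- region_mixers(list(c(-1, 1)), epsilon = 1)[[1]]
  expect_equal(mix$fn(0), 1)
  expect_equal(mix$fn(1.5), 0.5)
  expect_equal(mix$fn(2), 0)
  expect_equal(mix$fn(-3), 0)
  expect_true(all(mix$fn(seq(-1, 1, by = 0.05)) == 1))
})

test_that("adjacent mixers form a partition of unity on an epsilon gap", {
  mixers <- region_mixers(list(c(-5, 0), c(1, 6)), epsilon = 1)
  gap <- seq(0, 1, length.out = 21)
  total <- mixers[[1]]$fn(gap) + mixers[[2]]$fn(gap)
  expect_equal(total, rep(1, length(gap)))
})

test_that("the bpc layout puts full Brownian weight at x = -6", {
  mixers <- region_mixers(list(c(-Inf, -6), c(-5, 5), c(6, Inf)), epsilon = 1)
  w <- vapply(mixers, function(m) m$fn(-6), numeric(1))
  expect_equal(w, c(1, 0, 0))
  # and full Cauchy weight at the upper boundary
  expect_equal(vapply(mixers, function(m) m$fn(6), numeric(1)), c(0, 0, 1))
})

test_that("region and mixing-function validation rejects bad inputs", {
  expect_error(region_mixers(list(c(-1, 1), c(1.5, 3)), epsilon = 1),
               "distance")
  expect_error(mixing_function(function(x) -abs(x), 1, 1), "negative")
  expect_error(mixing_function(function(x) rep(2, length(x)), 1, 0), "bound")
  expect_error(mixing_function(function(x) 5 * pmax(0, x), 300, 1),
               "Lipschitz")
})

test_that("mixture exponent equals the weighted sum of component exponents", {
  fam <- named_family("bpc")
  components <- fam$components
  mixers <- fam$mixers
  set.seed(77)
  for (rep in 1:25) {
    x <- runif(1, -15, 15)
    xi <- runif(1, -5, 5)
    w <- vapply(mixers, function(m) m$fn(x), numeric(1))
    direct <- sum(vapply(seq_along(components), function(i)
      w[i] * components[[i]]$exponent(xi), complex(1)))
    expect_lt(Mod(fam$exponent(x, xi) - direct), 1e-12)
  }
})

test_that("a single-component mixture reproduces its component's law", {
  n <- 1e4
  comp <- levy_gamma(2, 1)
  fam <- degenerate_family(comp)
  a <- sample_increment(fam, x = 3, h = 0.7, n = n, seed = 401)
  b <- sample_increment(comp, h = 0.7, n = n, seed = 402)
  expect_gt(ks.test(a, b)$p.value, 0.01)
})

test_that("independent mixture components add their exponents", {
  fam <- mixture_family(list(levy_brownian(0, 1), levy_poisson(1)),
                        list(unit_mixer(), unit_mixer()))
  n <- 1e5
  d <- cf_distance(fam, x = 0, h = 1, n = n, seed = 403)
  expect_lt(d, 5 / sqrt(n))
})

test_that("zero-weight components contribute exactly 0 and consume no randomness", {
  bm <- levy_brownian(0, 1)
  mixers <- region_mixers(list(c(-Inf, -6), c(-5, Inf)), epsilon = 1)
  fam <- mixture_family(list(bm, levy_poisson(1)), mixers)
  # at x = -10 only the Brownian mixer is active
  a <- sample_increment(fam, x = -10, h = 1, n = 100, seed = 404)
  b <- sample_increment(bm, h = 1, n = 100, seed = 404)
  expect_identical(a, b)
})

test_that("mixtures whose weights vanish somewhere are rejected at construction", {
  mixers <- region_mixers(list(c(-10, -8), c(8, 10)), epsilon = 1)
  expect_error(
    mixture_family(list(levy_brownian(0, 1), levy_poisson(1)), mixers),
    "sum to 0 at x")
  expect_error(mixture_family(list(levy_brownian(0, 1)),
                              list(unit_mixer(), unit_mixer())),
               "equal length")
})

test_that("sample_increment is deterministic given a seed and validates h", {
  fam <- named_family("bpc")
  a <- sample_increment(fam, x = 0, h = 0.5, n = 50, seed = 11)
  b <- sample_increment(fam, x = 0, h = 0.5, n = 50, seed = 11)
  expect_identical(a, b)
  expect_error(sample_increment(fam, x = 0, h = 0, n = 10), "positive")
})

test_that("parameter-field constraint screening names the offending state", {
  expect_error(
    parameter_field_family("stable", list(alpha = 2.5, scale = 1)),
    "alpha.*at x = ")
  expect_error(
    parameter_field_family("stable",
                           list(alpha = function(x) 1.5 + 0.6 * sin(x),
                                scale = 1)),
    "alpha")
  expect_error(
    parameter_field_family("nig", list(alpha = 1, beta = 1, delta = 1, mu = 0)),
    "beta")
  expect_error(
    parameter_field_family("meixner", list(a = 1, b = pi, d = 1, m = 0)),
    "b\\(x\\)")
  expect_error(
    parameter_field_family("meixner", list(a = 1, b = 0, d = 0, m = 0)),
    "d\\(x\\)")
})

test_that("the stable-like default index oscillates within [1, 2)", {
  fam <- named_family("stable_like")
  alpha <- fam$constraints$param_fns$alpha
  x <- seq(-50, 50, length.out = 1e4)
  a <- alpha(x)
  expect_gte(min(a), 1)
  expect_lt(max(a), 2)
  # extrema to within the verification-grid resolution
  expect_lt(abs(min(a) - 1.01), 5e-3)
  expect_lt(abs(max(a) - 1.99), 5e-3)
})

test_that("a nearly-Gaussian stable-like family matches a Brownian run", {
  fam <- parameter_field_family("stable", list(alpha = 2 - 1e-2, scale = 1),
                                eps0 = 1e-2)
  bm <- degenerate_family(levy_brownian(0, sqrt(2)))
  a <- terminal_values(simulate_feller(fam, 0, 1, 0.01, n_paths = 500, seed = 21))
  b <- terminal_values(simulate_feller(bm, 0, 1, 0.01, n_paths = 500, seed = 22))
  expect_gt(ks.test(a, b)$p.value, 0.01)
})

test_that("state-dependent NIG skewness produces mean reversion", {
  fam <- parameter_field_family(
    "nig", list(alpha = 2, beta = function(x) -0.9 * tanh(x / 2), delta = 1,
                mu = 0), eps0 = 0.5)
  n <- 1e4
  up <- sample_increment(fam, x = -3, h = 1, n = n, seed = 411)
  dn <- sample_increment(fam, x = 3, h = 1, n = n, seed = 412)
  expect_gt(mean(up), 3 * sd(up) / sqrt(n))   # pushed up from below
  expect_lt(mean(dn), -3 * sd(dn) / sqrt(n))  # pushed down from above
})

test_that("named example families have their stated qualitative features", {
  # bpc at x = 0: pure Poisson region, non-negative integer counts
  z <- sample_increment(named_family("bpc"), x = 0, h = 1, n = 1e3, seed = 421)
  expect_true(all(z >= 0 & z == round(z)))
  # bpc at x = -10: Gaussian increments
  z <- sample_increment(named_family("bpc"), x = -10, h = 1, n = 1e4, seed = 422)
  expect_gt(ks.test(z, "pnorm")$p.value, 0.01)
  # bpc at x = 8: Cauchy increments with scale h
  z <- sample_increment(named_family("bpc"), x = 8, h = 0.5, n = 1e4, seed = 423)
  expect_gt(ks.test(z, "pcauchy", scale = 0.5)$p.value, 0.01)
  # meixner_like takes bigger steps near the origin
  mx <- named_family("meixner_like")
  a_fn <- mx$constraints$param_fns$a
  expect_gt(a_fn(0), a_fn(10))
  # nig_like is symmetric at the origin
  z <- sample_increment(named_family("nig_like"), x = 0, h = 1, n = 1e4,
                        seed = 424)
  expect_lt(abs(sample_skewness(z)), 3 * skewness_se(z))
  expect_error(named_family("no_such_model"), "available models")
})
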