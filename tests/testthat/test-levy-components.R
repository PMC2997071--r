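# Component Levy processes: exponent structure, increment laws, divisibility.

test_that("every exponent vanishes at 0, is Hermitian and has non-negative real part", {
  xi <- seq(-100, 100, length.out = 201)
  for (nm in names(component_matrix())) {
    comp <- component_matrix()[[nm]]
    psi <- comp$exponent(xi)
    expect_true(all(is.finite(Re(psi))), info = nm)
    expect_lt(Mod(comp$exponent(0)), 1e-12)
    expect_true(all(Re(psi) >= -1e-12), label = paste(nm, "Re psi >= 0"))
    expect_lt(max(Mod(comp$exponent(-xi) - Conj(psi))), 1e-12)
  }
})

test_that("increment laws match their closed forms", {
  n <- 1e5
  # Brownian variance over unit time
  z <- sample_increment(levy_brownian(0, 1), h = 1, n = n, seed = 101)
  expect_lt(abs(var(z) - 1), 3 * sqrt(2 / n))
  # Poisson counts: integer support and mean rate * h
  z <- sample_increment(levy_poisson(1), h = 2, n = n, seed = 102)
  expect_true(all(z >= 0 & z == round(z)))
  expect_lt(abs(mean(z) - 2), 3 * sqrt(2 / n))
  # Gamma subordinator: positive draws, mean shape_rate/rate * h
  z <- sample_increment(levy_gamma(2, 1), h = 1, n = n, seed = 103)
  expect_true(all(z > 0))
  expect_lt(abs(mean(z) - 2), 3 * sqrt(2 / n))
  # Cauchy (alpha = 1): P(|X| < 1) = 1/2 at h = 1, scale 1
  z <- sample_increment(levy_stable(1, 1), h = 1, n = n, seed = 104)
  frac <- mean(abs(z) < 1)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n))
  # alpha = 2 with scale 1/sqrt(2): standard Gaussian at h = 1
  z <- sample_increment(levy_stable(2, 1 / sqrt(2)), h = 1, n = 1e4, seed = 105)
  expect_gt(ks.test(z, "pnorm")$p.value, 0.01)
  # symmetric NIG: skewness within 3 SE of 0
  z <- sample_increment(levy_nig(2, 0, 1, 0), h = 1, n = n, seed = 106)
  expect_lt(abs(sample_skewness(z)), 3 * skewness_se(z))
  # symmetric Meixner: mean within 3 SE of 0
  z <- sample_increment(levy_meixner(1, 0, 1, 0), h = 1, n = n, seed = 107)
  expect_lt(abs(mean(z)), 3 * sd(z) / sqrt(n))
})

test_that("empirical CF matches exp(-h psi) on the standard grid for every component", {
  n <- 1e5
  for (h in c(0.1, 1)) {
    for (nm in names(component_matrix())) {
      comp <- component_matrix()[[nm]]
      d <- cf_distance(comp, h = h, n = n, seed = 42)
      expect_lt(d, 5 / sqrt(n), label = sprintf("%s at h=%g", nm, h))
    }
  }
})

test_that("draws at h agree in law with sums of two independent draws at h/2", {
  n <- 1e4
  continuous <- c("brownian_b", "stable_b", "gamma_a", "nig_a", "meixner_a")
  for (nm in continuous) {
    comp <- component_matrix()[[nm]]
    whole <- sample_increment(comp, h = 1, n = n, seed = 201)
    halves <- sample_increment(comp, h = 0.5, n = n, seed = 202) +
      sample_increment(comp, h = 0.5, n = n, seed = 203)
    expect_gt(suppressWarnings(ks.test(whole, halves)$p.value), 0.01,
              label = nm)
  }
  # Poisson: compare count law by chi-squared against Poisson(rate * h)
  rate <- 3.5
  halves <- sample_increment(levy_poisson(rate), h = 0.5, n = n, seed = 204) +
    sample_increment(levy_poisson(rate), h = 0.5, n = n, seed = 205)
  res <- distribution_check(halves, "poisson", list(lambda = rate))
  expect_gt(res$p.value, 0.01)
})

test_that("stable increments are self-similar: draws at h equal h^(1/alpha) times draws at 1", {
  n <- 1e4
  for (alpha in c(0.7, 1, 1.5)) {
    comp <- levy_stable(alpha, 1)
    h <- 0.3
    at_h <- sample_increment(comp, h = h, n = n, seed = 301)
    scaled <- h^(1 / alpha) * sample_increment(comp, h = 1, n = n, seed = 302)
    expect_gt(ks.test(at_h, scaled)$p.value, 0.01,
              label = sprintf("alpha=%g", alpha))
  }
})

test_that("constructors reject invalid parameters", {
  expect_error(levy_brownian(0, 0), "sigma")
  expect_error(levy_brownian(0, -1), "sigma")
  expect_error(levy_poisson(0), "rate")
  expect_error(levy_stable(0, 1), "alpha")
  expect_error(levy_stable(2.1, 1), "alpha")
  expect_error(levy_stable(1, -2), "scale")
  expect_error(levy_gamma(-1, 1), "shape_rate")
  expect_error(levy_gamma(1, 0), "rate")
  expect_error(levy_nig(1, 1.5, 1, 0), "beta")
  expect_error(levy_nig(1, 0, -1, 0), "delta")
  expect_error(levy_meixner(-1, 0, 1, 0), "`a`")
  expect_error(levy_meixner(1, pi, 1, 0), "`b`")
  expect_error(levy_meixner(1, 0, 0, 0), "`d`")
})

test_that("growth bound estimates the constant in |psi| <= C (1 + xi^2)", {
  expect_lte(exponent_growth_bound(levy_brownian(0, 1)), 0.5)
  expect_gt(exponent_growth_bound(levy_brownian(0, 1)), 0.45)
  lambda <- 2.5
  expect_lte(exponent_growth_bound(levy_poisson(lambda)), 2 * lambda)
  expect_equal(exponent_growth_bound(function(xi) 0 * xi), 0)
  for (nm in names(component_matrix())) {
    b <- exponent_growth_bound(component_matrix()[[nm]])
    expect_true(is.finite(b) && b >= 0, info = nm)
  }
  expect_error(exponent_growth_bound(levy_brownian(0, 1), xi_grid = 1:5),
               "grid")
  expect_error(exponent_growth_bound(function(xi) rep(NaN, length(xi))),
               "non-finite")
})

test_that("meixner sampler grid normalises and its quantile function is monotone", {
  qf <- fellersim:::meixner_quantile_grid(1, 1, 0.05, 0)
  u <- seq(0.001, 0.999, length.out = 101)
  q <- qf(u)
  expect_true(all(diff(q) >= 0))
  # the law it induces still matches the exponent at a small shape d*h
  expect_lt(cf_distance(levy_meixner(1, 1, 1, 0), h = 0.05, n = 1e5, seed = 7),
            5 / sqrt(1e5))
})
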