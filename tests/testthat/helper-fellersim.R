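# Shared fixtures, built in code.

# two parameter sets per component constructor
component_matrix <- function() {
  list(
    brownian_a = levy_brownian(0, 1),
    brownian_b = levy_brownian(-0.5, 2),
    poisson_a = levy_poisson(1),
    poisson_b = levy_poisson(3.5),
    stable_a = levy_stable(1, 1),        # Cauchy
    stable_b = levy_stable(1.5, 0.8),
    gamma_a = levy_gamma(2, 1),
    gamma_b = levy_gamma(0.7, 2.5),
    nig_a = levy_nig(2, 1, 1, 0),
    nig_b = levy_nig(1.5, -0.5, 0.8, 0.2),
    meixner_a = levy_meixner(1, 1, 1, 0),
    meixner_b = levy_meixner(0.7, -0.8, 1.3, 0.1)
  )
}

# mixing function identically 1 (degenerate mixture weight)
unit_mixer <- function() {
  mixing_function(function(x) rep(1, length(x)), bound = 1, lipschitz = 0)
}

# family that wraps one component as a degenerate mixture
degenerate_family <- function(component, label = component$name) {
  mixture_family(list(component), list(unit_mixer()), label = label)
}

# probe states used for each named example family
example_probes <- function() {
  list(bpc = c(-10, 0, 10),
       stable_like = c(0, pi / 2, 3),
       nig_like = c(-3, 0, 3),
       meixner_like = c(0, 2, 10))
}

sample_skewness <- function(x) {
  z <- (x - mean(x)) / stats::sd(x)
  mean(z^3)
}

# asymptotic SE of the sample skewness at a symmetric law, via the influence
# function z^3 - 3z (reduces to sqrt(6/n) in the Gaussian case)
skewness_se <- function(x) {
  z <- (x - mean(x)) / stats::sd(x)
  sqrt(mean((z^3 - 3 * z)^2) / length(x))
}

sample_excess_kurtosis <- function(x) {
  z <- (x - mean(x)) / stats::sd(x)
  mean(z^4) - 3
}
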