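---
title: "Methods: constructing and simulating Feller processes by mixing Lévy processes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constructing and simulating Feller processes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fellersim)
```

## The model

A one-dimensional Lévy process $L_t$ is determined by its Lévy exponent
$\psi$ through $E[e^{i\xi L_t}] = e^{-t\psi(\xi)}$. A Feller process
generalises this by letting the exponent depend on the current state: a
family $\{\psi_x\}_x$ of Lévy exponents corresponds (under regularity
conditions) to a Markov process that, started at $x$, initially moves like
the Lévy process with exponent $\psi_x$. `fellersim` realises two
constructive recipes for such families:

* **Mixtures.** With component exponents $\psi_1,\dots,\psi_n$ and
  non-negative, bounded, Lipschitz mixing functions $\phi_i$ satisfying
  $\sum_i \phi_i(x) > 0$,
  $$\psi_x(\xi) = \sum_i \phi_i(x)\,\psi_i(\xi)$$
  always defines an admissible family. When the $\phi_i$ are mollified
  indicators of uniformly separated regions, the process behaves exactly
  like component $i$ inside region $i$. Crucially, increments can be sampled
  exactly: $Z_x(h) \overset{d}{=} \sum_i L_i(\phi_i(x) h)$ with independent
  component draws, because independent Lévy exponents add.
* **Parameter fields.** A parametric class of exponents with its parameters
  made state-dependent, e.g. stable-like $\psi_x(\xi) = |\xi|^{\alpha(x)}$.
  Existence here is class-specific and requires the parameter functions to
  be smooth/bounded and bounded away from critical values; the package
  screens those bounds at construction time.

Sample paths come from the fixed-step recursion
$x_{k+1} = x_k + z_k$, $z_k \sim Z_{x_k}(h)$, the increment law re-resolved
at the current position each step. For a state-independent family this is
exact in law at every grid time (increments of a Lévy process add). For
state-dependent families the scheme converges weakly as $h \to 0$ under two
assumptions: the growth bound $|\psi_x(\xi)| \le C(1+\xi^2)$ uniformly in
$x$, which `exponent_growth_bound()` estimates on a grid and which every
built-in family satisfies, and uniqueness of the process for its restricted
generator, which a simulator cannot check and which we document as an
assumption. No pathwise (strong) error rate is claimed; the
`weak_convergence_probe()` output is Monte Carlo evidence of Cauchy-sequence
behaviour of expectations, not a proof.

## Conventions and components

The sign convention is fixed once: $E[e^{i\xi L_h}] = e^{-h\psi(\xi)}$, so
$\psi(0)=0$, $\operatorname{Re}\psi \ge 0$ and $\psi(-\xi) =
\overline{\psi(\xi)}$. All complex logarithms and square roots are principal
branches; diagnostic grids stay within $|\xi| \le 100$, where no branch
tracking is needed for the built-in exponents.

| component | exponent | sampler (exact in law) |
|---|---|---|
| Brownian$(\mu,\sigma)$ | $-i\mu\xi + \sigma^2\xi^2/2$ | Gaussian |
| Poisson$(\lambda)$ | $\lambda(1-e^{i\xi})$ | Poisson counts |
| stable$(\alpha,c)$ | $(c|\xi|)^\alpha$ | Chambers–Mallows–Stuck; Cauchy inversion at $\alpha=1$; Gaussian at $\alpha=2$ |
| Gamma$(\gamma,\lambda)$ | $\gamma\log(1 - i\xi/\lambda)$ | Gamma variates |
| NIG$(\alpha,\beta,\delta,\mu)$ | $-i\mu\xi + \delta(\sqrt{\alpha^2-(\beta+i\xi)^2}-\sqrt{\alpha^2-\beta^2})$ | normal variance–mean mixture over inverse-Gaussian time |
| Meixner$(a,b,d,m)$ | $-im\xi + 2d\log\frac{\cosh((a\xi-ib)/2)}{\cos(b/2)}$ | grid inverse-CDF |

Two conventions deserve a flag. At $\alpha = 2$ the stable exponent
$c^2\xi^2$ is Gaussian with variance $2c^2h$, not $c^2h$ — the factor 2 is a
consequence of the $|\xi|^\alpha$ normalisation, and the documentation and
tests treat it explicitly. And the NIG sampler's inverse-Gaussian mixing law
at elapsed time $h$ ($I \sim IG(\delta h/\gamma, (\delta h)^2)$ in the
mean/shape parametrisation) is not taken on trust: the test suite certifies
it against the exponent through the empirical characteristic function, so a
parametrisation error would surface as a CF mismatch, not a silent bias.

The Meixner law has no standard exact sampler. We tabulate its density
(which needs $|\Gamma(d + iy)|^2$ at complex argument, computed with
`pracma::gammaz`) on a uniform grid of $2^{14}$ points, extending the range
from mean $\pm(10\,\mathrm{sd} + 5a)$ until the density falls below
$10^{-12}$ of its mode — the tails are semiheavy (exponential times a
power), so this terminates quickly. The CDF is accumulated with a
third-order Newton–Cotes rule; its total mass must equal 1 within $10^{-6}$
or a numerical error with a diagnostic payload is raised (the third-order
rule keeps the discretisation error orders of magnitude below that tolerance
even at small shape $dh$, where the density is sharply peaked). The inverse
CDF is linearly interpolated; the resulting law is again certified by the CF
diagnostic. Grids are cached per elapsed time within a component, which
matters for repeated draws at fixed $h$ but not for parameter-field
simulation, where the component changes every step — simulating long
Meixner-like paths is therefore the package's slowest operation.

## Diagnostics as the correctness engine

Because increments of these families have no closed-form densities in
general, correctness is defined through the characteristic function: for $n$
i.i.d. draws the empirical CF deviates from the truth by $O(1/\sqrt n)$
uniformly on a compact grid, and the package uses $5/\sqrt n$ as a
conservative envelope on the standard grid of 21 equispaced points on
$[-5,5]$ (which resolves every built-in law at its default parameters).
`cf_distance()` is this max-distance; the acceptance suite drives it over
every component (two parameter sets each) and every example family (three
probe states each) at $h \in \{0.1, 0.5\}$ with $n = 10^5$, where the
envelope is 0.0158.

Moment checks use an oracle that differentiates $e^{-h\psi}$ numerically:
central finite differences at $\xi = 0$ with step $10^{-4}$ give mean and
variance with truncation error $O(\text{step}^2)$ times higher CF
derivatives — below $10^{-7}$ relative for the built-in laws, and verified
against closed forms for Brownian, Poisson and Gamma at $10^{-6}$ relative.
Laws without finite variance (stable with $\alpha < 2$, including Cauchy)
are rejected with an unsupported-law error rather than producing meaningless
comparisons.

Goodness-of-fit wrappers use Kolmogorov–Smirnov for continuous references
and a chi-squared test on binned counts for Poisson (bins merged from the
tails until every expected count is at least 5, the classical validity
rule). All pass/fail wrapping in tests uses significance 0.01 with fixed
seeds: under a true null a single seeded test passes with probability 0.99,
and the suite checks this calibration directly (at least 18 of 20 seeded
null repetitions above 0.01). One consequence worth stating: p-values of
*near*-null comparisons — e.g. stable $\alpha = 1.99$ against an exactly
Gaussian run — are approximately uniform and will occasionally dip below any
fixed level as seeds vary; that is the statistic behaving correctly.

## Example families: what the defaults emulate

The four named families reproduce qualitative regimes — a process that is
Gaussian in one region and heavy-tailed in another, an index field
oscillating between the Cauchy and Gaussian extremes, mean reversion induced
purely by skewness, state-dependent step sizes — with functional forms
chosen once as package defaults:

* `bpc`: Brownian$(0,1)$ on $(-\infty,-6]$, Poisson$(1)$ on $[-5,5]$,
  Cauchy (stable $\alpha=1$, scale 1) on $[6,\infty)$, ramps of width
  $\varepsilon = 1$ on the gaps. The gap width equal to the region
  separation makes the two ramps on each gap a partition of unity, so
  $\sum\phi_i \equiv 1$ everywhere.
* `stable_like`: $\alpha(x) = 1.5 + 0.49\,\mathrm{tri}(x)$ with $\mathrm{tri}$
  the unit triangle wave of period $2\pi$ — Lipschitz but not smooth, range
  $[1.01, 1.99]$, bounded away from both 0 and 2 as existence requires.
* `nig_like`: $\alpha=2$, $\delta=1$, $\mu=0$, $\beta(x) = -\tanh x$. The
  NIG mean has the sign of $\beta$, so the increment distribution is skewed
  back toward the origin from either side — mean reversion without any
  drift term. The margin $\epsilon_0 = 0.5$ keeps $|\beta| \le \alpha -
  \epsilon_0$ with room to spare.
* `meixner_like`: $b=0$, $d=1$, $m=0$, $a(x) = 0.5 + 1.5\,e^{-x^2/8}$. The
  parameter $a$ sets the rate of the exponential decay of the density's
  tails; enlarging it near the origin makes the process move with bigger
  steps there.

These defaults emulate regime-switching jump behaviour in an idealised way.
They do **not** emulate several features of real movement or transport data:
measurement noise, irregular sampling times, boundaries or reflecting
obstacles, multi-dimensional state, or time-inhomogeneity. Passing tests
certify that the simulator draws from exactly the laws the family declares —
they say nothing about whether those laws fit any particular dataset.

## Numerical and design choices

* **Constraint screening.** Mixing functions and parameter fields are
  validated on a dense grid — $x \in [-50, 50]$, $10^4$ points, plus region
  endpoints — with tolerance $10^{-8}$; the Lipschitz check is a sampled
  finite-difference bound, constructive validation rather than proof. An
  adversarial user function that misbehaves only between grid points can
  evade it; the grid is documented as the limit of the guarantee. Violations
  are construction errors naming the offending state, and never surface at
  sampling time.
* **Time grid.** With horizon $T$ not divisible by $h$ the path stops at
  $K = \lfloor T/h \rfloor$ full steps; a fractional final step would change
  the increment law. Paths are stored at grid times only; the right-
  continuous step rendering in plots is a presentation convention.
* **RNG.** One root seed initialises L'Ecuyer-CMRG; path $j$ uses substream
  $j$ (advanced incrementally, one `nextRNGStream` call per path), so path
  $j$ is identical whether simulated alone or in any ensemble, and
  byte-identical CSVs follow from identical configurations. Within a step,
  mixture components draw in declaration order; zero-weight components are
  skipped and consume no randomness.
* **Degenerate inputs.** A single-component mixture with unit weight is the
  component (tested by two-sample KS); $h \le 0$, empty step lists,
  non-resolvable model names and unwritable plot targets raise immediate
  errors; an empty ensemble cannot be plotted and leaves no file behind.
* **Test problem sizes.** CF certification uses $n = 10^5$ draws, two-sample
  KS checks $10^3$–$10^4$, ensembles $10^3$ paths at $h = 0.01$, the
  convergence probe 2000 paths at $h \in \{0.2, 0.1, 0.05\}$ — sizes chosen
  so each statistical check has comfortable power at significance 0.01
  while the full suite stays desk-scale.
* **Interface shape.** The package is a simulator, not an estimator: there
  is no data-fitting entry point, so the surface is constructors returning
  classed objects (`levy_component`, `levy_family`, `feller_paths`) with
  print/summary/plot methods, plus a thin command-line script over the same
  functions for shell use.

## Known limitations

One-dimensional processes only. No user-supplied Lévy–Khintchine triplets or
tempered/CGMY exponents (the component registry is the extension point). No
state-dependent killing, no time-inhomogeneity. Existence of the Feller
process for parameter-field families outside the screened bounds — and
uniqueness for the restricted generator, which the weak-convergence
guarantee needs — is assumed, not verified; there are families of perfectly
smooth deterministic drifts for which no Feller process exists at all, so
the screening bounds are genuinely load-bearing. Meixner-like path
simulation rebuilds the density grid at every step and is slow for long
horizons at small $h$.
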