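Package: fellersim
Title: Simulation of Feller Processes by State-Dependent Mixing of Levy Processes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Constructs Feller (Levy-type) processes as state-space-dependent
    mixtures of Levy processes and generates approximate sample paths by a
    fixed-step Markov-chain (Euler-type) scheme. Provides exact-in-law
    increment samplers and characteristic exponents for Brownian, Poisson,
    symmetric alpha-stable, Gamma, normal inverse Gaussian and Meixner
    components; finite mixtures over uniformly separated regions and
    parameter-field families (stable-like, NIG-like, Meixner-like); and
    statistical diagnostics that verify every simulated increment law against
    its analytic characteristic exponent via the empirical characteristic
    function. Includes trajectory export to CSV, color-coded path plots and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    parallel,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
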