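Package: opmfield
Title: Invariant Gaussian Random Field Models of Cortical Orientation Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and exact level-crossing statistics for invariant
    (homogeneous, isotropic, centered) complex Gaussian random fields used as
    models of orientation preference maps in primary visual cortex. Represents
    radial spectral measures (atoms, multi-ring constructions, uniform annuli)
    and derives their column-spacing wavelengths; evaluates Bessel-kernel
    covariances with analytic derivatives; computes expected iso-orientation
    crossing counts by the Kac-Rice formula, the exact Cramer-Leadbetter
    variance of crossing counts by oscillation-aware quadrature, and expected
    pinwheel (phase singularity) densities; synthesizes field realizations by
    seeded plane-wave superposition; and measures empirical crossing counts and
    winding-number pinwheel censuses on simulated or user-supplied maps, with
    Monte Carlo ensembles acting as the internal oracle for every closed form.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    pracma,
    png,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
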