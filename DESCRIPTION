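Package: photonmc
Title: Monte Carlo Photon Transport with Two-Step Analytic Verification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo simulation of photon transport in non-absorbing
    infinite media and laterally infinite layered slabs, together with the
    closed-form radiative-transfer benchmarks needed to verify such a
    simulator: exact statistical moments of the scattering-event coordinates
    per scattering order (Henyey-Greenstein, Rayleigh and isotropic phase
    functions), and invariant solutions for radiance, fluence rate and mean
    partial path lengths under Lambertian illumination, including the
    trapped-photon regime of non-scattering high-index slabs. Estimates are
    compared with the benchmarks through one-sample t-tests, giving a
    quantitative pass/fail verification report for the trajectory sampling
    routines (step 1) and the boundary-handling routines (step 2).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
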