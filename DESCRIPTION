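Package: radonlung
Title: Radon Progeny Deposition, Clearance and Bronchial Microdosimetry in
    Stochastic Airway Geometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Monte Carlo simulation of the radiation burden of the bronchial
    airways from inhaled short-lived radon progeny (Po-218, Pb-214, Bi-214,
    Po-214). Couples a stochastic airway-geometry sampler (with height
    scaling for children and probabilistic airway contraction for severe
    asthma), nasal and tracheobronchial aerosol deposition by diffusion,
    sedimentation and impaction, mucociliary clearance with full decay-chain
    transport, and alpha-particle microdosimetry of basal and secretory cell
    nuclei. Computes per-generation deposition rates and absorbed dose rates
    for configurable subjects exposed to indoor radon.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
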