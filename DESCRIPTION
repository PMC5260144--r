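Package: macpol
Title: Multiscale Simulation of Macrophage M1/M2 Polarization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multiscale stochastic simulator of macrophage polarization.
    Each macrophage agent embeds a synchronous Boolean gene regulatory
    network whose fixed points define commitment to the classically (M1,
    NOS2-marked) or alternatively (M2, Arg1-marked) activated phenotype.
    Agents (macrophages, B cells, helper T cells), antigen, antibody and
    cytokine tokens diffuse on a periodic three-dimensional lattice and
    interact through local stochastic reaction rules (a reactive lattice
    gas automaton). The package provides exact fixed-point enumeration for
    the regulatory network, the per-site reaction machinery, seeded
    ensemble experiments for three immunological challenge scenarios
    (Gram-negative bacterium, LPS-free vaccine plus IL-4, bacterium
    followed by IL-10), and outcome statistics such as the fraction of
    replicates in which IL-10 dampens antigen control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
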