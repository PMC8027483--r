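Package: cylpb
Title: Nonlinear Poisson-Boltzmann Double Layers Around Cylindrical
    Polyelectrolytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Solves the nonlinear Poisson-Boltzmann equation in cylindrical
    geometry for the ionic double layer around microtubules and their
    C-termini, with a Stern layer (distance of closest approach) and a
    field- and concentration-dependent relative permittivity (Booth
    dielectric saturation plus ion-volume-fraction mixing). Provides the
    analytic linearized (Debye-Hueckel) Bessel-function solutions,
    counterion and co-ion concentration profiles, thermal-voltage bound
    layers, bound charge per tubulin dimer, mean axial conductivity of the
    protein-ion complex, and the buffer-crossover concentration, over KCl
    concentrations from 10 micromolar to 500 millimolar. All results are
    returned as tibbles and chain with the pipe; fitted profiles have
    tidy(), glance() and autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
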