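Package: kbff
Title: Kirkwood-Buff Evaluation and Optimization of Aqueous Ion Force Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale pipeline for evaluating and optimizing nonpolarizable
    alkali-halide ion force fields in water. Implements finite-size-corrected
    ion solvation free energies from thermodynamic integration, activity
    derivatives of electrolyte solutions from finite-volume Kirkwood-Buff
    integrals with 1/R extrapolation, Einstein-Smoluchowski ionic conductivity
    with Yeh-Hummer diffusion corrections, and the static dielectric decrement
    from dipole and ion-current fluctuations. Production molecular dynamics is
    replaced by seeded synthetic generators (ideal gas, Metropolis Monte Carlo
    Lennard-Jones fluids, Brownian dynamics, Ornstein-Uhlenbeck dipole
    processes, and an analytic observable backend with a planted optimum) so
    that every estimator is verifiable against planted truths and closed forms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
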