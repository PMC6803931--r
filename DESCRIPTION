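Package: ratekin
Title: Rate-Constant Phenomenology, Transition-State Theory and Solution
    Kinetics Beyond the Arrhenius Law
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the temperature dependence of reaction rate
    constants when Arrhenius plots curve. Evaluates and fits five
    phenomenological rate laws (Arrhenius, Aquilanti-Mundim deformed
    exponential, Aquilanti-Sanchez-Coutinho-Carvalho,
    Nakamura-Takayanagi-Sato, Vogel-Fulcher-Tammann) by chi-square
    minimization with a Tsallis generalized-simulated-annealing optimizer,
    in the Arrhenius plane or in the transitivity plane (reciprocal
    apparent activation energy versus inverse temperature, where deformed
    Arrhenius behaviour linearizes). Computes gas-phase rate constants from
    molecular descriptors by transition-state theory with deformed-TST,
    Bell (1935), Bell (1958) and Skodje-Truhlar tunneling corrections,
    crossover-temperature regime classification, and solution-phase rates
    via Collins-Kimball diffusion-limited and Kramers friction
    formulations with a deformed-exponential solvent-viscosity law.
    Includes numerical transitivity plots with Savitzky-Golay smoothing,
    deterministic synthetic-data generators, readers for delimited rate
    tables and minimal quantum-chemistry frequency logs, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    graphics,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
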