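Package: sarcoeq
Title: Equatorial X-ray Diffraction Modelling for the Striated Muscle
    Filament Lattice
Version: 0.1.0
Authors@R:
    person("Sarcoeq", "Developers", email = "sarcoeq@example.org",
           role = c("aut", "cre"))
Description: Forward modelling of the equatorial small-angle X-ray
    diffraction pattern of striated muscle.  Builds 2D-projected electron
    densities of the hexagonal A-band filament lattice unit cell (one
    thick filament, two thin filaments) from atomic structures, analytic
    density rings and myosin head-state populations; evaluates structure
    factors at the reciprocal lattice points of the eight observable
    equatorial reflections with Debye-Waller lattice-disorder and Lorentz
    corrections; and fits the few free model parameters (filament
    temperature factors, parked-state head ring geometry) to experimental
    intensity tables by exhaustive grid search on the crystallographic
    R-factor.  Includes a Monte Carlo synthesiser of per-unit-cell
    crossbridge states and deterministic generators of synthetic
    stand-in structures so the full pipeline runs without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
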