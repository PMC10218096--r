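# sarcoeq — equatorial X-ray diffraction of the muscle filament lattice

`sarcoeq` is a forward model of the equatorial small-angle X-ray
diffraction pattern of vertebrate striated muscle, for structural muscle
physiologists who want to connect myosin head-state populations to the
measurable equatorial intensities instead of inverting the (badly
under-determined) pattern.

The A-band of every sarcomere is a hexagonal lattice (spacing
`d10`) with thick filaments at the lattice points and thin filaments at the
trigonal positions. The package:

1. builds 2D-projected electron densities of the unit cell (one thick, two
   thin filaments) from atomic structures plus analytic density rings —
   LMM backbone ribbons, titin ring, three S2 rings, the parked-state head
   (PSH) ring, the disordered unbound-head (UBMH) ring, the thin-filament
   repeat with tropomyosin/troponin/nebulin, bound heads and their partner
   heads;
2. evaluates the unit-cell structure factor at each reflection,
   `F_hk = F_thick + F_thin1 cos θ1 + F_thin2 cos θ2` with
   `θ1 = 2π(k/3 + 2h/3)`, `θ2 = 2π(2k/3 + h/3)`, attenuated by
   Debye–Waller disorder factors `D = exp(−2π² S² Δ²)` (separate Δ for
   thick and thin filaments), superposes all reflections with equal
   reciprocal radius `S_hk = S_10 √(h²+k²+hk)`, divides by the Lorentz
   factor `√(h²+k²+hk)`, and normalises `I(1,0) = 100`;
3. fits the free parameters — (Δ_M, Δ_A), and the parked-head ring centre
   and thickness — by exhaustive grid search on the crystallographic
   R-factor `R = Σ(Iᵒ−Iᵖ)² / Σ(Iᵒ)²`;
4. ships a Monte Carlo synthesiser of per-unit-cell crossbridge states and
   deterministic synthetic stand-in structures, so the full pipeline runs
   with no downloads (any PDB file can be substituted per role).

## Worked example

Predict the resting-muscle equator at the published lattice geometry
(`d10 = 34.21` nm), the relaxed head-state preset (1.95% bound, 17.67%
unbound, 80.38% parked) and the printed disorder factors, then score it
against the bundled experimental table:

```r
library(sarcoeq)

model <- build_sarcomere_model(population_preset("relaxed"))
pattern <- equatorial_pattern(model$cell, temperature_factors(2.58, 2.15))
print(round(pattern$intensity, 2))
#> [1] 100.00  32.70  18.80   7.03   2.63   0.45   0.99   0.16
phase_string(pattern)
#> [1] "++--++--"
r_factor(edl_intensity_table("resting"), pattern)
#> [1] 0.003706907
```

Reading the output: the eight numbers are the normalised intensities of the
(1,0), (1,1), (2,0), (2,1), (3,0), (2,2), (3,1), (4,0) families as percent
of I(1,0). The low `I11/I10 = 0.33` is the signature of resting muscle —
~80% of the myosin heads sit in the parked-state ring against the thick
filament backbone. The phase string is the sign of the real structure
factor per family, and the R-factor scores the prediction against the
measured resting table (experimental `I11 = 36.34`, etc.). Running the
contracted preset (`population_preset("contracted")`, Δ_A = 1.72) moves
head mass to the thin filaments and roughly doubles `I11/I10`.

Fitting instead of predicting:

```r
fit <- fit_temperature_factors(model$cell, edl_intensity_table("resting"))
fit$best_params     # exhaustive 451 x 451 grid over [0.5, 5] nm
#> delta_M delta_A
#>    3.11    2.33
```

## Command line

```sh
Rscript inst/cli/sarcoeq equator --state relaxed --out-dir out/
Rscript inst/cli/sarcoeq synth-states --state contracted --cells 10 --out states.csv
Rscript inst/cli/sarcoeq fit-temp --state relaxed --out fit.json
Rscript inst/cli/sarcoeq fixtures --kind toy-pdb --dir fixtures/
```

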