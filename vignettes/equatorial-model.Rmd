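---
title: "Modelling the equatorial X-ray diffraction pattern of striated muscle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the equatorial X-ray diffraction pattern of striated muscle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

In vertebrate striated muscle the myosin-containing thick filaments and the
actin-containing thin filaments form a hexagonal lattice in the A-band of
each sarcomere. Small-angle X-ray diffraction of intact muscle therefore
shows a characteristic series of equatorial reflections — (1,0), (1,1),
(2,0), (2,1), (3,0), (2,2), (3,1), (4,0) — whose relative intensities encode
the radial distribution of mass in the lattice cross-section. In particular
the intensity ratio $I_{1,1}/I_{1,0}$ rises as myosin head mass moves from
the thick filament backbone toward the thin filaments, which makes the
equator a sensitive reporter of crossbridge state in resting and contracting
muscle.

`sarcoeq` implements the corresponding *forward* model: given atomic
structures for the filament components, the lattice geometry, and the
occupancies of the myosin head states — parked (PS, held at the backbone),
disordered unbound, and actin-bound — it constructs 2D-projected electron
densities of the unit cell, evaluates the structure factors at the
reciprocal lattice points, and predicts the eight normalised equatorial
intensities. The few genuinely free parameters (two filament temperature
factors; the parked-state head ring geometry) are fitted to experimental
intensity tables by exhaustive grid search on the crystallographic R-factor.

## The model

**Unit cell.** The crystallographic cell is hexagonal with
$|\mathbf a_1| = |\mathbf a_2| = 2 d_{10}/\sqrt 3$ at $\gamma = 120^\circ$,
one thick filament at the origin and two thin filaments at the trigonal
positions $(2/3, 1/3)$ and $(1/3, 2/3)$. This is the only convention under
which three published facts hold simultaneously: the selection rule
$S_{hk} = S_{10}\sqrt{h^2+k^2+hk}$, the thin-filament phase angles
$\theta_1 = 2\pi(k/3 + 2h/3)$, $\theta_2 = 2\pi(2k/3 + h/3)$, and the
thick–thin spacing $d_{AM} = \tfrac23 d_{10}$. (A 60° cell, sometimes quoted
for this lattice, flips the sign of the cross term in the selection rule and
moves the trigonal positions; we therefore use 120° throughout.)

**Structure factors.** For each reflection,
$F_{hk} = F^{thick}_{hk} + F^{thin1}_{hk}\cos\theta_1 +
F^{thin2}_{hk}\cos\theta_2$, with each filament transform evaluated about
its own centre: analytic Bessel forms for ring components
($2\pi\int\rho(r) J_0(2\pi S r)\, r\,dr$, closed form for uniform rings,
composite Simpson quadrature for trapezoids) plus a discrete sum over
non-zero grid pixels for atomic densities. A complex mode
($e^{i\theta}$ phases) is available; it differs from the cosine mode only
when the two thin filaments carry different bound-head sets, and both modes
are tested for agreement on symmetric cells. Lattice disorder enters as
Debye–Waller factors $D_\alpha = \exp(-2\pi^2 S^2 \Delta_\alpha^2)$ with
separate rms displacements $\Delta_M$ (thick) and $\Delta_A$ (thin).
Observed intensities superpose all integer $(h,k)$ with the same reciprocal
radius (enumerated exhaustively over $|h|,|k| \le 8$, one member per Friedel
pair), are divided by the Lorentz factor $\sqrt{h^2+k^2+hk}$ (the
reciprocal-space radius; a switch restores the non-radical form for
sensitivity analysis), and are normalised to $I_{1,0} = 100$.

**Thick filament.** The density is assembled from: 18 LMM ribbons per
cross-section packed in three hexagonal shells between the 2.3 nm axial hole
and the 7 nm backbone radius (rendered as discrete projected cylinders by
default, or as an equivalent annulus); a uniform titin ring at 6.5–8.5 nm
carrying six ~2 MDa A-band titin portions; three trapezoid S2 rings starting
at 6 nm and ending at 9.75 / 9.5 / 11 nm for S2s attached to parked,
unbound, and bound crossbridges; a trapezoid parked-state head (PSH) ring at
9.75–15.25 nm; and a trapezoid unbound-head (UBMH) ring at 9.5–17.5 nm.
Component masses come from structural bookkeeping: linear electron density
of the S2 fragment structure scaled by the LMM (85.8 nm) and whole-S2
lengths and by per-state crossbridge counts, two heads per crossbridge, and
the titin molecular weight.

**Thin filament.** The base density re-projects the repeat structure
(actin + tropomyosin + troponin) rotated by 27.7° per 38.3 nm repeat, for as
many repeats as lie inside the A-band
($L_a - (SL - L_{thick})/2$, floored by the repeat spacing — 13 at the
reference geometry). A nebulin surrogate (the tropomyosin chains rotated by
90°) is added once per repeat without mass rescaling. Bound heads are added
either discretely (azimuth and lever state per head, e.g. from the state
synthesiser) or as a deterministic expectation: fractional expected head
counts smeared over evenly spaced azimuths, which is exactly the
expectation of the density under a uniform azimuth distribution.

## Choices where the source material is ambiguous

Several aspects of the published density scheme are stated loosely or
inconsistently; the package makes each choice explicit, keeps the
alternative available, and records the reasoning here.

* **LMM count.** "18 LMMs per cross-section" must be integrated over the
  crown span to be commensurate with the per-crossbridge head and S2
  masses: one LMM per crossbridge (147 per half filament, identically
  $18 \times \text{span}/85.8$ nm). Counting literally 18 molecules would
  under-weight the backbone roughly eightfold relative to the heads,
  contradicting both the published density profiles (backbone-dominant) and
  the head:rod mass ratio of a myosin molecule
  (`lmm_count_mode = "cross_section"` restores the literal reading).
* **Backbone rendering.** The discrete three-shell ribbon packing is the
  default. The azimuthally smeared annulus looks equivalent but is not: the
  ribbon layout's form factor is higher at $S_{1,1}$ and lower at $S_{2,0}$
  than the annulus, which moves those orders by several normalised units.
* **Partner heads.** The text places the non-bound partner heads of bound
  crossbridges both "in the UBMH ring" and "as a uniform cloud centred on
  the thin filament", in different sections. The default routes them to the
  UBMH ring (`partner_mode = "ubmh"`): with the cloud reading the predicted
  contracting $I_{1,1}$ overshoots the published simulation by ~25
  normalised units, with the ring reading it agrees to within ~2.
  `partner_mode = "cloud"` keeps the other reading available.
* **Titin conversion.** All structure-derived masses count heavy atoms only
  (~53 electrons per ~110 Da residue). Titin, the single component derived
  from a molecular weight, therefore uses the heavy-atom conversion
  0.482 e/Da in the assembled reference model so that it is bookkept
  consistently with the other components; the all-atom textbook value
  0.54 e/Da remains the interface default of `compute_mass_budget()`.
* **S2 length.** The whole-S2 tether length is not printed; we use 60 nm
  (the standard partition of the ~156 nm myosin rod into ~96 nm LMM and
  ~60 nm S2). It only scales the S2 ring masses.
* **Trapezoid taper.** "Density decaying proportional to the radius" is
  implemented as a linear profile from $\rho_{in}$ at the inner edge to
  $(r_{in}/r_{out})\rho_{in}$ at the outer edge (constant mass per unit
  radius), configurable per ring.
* **Bound-head placement.** The head's long axis points outward along its
  azimuth with the binding interface at the filament surface
  (`attach_radius`, default 3.6 nm = actin monomer centre radius 1.7 nm
  plus monomer radius 1.9 nm).

## Tunable parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `d10` | 34.21 | nm | lattice spacing; sets all reflection positions |
| `SL`, `thick_length`, `La` | 2.862, 1.58, 1.15 | µm | sarcomere geometry; fixes the A-band repeat count (13) |
| `delta_M`, `delta_A` | fitted (printed best fits 2.58, 2.15/1.72) | nm | rms lattice disorder of thick/thin filaments |
| head-state fractions | presets: relaxed 1.95/17.67/80.38%, contracted 22.93/42.67/34.40% | — | crossbridge occupancies driving the mass redistribution |
| `ps_r_inner`, `ps_r_outer` | 9.75, 15.25 | nm | parked-head ring; refitted by `fit_ps_ring()` over centre 12.5 ± 1 nm, thickness 4–6 nm |
| `pixel_size` | 0.05 | nm | projection grid; predictions are stable to ≤0.01 units between 0.05 and 0.1 |
| `s2_length` | 60 | nm | whole-S2 mass scaling |
| `electrons_per_dalton` | 0.482 (model) / 0.54 (budget API) | e/Da | titin conversion, see above |

## What the synthetic generators emulate — and what they do not

Real atomic inputs (an S2 coiled-coil fragment, a 38.3 nm thin-filament
repeat with tropomyosin and troponin, pre- and post-powerstroke myosin
heads) cannot be redistributed with the package, so deterministic
`synthetic_*` generators build stand-ins at residue resolution: every
residue becomes a fixed 8-heavy-atom cluster (5 C, 1 N, 2 O ≈ 53 electrons),
and residue counts, the 0.1485 nm coiled-coil rise, the actin helix
(14 monomers per 38.3 nm, −166.7° twist, monomer centres at 1.7 nm), the
tropomyosin radius (3.9 nm) and the motor-domain/lever partition of the
head follow the real proteins. Electron *ratios* between components — which
is what normalised intensities measure — are therefore set by residue
bookkeeping, not by the cluster details.

The stand-ins do not reproduce side-chain-level density fluctuations,
sub-nanometre surface texture, or the exact azimuthal mass distribution of
the real structures. A green acceptance run therefore establishes that the
*pipeline* (projection → transforms → disorder/Lorentz corrections →
normalisation → fitting) reproduces the published intensity tables given
faithful component masses and envelopes; it does not validate the atomic
detail of any particular PDB entry. Any PDB file can be substituted per
role through `model_structures()`.

The state synthesiser draws per-crossbridge states independently from the
target fractions. It emulates the occupancy statistics of a spatially
explicit mechanics simulation, not its kinetics: there is no Ca²⁺
regulation, no tropomyosin cooperativity, and no axial strain dependence,
so per-cell correlations beyond the multinomial are absent by construction
(flagged in the state-file metadata).

## Numerical choices

* Sphere projection uses the exact chord-length kernel evaluated at pixel
  centres and renormalised per atom, so every atom deposits exactly its
  electron count regardless of pixel size; mass conservation is tested at
  0.1%.
* Trapezoid ring transforms use a fixed 2000-panel composite Simpson rule
  (the integrand is smooth at small-angle arguments); uniform rings use the
  closed Bessel form. Analytic transforms are cross-checked against a
  brute-force DFT of rasterised rings at all eight reflection positions
  (≤0.5%).
* Grid searches are exhaustive with ties broken toward smaller parameter
  values, lexicographically; surfaces are returned whole, and runs are
  bit-reproducible. Infeasible parked-ring nodes (inner edge below the S2
  start radius) are excluded, and a surface whose total variation stays
  under twice its minimum sets an `insensitive` flag.
* Phases are reported from the sign of the real part of the canonical
  representative's structure factor; a vanishing real part yields an
  explicit undefined phase rather than a silent sign.
* Degenerate geometry (no thick–thin overlap) yields zero repeats with a
  warning; zero-mass rings are legal and contribute nothing.

## Known limitations

Only the equator is modelled — no layer lines or meridionals, no
instrument convolution, no absorption or polarisation corrections, and no
MyBP-C density. The deterministic expectation mode computes
$|F(\mathbb E \rho)|^2$, not $\mathbb E|F|^2$; the difference (per-cell
fluctuation scattering) is small at rest and can be quantified by averaging
discrete-state cells via `run_equator()` with a multi-cell state file.
Fitted temperature factors on stand-in densities land near, not at, the
published best-fit values, as expected for densities that are not
atom-for-atom the published ones.
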