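# Shared fixtures.  Everything is generated in code; the heavyweight
# reference models (default 0.05 nm pixel) are built once per test run and
# cached, since several files probe the same cells.

.cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.cache[[key]])) .cache[[key]] <- builder()
  .cache[[key]]
}

# full reference model with synthetic stand-in structures
ref_model <- function(state, pixel_size = 0.05) {
  cached(paste0("model_", state, "_", pixel_size), function() {
    build_sarcomere_model(population_preset(state),
                          spec = grid_spec(pixel_size = pixel_size))
  })
}

ref_pattern <- function(state, pixel_size = 0.05) {
  cached(paste0("pattern_", state, "_", pixel_size), function() {
    tf <- temperature_factors(2.58, if (state == "relaxed") 2.15 else 1.72)
    equatorial_pattern(ref_model(state, pixel_size)$cell, tf)
  })
}

# small deterministic atom tables for unit tests
toy_atoms <- function(n = 5, element = "C", spread = 0.8) {
  ang <- 2 * pi * (seq_len(n) - 1) / n
  data.frame(
    element = element,
    x = spread * cos(ang), y = spread * sin(ang),
    z = 0.1 * seq_len(n), chain = "A",
    electron_count = atomic_number(element),
    vdw_radius = vdw_radius(element),
    stringsAsFactors = FALSE
  )
}

# a tiny thin-filament repeat: an "actin" blob on chain A plus two
# off-axis "tropomyosin" chains
toy_repeat <- function() {
  a <- toy_atoms(24, spread = 1.2)
  tm <- rbind(toy_atoms(6, element = "N", spread = 2.5),
              toy_atoms(6, element = "N", spread = 2.5))
  tm$chain <- rep(c("T", "U"), each = 6)
  tm$y <- tm$y + 0.4
  rbind(a, tm)
}

# ring-only unit cell: analytic transforms, fast enough for fitting loops
toy_cell <- function(thick_mass = 1e6, thin_mass = 3e5) {
  spec <- grid_spec(pixel_size = 0.5, extent = 18)
  thick <- projected_density(spec)
  thick <- add_ring(thick, make_ring(2.3, 7, thick_mass * 0.5, "uniform"))
  thick <- add_ring(thick, make_ring(9.75, 15.25, thick_mass * 0.5, "trapezoid"))
  thin <- projected_density(spec)
  thin <- add_ring(thin, make_ring(0, 3.5, thin_mass, "uniform"))
  make_unit_cell(sarcomere_geometry(), thick, thin, thin)
}

# sharply contrasted ring-only cell for noise-recovery tests: the narrow
# thick shell keeps |F_thick| large at every order, which is what makes
# delta_M identifiable under multiplicative intensity noise
toy_cell_sharp <- function() {
  spec <- grid_spec(pixel_size = 0.5, extent = 18)
  thick <- add_ring(projected_density(spec), make_ring(6.8, 7.2, 1e6, "uniform"))
  thin <- add_ring(projected_density(spec), make_ring(0, 3, 5e5, "uniform"))
  make_unit_cell(sarcomere_geometry(), thick, thin, thin)
}

# independent quadrature oracle for ring masses
ring_mass_oracle <- function(ring) {
  2 * pi * stats::integrate(function(r) ring_density(ring, r) * r,
                            ring$r_inner, ring$r_outer, rel.tol = 1e-9)$value
}

# brute-force DFT of a gridded density at one wave vector (oracle; kept
# deliberately independent of density_transform)
dft_oracle <- function(density, Svec) {
  ax <- grid_axis(density$spec)
  px <- density$spec$pixel_size
  ph_x <- exp(2i * pi * ax * Svec[1])
  ph_y <- exp(2i * pi * ax * Svec[2])
  sum((density$grid * (ph_x %o% ph_y))) * px^2
}
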