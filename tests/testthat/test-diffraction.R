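# Lattice geometry, transforms, reflection families and the R-factor.

test_that("lattice and reciprocal vectors satisfy the hexagonal relations", {
  lv <- lattice_vectors(34.21)
  expect_equal(sqrt(sum(lv$a1^2)), 2 * 34.21 / sqrt(3), tolerance = 1e-9)
  expect_equal(sqrt(sum(lv$a1^2)), 39.50, tolerance = 1e-3)
  expect_equal(sqrt(sum(lv$b1^2)), 1 / 34.21, tolerance = 1e-9)
  expect_equal(sqrt(sum(lv$b2^2)), 1 / 34.21, tolerance = 1e-9)
  expect_equal(sum(lv$a1 * lv$b2), 0, tolerance = 1e-12)
  expect_equal(sum(lv$a2 * lv$b1), 0, tolerance = 1e-12)
  expect_equal(sum(lv$a1 * lv$b1), 1, tolerance = 1e-12)
})

test_that("unit cell places thin filaments at the trigonal positions", {
  cell <- toy_cell()
  for (thin in cell$thin_densities) {
    # distance to the nearest lattice point is dAM = (2/3) d10 = 22.81 nm
    d <- min(apply(expand.grid(i = -1:1, j = -1:1), 1, function(t) {
      sqrt(sum((thin$center - t[1] * cell$a1 - t[2] * cell$a2)^2))
    }))
    expect_equal(d, 22.81, tolerance = 1e-2)
    expect_equal(d, 2 / 3 * 34.21, tolerance = 1e-9)
  }
  expect_error(sarcomere_geometry(dAM = 24), "inconsistent")
})

test_that("phase angles follow the trigonal-position formula", {
  expect_equal(phase_angles(1, 0), c(4 * pi / 3, 2 * pi / 3), tolerance = 1e-12)
  expect_equal(cos(phase_angles(1, 0)[1]), -0.5, tolerance = 1e-12)
  expect_equal(phase_angles(1, 1), c(2 * pi, 2 * pi), tolerance = 1e-12)
  # theta1 + theta2 is always a multiple of 2 pi
  for (h in -4:4) for (k in -4:4) {
    s <- sum(phase_angles(h, k)) / (2 * pi)
    expect_equal(s, round(s), tolerance = 1e-9)
  }
})

test_that("uniform disk transform matches the closed-form Bessel oracle", {
  R <- 5.2; rho0 <- 3.7
  ring <- make_ring(0, R, rho0 * pi * R^2, "uniform")
  S <- c(0.01, 0.029, 0.05, 0.08, 0.117)
  oracle <- rho0 * R * besselJ(2 * pi * S * R, 1) / S
  expect_equal(sarcoeq:::ring_transform(ring, S), oracle, tolerance = 1e-9)
})

test_that("F(0,0) equals the total electrons in the unit cell", {
  cell <- toy_cell()
  F00 <- structure_factor(cell, 0, 0)
  total <- total_electrons(cell$thick_density) +
    2 * total_electrons(cell$thin_densities[[1]])
  expect_equal(Re(F00), total, tolerance = 1e-6)
  expect_equal(Im(F00), 0, tolerance = 1e-9)
})

test_that("analytic ring transforms agree with brute-force DFT of the raster", {
  spec <- grid_spec(pixel_size = 0.05, extent = 18)
  d10 <- 34.21
  fams <- equatorial_families()
  S <- sqrt(fams$h^2 + fams$k^2 + fams$h * fams$k) / d10
  for (ring in list(make_ring(9.75, 15.25, 1e6, "trapezoid"),
                    make_ring(2.3, 7.0, 1e6, "uniform"))) {
    raster <- rasterize_ring(ring, spec)
    scale <- ring$total_electrons / total_electrons(raster)  # pixelisation
    analytic <- sarcoeq:::ring_transform(ring, S)
    dft <- vapply(S, function(s) Re(dft_oracle(raster, c(s, 0))) * scale,
                  numeric(1))
    expect_equal(dft, analytic, tolerance = 5e-3)
  }
})

test_that("grid transforms match the DFT oracle and rings are centrosymmetric", {
  spec <- grid_spec(pixel_size = 0.1, extent = 4)
  d <- project_atoms(toy_atoms(7, spread = 1.3), spec)
  Svec <- c(0.05, -0.03)
  expect_equal(density_transform(d, matrix(Svec, 1)), dft_oracle(d, Svec),
               tolerance = 1e-9)
  # azimuthally symmetric ring-only cell: Im(F) = 0, phases strictly +/-
  p <- equatorial_pattern(toy_cell())
  expect_true(all(p$phase %in% c("+", "-")))
  for (i in seq_len(nrow(p))) {
    F <- structure_factor(toy_cell(), p$h[i], p$k[i])
    expect_equal(Im(F), 0, tolerance = 1e-6 * abs(Re(F)))
  }
})

test_that("family enumeration is exhaustive and obeys the selection rule", {
  # L^2 = 7: six Friedel-reduced members, found independently by scanning
  g <- expand.grid(h = -10:10, k = -10:10)
  g <- g[g$h^2 + g$k^2 + g$h * g$k == 7, ]
  expect_equal(nrow(g), 12)                     # full plane
  m <- family_members(2, 1)
  expect_equal(nrow(m), 6)                      # one per Friedel pair
  expect_true(all(m$h^2 + m$k^2 + m$h * m$k == 7))
  # no member duplicated as its own Friedel partner
  expect_false(any(paste(m$h, m$k) %in% paste(-m$h, -m$k)))

  fams <- equatorial_families()
  p <- equatorial_pattern(toy_cell())
  expect_equal(p$S * 34.21, sqrt(fams$h^2 + fams$k^2 + fams$h * fams$k),
               tolerance = 1e-9)
  expect_equal(p$S[p$h == 1 & p$k == 1] / p$S[p$h == 1 & p$k == 0], sqrt(3),
               tolerance = 1e-12)
  expect_equal(p$n_members, c(3L, 3L, 3L, 6L, 3L, 3L, 6L, 3L))
})

test_that("for ring-only densities the family sum is multiplicity x member", {
  cell <- toy_cell()
  p <- equatorial_pattern(cell, normalize = FALSE)
  for (i in seq_len(nrow(p))) {
    F <- structure_factor(cell, p$h[i], p$k[i])
    expect_equal(p$intensity[i],
                 p$n_members[i] * Mod(F)^2 / lorentz_factor(p$h[i], p$k[i]),
                 tolerance = 1e-9)
  }
})

test_that("temperature factor has the right value and monotonicity", {
  expect_equal(temperature_factor(0, 3), 1)
  expect_equal(temperature_factor(0.4, 0), 1)
  expect_equal(temperature_factor(1 / 34.21, 2.58), 0.8938, tolerance = 1e-4)
  # strictly decreasing in S for positive delta
  S <- seq(0.01, 0.12, by = 0.01)
  expect_true(all(diff(temperature_factor(S, 2)) < 0))
  expect_error(temperature_factor(0.1, -1), "non-negative")
  # every normalised family intensity above (1,0) is non-increasing in delta
  cell <- toy_cell()
  deltas <- c(0, 1, 2, 3)
  mats <- sapply(deltas, function(d) {
    equatorial_pattern(cell, temperature_factors(d, d))$intensity
  })
  for (i in 2:8) expect_true(all(diff(mats[i, ]) <= 1e-9))
})

test_that("cosine and complex modes agree for identical thin filaments", {
  cell <- toy_cell()
  for (i in seq_len(nrow(equatorial_families()))) {
    h <- equatorial_families()$h[i]; k <- equatorial_families()$k[i]
    expect_equal(structure_factor(cell, h, k, "cosine"),
                 structure_factor(cell, h, k, "complex"), tolerance = 1e-9)
  }
  pc <- equatorial_pattern(cell, mode = "cosine")
  px <- equatorial_pattern(cell, mode = "complex")
  expect_equal(pc$intensity, px$intensity, tolerance = 1e-9)
})

test_that("pattern interface validates its inputs", {
  cell <- toy_cell()
  expect_error(equatorial_pattern(cell, families = data.frame(h = 0, k = 0)),
               "Lorentz")
  expect_error(equatorial_pattern(cell, families = data.frame(h = 2, k = 0)),
               "\\(1,0\\)")
  expect_error(lorentz_factor(0, 0), "undefined")
  p <- equatorial_pattern(cell)
  expect_equal(p$intensity[p$h == 1 & p$k == 0], 100)
  expect_true(all(p$intensity >= 0))
})

test_that("R-factor matches hand arithmetic and the identity case", {
  mk <- function(i) structure(data.frame(h = c(1, 1), k = c(0, 1), intensity = i),
                              class = c("reflection_set", "data.frame"))
  expect_equal(r_factor(mk(c(100, 50)), mk(c(100, 50))), 0)
  expect_equal(r_factor(mk(c(100, 50)), mk(c(90, 60))), 200 / 12500)
  expect_error(r_factor(mk(c(100, 50)),
                        structure(data.frame(h = 1, k = 0, intensity = 100),
                                  class = c("reflection_set", "data.frame"))),
               "different")
  obs <- mk(c(100, 50)); obs$error <- c(NA, 2)
  expect_equal(r_factor(obs, mk(c(90, 60)), weighted = TRUE),
               (100 / 4) / (2500 / 4))
})

test_that("the paper-style R-factor arithmetic reproduces the published value", {
  # frozen simulated rows, compared against the bundled experimental table:
  # an independent check of the Eq-form (all eight reflections, (1,0) in
  # the denominator)
  sim <- structure(data.frame(
    h = c(1, 1, 2, 2, 3, 2, 3, 4), k = c(0, 1, 0, 1, 0, 2, 1, 0),
    intensity = c(100, 34.05, 18.73, 9.13, 1.77, 0.35, 1.17, 0.22)),
    class = c("reflection_set", "data.frame"))
  expect_equal(r_factor(edl_intensity_table("resting"), sim), 0.0043,
               tolerance = 2e-2)
})

test_that("moving head mass from the PSH ring to the thin filaments raises I11/I10", {
  base <- toy_cell(thick_mass = 1e6, thin_mass = 3e5)
  ratio <- function(cell) {
    p <- equatorial_pattern(cell)
    p$intensity[p$h == 1 & p$k == 1] / 100
  }
  shift <- function(cell, x) {
    # remove x electrons from the PSH ring, add x/2 as bound-head mass
    # around each thin filament
    psh <- cell$thick_density$rings[[2]]
    cell$thick_density$rings[[2]] <- make_ring(psh$r_inner, psh$r_outer,
                                               psh$total_electrons - x,
                                               "trapezoid")
    cell$thin_densities <- lapply(cell$thin_densities, function(d) {
      add_ring(d, make_ring(3.6, 10, x / 2, "trapezoid"))
    })
    cell
  }
  ratios <- vapply(c(0, 1e5, 2e5, 3e5), function(x) ratio(shift(base, x)),
                   numeric(1))
  expect_true(all(diff(ratios) > 0))
})
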