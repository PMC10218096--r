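# Atom tables, PDB round trips, sphere projection and analytic rings.

test_that("PDB round trip preserves atoms, elements and unit conversion", {
  atoms <- synthetic_carbon_ring(n = 3, radius = 0.1)
  atoms$x <- c(0.1, 0.2, 0.3); atoms$y <- c(0.2, 0.3, 0.4); atoms$z <- c(0.3, 0.4, 0.5)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(atoms, path)
  back <- read_pdb_atoms(path)
  expect_equal(nrow(back), 3)
  expect_equal(back$electron_count, rep(6L, 3))       # carbon has 6 electrons
  expect_equal(back$x, atoms$x, tolerance = 1e-6)     # Angstrom -> nm on read
  expect_equal(back$z, atoms$z, tolerance = 1e-6)

  # record count equals an independent line-count of ATOM/HETATM records
  big <- synthetic_s2_structure(n_res = 30)
  path2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(big, path2)
  n_lines <- sum(grepl("^(ATOM  |HETATM)", readLines(path2)))
  expect_equal(nrow(read_pdb_atoms(path2)), n_lines)

  # chain filter
  expect_equal(unique(read_pdb_atoms(path2, chain_filter = "A")$chain), "A")
})

test_that("read_pdb_atoms rejects bad input with located errors", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  C   GLY A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  Q   GLY A   1       1.000   2.000   3.000  1.00  0.00          QQ"
  ), path)
  expect_error(read_pdb_atoms(path), "line 2")
  expect_error(read_pdb_atoms(file.path(tempdir(), "nope.pdb")), "cannot read")
  expect_error(atomic_number("Xx"), "unknown element")
  expect_error(vdw_radius("Zz"), "van der Waals")
})

test_that("sphere projection conserves mass, is additive and has bounded support", {
  spec <- grid_spec(pixel_size = 0.02, extent = 2)
  one <- data.frame(element = "C", x = 0.31, y = -0.22, z = 0, chain = "A",
                    electron_count = 6L, vdw_radius = 0.17)
  d1 <- project_atoms(one, spec)
  expect_equal(total_electrons(d1), 6, tolerance = 1e-3)    # mass conservation

  two <- rbind(one, one)                                    # same (x, y)
  d2 <- project_atoms(two, spec)
  expect_equal(d2$grid, 2 * d1$grid, tolerance = 1e-12)     # additivity

  ax <- grid_axis(spec)
  r <- sqrt(outer((ax - 0.31)^2, (ax + 0.22)^2, `+`))
  out <- d1$grid[r > 0.17 + spec$pixel_size]                # support bound
  expect_true(all(out == 0))
})

test_that("projection is invariant under rotation about the filament axis", {
  spec <- grid_spec(pixel_size = 0.05, extent = 4)
  atoms <- toy_atoms(12, spread = 1.5)
  rot <- sarcoeq:::.rotate_atoms_z(atoms, 73)
  d0 <- project_atoms(atoms, spec)
  d1 <- project_atoms(rot, spec)
  expect_equal(total_electrons(d0), total_electrons(d1), tolerance = 1e-9)
  # cumulative radial mass profile unchanged to within pixel error (the
  # cumulative form is insensitive to mass straddling bin edges)
  ax <- grid_axis(spec)
  r <- sqrt(outer(ax^2, ax^2, `+`))
  # edges chosen clear of the atoms' own radius (1.5 +- vdW) so no
  # footprint straddles a cut
  edges <- c(0.5, 1.0, 2.5, 3.5)
  c0 <- vapply(edges, function(e) sum(d0$grid[r <= e]), numeric(1))
  c1 <- vapply(edges, function(e) sum(d1$grid[r <= e]), numeric(1))
  expect_lt(max(abs(c0 - c1)) / max(c0), 0.01)
})

test_that("atoms outside the field raise a bounds error naming the atom", {
  spec <- grid_spec(pixel_size = 0.05, extent = 1)
  bad <- data.frame(element = "C", x = 1.2, y = 0, z = 0, chain = "A",
                    electron_count = 6L, vdw_radius = 0.17)
  expect_error(project_atoms(bad, spec), "footprint exceeds.*x=1.200")
})

test_that("ring components integrate to their stated mass", {
  # uniform disk: closed form rho0 = M / (pi r^2)
  disk <- make_ring(0, 1, 10, "uniform")
  expect_equal(disk$rho_in, 10 / pi, tolerance = 1e-12)

  # degenerate trapezoid (taper 1) equals the uniform ring
  tz1 <- make_ring(2, 5, 7, "trapezoid", taper_ratio = 1)
  un <- make_ring(2, 5, 7, "uniform")
  r <- seq(1.5, 5.5, by = 0.05)
  expect_equal(ring_density(tz1, r), ring_density(un, r), tolerance = 1e-12)

  # quadrature oracle on the S2-like ring of the model
  tz <- make_ring(6, 9.75, 1000, "trapezoid", taper_ratio = 6 / 9.75)
  expect_equal(ring_mass_oracle(tz), 1000, tolerance = 1e-3)

  # every ring of the built thick filament integrates to its budget entry
  for (ring in ref_model("relaxed")$cell$thick_density$rings) {
    if (ring$total_electrons > 0) {
      expect_equal(ring_mass_oracle(ring), ring$total_electrons,
                   tolerance = 1e-3)
    }
  }
})

test_that("ring constructors reject invalid geometry", {
  expect_error(make_ring(2, 2, 5), "geometry")
  expect_error(make_ring(3, 2, 5), "geometry")
  expect_error(make_ring(1, 2, -5), "non-negative")
  expect_error(make_ring(1, 2, 5, taper_ratio = 0), "taper_ratio")
})

test_that("total_electrons sums grid and rings; empty density is zero", {
  spec <- grid_spec(pixel_size = 0.05, extent = 2)
  expect_equal(total_electrons(projected_density(spec)), 0)
  d <- project_atoms(toy_atoms(1), spec)
  d <- add_ring(d, make_ring(0.5, 1.5, 5, "uniform"))
  expect_equal(total_electrons(d), 11, tolerance = 1e-3)    # 6 e atom + 5 e ring
})

test_that("density text export round-trips", {
  spec <- grid_spec(pixel_size = 0.1, extent = 2)
  d <- project_atoms(toy_atoms(4), spec)
  d <- add_ring(d, make_ring(1, 1.8, 3, "trapezoid"))
  path <- withr::local_tempfile(fileext = ".txt")
  write_density(d, path)
  back <- read_density(path)
  expect_equal(back$grid, d$grid, tolerance = 1e-6)
  expect_equal(total_electrons(back), total_electrons(d), tolerance = 1e-6)
  expect_equal(back$rings[[1]]$taper_ratio, d$rings[[1]]$taper_ratio)
})
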