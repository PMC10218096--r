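# Exhaustive grid searches: recovery oracles, exhaustiveness, determinism.

small_spec <- grid_search_spec(delta_M_range = c(1.0, 3.0, 0.05),
                               delta_A_range = c(1.0, 3.0, 0.05))

test_that("noiseless temperature factors are recovered within one grid step", {
  cell <- toy_cell()
  truth <- temperature_factors(2.0, 1.5)
  obs <- equatorial_pattern(cell, truth)
  fit <- fit_temperature_factors(cell, obs, small_spec)
  expect_lte(abs(fit$best_params["delta_M"] - 2.0), 0.05)
  expect_lte(abs(fit$best_params["delta_A"] - 1.5), 0.05)
  # observed generated exactly on a grid node: R = 0 there
  expect_lt(fit$best_R, 1e-20)
})

test_that("the search is exhaustive, deterministic and validates inputs", {
  cell <- toy_cell()
  obs <- equatorial_pattern(cell, temperature_factors(1.8, 1.3))
  fit1 <- fit_temperature_factors(cell, obs, small_spec)
  fit2 <- fit_temperature_factors(cell, obs, small_spec)
  expect_identical(fit1$R_surface, fit2$R_surface)     # bit-reproducible
  expect_equal(dim(fit1$R_surface),
               c(length(fit1$delta_M_axis), length(fit1$delta_A_axis)))
  expect_equal(fit1$best_R, min(fit1$R_surface))
  expect_error(grid_search_spec(delta_M_range = c(2, 1, 0.1)), "invalid")
  expect_error(grid_search_spec(delta_A_range = c(1, 2, 0)), "invalid")
})

test_that("ties break toward smaller deltas", {
  # a flat-R situation: observed equal to the delta-free pattern of a cell
  # whose intensities do not depend on the deltas at all is impossible, so
  # force ties by a degenerate one-node axis instead and check reporting
  cell <- toy_cell()
  obs <- equatorial_pattern(cell, temperature_factors(1.5, 1.5))
  spec1 <- grid_search_spec(delta_M_range = c(1.5, 1.5, 0.1),
                            delta_A_range = c(1.5, 1.5, 0.1))
  fit <- fit_temperature_factors(cell, obs, spec1)
  expect_equal(unname(fit$best_params), c(1.5, 1.5))
  expect_gte(fit$ties, 1)
})

test_that("recovery tolerates 5% multiplicative noise in >= 90% of replicates", {
  # the grid step (0.15 nm) is commensurate with the parameter resolution
  # that 5% intensity noise leaves in the eight reflections (delta_M is
  # resolved to ~0.13 nm rms; searching much finer than the data resolve
  # would make "2 grid steps" an arbitrary fraction of the posterior width)
  cell <- toy_cell_sharp()
  truth <- temperature_factors(2.0, 1.55)
  clean <- equatorial_pattern(cell, truth)
  gs <- grid_search_spec(delta_M_range = c(0.5, 3.5, 0.15),
                         delta_A_range = c(0.5, 3.5, 0.15))
  set.seed(42)
  hits <- 0L
  for (r in 1:100) {
    noisy <- clean
    noisy$intensity <- clean$intensity * (1 + stats::rnorm(8, 0, 0.05))
    noisy$intensity <- 100 * noisy$intensity / noisy$intensity[1]
    fit <- fit_temperature_factors(cell, noisy, gs)
    ok <- abs(fit$best_params["delta_M"] - 2.0) <= 2 * 0.15 + 1e-9 &&
      abs(fit$best_params["delta_A"] - 1.55) <= 2 * 0.15 + 1e-9
    hits <- hits + ok
  }
  expect_gte(hits, 90)
})

test_that("the PS-ring search recovers a known geometry and flags the rest", {
  # model: toy thick cell whose PSH ring is scanned; truth off the default
  # centre so recovery is informative
  base <- toy_cell()
  params <- thick_params()
  pop <- population_preset("relaxed")
  budget <- list(heads_ps = 5e5, s2_ps = 1e5)
  mk_builder <- function(cell) {
    # stand-in builder on the ring-only toy cell: replace its outer ring
    function(ctr, thk) {
      cell$thick_density$rings[[2]] <- make_ring(ctr - thk / 2, ctr + thk / 2,
                                                 5e5, "trapezoid")
      equatorial_pattern(cell, temperature_factors(1, 1))
    }
  }
  build <- mk_builder(base)
  truth <- build(12.2, 4.6)
  spec <- grid_search_spec(ps_center_range = c(11.5, 13.5, 0.1),
                           ps_thickness_range = c(4, 6, 0.1))
  fit <- fit_ps_ring(build, truth, spec)
  expect_lte(abs(fit$best_params["ps_center"] - 12.2), 0.1)
  expect_lte(abs(fit$best_params["ps_thickness"] - 4.6), 0.1)
  expect_lt(fit$best_R, 1e-20)
  expect_equal(unname(fit$best_params["s2_r_outer_ps"]),
               unname(fit$best_params["ps_center"] -
                        fit$best_params["ps_thickness"] / 2))
  # exhaustive surface with the grid's shape
  expect_equal(dim(fit$R_surface), c(21L, 21L))
})

test_that("infeasible PS nodes (ring below the S2 start) are excluded", {
  base <- toy_cell()
  build <- function(ctr, thk) {
    base$thick_density$rings[[2]] <- make_ring(ctr - thk / 2, ctr + thk / 2,
                                               5e5, "trapezoid")
    equatorial_pattern(base, temperature_factors(1, 1))
  }
  obs <- build(8, 3)
  spec <- grid_search_spec(ps_center_range = c(6.5, 9, 0.5),
                           ps_thickness_range = c(2, 4, 1))
  fit <- fit_ps_ring(build, obs, spec, s2_r_start = 6)
  # nodes with centre - thickness/2 < 6 are NA in the surface
  expect_true(any(is.na(fit$R_surface)))
  feas <- outer(fit$ps_center_axis, fit$ps_thickness_axis,
                function(c, t) c - t / 2 >= 6)
  expect_identical(as.vector(is.na(fit$R_surface)), as.vector(!feas))
})

test_that("a flat R surface raises the insensitive flag", {
  flat <- function(ctr, thk) {
    structure(data.frame(h = c(1, 1), k = c(0, 1), intensity = c(100, 50)),
              class = c("reflection_set", "data.frame"))
  }
  obs <- structure(data.frame(h = c(1, 1), k = c(0, 1), intensity = c(100, 49)),
                   class = c("reflection_set", "data.frame"))
  fit <- fit_ps_ring(flat, obs, grid_search_spec(
    ps_center_range = c(11.5, 12.5, 0.5), ps_thickness_range = c(4, 5, 0.5)))
  expect_true(fit$insensitive)
})

test_that("the cached PS builder matches a from-scratch pattern", {
  m <- ref_model("relaxed", pixel_size = 0.1)
  tf <- temperature_factors(2.58, 2.15)
  builder <- make_ps_pattern_builder(m$cell, m$thick_params, m$pop, m$budget, tf)
  direct <- equatorial_pattern(m$cell, tf)
  viabuilder <- builder(12.5, 5.5)             # the as-built geometry
  expect_equal(viabuilder$intensity, direct$intensity, tolerance = 1e-6)
  expect_equal(phase_string(viabuilder), phase_string(direct))
})
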