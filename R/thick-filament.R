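# Thick filament projected density: LMM backbone, titin ring, three S2
# rings, the parked-state head (PSH) ring and the disordered unbound head
# (UBMH) ring, with masses set by structural bookkeeping and the head-state
# population.

#' Thick filament structural parameters
#'
#' Defaults follow the equatorial density scheme for the vertebrate
#' three-stranded thick filament: 2.3 nm axial hole, 7 nm backbone outer
#' radius (18 LMMs per cross-section in three hexagonal layers), 7.9 nm
#' bare-zone overlap radius, titin ring 6.5-8.5 nm, S2 rings starting at
#' 6 nm and ending at 9.75 / 9.5 / 11 nm for parked / unbound / bound
#' crossbridges, PSH ring 9.75-15.25 nm, UBMH ring 9.5-17.5 nm.  The full
#' S2 tether length (`s2_length`, used to scale the S2 fragment density up
#' to whole-S2 mass) is not a measured ring radius; the 60 nm default is the
#' standard myosin rod partition (~156 nm rod = ~96 nm LMM + ~60 nm S2).
#'
#' @param ... override any default by name.
#' @return object of class `thick_params`.
#' @export
thick_params <- function(...) {
  p <- list(
    backbone_outer_radius = 7.0,
    backbone_hole_radius = 2.3,
    bare_zone_radius = 7.9,
    n_lmm_cross_section = 18L,
    lmm_length = 6 * 14.3,
    titin_r_inner = 6.5,
    titin_r_outer = 8.5,
    titin_aband_mw = 2e6,
    titin_n_molecules = 6L,
    s2_r_start = 6.0,
    s2_r_outer_ps = 9.75,
    s2_r_outer_unbound = 9.5,
    s2_r_outer_bound = 11.0,
    ps_r_inner = 9.75,
    ps_r_outer = 15.25,
    ubmh_r_inner = 9.5,
    ubmh_r_outer = 17.5,
    s2_length = 60,
    crown_spacing = 14.3,
    crown_rotation = 40,
    n_crossbridges_half_filament = 147L,
    thick_length = 1.58,
    bare_zone_length = 0.16
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) stop("unknown thick_params field(s): ",
                            paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  with(p, {
    stopifnot(
      backbone_hole_radius > 0, backbone_hole_radius < backbone_outer_radius,
      ps_r_inner < ps_r_outer, ubmh_r_inner < ubmh_r_outer,
      s2_r_start < s2_r_outer_ps, s2_r_start < s2_r_outer_unbound,
      s2_r_start < s2_r_outer_bound, s2_length > 0, lmm_length > 0
    )
  })
  structure(p, class = "thick_params")
}

#' Head-state population of a unit cell
#'
#' Fractions of crossbridges in the parked state (PS), disordered unbound
#' state, and bound to actin; they must partition (sum to 1).
#'
#' @param frac_bound,frac_unbound,frac_ps crossbridge fractions in `[0, 1]`.
#' @param frac_prestroke_of_bound fraction of bound heads in the
#'   pre-powerstroke conformation.
#' @return object of class `head_state_population`.
#' @export
head_state_population <- function(frac_bound, frac_unbound, frac_ps,
                                  frac_prestroke_of_bound = 0.5) {
  v <- c(frac_bound, frac_unbound, frac_ps, frac_prestroke_of_bound)
  if (any(v < 0 | v > 1)) stop("fractions must lie in [0, 1]")
  if (abs(frac_bound + frac_unbound + frac_ps - 1) > 1e-6) {
    stop("frac_bound + frac_unbound + frac_ps must equal 1")
  }
  structure(
    list(frac_bound = frac_bound, frac_unbound = frac_unbound,
         frac_ps = frac_ps,
         frac_prestroke_of_bound = frac_prestroke_of_bound),
    class = "head_state_population"
  )
}

#' Head-state presets for resting and contracting EDL muscle
#'
#' Simulation-derived crossbridge fractions: relaxed 1.95% bound, 17.67%
#' unbound, 80.38% parked; contracted 22.93% / 42.67% / 34.40%.
#'
#' @param state `"relaxed"` or `"contracted"`.
#' @return a [head_state_population()].
#' @export
population_preset <- function(state = c("relaxed", "contracted")) {
  state <- match.arg(state)
  if (state == "relaxed") head_state_population(0.0195, 0.1767, 0.8038)
  else head_state_population(0.2293, 0.4267, 0.3440)
}

#' Re-split parked and disordered unbound fractions
#'
#' Overrides the parked:(parked+unbound) ratio while preserving the bound
#' fraction, for exploring intermediate degrees of head order.
#'
#' @param pop a [head_state_population()].
#' @param ps_of_unbound desired PS share of all non-bound crossbridges.
#' @return a new [head_state_population()].
#' @export
resplit_parked <- function(pop, ps_of_unbound) {
  stopifnot(ps_of_unbound >= 0, ps_of_unbound <= 1)
  free <- 1 - pop$frac_bound
  head_state_population(pop$frac_bound, free * (1 - ps_of_unbound),
                        free * ps_of_unbound, pop$frac_prestroke_of_bound)
}

#' Positions of LMM ribbons in the backbone cross-section
#'
#' Packs `n_lmm_cross_section` LMMs into three concentric hexagonal shells
#' of equal count between the axial hole and the backbone outer radius,
#' successive shells rotated by 30 degrees.
#'
#' @param params a [thick_params()].
#' @return data.frame with columns `x`, `y` (nm) and `shell`.
#' @export
backbone_lmm_layout <- function(params) {
  n <- params$n_lmm_cross_section
  if (n %% 3L != 0L) stop("n_lmm_cross_section must be divisible by 3")
  per <- n %/% 3L
  lo <- params$backbone_hole_radius
  hi <- params$backbone_outer_radius
  width <- (hi - lo) / 3
  if (width <= 0) stop("backbone radii too tight to place three shells")
  out <- do.call(rbind, lapply(1:3, function(s) {
    r <- lo + (s - 0.5) * width
    ang <- 2 * pi * (seq_len(per) - 1) / per + (s - 1) * (30 * pi / 180)
    data.frame(x = r * cos(ang), y = r * sin(ang), shell = s)
  }))
  rownames(out) <- NULL
  out
}

#' Electron mass budget of the thick filament components
#'
#' Converts structural bookkeeping into electrons per component for one half
#' thick filament:
#' * `backbone_lmm`: LMM mass from the rod fragment's linear electron
#'   density (`electrons(fragment) / axial extent`) scaled to the LMM length
#'   and molecule count.  The default molecule count is one LMM per
#'   crossbridge (18 per cross-section times the crown span over the LMM
#'   length, = `n_crossbridges`), which keeps the backbone consistent with
#'   the per-crossbridge head and S2 masses; `"cross_section"` restores the
#'   literal single-span 18-molecule count.
#' * `titin`: six molecules times the conserved ~2 MDa A-band portion,
#'   converted with `electrons_per_dalton`.
#' * `s2_*`: per-state crossbridge counts times whole-S2 mass
#'   (`s2_length / fragment extent * electrons(fragment)`).
#' * `heads_ps`, `heads_unbound`: two heads per crossbridge in the state.
#'   Partner heads of bound crossbridges belong to the thin-filament cloud,
#'   not to the UBMH ring.
#'
#' @param params a [thick_params()].
#' @param pop a [head_state_population()].
#' @param s2_atoms atom table of the S2 fragment structure (the axial extent
#'   is measured from its z range, so a projection is not sufficient).
#' @param head_electrons electrons in one myosin head structure.
#' @param electrons_per_dalton conversion for titin (only titin's mass comes
#'   from a molecular weight; default 0.54 e/Da, typical protein).
#' @param lmm_count_mode `"per_crossbridge"` (default) or `"cross_section"`.
#' @return named list of class `mass_budget`, entries in electrons.
#' @export
compute_mass_budget <- function(params, pop, s2_atoms, head_electrons,
                                electrons_per_dalton = 0.54,
                                lmm_count_mode = c("per_crossbridge",
                                                   "cross_section")) {
  lmm_count_mode <- match.arg(lmm_count_mode)
  if (missing(head_electrons) || is.null(head_electrons)) {
    stop("head_electrons is required (electrons of one myosin head structure)")
  }
  e_frag <- sum(s2_atoms$electron_count)
  if (!(e_frag > 0)) stop("S2 structure has no electrons")
  len_frag <- diff(range(s2_atoms$z))
  if (!(len_frag > 0)) stop("S2 structure has no axial extent")
  lin <- e_frag / len_frag                       # electrons per nm of coiled coil
  ncb <- params$n_crossbridges_half_filament
  n_lmm <- if (lmm_count_mode == "per_crossbridge") {
    params$n_lmm_cross_section * (ncb / 3 * params$crown_spacing) / params$lmm_length
  } else {
    params$n_lmm_cross_section
  }
  s2_e <- params$s2_length * lin                 # whole-S2 electrons per molecule
  n_ps <- ncb * pop$frac_ps
  n_ub <- ncb * pop$frac_unbound
  n_b  <- ncb * pop$frac_bound
  structure(list(
    backbone_lmm = n_lmm * params$lmm_length * lin,
    titin = params$titin_n_molecules * params$titin_aband_mw * electrons_per_dalton,
    s2_ps = n_ps * s2_e,
    s2_unbound = n_ub * s2_e,
    s2_bound = n_b * s2_e,
    heads_ps = 2 * n_ps * head_electrons,
    heads_unbound = 2 * n_ub * head_electrons
  ), class = "mass_budget")
}

#' Sum of a mass budget, electrons
#' @param x a `mass_budget`.
#' @param ... ignored.
#' @export
total_electrons.mass_budget <- function(x, ...) sum(unlist(x))

#' Build the thick filament projected density
#'
#' Assembles, centred on the unit-cell origin: the LMM backbone (uniform
#' annulus between the hole and outer radius by default, or 18 projected
#' ribbon cylinders), the uniform titin ring, three trapezoid S2 rings, the
#' trapezoid PSH ring and the trapezoid UBMH ring, with masses taken from
#' the budget.
#'
#' @param params a [thick_params()].
#' @param pop a [head_state_population()] (consistency only).
#' @param budget a [compute_mass_budget()] result.
#' @param spec a [grid_spec()] (used only in ribbon mode).
#' @param backbone_mode `"ribbon"` (default: 18 projected cylinders at the
#'   [backbone_lmm_layout()] positions, the model's actual packing) or
#'   `"annulus"` (azimuthally smeared equivalent).  The choice is not
#'   innocuous: the discrete three-shell packing raises the backbone
#'   transform at the (1,1) order and lowers it at (2,0) relative to a
#'   filled annulus.
#' @param include_bare_zone add a second annulus out to the bare-zone radius
#'   carrying the bare-zone share `bare_zone_length / thick_length` of the
#'   backbone mass (off by default; its axial extent is small).
#' @return a [projected_density()].
#' @export
build_thick_density <- function(params, pop, budget, spec = grid_spec(),
                                backbone_mode = c("ribbon", "annulus"),
                                include_bare_zone = FALSE) {
  backbone_mode <- match.arg(backbone_mode)
  if (any(unlist(budget) < 0)) stop("mass budget entries must be non-negative")
  backbone_mass <- budget$backbone_lmm
  bz_mass <- 0
  if (include_bare_zone) {
    bz_mass <- backbone_mass * params$bare_zone_length / params$thick_length
  }
  dens <- projected_density(spec, center = c(0, 0))
  if (backbone_mode == "annulus") {
    dens <- add_ring(dens, make_ring(params$backbone_hole_radius,
                                     params$backbone_outer_radius,
                                     backbone_mass, "uniform"))
  } else {
    lay <- backbone_lmm_layout(params)
    rc <- 0.65                                  # ribbon cylinder radius, nm
    ax <- grid_axis(spec)
    g <- matrix(0, spec$n, spec$n)
    for (i in seq_len(nrow(lay))) {
      d2 <- outer((ax - lay$x[i])^2, (ax - lay$y[i])^2, `+`)
      g <- g + (d2 <= rc^2)
    }
    g <- g * (backbone_mass / (sum(g) * spec$pixel_size^2))
    dens <- projected_density(spec, grid = g, center = c(0, 0))
  }
  if (bz_mass > 0) {
    dens <- add_ring(dens, make_ring(params$backbone_hole_radius,
                                     params$bare_zone_radius, bz_mass,
                                     "uniform"))
  }
  dens <- add_ring(dens, make_ring(params$titin_r_inner, params$titin_r_outer,
                                   budget$titin, "uniform"))
  dens <- add_ring(dens, make_ring(params$s2_r_start, params$s2_r_outer_ps,
                                   budget$s2_ps, "trapezoid"))
  dens <- add_ring(dens, make_ring(params$s2_r_start, params$s2_r_outer_unbound,
                                   budget$s2_unbound, "trapezoid"))
  dens <- add_ring(dens, make_ring(params$s2_r_start, params$s2_r_outer_bound,
                                   budget$s2_bound, "trapezoid"))
  dens <- add_ring(dens, make_ring(params$ps_r_inner, params$ps_r_outer,
                                   budget$heads_ps, "trapezoid"))
  dens <- add_ring(dens, make_ring(params$ubmh_r_inner, params$ubmh_r_outer,
                                   budget$heads_unbound, "trapezoid"))
  dens
}
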