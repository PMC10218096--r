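# High-level model assembly: structures -> budget -> densities -> unit cell
# -> equatorial pattern, in either deterministic expected-fraction mode or
# per-cell discrete-state mode.

#' Default structure set (synthetic stand-ins)
#'
#' Loads the four structural roles from PDB files when paths are given,
#' otherwise generates the deterministic synthetic stand-ins.  `tm_chains`
#' names the tropomyosin chains of the thin repeat (structure-specific).
#'
#' @param s2,thin_repeat,head_pre,head_post optional PDB paths.
#' @param tm_chains tropomyosin chain ids within the thin repeat.
#' @return named list of atom tables plus `tm_chains`.
#' @export
model_structures <- function(s2 = NULL, thin_repeat = NULL, head_pre = NULL,
                             head_post = NULL,
                             tm_chains = c("T", "U", "V", "W")) {
  list(
    s2 = if (is.null(s2)) synthetic_s2_structure() else read_pdb_atoms(s2),
    thin_repeat = if (is.null(thin_repeat)) synthetic_thin_repeat()
    else read_pdb_atoms(thin_repeat),
    head_pre = if (is.null(head_pre)) synthetic_myosin_head("pre")
    else read_pdb_atoms(head_pre),
    head_post = if (is.null(head_post)) synthetic_myosin_head("post")
    else read_pdb_atoms(head_post),
    tm_chains = tm_chains
  )
}

#' Assemble the full unit-cell model
#'
#' Builds the thick and thin filament densities for a head-state population
#' and returns the assembled unit cell with its bookkeeping.  In the default
#' deterministic mode, bound heads and partner clouds enter at their
#' expected (possibly fractional) counts, split equally between the two
#' thin filaments and smeared over azimuth; with `bound_heads_1/2` given
#' (e.g. from [bound_heads_from_states()]), discrete head structures are
#' placed instead.
#'
#' @param pop a [head_state_population()].
#' @param geometry a [sarcomere_geometry()].
#' @param thick a [thick_params()].
#' @param thin a [thin_params()].
#' @param spec a [grid_spec()].
#' @param structures a [model_structures()] list.
#' @param bound_heads_1,bound_heads_2 optional discrete bound-head tables
#'   for the two thin filaments.
#' @param partner_mode where the non-bound partner heads of bound
#'   crossbridges live: `"ubmh"` (default; added to the thick filament's
#'   disordered unbound-head ring) or `"cloud"` (a uniform disk centred on
#'   each thin filament).
#' @param electrons_per_dalton titin conversion.  The default 0.482 e/Da is
#'   the heavy-atom value (~53 electrons per ~110 Da residue), consistent
#'   with the hydrogen-less atomic structures used for every other
#'   component; 0.54 is the all-atom value.
#' @param backbone_mode passed to [build_thick_density()].
#' @param lmm_count_mode passed to [compute_mass_budget()].
#' @return list of class `sarcomere_model`: `cell`, `budget`,
#'   `head_electrons`, `pop`, `params` (thick/thin), `n_repeats`.
#' @export
build_sarcomere_model <- function(pop = population_preset("relaxed"),
                                  geometry = sarcomere_geometry(),
                                  thick = thick_params(),
                                  thin = thin_params(),
                                  spec = grid_spec(),
                                  structures = model_structures(),
                                  bound_heads_1 = NULL, bound_heads_2 = NULL,
                                  partner_mode = c("ubmh", "cloud"),
                                  electrons_per_dalton = 0.482,
                                  backbone_mode = "ribbon",
                                  lmm_count_mode = "per_crossbridge") {
  partner_mode <- match.arg(partner_mode)
  head_electrons <- sum(structures$head_post$electron_count)
  budget <- compute_mass_budget(thick, pop, structures$s2, head_electrons,
                                electrons_per_dalton = electrons_per_dalton,
                                lmm_count_mode = lmm_count_mode)
  ncb <- thick$n_crossbridges_half_filament
  n_partner <- ncb * pop$frac_bound        # one partner head per bound xbridge
  if (partner_mode == "ubmh") {
    budget$heads_unbound <- budget$heads_unbound + n_partner * head_electrons
  }
  thick_dens <- build_thick_density(thick, pop, budget, spec,
                                    backbone_mode = backbone_mode)
  n_rep <- aband_repeat_count(thin, geometry)
  heads <- list(pre = structures$head_pre, post = structures$head_post)
  cloud_per_fil <- if (partner_mode == "cloud") n_partner / 2 else 0
  discrete <- !is.null(bound_heads_1) || !is.null(bound_heads_2)
  if (discrete) {
    bh <- list(bound_heads_1, bound_heads_2)
    thins <- lapply(1:2, function(i) {
      nbi <- if (is.null(bh[[i]])) 0 else nrow(bh[[i]])
      build_thin_density(thin, structures$thin_repeat, spec,
                         n_repeats = n_rep, tm_chains = structures$tm_chains,
                         bound_heads = bh[[i]], head_structures = heads,
                         n_partner_heads = if (partner_mode == "cloud") nbi else 0,
                         head_electrons = head_electrons)
    })
  } else {
    nb_per_fil <- ncb * pop$frac_bound / 2
    one <- build_thin_density(
      thin, structures$thin_repeat, spec, n_repeats = n_rep,
      tm_chains = structures$tm_chains,
      head_structures = if (nb_per_fil > 0) heads else NULL,
      expected_bound = list(n_heads = nb_per_fil,
                            prestroke = pop$frac_prestroke_of_bound),
      n_partner_heads = cloud_per_fil, head_electrons = head_electrons
    )
    thins <- list(one, one)
  }
  cell <- make_unit_cell(geometry, thick_dens, thins[[1]], thins[[2]])
  structure(list(cell = cell, budget = budget,
                 head_electrons = head_electrons, pop = pop,
                 thick_params = thick, thin_params = thin,
                 n_repeats = n_rep, spec = spec),
            class = "sarcomere_model")
}

#' Run the equatorial pipeline from a configuration
#'
#' Builds densities, computes the eight-reflection pattern and writes the
#' intensity CSV plus a human-readable report.  With a state file the
#' pattern is computed per unit cell and reported as the mean with its
#' standard error over cells; otherwise the deterministic expected-fraction
#' model is used.
#'
#' @param config named list (or path to a `key = value` file, see
#'   [read_run_config()]).  Recognised keys: `state`
#'   (`"relaxed"`/`"contracted"`), `delta_M`, `delta_A` (nm), `pixel_size`,
#'   `extent` (nm), `mode`, `state_file`, `s2_pdb`, `thin_pdb`,
#'   `head_pre_pdb`, `head_post_pdb`, `tm_chains` (comma-separated),
#'   `out_dir`.
#' @return list with `pattern` (a `reflection_set`; mean over cells in
#'   state-file mode, with `sem` column), `per_cell` (list or NULL),
#'   `phases`, and the output file paths.
#' @export
run_equator <- function(config = list()) {
  if (is.character(config)) config <- read_run_config(config)
  get <- function(key, default) {
    if (!is.null(config[[key]])) config[[key]] else default
  }
  state <- get("state", "relaxed")
  pop <- population_preset(state)
  tf <- temperature_factors(get("delta_M", 2.58),
                            get("delta_A", if (state == "relaxed") 2.15 else 1.72))
  spec <- grid_spec(pixel_size = get("pixel_size", 0.05),
                    extent = get("extent", 18))
  mode <- get("mode", "cosine")
  tm_chains <- get("tm_chains", "T,U,V,W")
  if (is.character(tm_chains)) tm_chains <- strsplit(tm_chains, ",")[[1]]
  structures <- model_structures(
    s2 = get("s2_pdb", NULL), thin_repeat = get("thin_pdb", NULL),
    head_pre = get("head_pre_pdb", NULL), head_post = get("head_post_pdb", NULL),
    tm_chains = trimws(tm_chains)
  )
  geometry <- sarcomere_geometry(SL = get("SL", 2.862), d10 = get("d10", 34.21))
  thick <- thick_params(s2_length = get("s2_length", 60))
  thin <- thin_params()

  per_cell <- NULL
  if (!is.null(config$state_file)) {
    states <- read_states(config$state_file)
    cells <- unique(states$cell_id)
    per_cell <- lapply(cells, function(cid) {
      pc <- population_from_states(states, cid)
      m <- build_sarcomere_model(
        pc, geometry, thick, thin, spec, structures,
        bound_heads_1 = bound_heads_from_states(states, cid, 1),
        bound_heads_2 = bound_heads_from_states(states, cid, 2),
        partner_mode = get("partner_mode", "ubmh"),
        electrons_per_dalton = get("electrons_per_dalton", 0.482)
      )
      equatorial_pattern(m$cell, tf, mode = mode)
    })
    pattern <- per_cell[[1]]
    im <- sapply(per_cell, function(p) p$intensity)
    pattern$intensity <- rowMeans(im)
    pattern$sem <- apply(im, 1, stats::sd) / sqrt(length(per_cell))
    # majority phase across cells
    ph <- sapply(per_cell, function(p) p$phase)
    pattern$phase <- apply(ph, 1, function(v) names(which.max(table(v))))
  } else {
    model <- build_sarcomere_model(
      pop, geometry, thick, thin, spec, structures,
      partner_mode = get("partner_mode", "ubmh"),
      electrons_per_dalton = get("electrons_per_dalton", 0.482))
    pattern <- equatorial_pattern(model$cell, tf, mode = mode)
  }

  out_dir <- get("out_dir", NULL)
  files <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    csv <- file.path(out_dir, sprintf("equator_%s.csv", state))
    write_intensity_table(pattern, csv)
    rpt <- file.path(out_dir, sprintf("equator_%s_report.txt", state))
    lines <- c(
      sprintf("equatorial prediction (%s; delta_M = %.3g nm, delta_A = %.3g nm)",
              state, tf$delta_M, tf$delta_A),
      sprintf("phases: %s", phase_string(pattern)),
      sprintf("  (%d,%d)  I = %8.3f%s", pattern$h, pattern$k, pattern$intensity,
              if (!is.null(pattern$sem)) sprintf(" +- %.3f (SEM over %d cells)",
                                                 pattern$sem, length(per_cell))
              else "")
    )
    writeLines(lines, rpt)
    files <- c(csv, rpt)
  }
  list(pattern = pattern, per_cell = per_cell,
       phases = phase_string(pattern), files = files)
}
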