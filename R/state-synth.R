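# Monte Carlo synthesis of per-unit-cell crossbridge state assignments.
#
# Emulates, at the occupancy level, the per-cell output of a spatially
# explicit mechanics simulation: each crossbridge of each cell draws its
# state (parked / unbound / bound) independently from the target fractions.
# Kinetics and spatial cooperativity are out of scope; independence is an
# assumption recorded in the file metadata.

#' Configuration for the crossbridge state synthesiser
#'
#' @param fractions a [head_state_population()]; defaults to the relaxed
#'   preset.
#' @param n_crowns crowns per half thick filament (default 49; three
#'   crossbridges per crown, 14.3 nm axial spacing, 40 degree rotation).
#' @param n_cells number of unit cells to draw.
#' @param seed RNG seed (the draw is deterministic given the config).
#' @param prestroke_fraction fraction of bound heads drawn pre-powerstroke.
#' @param crown_spacing,crown_rotation crown geometry (nm, degrees).
#' @return object of class `state_synth_config`.
#' @export
state_synth_config <- function(fractions = population_preset("relaxed"),
                               n_crowns = 49L, n_cells = 1L, seed = 1L,
                               prestroke_fraction = 0.5,
                               crown_spacing = 14.3, crown_rotation = 40) {
  stopifnot(inherits(fractions, "head_state_population"),
            n_crowns >= 1, n_cells >= 1,
            prestroke_fraction >= 0, prestroke_fraction <= 1)
  structure(list(
    fractions = fractions, n_crowns = as.integer(n_crowns),
    n_crossbridges = 3L * as.integer(n_crowns),
    n_cells = as.integer(n_cells), seed = as.integer(seed),
    prestroke_fraction = prestroke_fraction,
    crown_spacing = crown_spacing, crown_rotation = crown_rotation
  ), class = "state_synth_config")
}

# run code under a local RNG state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Draw per-unit-cell crossbridge states
#'
#' Every crossbridge of every cell draws its state independently with the
#' configured probabilities; bound crossbridges draw their target thin
#' filament uniformly from \{1, 2\} and their lever conformation from the
#' pre-stroke fraction.  Azimuths follow the crown geometry:
#' `(crown * rotation + position * 120) mod 360` (0-based crown and
#' in-crown position).
#'
#' @param config a [state_synth_config()].
#' @return data.frame of class `crossbridge_states`: `cell_id`,
#'   `crown_index`, `position_in_crown`, `state` (`"PS"`, `"unbound"`,
#'   `"bound"`), `bound_filament` (1, 2 or NA), `azimuth` (degrees),
#'   `stroke` (`"pre"`, `"post"` or NA).
#' @export
synth_states <- function(config) {
  stopifnot(inherits(config, "state_synth_config"))
  fr <- config$fractions
  probs <- c(PS = fr$frac_ps, unbound = fr$frac_unbound, bound = fr$frac_bound)
  if (abs(sum(probs) - 1) > 1e-6) stop("state fractions must sum to 1")
  n <- config$n_crossbridges * config$n_cells
  crown <- rep(rep(seq_len(config$n_crowns) - 1L, each = 3L), config$n_cells)
  posn <- rep(rep(0:2, config$n_crowns), config$n_cells)
  .with_seed(config$seed, {
    state <- sample(names(probs), n, replace = TRUE, prob = probs)
    bound <- state == "bound"
    filament <- rep(NA_integer_, n)
    stroke <- rep(NA_character_, n)
    nb <- sum(bound)
    if (nb) {
      filament[bound] <- sample(1:2, nb, replace = TRUE)
      stroke[bound] <- sample(c("pre", "post"), nb, replace = TRUE,
                              prob = c(config$prestroke_fraction,
                                       1 - config$prestroke_fraction))
    }
    out <- data.frame(
      cell_id = rep(seq_len(config$n_cells), each = config$n_crossbridges),
      crown_index = crown,
      position_in_crown = posn,
      state = state,
      bound_filament = filament,
      azimuth = (crown * config$crown_rotation + posn * 120) %% 360,
      stroke = stroke,
      stringsAsFactors = FALSE
    )
    structure(out, class = c("crossbridge_states", "data.frame"),
              config = config)
  })
}

#' Empirical head-state population of one synthesised cell
#'
#' @param states a [synth_states()] result.
#' @param cell_id which cell to summarise.
#' @return a [head_state_population()] of the empirical fractions (the
#'   pre-stroke fraction falls back to the config value when the cell has
#'   no bound crossbridges).
#' @export
population_from_states <- function(states, cell_id) {
  sub <- states[states$cell_id == cell_id, , drop = FALSE]
  if (!nrow(sub)) stop("unknown cell_id: ", cell_id)
  n <- nrow(sub)
  nb <- sum(sub$state == "bound")
  pre <- if (nb > 0) mean(sub$stroke[sub$state == "bound"] == "pre")
  else attr(states, "config")$prestroke_fraction
  if (is.null(pre)) pre <- 0.5
  head_state_population(nb / n, sum(sub$state == "unbound") / n,
                        sum(sub$state == "PS") / n, pre)
}

#' Bound-head records of one cell and thin filament
#'
#' Extracts the discrete bound heads targeting one of the two unit-cell
#' thin filaments in the format consumed by [build_thin_density()].
#'
#' @param states a [synth_states()] result.
#' @param cell_id which cell.
#' @param filament 1 or 2.
#' @return data.frame with `azimuth` and `stroke` columns.
#' @export
bound_heads_from_states <- function(states, cell_id, filament) {
  sub <- states[states$cell_id == cell_id & states$state == "bound" &
                  !is.na(states$bound_filament) &
                  states$bound_filament == filament, , drop = FALSE]
  data.frame(azimuth = sub$azimuth, stroke = sub$stroke,
             stringsAsFactors = FALSE)
}

#' Write synthesised states to CSV with a JSON metadata header
#'
#' The CSV holds one row per crossbridge; `<path>.json` carries the config,
#' seed and the independence-assumption flag, so external state tables can
#' be converted to the same format.
#'
#' @param states a [synth_states()] result.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_states <- function(states, path) {
  utils::write.csv(as.data.frame(states), path, row.names = FALSE, quote = FALSE)
  cfg <- attr(states, "config")
  meta <- list(
    n_crowns = cfg$n_crowns, n_crossbridges = cfg$n_crossbridges,
    n_cells = cfg$n_cells, seed = cfg$seed,
    prestroke_fraction = cfg$prestroke_fraction,
    crown_spacing = cfg$crown_spacing, crown_rotation = cfg$crown_rotation,
    fractions = unclass(cfg$fractions),
    assumptions = "independent per-crossbridge draws; no spatial cooperativity"
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a state file written by [write_states()]
#' @param path CSV path (JSON header expected at `<path>.json`).
#' @return a `crossbridge_states` data.frame with the config attached.
#' @export
read_states <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "crown_index", "position_in_crown", "state",
            "bound_filament", "azimuth", "stroke")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("state file missing column(s): ",
                         paste(miss, collapse = ", "))
  jp <- paste0(path, ".json")
  cfg <- NULL
  if (file.exists(jp)) {
    meta <- jsonlite::read_json(jp, simplifyVector = TRUE)
    fr <- meta$fractions
    cfg <- state_synth_config(
      head_state_population(fr$frac_bound, fr$frac_unbound, fr$frac_ps,
                            fr$frac_prestroke_of_bound),
      n_crowns = meta$n_crowns, n_cells = meta$n_cells, seed = meta$seed,
      prestroke_fraction = meta$prestroke_fraction,
      crown_spacing = meta$crown_spacing, crown_rotation = meta$crown_rotation
    )
  }
  structure(df, class = c("crossbridge_states", "data.frame"), config = cfg)
}
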