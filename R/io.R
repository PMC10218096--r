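# Intensity tables, bundled reference data, fixture generation and run
# configuration files.

#' Read an equatorial intensity table
#'
#' CSV with columns `family_h`, `family_k`, `intensity` and optionally
#' `error` and `phase`.  The table must contain the (1,0) family; if it is
#' not already on the I(1,0) = 100 scale it is renormalised (errors scale
#' along).
#'
#' @param path CSV path.
#' @return a `reflection_set` data.frame with columns `h`, `k`, `L`,
#'   `intensity` and, when present, `error` and `phase`.
#' @export
read_intensity_table <- function(path) {
  if (!file.exists(path)) stop("cannot read intensity table: ", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("parse error in ", path, ": ",
                                          conditionMessage(e)))
  need <- c("family_h", "family_k", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("intensity table missing column(s): ",
                         paste(miss, collapse = ", "))
  for (cn in need) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) & !is.na(df[[cn]]) & df[[cn]] != "NA")
    if (length(bad)) stop("non-numeric value in column ", cn, " at data line ",
                          bad[1], " of ", path)
    df[[cn]] <- v
  }
  i10 <- which(df$family_h == 1 & df$family_k == 0)
  if (!length(i10)) stop("intensity table has no (1,0) row: ", path)
  scale <- 100 / df$intensity[i10[1]]
  out <- data.frame(h = as.integer(df$family_h), k = as.integer(df$family_k),
                    intensity = df$intensity * scale)
  out$L <- sqrt(out$h^2 + out$k^2 + out$h * out$k)
  if ("error" %in% names(df)) {
    out$error <- suppressWarnings(as.numeric(df$error)) * scale
  }
  if ("phase" %in% names(df)) out$phase <- as.character(df$phase)
  structure(out, class = c("reflection_set", "data.frame"))
}

#' Write a reflection set as an intensity table CSV
#' @param x a `reflection_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_intensity_table <- function(x, path) {
  df <- data.frame(family_h = x$h, family_k = x$k,
                   intensity = round(x$intensity, 6))
  df$error <- if (!is.null(x$error)) x$error else NA
  df$phase <- if (!is.null(x$phase)) x$phase else ""
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Bundled experimental equatorial intensities (rat EDL muscle)
#'
#' The measured eight-reflection tables for resting and isometrically
#' contracting EDL muscle (means over six muscles, normalised to
#' I(1,0) = 100, with standard errors and observed phases), shipped as CSV
#' under `inst/extdata`.
#'
#' @param state `"resting"` or `"contracting"`.
#' @return a `reflection_set` data.frame.
#' @export
edl_intensity_table <- function(state = c("resting", "contracting")) {
  state <- match.arg(state)
  path <- system.file("extdata",
                      sprintf("edl_%s_intensities.csv", state),
                      package = "sarcoeq", mustWork = TRUE)
  read_intensity_table(path)
}

#' Worked example: parked-state percentage from a layer-line gain
#'
#' If complete sequestration of heads raises a myosin layer-line intensity
#' by a factor `1 + gain` over rest, and layer-line intensity scales as the
#' square of the number of helically ordered heads, the resting
#' parked-state share is `100 / sqrt(1 + gain)` percent (75% for the
#' observed 80% gain under blebbistatin).
#'
#' @param gain fractional intensity increase (0.8 = +80%).
#' @return percentage of heads in the parked state at rest.
#' @export
ps_fraction_from_layerline_gain <- function(gain = 0.8) {
  stopifnot(gain > -1)
  100 / sqrt(1 + gain)
}

#' Inner radius of the disordered unbound-head ring
#'
#' Unbound heads tilt toward the filament axis, so their in-plane radial
#' extent is about `head_projection` (8 nm); the ring inner radius is the
#' maximum observed filament radius minus that projection.
#'
#' @param r_outer outer radius, nm (17.5 = maximum thick filament radius).
#' @param head_projection average in-plane radial extent of a head, nm.
#' @return inner radius, nm.
#' @export
ubmh_inner_radius <- function(r_outer = 17.5, head_projection = 8) {
  r_outer - head_projection
}

#' Generate fixture files
#'
#' `"toy-pdb"` writes small deterministic PDB structures (carbon ring,
#' coiled-coil stand-in, thin-repeat stand-in, pre/post head stand-ins) that
#' exercise every density path without downloads; `"intensity-tables"`
#' copies the bundled experimental tables; `"state-file"` writes a seeded
#' [synth_states()] draw.
#'
#' @param kind `"toy-pdb"`, `"intensity-tables"` or `"state-file"`.
#' @param dir output directory (created if needed).
#' @param seed seed for the state file.
#' @return character vector of the files written.
#' @export
generate_fixtures <- function(kind = c("toy-pdb", "intensity-tables",
                                       "state-file"),
                              dir = ".", seed = 1L) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  if (kind == "toy-pdb") {
    write_pdb(synthetic_carbon_ring(), fp("synthetic-carbon-ring.pdb"))
    write_pdb(synthetic_s2_structure(), fp("synthetic-s2-coiledcoil.pdb"))
    write_pdb(synthetic_thin_repeat(), fp("synthetic-thin-repeat.pdb"))
    write_pdb(synthetic_myosin_head("post"), fp("synthetic-head-post.pdb"))
    write_pdb(synthetic_myosin_head("pre"), fp("synthetic-head-pre.pdb"))
    files <- fp(c("synthetic-carbon-ring.pdb", "synthetic-s2-coiledcoil.pdb",
                  "synthetic-thin-repeat.pdb", "synthetic-head-post.pdb",
                  "synthetic-head-pre.pdb"))
  } else if (kind == "intensity-tables") {
    files <- fp(c("edl_resting_intensities.csv",
                  "edl_contracting_intensities.csv"))
    file.copy(system.file("extdata", basename(files), package = "sarcoeq",
                          mustWork = TRUE),
              files, overwrite = TRUE)
  } else {
    st <- synth_states(state_synth_config(n_cells = 10L, seed = seed))
    write_states(st, fp("synthetic-states.csv"))
    files <- fp(c("synthetic-states.csv", "synthetic-states.csv.json"))
  }
  files
}

#' Read a flat key = value run configuration file
#'
#' Lines of the form `key = value` (comments with `#`); values are parsed
#' as numbers when possible.  Units follow the parameter documentation
#' (radii nm, lengths um).
#'
#' @param path config file path.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("cannot read config file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", lines))
  bad <- which(vapply(kv, length, integer(1)) != 3)
  if (length(bad)) stop("malformed config line: ", lines[bad[1]])
  vals <- lapply(kv, function(m) {
    v <- trimws(m[3])
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  stats::setNames(vals, vapply(kv, `[[`, character(1), 2))
}
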