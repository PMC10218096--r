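# Atomic structures -> 2D projected electron densities.
#
# A filament density is a hybrid object: a pixel grid (electrons/nm^2) for
# atomic detail plus a list of analytic ring components for azimuthally
# smeared mass.  All coordinates are nm; PDB files are converted on read.

# -- element bookkeeping -----------------------------------------------------

.element_numbers <- c(
  H = 1L, HE = 2L, LI = 3L, BE = 4L, B = 5L, C = 6L, N = 7L, O = 8L,
  F = 9L, NE = 10L, `NA` = 11L, MG = 12L, AL = 13L, SI = 14L, P = 15L,
  S = 16L, CL = 17L, K = 19L, CA = 20L, MN = 25L, FE = 26L, CO = 27L,
  NI = 28L, CU = 29L, ZN = 30L, SE = 34L, BR = 35L, I = 53L
)

# Bondi-style van der Waals radii, nm.  Unknown elements error on lookup
# rather than defaulting silently.
.element_vdw <- c(
  H = 0.120, HE = 0.140, LI = 0.182, BE = 0.153, B = 0.192, C = 0.170,
  N = 0.155, O = 0.152, F = 0.147, NE = 0.154, `NA` = 0.227, MG = 0.173,
  AL = 0.184, SI = 0.210, P = 0.180, S = 0.180, CL = 0.175, K = 0.275,
  CA = 0.231, MN = 0.205, FE = 0.205, CO = 0.200, NI = 0.163, CU = 0.140,
  ZN = 0.139, SE = 0.190, BR = 0.185, I = 0.198
)

#' Atomic number (= electron count) of an element symbol
#'
#' Electron count per atom is taken as the atomic number; formal charges are
#' ignored, which is inconsequential for relative intensities at equatorial
#' resolution.
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return integer vector of atomic numbers.
#' @export
atomic_number <- function(element) {
  z <- .element_numbers[toupper(trimws(element))]
  if (anyNA(z)) {
    bad <- unique(element[is.na(z)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  unname(z)
}

#' Van der Waals radius of an element symbol, nm
#' @inheritParams atomic_number
#' @return numeric vector of radii in nm.
#' @export
vdw_radius <- function(element) {
  r <- .element_vdw[toupper(trimws(element))]
  if (anyNA(r)) {
    bad <- unique(element[is.na(r)])
    stop("no van der Waals radius tabulated for: ", paste(bad, collapse = ", "))
  }
  unname(r)
}

# -- PDB input/output --------------------------------------------------------

#' Read atoms from a PDB-format file
#'
#' Parses fixed-column ATOM/HETATM records.  Coordinates are converted from
#' Angstrom to nm.  Hydrogens are kept when present; no implicit hydrogens
#' are added.  The element symbol is taken from columns 77-78 when present,
#' otherwise inferred from the atom name.
#'
#' @param path path to a PDB file.
#' @param chain_filter optional character vector of chain identifiers; when
#'   given, only atoms on those chains are returned.
#' @return a data.frame of atom records with columns `element`, `x`, `y`, `z`
#'   (nm), `chain`, `electron_count`, `vdw_radius`.
#' @export
read_pdb_atoms <- function(path, chain_filter = NULL) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  keep <- which(rec == "ATOM  " | rec == "HETATM")
  if (!length(keep)) stop("no ATOM/HETATM records in ", path)
  ln <- lines[keep]
  elem <- trimws(substr(ln, 77L, 78L))
  noel <- !nzchar(elem)
  if (any(noel)) {
    # fall back to the first alphabetic character(s) of the atom name
    nm <- gsub("[^A-Za-z].*$", "", gsub("^[^A-Za-z]*", "", substr(ln[noel], 13L, 16L)))
    two <- toupper(substr(nm, 1L, 2L)) %in% names(.element_numbers) &
      !(toupper(substr(nm, 1L, 1L)) %in% c("C", "N", "O", "H", "P", "S"))
    elem[noel] <- ifelse(two, substr(nm, 1L, 2L), substr(nm, 1L, 1L))
  }
  elem <- toupper(elem)
  bad <- which(!(elem %in% names(.element_numbers)))
  if (length(bad)) {
    stop("unknown element symbol '", elem[bad[1L]], "' at line ",
         keep[bad[1L]], " of ", path)
  }
  atoms <- data.frame(
    element = elem,
    x = as.numeric(substr(ln, 31L, 38L)) / 10,
    y = as.numeric(substr(ln, 39L, 46L)) / 10,
    z = as.numeric(substr(ln, 47L, 54L)) / 10,
    chain = substr(ln, 22L, 22L),
    stringsAsFactors = FALSE
  )
  if (anyNA(atoms$x) || anyNA(atoms$y) || anyNA(atoms$z)) {
    stop("malformed coordinates in ", path)
  }
  atoms$electron_count <- atomic_number(atoms$element)
  atoms$vdw_radius <- vdw_radius(atoms$element)
  if (!is.null(chain_filter)) atoms <- atoms[atoms$chain %in% chain_filter, ]
  rownames(atoms) <- NULL
  atoms
}

#' Write an atom table to a PDB-format file
#'
#' Counterpart of [read_pdb_atoms()], used by the synthetic structure
#' generators.  Coordinates are written in Angstrom.
#'
#' @param atoms atom data.frame with `element`, `x`, `y`, `z` (nm) and
#'   optionally `chain`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(atoms, path) {
  n <- nrow(atoms)
  chain <- if ("chain" %in% names(atoms)) atoms$chain else rep("A", n)
  serial <- ((seq_len(n) - 1L) %% 99999L) + 1L
  resseq <- ((seq_len(n) - 1L) %/% 10L %% 9999L) + 1L
  # fixed PDB columns: name 13-16, resName 18-20, chainID 22, resSeq 23-26,
  # x/y/z 31-54, element 77-78
  name <- sprintf(" %-3s", substr(atoms$element, 1L, 2L))
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    serial, name, "GLY", chain, resseq,
    atoms$x * 10, atoms$y * 10, atoms$z * 10, 1, 0, toupper(atoms$element)
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# -- grids and densities -----------------------------------------------------

#' Specify a square projection grid
#'
#' The field is a (2n+1)^2 square of pixels centred on `origin`; by default
#' it spans +-18 nm, enough for the largest model radius (17.5 nm) plus one
#' van der Waals radius.
#'
#' @param pixel_size pixel edge, nm (default 0.05).
#' @param extent half-width of the field, nm (default 18).
#' @param origin centre of the field in filament coordinates, nm.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(pixel_size = 0.05, extent = 18, origin = c(0, 0)) {
  stopifnot(pixel_size > 0, extent > 0, length(origin) == 2)
  n_half <- as.integer(round(extent / pixel_size))
  structure(
    list(pixel_size = pixel_size, extent = extent, origin = as.numeric(origin),
         n_half = n_half, n = 2L * n_half + 1L),
    class = "grid_spec"
  )
}

#' Pixel-centre coordinates of a grid axis
#' @param spec a [grid_spec()].
#' @return numeric vector of length `spec$n`.
#' @export
grid_axis <- function(spec) {
  (seq_len(spec$n) - spec$n_half - 1L) * spec$pixel_size
}

#' Construct a projected density container
#'
#' @param spec a [grid_spec()].
#' @param grid optional `n x n` matrix of projected density, electrons/nm^2.
#' @param rings list of [make_ring()] components.
#' @param center filament centre in unit-cell coordinates, nm.
#' @return object of class `projected_density`.
#' @export
projected_density <- function(spec, grid = NULL, rings = list(), center = c(0, 0)) {
  if (is.null(grid)) grid <- matrix(0, spec$n, spec$n)
  stopifnot(nrow(grid) == spec$n, ncol(grid) == spec$n)
  if (any(grid < -1e-9)) stop("projected density must be non-negative")
  structure(
    list(grid = grid, spec = spec, rings = rings, center = as.numeric(center)),
    class = "projected_density"
  )
}

#' @export
print.projected_density <- function(x, ...) {
  cat(sprintf(
    "projected density: %d x %d px @ %.3g nm, %d ring(s), %.4g electrons\n",
    x$spec$n, x$spec$n, x$spec$pixel_size, length(x$rings), total_electrons(x)
  ))
  invisible(x)
}

# Accumulate chord-length sphere projections of a block of atoms (shared
# footprint half-width K) into a dense grid vector.  Exact sub-pixel kernel:
# weight at a pixel centre at distance d from the atom axis is
# sqrt(R^2 - d^2), renormalised so each atom deposits exactly its electrons.
.project_block <- function(gridvec, atoms, spec, K) {
  n <- spec$n
  px <- spec$pixel_size
  ax <- (atoms$x - spec$origin[1]) / px
  ay <- (atoms$y - spec$origin[2]) / px
  ix0 <- round(ax)
  iy0 <- round(ay)
  off <- seq.int(-K, K)
  grd <- expand.grid(dx = off, dy = off)
  m <- nrow(grd)
  na <- nrow(atoms)
  # distances from true atom centre to candidate pixel centres, nm
  ddx <- (outer(ix0, grd$dx, `+`) - ax) * px
  ddy <- (outer(iy0, grd$dy, `+`) - ay) * px
  w <- sqrt(pmax(atoms$vdw_radius^2 - (ddx * ddx + ddy * ddy), 0))
  rs <- rowSums(w)
  if (any(rs == 0)) {
    # atom smaller than the pixel spacing: deposit on the nearest pixel
    zi <- which(rs == 0)
    ctr <- which(grd$dx == 0L & grd$dy == 0L)
    w[zi, ctr] <- 1
    rs[zi] <- 1
  }
  w <- w * (atoms$electron_count / rs)
  jx <- outer(ix0, grd$dx, `+`) + spec$n_half + 1L
  jy <- outer(iy0, grd$dy, `+`) + spec$n_half + 1L
  live <- w > 0
  oob <- live & (jx < 1L | jx > n | jy < 1L | jy > n)
  if (any(oob)) {
    bad <- which(rowSums(oob) > 0)[1L]
    stop(sprintf(
      "atom footprint exceeds the grid field (atom at x=%.3f, y=%.3f nm, vdW %.3f nm)",
      atoms$x[bad], atoms$y[bad], atoms$vdw_radius[bad]))
  }
  idx <- (jy[live] - 1L) * n + jx[live]
  acc <- rowsum(w[live], idx, reorder = FALSE)
  gridvec[as.integer(rownames(acc))] <- gridvec[as.integer(rownames(acc))] + acc[, 1L]
  gridvec
}

#' Project atoms onto a 2D grid along the filament (z) axis
#'
#' Each atom is modelled as a uniform-density sphere of its van der Waals
#' radius carrying `electron_count` electrons.  Projection along z gives the
#' chord-length law: projected density proportional to sqrt(R^2 - d^2) within
#' distance d <= R of the atom axis, normalised so that every atom's column
#' integrates exactly to its electron count.  Contributions accumulate
#' additively.
#'
#' @param atoms atom data.frame from [read_pdb_atoms()] or a generator.
#' @param spec a [grid_spec()]; must cover every atom footprint.
#' @param center recorded filament centre for the resulting density.
#' @return a [projected_density()] with an empty ring list.
#' @export
project_atoms <- function(atoms, spec, center = c(0, 0)) {
  stopifnot(nrow(atoms) >= 1)
  gridvec <- numeric(spec$n^2)
  # block by footprint size so every atom in a block shares a stencil extent
  K_all <- pmax(1L, as.integer(ceiling(atoms$vdw_radius / spec$pixel_size)) + 1L)
  for (K in sort(unique(K_all))) {
    sel <- which(K_all == K)
    chunk <- 60000L
    for (s in split(sel, ceiling(seq_along(sel) / chunk))) {
      gridvec <- .project_block(gridvec, atoms[s, , drop = FALSE], spec, K)
    }
  }
  projected_density(
    spec,
    grid = matrix(gridvec, spec$n, spec$n) / spec$pixel_size^2,
    center = center
  )
}

# -- ring components ---------------------------------------------------------

#' Create an analytic ring density component
#'
#' Rings carry azimuthally smeared mass between `r_inner` and `r_outer`.
#' `uniform` rings have constant areal density; `trapezoid` rings are linear
#' in radius, from rho_in at the inner edge down to `taper_ratio * rho_in`
#' at the outer edge, with rho_in solved so the ring integrates to
#' `total_electrons`.  The default taper `r_inner/r_outer` keeps the mass per
#' unit radius roughly constant (density falling off like 1/r, sampled
#' linearly).
#'
#' @param r_inner,r_outer ring radii, nm (`0 <= r_inner < r_outer`).
#' @param total_electrons ring mass, electrons (>= 0).
#' @param profile `"trapezoid"` or `"uniform"`.
#' @param taper_ratio outer/inner density ratio in (0, 1]; trapezoid only.
#' @return object of class `ring_component`.
#' @export
make_ring <- function(r_inner, r_outer, total_electrons,
                      profile = c("trapezoid", "uniform"),
                      taper_ratio = if (r_inner > 0) r_inner / r_outer else 1) {
  profile <- match.arg(profile)
  if (!(r_inner >= 0 && r_inner < r_outer)) {
    stop("ring geometry error: need 0 <= r_inner < r_outer")
  }
  if (total_electrons < 0) stop("ring mass must be non-negative")
  if (!(taper_ratio > 0 && taper_ratio <= 1)) {
    stop("taper_ratio must lie in (0, 1]")
  }
  if (profile == "uniform") {
    rho_in <- total_electrons / (pi * (r_outer^2 - r_inner^2))
    taper_ratio <- 1
  } else {
    # M = 2*pi*rho_in * [ I0 + (t - 1)/(r2 - r1) * I1 ]
    i0 <- (r_outer^2 - r_inner^2) / 2
    i1 <- (r_outer^3 - r_inner^3) / 3 - r_inner * (r_outer^2 - r_inner^2) / 2
    rho_in <- total_electrons /
      (2 * pi * (i0 + (taper_ratio - 1) / (r_outer - r_inner) * i1))
  }
  structure(
    list(r_inner = r_inner, r_outer = r_outer,
         total_electrons = total_electrons, profile = profile,
         taper_ratio = taper_ratio, rho_in = rho_in),
    class = "ring_component"
  )
}

#' Areal density of a ring at given radii
#' @param ring a [make_ring()] component.
#' @param r radii, nm.
#' @return electrons/nm^2 at each radius (0 outside the ring).
#' @export
ring_density <- function(ring, r) {
  inside <- r >= ring$r_inner & r <= ring$r_outer
  rho <- numeric(length(r))
  if (ring$profile == "uniform") {
    rho[inside] <- ring$rho_in
  } else {
    f <- (r[inside] - ring$r_inner) / (ring$r_outer - ring$r_inner)
    rho[inside] <- ring$rho_in * (1 + (ring$taper_ratio - 1) * f)
  }
  rho
}

#' Add a ring component to a projected density
#' @param density a [projected_density()].
#' @param ring a [make_ring()] component.
#' @return the density with the ring appended.
#' @export
add_ring <- function(density, ring) {
  stopifnot(inherits(density, "projected_density"), inherits(ring, "ring_component"))
  density$rings <- c(density$rings, list(ring))
  density
}

#' Rasterise a ring onto a density grid (oracle / visualisation path)
#'
#' Evaluates the ring's areal density at pixel centres.  Used by the
#' analytic-vs-DFT cross-checks; the analytic transform remains the default
#' computational route.
#'
#' @inheritParams add_ring
#' @param spec a [grid_spec()].
#' @return a [projected_density()] holding only a grid.
#' @export
rasterize_ring <- function(ring, spec) {
  ax <- grid_axis(spec)
  r <- sqrt(outer(ax^2, ax^2, `+`))
  projected_density(spec, grid = matrix(ring_density(ring, r), spec$n, spec$n))
}

# -- totals and export -------------------------------------------------------

#' Total electrons in a density (grid integral plus ring masses)
#' @param x a [projected_density()] (other types may add methods).
#' @param ... passed to methods.
#' @return electrons.
#' @export
total_electrons <- function(x, ...) UseMethod("total_electrons")

#' @export
total_electrons.projected_density <- function(x, ...) {
  sum(x$grid) * x$spec$pixel_size^2 +
    sum(vapply(x$rings, `[[`, numeric(1), "total_electrons"))
}

#' @export
total_electrons.default <- function(x, ...) {
  if (is.data.frame(x) && "electron_count" %in% names(x)) {
    return(sum(x$electron_count))
  }
  stop("no total_electrons method for this object")
}

#' Export a density as a plain-text matrix with a JSON sidecar
#'
#' @param density a [projected_density()].
#' @param path output path for the matrix; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_density <- function(density, path) {
  utils::write.table(density$grid, path, row.names = FALSE, col.names = FALSE)
  side <- list(
    pixel_size = density$spec$pixel_size,
    extent = density$spec$extent,
    origin = density$spec$origin,
    center = density$center,
    grid_electrons = sum(density$grid) * density$spec$pixel_size^2,
    ring_electrons = sum(vapply(density$rings, `[[`, numeric(1), "total_electrons")),
    rings = lapply(density$rings, function(r) r[c("r_inner", "r_outer",
                                                  "total_electrons", "profile",
                                                  "taper_ratio")])
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a density written by [write_density()]
#' @param path matrix path (the JSON sidecar must sit at `<path>.json`).
#' @return a [projected_density()].
#' @export
read_density <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  grid <- as.matrix(utils::read.table(path))
  dimnames(grid) <- NULL
  spec <- grid_spec(side$pixel_size, side$extent, side$origin)
  rings <- lapply(
    if (length(side$rings)) seq_len(nrow(as.data.frame(side$rings))) else integer(),
    function(i) {
      r <- as.data.frame(side$rings)[i, ]
      make_ring(r$r_inner, r$r_outer, r$total_electrons, r$profile,
                if (r$profile == "uniform") 1 else r$taper_ratio)
    })
  projected_density(spec, grid = grid, rings = rings, center = side$center)
}
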