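# Thin filament projected density: the actin/tropomyosin/troponin repeat
# rendered with its per-repeat axial rotation, a nebulin surrogate, bound
# myosin heads in pre/post-powerstroke conformations, and the uniform cloud
# of their partner heads.

#' Thin filament structural parameters
#'
#' The repeat structure rotates by `repeat_rotation` (27.7 degrees) after
#' every `monomers_per_repeat` (14) actin monomers, i.e. once per 38.3 nm
#' troponin repeat.  The nebulin surrogate is the tropomyosin portion of the
#' repeat rotated azimuthally by `nebulin_rotation` (90 degrees).
#'
#' `attach_radius` is the filament surface radius where a bound head's
#' actin-binding interface lands (monomer centre radius plus monomer
#' radius).
#'
#' @param ... override any default by name.
#' @return object of class `thin_params`.
#' @export
thin_params <- function(...) {
  p <- list(
    repeat_rotation = 27.7,
    monomers_per_repeat = 14L,
    nebulin_rotation = 90,
    tn_spacing = 38.3,
    filament_length = 1.15,
    cloud_r_outer = 9.5,
    attach_radius = 3.6
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) stop("unknown thin_params field(s): ",
                            paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  if (any(unlist(p[c("repeat_rotation", "monomers_per_repeat", "tn_spacing",
                     "filament_length", "cloud_r_outer")]) <= 0)) {
    stop("thin_params fields must be positive")
  }
  structure(p, class = "thin_params")
}

#' Number of whole thin-filament repeats inside the A-band
#'
#' Thin filaments in the I-band are too disordered to diffract coherently,
#' so only the A-band portion is rendered: the in-A-band thin length is
#' `filament_length - (SL - thick_length)/2`, floored by the repeat spacing.
#' `mode = "whole"` counts repeats over the whole filament instead (for
#' sensitivity checks).
#'
#' @param params a [thin_params()].
#' @param geometry a [sarcomere_geometry()].
#' @param mode `"aband"` or `"whole"`.
#' @return integer repeat count; 0 (with a warning) when the overlap is
#'   non-positive.
#' @export
aband_repeat_count <- function(params, geometry, mode = c("aband", "whole")) {
  mode <- match.arg(mode)
  len_um <- if (mode == "whole") params$filament_length
  else params$filament_length - (geometry$SL - geometry$thick_length) / 2
  if (len_um <= 0) {
    warning("no thick-thin overlap at this sarcomere length; 0 repeats")
    return(0L)
  }
  as.integer(floor(len_um * 1000 / params$tn_spacing))
}

# rotate atom x/y about the z axis by `deg` degrees
.rotate_atoms_z <- function(atoms, deg) {
  a <- deg * pi / 180
  x <- atoms$x * cos(a) - atoms$y * sin(a)
  atoms$y <- atoms$x * sin(a) + atoms$y * cos(a)
  atoms$x <- x
  atoms
}

#' Orient a myosin head structure for placement
#'
#' Centres the structure, aligns its longest principal axis with +x, points
#' the bulkier (motor-domain) end toward -x and shifts it so the binding end
#' sits at x = 0.  Placement then reduces to a translation to the attachment
#' radius and a rotation to the target azimuth.
#'
#' @param atoms head atom table.
#' @return the reoriented atom table.
#' @export
orient_head <- function(atoms) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  xyz <- sweep(xyz, 2, ctr)
  ev <- eigen(stats::cov(xyz), symmetric = TRUE)
  v <- ev$vectors[, 1]
  # rotation taking v onto e1 (Rodrigues)
  e1 <- c(1, 0, 0)
  cth <- sum(v * e1)
  if (cth < 0) { v <- -v; cth <- -cth }
  ax <- c(0, v[3], -v[2])                       # v x e1
  s <- sqrt(sum(ax^2))
  if (s > 1e-12) {
    k <- ax / s
    K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
                byrow = TRUE)
    R <- diag(3) + s * K + (1 - cth) * K %*% K
    xyz <- xyz %*% t(R)
  }
  # heavier end (motor domain) toward -x
  w <- atoms$electron_count
  if (sum(w * xyz[, 1]) / sum(w) > (min(xyz[, 1]) + max(xyz[, 1])) / 2) {
    xyz[, 1] <- -xyz[, 1]
  }
  xyz[, 1] <- xyz[, 1] - min(xyz[, 1])
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms
}

# place an oriented head at an azimuth (degrees) and radial offset (nm)
.place_head <- function(oriented, azimuth, radial_offset) {
  oriented$x <- oriented$x + radial_offset
  .rotate_atoms_z(oriented, azimuth)
}

#' Build a thin filament projected density
#'
#' The base density renders `n_repeats` copies of the repeat structure,
#' successive copies rotated by `repeat_rotation` about the filament axis
#' (projection collapses the axial dimension, so the axial shift enters only
#' through this rotation).  A nebulin surrogate - the tropomyosin chains
#' rotated by `nebulin_rotation` - is added once per repeat.  Bound myosin
#' heads are added either discretely (a `bound_heads` table with `azimuth`,
#' `stroke` and optional `radial_offset`) or as a deterministic expectation
#' (`expected_bound`: possibly fractional head counts smeared over
#' `n_azimuth` evenly spaced azimuths).  Partner heads of bound crossbridges
#' enter as a uniform disk of electron density centred on the filament.
#'
#' @param params a [thin_params()].
#' @param repeat_atoms atom table of one repeat (actin + Tm + Tn).
#' @param spec a [grid_spec()].
#' @param n_repeats number of repeats to render.
#' @param tm_chains chain identifiers of the tropomyosin chains within
#'   `repeat_atoms` (structure-specific; used for the nebulin surrogate).
#' @param bound_heads optional data.frame of discrete bound heads with
#'   columns `azimuth` (degrees, in `[0, 360)`), `stroke` (`"pre"`/`"post"`)
#'   and optional `radial_offset` (nm; default `params$attach_radius`).
#' @param head_structures list with `pre` and `post` atom tables (required
#'   when heads are present).
#' @param expected_bound optional list `list(n_heads =, prestroke =,
#'   n_azimuth = 24)` for the expectation mode.
#' @param n_partner_heads partner-head count for the cloud (may be
#'   fractional in expectation mode).
#' @param head_electrons electrons per head (required when
#'   `n_partner_heads > 0`).
#' @param center filament centre in unit-cell coordinates, nm.
#' @return a [projected_density()].
#' @export
build_thin_density <- function(params, repeat_atoms, spec = grid_spec(),
                               n_repeats, tm_chains = c("T", "U", "V", "W"),
                               bound_heads = NULL, head_structures = NULL,
                               expected_bound = NULL,
                               n_partner_heads = 0, head_electrons = NULL,
                               center = c(0, 0)) {
  if (is.null(repeat_atoms) || nrow(repeat_atoms) == 0) {
    stop("repeat_atoms must be non-empty")
  }
  stopifnot(n_repeats >= 1)
  tm <- repeat_atoms[repeat_atoms$chain %in% tm_chains, , drop = FALSE]
  pieces <- vector("list", 2L * n_repeats)
  for (k in seq_len(n_repeats) - 1L) {
    rot <- k * params$repeat_rotation
    pieces[[2L * k + 1L]] <- .rotate_atoms_z(repeat_atoms, rot)
    if (nrow(tm)) {
      pieces[[2L * k + 2L]] <- .rotate_atoms_z(tm, rot + params$nebulin_rotation)
    }
  }
  base <- project_atoms(do.call(rbind, pieces), spec, center = center)
  grid <- base$grid

  has_discrete <- !is.null(bound_heads) && nrow(bound_heads) > 0
  has_expected <- !is.null(expected_bound) && expected_bound$n_heads > 0
  if ((has_discrete || has_expected) &&
      (is.null(head_structures) || is.null(head_structures$pre) ||
       is.null(head_structures$post))) {
    stop("head_structures with non-empty $pre and $post are required when bound heads are present")
  }
  if (has_discrete) {
    if (any(bound_heads$azimuth < 0 | bound_heads$azimuth >= 360)) {
      stop("bound head azimuth out of range [0, 360)")
    }
    oriented <- list(pre = orient_head(head_structures$pre),
                     post = orient_head(head_structures$post))
    roff <- if ("radial_offset" %in% names(bound_heads)) {
      ifelse(is.na(bound_heads$radial_offset), params$attach_radius,
             bound_heads$radial_offset)
    } else rep(params$attach_radius, nrow(bound_heads))
    placed <- do.call(rbind, lapply(seq_len(nrow(bound_heads)), function(i) {
      .place_head(oriented[[bound_heads$stroke[i]]],
                  bound_heads$azimuth[i], roff[i])
    }))
    grid <- grid + project_atoms(placed, spec)$grid
  }
  if (has_expected) {
    n_az <- if (is.null(expected_bound$n_azimuth)) 24L else expected_bound$n_azimuth
    pre_frac <- if (is.null(expected_bound$prestroke)) 0.5 else expected_bound$prestroke
    az <- 360 * (seq_len(n_az) - 1) / n_az
    for (st in c("pre", "post")) {
      w <- expected_bound$n_heads *
        (if (st == "pre") pre_frac else 1 - pre_frac) / n_az
      if (w <= 0) next
      ohead <- orient_head(head_structures[[st]])
      placed <- do.call(rbind, lapply(az, function(a) {
        .place_head(ohead, a, params$attach_radius)
      }))
      grid <- grid + w * project_atoms(placed, spec)$grid
    }
  }
  dens <- projected_density(spec, grid = grid, center = center)
  if (n_partner_heads > 0) {
    if (is.null(head_electrons)) {
      stop("head_electrons is required for the partner-head cloud")
    }
    dens <- add_ring(dens, make_ring(0, params$cloud_r_outer,
                                     n_partner_heads * head_electrons,
                                     "uniform"))
  }
  dens
}
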