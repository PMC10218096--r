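# Unit-cell assembly and equatorial diffraction: structure factors at the
# reciprocal hexagonal lattice points, temperature factors, Lorentz
# correction, symmetry superposition, normalisation, and the R-factor.
#
# The filament lattice is the crystallographic hexagonal cell (gamma = 120
# degrees): thick filaments at lattice points, thin filaments at the
# trigonal positions (2/3, 1/3) and (1/3, 2/3).  This is the convention
# under which the selection rule S_hk = S_10 * sqrt(h^2 + k^2 + hk), the
# phase angles theta_i and d_AM = (2/3) d_10 all hold simultaneously.

#' Sarcomere geometry
#'
#' @param SL sarcomere length, um.
#' @param d10 lattice spacing of the (1,0) planes, nm.
#' @param dAM thick-thin centre distance, nm; defaults to the hexagonal
#'   relation (2/3) d10 and must agree with it to 0.01 nm when supplied.
#' @param thick_length thick filament length, um.
#' @param La thin filament length, um.
#' @return object of class `sarcomere_geometry`.
#' @export
sarcomere_geometry <- function(SL = 2.862, d10 = 34.21, dAM = NULL,
                               thick_length = 1.58, La = 1.15) {
  stopifnot(SL > 0, d10 > 0, thick_length > 0, La > 0)
  derived <- 2 / 3 * d10
  if (is.null(dAM)) dAM <- derived
  if (abs(dAM - derived) > 0.01) {
    stop(sprintf("dAM (%.3f) inconsistent with (2/3) d10 (%.3f)", dAM, derived))
  }
  structure(list(SL = SL, d10 = d10, dAM = dAM, thick_length = thick_length,
                 La = La), class = "sarcomere_geometry")
}

#' Direct and reciprocal lattice vectors of the filament lattice
#'
#' `|a1| = |a2| = 2 d10 / sqrt(3)` at 120 degrees; `b1`, `b2` satisfy
#' `a_i . b_j = delta_ij` with `|b1| = |b2| = 1/d10 = S_10`.
#'
#' @param d10 lattice spacing, nm.
#' @return list with 2-vectors `a1`, `a2`, `b1`, `b2`.
#' @export
lattice_vectors <- function(d10) {
  a <- 2 * d10 / sqrt(3)
  a1 <- c(a, 0)
  a2 <- a * c(-0.5, sqrt(3) / 2)
  A <- rbind(a1, a2)
  B <- solve(A)                                 # columns satisfy A %*% B = I
  list(a1 = a1, a2 = a2, b1 = B[, 1], b2 = B[, 2])
}

#' Assemble the unit cell (one thick, two thin filaments)
#'
#' @param geometry a [sarcomere_geometry()].
#' @param thick thick filament [projected_density()] (placed at the origin).
#' @param thin1,thin2 thin filament densities (placed at fractional
#'   positions (2/3, 1/3) and (1/3, 2/3)).
#' @return object of class `unit_cell`.
#' @export
make_unit_cell <- function(geometry, thick, thin1, thin2) {
  stopifnot(inherits(geometry, "sarcomere_geometry"),
            inherits(thick, "projected_density"),
            inherits(thin1, "projected_density"),
            inherits(thin2, "projected_density"))
  lv <- lattice_vectors(geometry$d10)
  p1 <- 2 / 3 * lv$a1 + 1 / 3 * lv$a2
  p2 <- 1 / 3 * lv$a1 + 2 / 3 * lv$a2
  thick$center <- c(0, 0)
  thin1$center <- p1
  thin2$center <- p2
  structure(
    list(geometry = geometry, a1 = lv$a1, a2 = lv$a2, b1 = lv$b1, b2 = lv$b2,
         thick_density = thick, thin_densities = list(thin1, thin2)),
    class = "unit_cell"
  )
}

#' Phase angles of the two thin filaments for reflection (h, k)
#'
#' `theta1 = 2 pi (k/3 + 2h/3)`, `theta2 = 2 pi (2k/3 + h/3)`; their sum is
#' always a multiple of 2 pi.
#'
#' @param h,k integer Miller indices.
#' @return numeric vector `c(theta1, theta2)`, radians.
#' @export
phase_angles <- function(h, k) {
  c(2 * pi * (k / 3 + 2 * h / 3), 2 * pi * (2 * k / 3 + h / 3))
}

#' Debye-Waller temperature factor
#'
#' `D(S) = exp(-2 pi^2 S^2 Delta^2)` for root-mean-square isotropic filament
#' displacement `Delta`.
#'
#' @param S reciprocal radius, 1/nm.
#' @param delta rms displacement, nm (>= 0).
#' @return attenuation factor in (0, 1].
#' @export
temperature_factor <- function(S, delta) {
  if (any(delta < 0)) stop("delta must be non-negative")
  exp(-2 * pi^2 * S^2 * delta^2)
}

#' Pair of filament temperature factors
#' @param delta_M thick filament rms displacement, nm.
#' @param delta_A thin filament rms displacement, nm.
#' @return object of class `temperature_factors`.
#' @export
temperature_factors <- function(delta_M = 0, delta_A = 0) {
  if (delta_M < 0 || delta_A < 0) stop("displacements must be non-negative")
  structure(list(delta_M = delta_M, delta_A = delta_A),
            class = "temperature_factors")
}

# -- transforms --------------------------------------------------------------

# 2D Fourier transform of one ring at reciprocal radii S (1/nm).  Uniform
# rings are closed-form Bessel expressions; trapezoid rings use composite
# Simpson quadrature of 2 pi Int rho(r) J0(2 pi S r) r dr (the integrand is
# smooth and the small-angle arguments are mild, so a fixed 2000-panel rule
# is accurate to ~1e-12 relative and deterministic).
ring_transform <- function(ring, S) {
  if (ring$total_electrons == 0) return(numeric(length(S)))
  if (ring$profile == "uniform") {
    return(vapply(S, function(s) {
      if (s < 1e-12) return(ring$total_electrons)
      r2 <- ring$r_outer; r1 <- ring$r_inner
      ring$rho_in * (r2 * besselJ(2 * pi * s * r2, 1) -
                     r1 * besselJ(2 * pi * s * r1, 1)) / s
    }, numeric(1)))
  }
  n <- 2000L
  r <- seq(ring$r_inner, ring$r_outer, length.out = n + 1L)
  h <- (ring$r_outer - ring$r_inner) / n
  wts <- c(1, rep(c(4, 2), length.out = n - 1L), 1) * h / 3
  g <- ring_density(ring, r) * r
  vapply(S, function(s) {
    if (s < 1e-12) return(ring$total_electrons)
    2 * pi * sum(wts * g * besselJ(2 * pi * s * r, 0))
  }, numeric(1))
}

# cache of the non-zero pixels of a density grid
.grid_support <- function(density) {
  nz <- which(density$grid != 0)
  if (!length(nz)) return(list(x = numeric(), y = numeric(), w = numeric()))
  ax <- grid_axis(density$spec)
  n <- density$spec$n
  ix <- ((nz - 1L) %% n) + 1L
  iy <- ((nz - 1L) %/% n) + 1L
  list(x = ax[ix], y = ax[iy],
       w = density$grid[nz] * density$spec$pixel_size^2)
}

#' Fourier transform of a projected density at wave vectors
#'
#' Evaluates the filament's 2D transform about its own centre: analytic
#' Bessel forms for ring components plus a discrete sum over non-zero grid
#' pixels.
#'
#' @param density a [projected_density()].
#' @param Smat numeric matrix with two columns (Sx, Sy), 1/nm.
#' @return complex vector, one value per row of `Smat`.
#' @export
density_transform <- function(density, Smat) {
  Smat <- matrix(as.numeric(Smat), ncol = 2)
  Sabs <- sqrt(rowSums(Smat^2))
  Fv <- complex(real = numeric(nrow(Smat)))
  for (ring in density$rings) Fv <- Fv + ring_transform(ring, Sabs)
  sup <- .grid_support(density)
  if (length(sup$w)) {
    for (i in seq_len(nrow(Smat))) {
      ph <- 2 * pi * (sup$x * Smat[i, 1] + sup$y * Smat[i, 2])
      Fv[i] <- Fv[i] + sum(sup$w * complex(real = cos(ph), imaginary = sin(ph)))
    }
  }
  Fv
}

#' Structure factor of the unit cell at reflection (h, k)
#'
#' Combines the filament transforms with the thin-filament phase angles:
#' cosine mode (default, the classical real combination)
#' `F = F_thick + F_thin1 cos(theta1) + F_thin2 cos(theta2)`; complex mode
#' uses `exp(i theta)` phases instead, which matters only when the two thin
#' filaments differ.  Temperature factors, when supplied, attenuate the
#' thick and thin terms with their respective Deltas.
#'
#' @param cell a [make_unit_cell()].
#' @param h,k integer Miller indices.
#' @param mode `"cosine"` or `"complex"`.
#' @param tf optional [temperature_factors()].
#' @return complex structure factor.
#' @export
structure_factor <- function(cell, h, k, mode = c("cosine", "complex"),
                             tf = NULL) {
  mode <- match.arg(mode)
  Svec <- h * cell$b1 + k * cell$b2
  S <- sqrt(sum(Svec^2))
  Ft <- density_transform(cell$thick_density, matrix(Svec, 1))
  F1 <- density_transform(cell$thin_densities[[1]], matrix(Svec, 1))
  F2 <- density_transform(cell$thin_densities[[2]], matrix(Svec, 1))
  th <- phase_angles(h, k)
  dm <- da <- 1
  if (!is.null(tf)) {
    dm <- temperature_factor(S, tf$delta_M)
    da <- temperature_factor(S, tf$delta_A)
  }
  if (mode == "cosine") {
    dm * Ft + da * (F1 * cos(th[1]) + F2 * cos(th[2]))
  } else {
    dm * Ft + da * (F1 * exp(1i * th[1]) + F2 * exp(1i * th[2]))
  }
}

# -- reflection families -----------------------------------------------------

#' The eight observable equatorial reflection families
#' @return data.frame with columns `h`, `k`.
#' @export
equatorial_families <- function() {
  data.frame(h = c(1, 1, 2, 2, 3, 2, 3, 4), k = c(0, 1, 0, 1, 0, 2, 1, 0))
}

#' Enumerate the symmetry-equivalent members of a reflection family
#'
#' All integer `(h', k')` with `h'^2 + k'^2 + h'k' = h^2 + k^2 + hk`,
#' restricted to one member of each Friedel pair (half-plane `k > 0`, or
#' `k = 0` and `h > 0`), found by exhaustive scan over `|h'|, |k'| <= hmax`.
#'
#' @param h,k family representative.
#' @param hmax scan bound (8 covers all families up to L^2 = 16).
#' @return data.frame with columns `h`, `k`.
#' @export
family_members <- function(h, k, hmax = 8L) {
  Lsq <- h^2 + k^2 + h * k
  g <- expand.grid(h = -hmax:hmax, k = -hmax:hmax)
  g <- g[g$h^2 + g$k^2 + g$h * g$k == Lsq, ]
  g <- g[g$k > 0 | (g$k == 0 & g$h > 0), ]
  rownames(g) <- NULL
  g
}

#' Lorentz factor of a reflection family
#'
#' The radius in reciprocal space, `sqrt(h^2 + k^2 + hk)` (in units of
#' S_10).  `literal = TRUE` returns `h^2 + k^2 + hk` without the radical for
#' sensitivity analysis against the non-radical convention.
#'
#' @param h,k Miller indices.
#' @param literal use the non-radical form.
#' @return positive scalar.
#' @export
lorentz_factor <- function(h, k, literal = FALSE) {
  Lsq <- h^2 + k^2 + h * k
  if (Lsq == 0) stop("Lorentz factor undefined for (0,0)")
  if (literal) Lsq else sqrt(Lsq)
}

#' Predict the equatorial reflection pattern of a unit cell
#'
#' For each family, sums `|F|^2` (with per-filament temperature factors)
#' over one member of each Friedel pair of all symmetry-equivalent
#' reflections, divides by the Lorentz factor, and normalises the (1,0)
#' family to 100.  The phase (0 or pi, reported as `"+"`/`"-"`) is the sign
#' of the real part of the canonical representative's structure factor.
#'
#' @param cell a [make_unit_cell()].
#' @param tf a [temperature_factors()] (default: no disorder).
#' @param families data.frame of family representatives (must contain
#'   (1,0); must not contain (0,0)).
#' @param mode `"cosine"` or `"complex"` (see [structure_factor()]).
#' @param lorentz_literal use the non-radical Lorentz form.
#' @param normalize scale so I(1,0) = 100.
#' @return a `reflection_set` data.frame with columns `h`, `k`, `L`, `S`,
#'   `intensity`, `phase`, `n_members`; the raw (1,0) intensity is kept in
#'   the `normalization` attribute.
#' @export
equatorial_pattern <- function(cell, tf = temperature_factors(0, 0),
                               families = equatorial_families(),
                               mode = c("cosine", "complex"),
                               lorentz_literal = FALSE, normalize = TRUE) {
  mode <- match.arg(mode)
  if (!nrow(families)) stop("families must be non-empty")
  if (any(families$h == 0 & families$k == 0)) {
    stop("(0,0) is not a reflection family (Lorentz factor undefined)")
  }
  if (!any(families$h == 1 & families$k == 0)) {
    stop("families must include (1,0) for normalisation")
  }
  members <- lapply(seq_len(nrow(families)), function(i) {
    family_members(families$h[i], families$k[i])
  })
  allm <- do.call(rbind, members)
  Smat <- cbind(outer(allm$h, cell$b1[1]) + outer(allm$k, cell$b2[1]),
                outer(allm$h, cell$b1[2]) + outer(allm$k, cell$b2[2]))
  Sabs <- sqrt(rowSums(Smat^2))
  Ft <- density_transform(cell$thick_density, Smat)
  F1 <- density_transform(cell$thin_densities[[1]], Smat)
  F2 <- density_transform(cell$thin_densities[[2]], Smat)
  th1 <- 2 * pi * (allm$k / 3 + 2 * allm$h / 3)
  th2 <- 2 * pi * (2 * allm$k / 3 + allm$h / 3)
  dm <- temperature_factor(Sabs, tf$delta_M)
  da <- temperature_factor(Sabs, tf$delta_A)
  Fall <- if (mode == "cosine") {
    dm * Ft + da * (F1 * cos(th1) + F2 * cos(th2))
  } else {
    dm * Ft + da * (F1 * exp(1i * th1) + F2 * exp(1i * th2))
  }
  idx <- rep(seq_along(members), vapply(members, nrow, integer(1)))
  out <- families
  out$L <- sqrt(out$h^2 + out$k^2 + out$h * out$k)
  out$S <- out$L / cell$geometry$d10
  out$n_members <- as.integer(table(idx)[as.character(seq_along(members))])
  out$intensity <- vapply(seq_along(members), function(i) {
    sum(Mod(Fall[idx == i])^2) / lorentz_factor(families$h[i], families$k[i],
                                                lorentz_literal)
  }, numeric(1))
  out$phase <- vapply(seq_along(members), function(i) {
    mm <- members[[i]]
    pref <- which(mm$h == families$h[i] & mm$k == families$k[i])
    j <- if (length(pref)) pref[1] else 1L
    fre <- Re(Fall[idx == i][j])
    if (abs(fre) < 1e-9 * max(1, Mod(Fall[idx == i][j]))) NA_character_
    else if (fre > 0) "+" else "-"
  }, character(1))
  raw10 <- out$intensity[out$h == 1 & out$k == 0]
  if (normalize) {
    if (raw10 <= 0) stop("cannot normalise: (1,0) intensity is zero")
    out$intensity <- 100 * out$intensity / raw10
  }
  structure(out, class = c("reflection_set", "data.frame"),
            normalization = raw10)
}

#' Phase string of a reflection set
#' @param x a `reflection_set`.
#' @return a string such as `"++--++--"` (`?` for undefined phases).
#' @export
phase_string <- function(x) {
  paste(ifelse(is.na(x$phase), "?", x$phase), collapse = "")
}

#' Crystallographic R-factor between observed and predicted intensities
#'
#' `R = sum (Io - Ip)^2 / sum Io^2` over all families including (1,0), both
#' sets normalised to I(1,0) = 100.  The weighted variant divides each
#' squared residual (and each squared observation) by the squared observed
#' error; reflections with missing or zero error are dropped from the
#' weighted sums.
#'
#' @param observed,predicted `reflection_set`s over the same families.
#' @param weighted use the error-weighted form (requires an `error` column
#'   on `observed`).
#' @return non-negative scalar.
#' @export
r_factor <- function(observed, predicted, weighted = FALSE) {
  key_o <- paste(observed$h, observed$k)
  key_p <- paste(predicted$h, predicted$k)
  if (length(key_o) != length(key_p) || !setequal(key_o, key_p)) {
    stop("observed and predicted cover different reflection families")
  }
  Ip <- predicted$intensity[match(key_o, key_p)]
  Io <- observed$intensity
  if (!weighted) {
    sum((Io - Ip)^2) / sum(Io^2)
  } else {
    if (is.null(observed$error)) stop("weighted R requires observed errors")
    w <- 1 / observed$error^2
    ok <- is.finite(w)
    if (!any(ok)) stop("no finite weights for weighted R")
    sum(w[ok] * (Io[ok] - Ip[ok])^2) / sum(w[ok] * Io[ok]^2)
  }
}
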