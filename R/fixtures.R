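# Deterministic synthetic stand-in structures.
#
# Real atomic models of the sarcomere components (an S2 coiled-coil fragment,
# a thin-filament repeat with tropomyosin/troponin, pre- and post-powerstroke
# myosin heads) cannot be bundled, so these generators emit stand-ins whose
# residue counts, linear densities and overall envelopes match the real
# components.  They are fully deterministic (no RNG): every residue is
# rendered as a fixed eight-heavy-atom cluster (5 C, 1 N, 2 O = 53 electrons,
# close to the ~54 electrons of an average hydrogen-less residue), so electron
# ratios between components are set purely by residue counts.

.residue_cluster <- local({
  # fixed local offsets (nm) roughly filling a 0.25 nm-radius blob
  off <- rbind(
    c(0.00, 0.00, 0.00), c(0.15, 0.05, -0.05), c(-0.12, 0.10, 0.06),
    c(0.05, -0.14, 0.08), c(-0.06, -0.08, -0.12), c(0.10, 0.12, 0.10),
    c(-0.15, -0.02, 0.12), c(0.02, 0.15, -0.12)
  )
  list(elements = c("C", "C", "C", "C", "C", "N", "O", "O"), offsets = off)
})

# expand residue centres (matrix n x 3) into an atom data.frame
.residues_to_atoms <- function(centers, chain = "A") {
  n <- nrow(centers)
  cl <- .residue_cluster
  m <- length(cl$elements)
  # deterministic per-residue rotation of the cluster about z (golden angle)
  ang <- (seq_len(n) - 1) * 2.399963
  ca <- cos(ang); sa <- sin(ang)
  ox <- rep(cl$offsets[, 1], times = n)
  oy <- rep(cl$offsets[, 2], times = n)
  oz <- rep(cl$offsets[, 3], times = n)
  car <- rep(ca, each = m); sar <- rep(sa, each = m)
  data.frame(
    element = rep(cl$elements, times = n),
    x = rep(centers[, 1], each = m) + ox * car - oy * sar,
    y = rep(centers[, 2], each = m) + ox * sar + oy * car,
    z = rep(centers[, 3], each = m) + oz,
    chain = rep(chain, length.out = n * m),
    stringsAsFactors = FALSE
  )
}

.finish_atoms <- function(atoms) {
  atoms$electron_count <- atomic_number(atoms$element)
  atoms$vdw_radius <- vdw_radius(atoms$element)
  atoms
}

# deterministic quasi-uniform points in a unit ball (Fibonacci sphere shells)
.ball_points <- function(n) {
  i <- seq_len(n)
  phi <- 2.399963 * i
  cz <- 1 - 2 * (i - 0.5) / n
  sz <- sqrt(pmax(1 - cz^2, 0))
  r <- (i / n)^(1 / 3)
  cbind(r * sz * cos(phi), r * sz * sin(phi), r * cz)
}

#' Synthetic two-chain coiled-coil (S2 / LMM surrogate)
#'
#' A straight two-stranded alpha-helical coiled coil along z with the
#' canonical 0.1485 nm rise per residue, mimicking the myosin S2 fragment
#' used as the rod-density source.  126 residues per chain give an axial
#' extent of ~18.7 nm.
#'
#' @param n_res residues per chain.
#' @param rise axial rise per residue, nm.
#' @param radius helix-axis offset of each chain from the coil axis, nm.
#' @return atom data.frame (chains A and B).
#' @export
synthetic_s2_structure <- function(n_res = 126, rise = 0.1485, radius = 0.5) {
  one_chain <- function(phase, chain) {
    i <- seq_len(n_res) - 1
    ang <- phase + i * (4 * pi / 180)          # slow supercoil twist
    centers <- cbind(radius * cos(ang), radius * sin(ang), i * rise)
    .residues_to_atoms(centers, chain)
  }
  .finish_atoms(rbind(one_chain(0, "A"), one_chain(pi, "B")))
}

#' Synthetic thin-filament repeat (actin + tropomyosin + troponin)
#'
#' One 38.3 nm axial repeat of the thin filament: 14 actin monomers on the
#' single-start genetic helix (rise 38.3/14 nm, twist -166.7 deg), two
#' tropomyosin coiled coils (chains T/U and V/W) following the long-pitch
#' grooves, and two troponin complexes (chains X, Y).  Residue counts follow
#' the real proteins (375 per actin, 284 per Tm chain, 630 per Tn complex).
#'
#' @param tn_spacing axial repeat, nm.
#' @param monomers actin monomers per repeat.
#' @param actin_radius radius of actin monomer centres, nm (1.7 nm, the
#'   subunit centre-of-mass radius of filament models of F-actin).
#' @param tm_radius radius of the tropomyosin strands, nm.
#' @return atom data.frame; tropomyosin sits on chains `c("T","U","V","W")`.
#' @export
synthetic_thin_repeat <- function(tn_spacing = 38.3, monomers = 14,
                                  actin_radius = 1.7, tm_radius = 3.9) {
  rise <- tn_spacing / monomers
  twist <- -166.7 * pi / 180
  actin <- do.call(rbind, lapply(seq_len(monomers) - 1, function(m) {
    ctr <- c(actin_radius * cos(m * twist), actin_radius * sin(m * twist),
             m * rise + rise / 2)
    pts <- .ball_points(375) * 1.9
    .residues_to_atoms(sweep(pts, 2, ctr, `+`), "A")
  }))
  # long-pitch strand azimuth drifts by the repeat rotation over one repeat
  drift <- 27.7 * pi / 180 / tn_spacing
  tm_chain <- function(az0, pair_off, chain) {
    zz <- seq(0, tn_spacing, length.out = 284)
    ang <- az0 + pair_off + zz * drift
    centers <- cbind(tm_radius * cos(ang), tm_radius * sin(ang), zz)
    .residues_to_atoms(centers, chain)
  }
  tm <- rbind(
    tm_chain(pi / 2, +0.10, "T"), tm_chain(pi / 2, -0.10, "U"),
    tm_chain(-pi / 2, +0.10, "V"), tm_chain(-pi / 2, -0.10, "W")
  )
  tn_blob <- function(az, chain) {
    ctr <- c(5.0 * cos(az), 5.0 * sin(az), tn_spacing / 2)
    pts <- .ball_points(630) * 1.8
    .residues_to_atoms(sweep(pts, 2, ctr, `+`), chain)
  }
  tn <- rbind(tn_blob(pi / 2 + 0.5, "X"), tn_blob(-pi / 2 + 0.5, "Y"))
  .finish_atoms(rbind(actin, tm, tn))
}

#' Synthetic myosin head (S1 + light chains)
#'
#' An ellipsoidal ~700-residue motor domain with its actin-binding face at
#' x = 0, plus a ~460-residue lever/light-chain arm.  In the post-powerstroke
#' state the lever continues roughly radially (long in-plane projection); in
#' the pre-powerstroke state it is strongly tilted toward the filament axis,
#' shortening the radial projection, as the lever swing does.
#'
#' @param stroke `"post"` or `"pre"`.
#' @return atom data.frame with the head long axis along +x and its binding
#'   end at x = 0.
#' @export
synthetic_myosin_head <- function(stroke = c("post", "pre")) {
  stroke <- match.arg(stroke)
  motor <- .ball_points(700)
  motor <- cbind(motor[, 1] * 3.2 + 3.2, motor[, 2] * 2.2, motor[, 3] * 2.2)
  # lever axis tilt out of the projection plane: rigor-like post-stroke
  # levers sit ~45 deg to the filament axis, primed pre-stroke levers are
  # swung further toward it, shortening the in-plane radial reach
  dirv <- if (stroke == "post") c(cos(45 * pi / 180), 0, sin(45 * pi / 180))
          else c(cos(75 * pi / 180), 0, sin(75 * pi / 180))
  t <- seq(0, 9, length.out = 460)
  wob <- 0.8 * cos(t * 4)
  lever <- cbind(6.0 + dirv[1] * t, wob * 0.5, dirv[3] * t + 0.8 * sin(t * 4) * 0.5)
  atoms <- rbind(.residues_to_atoms(motor, "A"), .residues_to_atoms(lever, "A"))
  .finish_atoms(atoms)
}

#' Toy structure: a planar ring of carbons
#'
#' Minimal fixture for exercising the PDB and projection paths.
#'
#' @param n number of atoms.
#' @param radius ring radius, nm.
#' @return atom data.frame.
#' @export
synthetic_carbon_ring <- function(n = 12, radius = 1) {
  ang <- 2 * pi * (seq_len(n) - 1) / n
  .finish_atoms(data.frame(
    element = "C",
    x = radius * cos(ang), y = radius * sin(ang), z = numeric(n),
    chain = "A", stringsAsFactors = FALSE
  ))
}
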