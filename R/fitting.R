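# Exhaustive grid-search fitting on the crystallographic R-factor: the two
# filament temperature factors (Delta_M, Delta_A), and the parked-state
# head-ring geometry (radial centre, thickness).  No stochastic or gradient
# optimisers: every node of the grid is evaluated, so the surfaces are
# exhaustive and runs are bit-reproducible.

#' Grid specification for the exhaustive searches
#'
#' Each range is `(lo, hi, step)`.  Defaults: Delta grids span 0.5-5.0 nm in
#' 0.01 nm steps ("all reasonable values on a fine grid"); the parked-state
#' ring grids span the physically realistic windows 12.5 +- 1 nm (radial
#' centre of mass) and 4-6 nm (ring thickness) in 0.05 nm steps.
#'
#' @param delta_M_range,delta_A_range,ps_center_range,ps_thickness_range
#'   numeric triples `c(lo, hi, step)`.
#' @return object of class `grid_search_spec`.
#' @export
grid_search_spec <- function(delta_M_range = c(0.5, 5.0, 0.01),
                             delta_A_range = c(0.5, 5.0, 0.01),
                             ps_center_range = c(11.5, 13.5, 0.05),
                             ps_thickness_range = c(4.0, 6.0, 0.05)) {
  chk <- function(r, nm) {
    if (length(r) != 3 || r[1] > r[2] || r[3] <= 0) {
      stop("invalid range for ", nm, ": need (lo <= hi, step > 0)")
    }
    r
  }
  structure(list(
    delta_M_range = chk(delta_M_range, "delta_M"),
    delta_A_range = chk(delta_A_range, "delta_A"),
    ps_center_range = chk(ps_center_range, "ps_center"),
    ps_thickness_range = chk(ps_thickness_range, "ps_thickness")
  ), class = "grid_search_spec")
}

.grid_axis_vals <- function(r) seq(r[1], r[2], by = r[3])

#' Fit the filament temperature factors by exhaustive grid search
#'
#' Evaluates the predicted pattern and R-factor at every (Delta_M, Delta_A)
#' node.  The filament structure factors do not depend on the Deltas, so
#' they are precomputed once per family member and only the Debye-Waller
#' attenuations vary across the grid; the search is exact and deterministic.
#' Ties in R are broken toward smaller (Delta_M, Delta_A), lexicographically.
#'
#' @param cell a [make_unit_cell()] (the model densities are fixed).
#' @param observed a `reflection_set` normalised to I(1,0) = 100, with an
#'   optional `error` column for the reported weighted R.
#' @param spec a [grid_search_spec()].
#' @param mode structure-factor combination mode (see [structure_factor()]).
#' @param lorentz_literal use the non-radical Lorentz form.
#' @return object of class `fit_result`: `best_params`, `best_R`,
#'   `R_surface` (matrix Delta_M x Delta_A with axes in `dimnames`),
#'   `predicted` at the optimum, `weighted_R` (when errors are available),
#'   and `ties` (number of grid nodes attaining the minimum).
#' @export
fit_temperature_factors <- function(cell, observed, spec = grid_search_spec(),
                                    mode = c("cosine", "complex"),
                                    lorentz_literal = FALSE) {
  mode <- match.arg(mode)
  dm_ax <- .grid_axis_vals(spec$delta_M_range)
  da_ax <- .grid_axis_vals(spec$delta_A_range)
  if (!length(dm_ax) || !length(da_ax)) stop("empty search grid")
  fams <- observed[, c("h", "k")]
  if (!any(fams$h == 1 & fams$k == 0)) stop("observed must include (1,0)")

  members <- lapply(seq_len(nrow(fams)), function(i) {
    family_members(fams$h[i], fams$k[i])
  })
  allm <- do.call(rbind, members)
  idx <- rep(seq_along(members), vapply(members, nrow, integer(1)))
  Smat <- cbind(allm$h * cell$b1[1] + allm$k * cell$b2[1],
                allm$h * cell$b1[2] + allm$k * cell$b2[2])
  A <- density_transform(cell$thick_density, Smat)
  F1 <- density_transform(cell$thin_densities[[1]], Smat)
  F2 <- density_transform(cell$thin_densities[[2]], Smat)
  th1 <- 2 * pi * (allm$k / 3 + 2 * allm$h / 3)
  th2 <- 2 * pi * (2 * allm$k / 3 + allm$h / 3)
  B <- if (mode == "cosine") F1 * cos(th1) + F2 * cos(th2)
       else F1 * exp(1i * th1) + F2 * exp(1i * th2)
  # per-family quadratic-form coefficients of I = |dm A + da B|^2
  fidx <- factor(idx, levels = seq_along(members))
  aa <- vapply(split(Mod(A)^2, fidx), sum, numeric(1))
  cc <- vapply(split(Mod(B)^2, fidx), sum, numeric(1))
  xx <- vapply(split(Re(A * Conj(B)), fidx), sum, numeric(1))
  Lf <- vapply(seq_len(nrow(fams)), function(i) {
    lorentz_factor(fams$h[i], fams$k[i], lorentz_literal)
  }, numeric(1))
  Sfam <- vapply(split(sqrt(rowSums(Smat^2)), fidx), function(s) s[1], numeric(1))

  DM <- vapply(Sfam, function(s) temperature_factor(s, dm_ax), numeric(length(dm_ax)))
  DA <- vapply(Sfam, function(s) temperature_factor(s, da_ax), numeric(length(da_ax)))
  DM <- matrix(DM, nrow = length(dm_ax))
  DA <- matrix(DA, nrow = length(da_ax))

  nf <- nrow(fams)
  If <- vector("list", nf)
  for (f in seq_len(nf)) {
    If[[f]] <- (aa[f] * outer(DM[, f]^2, rep(1, length(da_ax))) +
                2 * xx[f] * outer(DM[, f], DA[, f]) +
                cc[f] * outer(rep(1, length(dm_ax)), DA[, f]^2)) / Lf[f]
  }
  i10 <- which(fams$h == 1 & fams$k == 0)
  num <- 0
  for (f in seq_len(nf)) {
    num <- num + (observed$intensity[f] - 100 * If[[f]] / If[[i10]])^2
  }
  Rsurf <- num / sum(observed$intensity^2)
  dimnames(Rsurf) <- list(delta_M = format(dm_ax), delta_A = format(da_ax))

  best <- min(Rsurf)
  hits <- which(Rsurf <= best, arr.ind = TRUE)
  ord <- order(dm_ax[hits[, 1]], da_ax[hits[, 2]])
  pick <- hits[ord[1], ]
  tf <- temperature_factors(dm_ax[pick[1]], da_ax[pick[2]])
  predicted <- equatorial_pattern(cell, tf, fams, mode = mode,
                                  lorentz_literal = lorentz_literal)
  wR <- if (!is.null(observed$error)) {
    tryCatch(r_factor(observed, predicted, weighted = TRUE),
             error = function(e) NA_real_)
  } else NA_real_
  structure(list(
    best_params = c(delta_M = unname(dm_ax[pick[1]]),
                    delta_A = unname(da_ax[pick[2]])),
    best_R = best, R_surface = Rsurf,
    delta_M_axis = dm_ax, delta_A_axis = da_ax,
    predicted = predicted, weighted_R = wR, ties = nrow(hits)
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("grid-search fit:", paste(names(x$best_params), "=",
                                signif(x$best_params, 4), collapse = ", "),
      sprintf("| R = %.3g", x$best_R),
      if (isTRUE(x$insensitive)) "(surface flat: insensitive)" else "", "\n")
  invisible(x)
}

#' Fit the parked-state head-ring geometry by exhaustive grid search
#'
#' Scans the (radial centre, thickness) grid; at each node the PSH ring is
#' rebuilt as `[center - thickness/2, center + thickness/2]`, the pattern is
#' recomputed through `build_pattern`, and the R-factor against `observed`
#' is recorded.  Nodes whose ring would extend below `s2_r_start` are marked
#' infeasible (NA in the surface) and excluded from the argmin.  The S2-PS
#' outer radius tied to the ring inner edge is reported with the optimum.
#' When the whole feasible surface varies by less than a factor of two of
#' its minimum, the fit is flagged `insensitive`.
#'
#' @param build_pattern function `(ps_center, ps_thickness) -> reflection
#'   set` embodying the parameterised model (see
#'   [make_ps_pattern_builder()]).
#' @param observed a `reflection_set` normalised to I(1,0) = 100.
#' @param spec a [grid_search_spec()].
#' @param s2_r_start lower feasibility bound for the ring inner edge, nm.
#' @return a `fit_result` with `best_params` `(ps_center, ps_thickness,
#'   s2_r_outer_ps)` and the R surface (centre x thickness).
#' @export
fit_ps_ring <- function(build_pattern, observed, spec = grid_search_spec(),
                        s2_r_start = 6.0) {
  ctr_ax <- .grid_axis_vals(spec$ps_center_range)
  thk_ax <- .grid_axis_vals(spec$ps_thickness_range)
  if (!length(ctr_ax) || !length(thk_ax)) stop("empty search grid")
  Rsurf <- matrix(NA_real_, length(ctr_ax), length(thk_ax),
                  dimnames = list(ps_center = format(ctr_ax),
                                  ps_thickness = format(thk_ax)))
  for (i in seq_along(ctr_ax)) {
    for (j in seq_along(thk_ax)) {
      inner <- ctr_ax[i] - thk_ax[j] / 2
      if (inner < s2_r_start) next              # infeasible node
      pred <- build_pattern(ctr_ax[i], thk_ax[j])
      Rsurf[i, j] <- r_factor(observed, pred)
    }
  }
  if (all(is.na(Rsurf))) stop("no feasible node in the parked-state ring grid")
  best <- min(Rsurf, na.rm = TRUE)
  hits <- which(!is.na(Rsurf) & Rsurf <= best, arr.ind = TRUE)
  ord <- order(ctr_ax[hits[, 1]], thk_ax[hits[, 2]])
  pick <- hits[ord[1], ]
  ctr <- ctr_ax[pick[1]]; thk <- thk_ax[pick[2]]
  feas <- Rsurf[!is.na(Rsurf)]
  structure(list(
    best_params = c(ps_center = unname(ctr), ps_thickness = unname(thk),
                    s2_r_outer_ps = unname(ctr - thk / 2)),
    best_R = best, R_surface = Rsurf,
    ps_center_axis = ctr_ax, ps_thickness_axis = thk_ax,
    predicted = build_pattern(ctr, thk),
    insensitive = max(feas) < 2 * min(feas),
    ties = nrow(hits)
  ), class = "fit_result")
}

#' Builder closure for the parked-state ring search
#'
#' Returns `function(ps_center, ps_thickness) -> reflection_set` that
#' rebuilds only the thick filament rings (the PSH ring at the requested
#' geometry, with the S2-PS ring outer radius coupled to the PSH inner
#' edge) while reusing the fixed thin filament transforms, as the
#' parked-state refinement holds the populations and thin filaments fixed.
#'
#' @param cell a [make_unit_cell()] for the baseline model.
#' @param params the [thick_params()] used to build the thick density.
#' @param pop the [head_state_population()] used for the budget.
#' @param budget the [compute_mass_budget()] of the model.
#' @param tf [temperature_factors()] applied inside the returned builder.
#' @param mode structure-factor mode.
#' @param couple_s2 couple `s2_r_outer_ps` to the PSH inner edge (default
#'   TRUE).
#' @return a function `(ps_center, ps_thickness)` returning a
#'   `reflection_set`.
#' @export
make_ps_pattern_builder <- function(cell, params, pop, budget,
                                    tf = temperature_factors(0, 0),
                                    mode = "cosine", couple_s2 = TRUE,
                                    families = equatorial_families()) {
  # Everything except the PSH ring and (when coupled) the S2-PS ring is
  # fixed across the scan, so the thin transforms, the thick grid/backbone
  # transform and the static thick rings are evaluated once up front.
  members <- lapply(seq_len(nrow(families)), function(i) {
    family_members(families$h[i], families$k[i])
  })
  allm <- do.call(rbind, members)
  idx <- rep(seq_along(members), vapply(members, nrow, integer(1)))
  Smat <- cbind(allm$h * cell$b1[1] + allm$k * cell$b2[1],
                allm$h * cell$b1[2] + allm$k * cell$b2[2])
  Sabs <- sqrt(rowSums(Smat^2))
  uS <- sort(unique(round(Sabs, 12)))
  iS <- match(round(Sabs, 12), uS)
  th1 <- 2 * pi * (allm$k / 3 + 2 * allm$h / 3)
  th2 <- 2 * pi * (2 * allm$k / 3 + allm$h / 3)
  F1 <- density_transform(cell$thin_densities[[1]], Smat)
  F2 <- density_transform(cell$thin_densities[[2]], Smat)
  thin_part <- if (mode == "cosine") F1 * cos(th1) + F2 * cos(th2)
               else F1 * exp(1i * th1) + F2 * exp(1i * th2)
  dm <- temperature_factor(Sabs, tf$delta_M)
  da <- temperature_factor(Sabs, tf$delta_A)
  # static thick pieces: backbone grid plus every ring except PSH and S2-PS
  static_thick <- projected_density(cell$thick_density$spec,
                                    grid = cell$thick_density$grid)
  base_static <- density_transform(static_thick, Smat)
  for (ring in cell$thick_density$rings) {
    same_ps <- isTRUE(all.equal(c(ring$r_inner, ring$r_outer),
                                c(params$ps_r_inner, params$ps_r_outer)))
    same_s2 <- couple_s2 &&
      isTRUE(all.equal(c(ring$r_inner, ring$r_outer),
                       c(params$s2_r_start, params$s2_r_outer_ps)))
    if (!same_ps && !same_s2) base_static <- base_static + ring_transform(ring, Sabs)
  }
  Lf <- vapply(seq_len(nrow(families)), function(i) {
    lorentz_factor(families$h[i], families$k[i])
  }, numeric(1))
  out_template <- families
  out_template$L <- sqrt(families$h^2 + families$k^2 + families$h * families$k)
  out_template$S <- out_template$L / cell$geometry$d10
  out_template$n_members <- as.integer(table(factor(idx, seq_along(members))))

  function(ps_center, ps_thickness) {
    inner <- ps_center - ps_thickness / 2
    psh <- make_ring(inner, ps_center + ps_thickness / 2, budget$heads_ps,
                     "trapezoid")
    Ft <- base_static + ring_transform(psh, uS)[iS]
    if (couple_s2) {
      s2ps <- make_ring(params$s2_r_start, inner, budget$s2_ps, "trapezoid")
      Ft <- Ft + ring_transform(s2ps, uS)[iS]
    }
    Fall <- dm * Ft + da * thin_part
    inten <- vapply(seq_along(members), function(i) {
      sum(Mod(Fall[idx == i])^2) / Lf[i]
    }, numeric(1))
    out <- out_template
    raw10 <- inten[families$h == 1 & families$k == 0]
    out$intensity <- 100 * inten / raw10
    out$phase <- ifelse(vapply(seq_along(members), function(i) {
      Re(Fall[idx == i][1]) > 0
    }, logical(1)), "+", "-")
    structure(out, class = c("reflection_set", "data.frame"),
              normalization = raw10)
  }
}
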