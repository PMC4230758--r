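#' Beam line model for the scanned carbon pencil beam
#'
#' Machine-level constants of the simplified dose engine: lateral
#' Gaussian sigma (from the printed 80-20% penumbra), iso-energy layer
#' pitch in WEPL, lateral spot pitch, and the analytic pristine-peak
#' depth profile (proximal plateau rising to the peak, sharp distal
#' Gaussian falloff).
#'
#' @param penumbra_8020_mm lateral 80-20% penumbra, mm (default 5.0).
#' @param layer_spacing_wepl_mm layer pitch in WEPL, mm (default 3.0).
#' @param spot_spacing_lat_mm lateral spot pitch, mm (default 2.0).
#' @param depth_tail proximal plateau level relative to the peak.
#' @param depth_rise_sigma_mm width of the rise to the peak, mm WEPL.
#' @param depth_fall_sigma_mm distal falloff sigma, mm WEPL.
#' @param n_energies number of synchrotron energies (metadata only).
#' @return object of class `beam_line_model` (includes `sigma_lat_mm`).
#' @export
beam_line_model <- function(penumbra_8020_mm = 5.0,
                            layer_spacing_wepl_mm = 3.0,
                            spot_spacing_lat_mm = 2.0,
                            depth_tail = 0.35,
                            depth_rise_sigma_mm = 3.0,
                            depth_fall_sigma_mm = 1.5,
                            n_energies = 11L) {
  structure(list(sigma_lat_mm = penumbra_to_sigma(penumbra_8020_mm),
                 penumbra_8020_mm = penumbra_8020_mm,
                 layer_spacing_wepl_mm = layer_spacing_wepl_mm,
                 spot_spacing_lat_mm = spot_spacing_lat_mm,
                 depth_tail = depth_tail,
                 depth_rise_sigma_mm = depth_rise_sigma_mm,
                 depth_fall_sigma_mm = depth_fall_sigma_mm,
                 n_energies = n_energies),
            class = "beam_line_model")
}

#' Convert an 80-20% penumbra to a Gaussian sigma
#'
#' The 80-20% distance of a Gaussian-blurred edge is
#' (qnorm(0.8) - qnorm(0.2)) * sigma = 1.6832 * sigma.
#'
#' @param p8020_mm 80-20% lateral penumbra, mm (> 0).
#' @return Gaussian sigma in mm.
#' @export
penumbra_to_sigma <- function(p8020_mm) {
  stopifnot(p8020_mm > 0)
  p8020_mm / (2 * qnorm(0.8))
}

#' @rdname penumbra_to_sigma
#' @param sigma_mm Gaussian sigma, mm (> 0).
#' @export
sigma_to_penumbra <- function(sigma_mm) {
  stopifnot(sigma_mm > 0)
  sigma_mm * 2 * qnorm(0.8)
}

#' Relative depth-dose of a pristine layer
#'
#' Peak-normalized dose vs (WEPL - layer range): for x <= 0 a plateau
#' `depth_tail` rising as a Gaussian of width `depth_rise_sigma_mm` to 1
#' at x = 0; for x > 0 a Gaussian falloff of sigma
#' `depth_fall_sigma_mm`.
#'
#' @param x_mm WEPL minus layer range, mm (vector).
#' @param model a [beam_line_model()].
#' @return relative dose values.
#' @export
depth_profile <- function(x_mm, model = beam_line_model()) {
  cpp_depth_profile(as.numeric(x_mm), model$depth_tail,
                    model$depth_rise_sigma_mm, model$depth_fall_sigma_mm)
}

#' Place spots on an FTV (unit weights)
#'
#' Iso-energy layers at the WEPL pitch span from the maximum distal
#' bound down to (minimum proximal - one pitch); each layer covers, on
#' the lateral raster, every ray whose proximal-distal interval contains
#' the layer range, plus one raster ring of margin.  Layers covering no
#' ray are dropped.  Spots are ordered on a serpentine (boustrophedon)
#' path per layer.
#'
#' @param ftv a [build_ftv()] result.
#' @param model a [beam_line_model()].
#' @return a `spot_map`: data frame with columns `layer`,
#'   `range_wepl_mm`, `u_mm`, `v_mm`, `weight`, `path_order`; layers
#'   ordered distal to proximal.
#' @export
place_spots <- function(ftv, model = beam_line_model()) {
  rays <- ftv$rays
  if (nrow(rays) == 0) stop("FTV is empty")
  pitch <- model$layer_spacing_wepl_mm
  sp <- model$spot_spacing_lat_mm
  dist_max <- max(rays$distal_wepl)
  prox_min <- min(rays$proximal_wepl)
  nlay <- floor((dist_max - (prox_min - pitch)) / pitch + 1e-9)
  ranges <- dist_max - (0:nlay) * pitch

  iu_all <- round(rays$u / sp)
  iv_all <- round(rays$v / sp)
  out <- NULL
  layer_id <- 0L
  for (rg in ranges) {
    covered <- rays$proximal_wepl <= rg + 1e-9 &
      rays$distal_wepl >= rg - 1e-9
    if (!any(covered)) next
    cells <- unique(cbind(iu_all[covered], iv_all[covered]))
    # one raster ring of margin (8-neighborhood dilation)
    ring <- expand.grid(du = -1:1, dv = -1:1)
    grown <- unique(do.call(rbind, lapply(seq_len(nrow(ring)), function(r)
      cbind(cells[, 1] + ring$du[r], cells[, 2] + ring$dv[r]))))
    layer_id <- layer_id + 1L
    # serpentine: rows in v order, u direction alternating per row
    o <- order(grown[, 2], grown[, 1])
    g <- grown[o, , drop = FALSE]
    vs <- unique(g[, 2])
    path <- do.call(rbind, lapply(seq_along(vs), function(ri) {
      row <- g[g[, 2] == vs[ri], , drop = FALSE]
      if (ri %% 2 == 0) row[rev(seq_len(nrow(row))), , drop = FALSE] else row
    }))
    out <- rbind(out, data.frame(layer = layer_id, range_wepl_mm = rg,
                                 u_mm = path[, 1] * sp, v_mm = path[, 2] * sp,
                                 weight = 1,
                                 path_order = seq_len(nrow(path))))
  }
  out$spot_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "model") <- model
  attr(out, "beam") <- ftv$beam
  class(out) <- c("spot_map", class(out))
  out
}

#' @exportS3Method base::print
print.spot_map <- function(x, ...) {
  cat("spot_map:", nrow(x), "spots in", length(unique(x$layer)),
      "layers; ranges", signif(min(x$range_wepl_mm), 4), "-",
      signif(max(x$range_wepl_mm), 4), "mm WEPL\n")
  invisible(x)
}

spot_matrix <- function(spots, weights = spots$weight) {
  cbind(spots$u_mm, spots$v_mm, spots$range_wepl_mm, weights)
}

#' Per-field dose geometry cache
#'
#' Precomputes, for one phantom and beam port, the per-voxel
#' beam's-eye-view lateral coordinates and the per-phase WEPL grids that
#' the dose engine needs.  Computing this once per field avoids
#' re-tracing rays for every dose evaluation.
#'
#' @param phantom a `phantom4d`.
#' @param beam a [beam_port()].
#' @param phases phases for which WEPL grids are built (default all).
#' @return list with `u`, `v` (per-voxel vectors) and `wepl` (named list
#'   of per-phase WEPL vectors).
#' @export
field_geometry <- function(phantom, beam, phases = phantom$phases) {
  geom <- phantom$geom
  pts <- grid_centers(geom)
  uv <- bev_coords(pts, beam)
  wepl <- lapply(phantom$density[phases], function(dens)
    cpp_wepl_points(as.numeric(dens), geom$dim, geom$spacing, geom$origin,
                    beam$dir, pts))
  list(u = uv[, "u"], v = uv[, "v"], wepl = wepl, geom = geom, beam = beam)
}

#' Dose of a spot map on one phase geometry
#'
#' Pencil-beam superposition: each spot contributes
#' weight * exp(-r_lat^2 / (2 sigma^2)) * depth_profile(WEPL - range),
#' with lateral distance in beam's-eye view and WEPL evaluated on the
#' phase's density.  Linear in the weights.
#'
#' @param spots a `spot_map` (or data frame with the same columns).
#' @param fgeom a [field_geometry()].
#' @param phase phase label (selects the WEPL grid).
#' @param weights optional replacement spot weights.
#' @param model a [beam_line_model()] (defaults to the spot map's).
#' @return dose array on the phantom grid at that phase.
#' @export
spot_dose <- function(spots, fgeom, phase, weights = spots$weight,
                      model = attr(spots, "model")) {
  if (is.null(model)) model <- beam_line_model()
  d <- cpp_spot_dose(fgeom$wepl[[phase]], fgeom$u, fgeom$v,
                     spot_matrix(spots, weights), model$sigma_lat_mm,
                     model$depth_tail, model$depth_rise_sigma_mm,
                     model$depth_fall_sigma_mm, 5.0)
  grid_array(d, fgeom$geom)
}

#' Sparse dose-influence matrix for target voxels
#'
#' Unit-weight dose of every spot at a subset of voxels, as a sparse
#' matrix (voxels x spots), for spot-weight optimization.
#'
#' @param spots a `spot_map`.
#' @param fgeom a [field_geometry()].
#' @param voxel_idx linear indices of the target voxels.
#' @param phase phase whose WEPL grid is used (reference by default).
#' @param model a [beam_line_model()].
#' @return `dgCMatrix` of dimension length(voxel_idx) x nrow(spots).
#' @export
influence_matrix <- function(spots, fgeom, voxel_idx, phase = "T50",
                             model = attr(spots, "model")) {
  if (is.null(model)) model <- beam_line_model()
  tr <- cpp_influence(fgeom$wepl[[phase]][voxel_idx], fgeom$u[voxel_idx],
                      fgeom$v[voxel_idx],
                      spot_matrix(spots)[, 1:3, drop = FALSE],
                      model$sigma_lat_mm, model$depth_tail,
                      model$depth_rise_sigma_mm, model$depth_fall_sigma_mm,
                      5.0, 1e-9)
  Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                       dims = c(length(voxel_idx), nrow(spots)))
}

#' Single-uniform-field spot-weight optimization
#'
#' Finds nonnegative spot weights minimizing the squared deviation of
#' the dose from the prescription over the FTV voxels (deterministic
#' NNLS-style cyclic coordinate descent on the sparse dose-influence
#' matrix, monotone in the objective), then rescales globally so that
#' the minimum FTV dose equals 0.95 x prescription ("enclosed at
#' minimum by the 95% isodose line").
#'
#' @param spots a `spot_map` with unit (or any initial) weights.
#' @param ftv the [build_ftv()] result the spots were placed on.
#' @param fgeom the field's [field_geometry()].
#' @param prescription_gyrbe prescribed dose, Gy(RBE) (> 0).
#' @param tol convergence tolerance: the solver stops once the residual
#'   norm improves by less than `tol` (relative) over a 10-sweep
#'   window, i.e. the residual has plateaued at its least-squares floor
#'   (a perfectly flat FTV dose is not attainable, so the floor is
#'   nonzero and a fixed residual target would never be met).
#' @param maxit sweep cap; reaching it before the plateau is an error
#'   reporting the residual.
#' @return the spot map with optimized `weight`; attributes
#'   `optimization` (iterations, residual, ftv dose range) are attached.
#' @export
optimize_weights <- function(spots, ftv, fgeom, prescription_gyrbe,
                             tol = 1e-4, maxit = 5000L) {
  stopifnot(prescription_gyrbe > 0)
  vox <- which(as.logical(ftv$mask))
  if (length(vox) == 0) stop("FTV mask is empty")
  A <- influence_matrix(spots, fgeom, vox)
  p <- rep(prescription_gyrbe, length(vox))

  fit <- cpp_nnls_cd(A@p, A@i, A@x, nrow(A), p, as.integer(maxit), tol)
  if (!fit$converged)
    stop("spot-weight optimization did not converge: residual ",
         signif(fit$residual, 6), " after ", maxit, " sweeps")
  w <- fit$w
  iters <- fit$sweeps

  dmin <- min(as.numeric(A %*% w))
  if (dmin <= 0) stop("optimized dose not positive over the FTV")
  scale <- 0.95 * prescription_gyrbe / dmin
  spots$weight <- w * scale
  dvec <- as.numeric(A %*% spots$weight)
  attr(spots, "optimization") <- list(
    iterations = iters, residual = fit$residual, scale = scale,
    ftv_dmin = min(dvec), ftv_dmax = max(dvec),
    ftv_hi_pct = 100 * sd(dvec) / prescription_gyrbe)
  spots
}

#' Planning (interplay-free reference) dose
#'
#' Every spot's weight is split equally over the given phases; the dose
#' of each share is computed on that phase's density, pulled back to the
#' reference phase through the phantom deformation, and summed.
#'
#' @param spots an optimized `spot_map`.
#' @param phantom a `phantom4d`.
#' @param fgeom the field's [field_geometry()].
#' @param phases phases the spots are spread over (default all ten).
#' @return dose array, Gy(RBE), at the reference phase T50.
#' @export
planning_dose <- function(spots, phantom, fgeom, phases = phantom$phases) {
  if (length(phases) == 0) stop("empty phase set")
  acc <- array(0, phantom$geom$dim)
  for (p in phases) {
    d <- spot_dose(spots, fgeom, p, weights = spots$weight / length(phases))
    acc <- acc + warp_to_reference(d, phantom, p)
  }
  acc
}
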