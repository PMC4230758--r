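#' Beam port (parallel broad-beam geometry)
#'
#' Gantry angle in the axial plane: 0 degrees is an anterior beam
#' (travelling anterior to posterior), increasing clockwise viewed from
#' the patient's feet.  Rays are parallel (no source divergence).
#' Beam's-eye-view coordinates: u is lateral in the axial plane, v is
#' superior-inferior.
#'
#' @param gantry_angle_deg gantry angle in degrees.
#' @param isocenter_mm 3-vector, mm (default origin).
#' @return object of class `beam_port` with unit vectors `dir` (beam
#'   travel), `u_hat`, `v_hat`.
#' @export
beam_port <- function(gantry_angle_deg, isocenter_mm = c(0, 0, 0)) {
  th <- gantry_angle_deg * pi / 180
  dir <- c(-sin(th), -cos(th), 0)
  structure(list(gantry_angle_deg = gantry_angle_deg,
                 isocenter_mm = as.numeric(isocenter_mm),
                 dir = dir,
                 u_hat = c(-cos(th), sin(th), 0),
                 v_hat = c(0, 0, 1)),
            class = "beam_port")
}

# Beam's-eye-view coordinates (u, v) of world points for a port.
bev_coords <- function(pts, beam) {
  rel <- sweep(pts, 2, beam$isocenter_mm)
  cbind(u = as.numeric(rel %*% beam$u_hat),
        v = as.numeric(rel %*% beam$v_hat))
}

# World point of a BEV lateral position (on the plane through isocenter).
bev_point <- function(u, v, beam) {
  cbind(beam$isocenter_mm[1] + u * beam$u_hat[1] + v * beam$v_hat[1],
        beam$isocenter_mm[2] + u * beam$u_hat[2] + v * beam$v_hat[2],
        beam$isocenter_mm[3] + u * beam$u_hat[3] + v * beam$v_hat[3])
}

#' Cumulative WEPL profile along one ray
#'
#' Exact voxel-boundary (Siddon-style) integration of water-equivalent
#' density along the ray at lateral position `ray_uv` of a beam port.
#' Depth 0 is the ray's entry into the grid.
#'
#' @param density numeric array of relative stopping power.
#' @param geom the grid's [grid_geometry()].
#' @param beam a [beam_port()].
#' @param ray_uv lateral position c(u, v) in mm (beam's-eye view).
#' @return object of class `wepl_profile`: data frame columns
#'   `depth_mm`, `wepl_mm` at every voxel-boundary crossing (empty when
#'   the ray misses the grid).
#' @export
trace_wepl <- function(density, geom, beam, ray_uv = c(0, 0)) {
  p0 <- bev_point(ray_uv[1], ray_uv[2], beam)
  m <- cpp_trace_profile(as.numeric(density), geom$dim, geom$spacing,
                         geom$origin, as.numeric(p0), beam$dir)
  out <- as.data.frame(m)
  class(out) <- c("wepl_profile", class(out))
  out
}

#' Interpolate a WEPL profile at geometric depths
#' @param profile a [trace_wepl()] result.
#' @param depth_mm depths (mm) from grid entry.
#' @return WEPL (mm) by piecewise-linear interpolation.
#' @export
wepl_at <- function(profile, depth_mm) {
  if (nrow(profile) == 0) return(rep(NA_real_, length(depth_mm)))
  approx(profile$depth_mm, profile$wepl_mm, xout = depth_mm, rule = 2)$y
}

#' Per-voxel WEPL grid for a beam port
#'
#' WEPL from the grid entry to every voxel center along the port
#' direction, by exact ray marching.
#'
#' @inheritParams trace_wepl
#' @return numeric array of WEPL (mm) on the grid.
#' @export
wepl_grid <- function(density, geom, beam) {
  pts <- grid_centers(geom)
  grid_array(cpp_wepl_points(as.numeric(density), geom$dim, geom$spacing,
                             geom$origin, beam$dir, pts), geom)
}

#' Field-specific target volume from phase-wise WEPL envelopes
#'
#' For every ray of a fine lateral raster that crosses the CTV in any of
#' the selected phases, the distal bound is the maximum over phases of
#' the WEPL at the CTV exit, and the proximal bound the minimum over
#' phases of the WEPL at the CTV entry.  Rays crossing no CTV are
#' excluded.  The geometric mask collects reference-phase voxels whose
#' ray is in the footprint and whose WEPL lies within the bounds.
#'
#' @param phantom a `phantom4d`.
#' @param beam a [beam_port()].
#' @param phases phase labels used for the envelope (gated: T40-T60;
#'   ungated: all ten).
#' @param ctv_masks optional per-phase list of CTV masks (defaults to
#'   the phantom's CTV structure).
#' @param ray_spacing_mm lateral raster pitch of the rays (mm).
#' @return object of class `field_target_volume`: `rays` data frame
#'   (u, v, proximal/distal WEPL), `mask` (logical array at T50),
#'   `beam`, `phases`.
#' @export
build_ftv <- function(phantom, beam, phases, ctv_masks = NULL,
                      ray_spacing_mm = 1.0) {
  stopifnot(length(phases) >= 1, all(phases %in% phantom$phases))
  if (is.null(ctv_masks)) ctv_masks <- phantom$structures$ctv
  geom <- phantom$geom

  # lateral raster covering the all-phase CTV footprint plus margin
  uv_lim <- NULL
  for (p in phases) {
    idx <- which(ctv_masks[[p]], arr.ind = TRUE)
    if (nrow(idx) == 0) next
    pts <- cbind(geom$origin[1] + (idx[, 1] - 1) * geom$spacing[1],
                 geom$origin[2] + (idx[, 2] - 1) * geom$spacing[2],
                 geom$origin[3] + (idx[, 3] - 1) * geom$spacing[3])
    uv <- bev_coords(pts, beam)
    uv_lim <- rbind(uv_lim, cbind(range(uv[, 1]), range(uv[, 2])))
  }
  if (is.null(uv_lim)) stop("beam port misses the CTV at all phases")
  pad <- 3 * max(geom$spacing)
  us <- seq(floor(min(uv_lim[, 1]) - pad), ceiling(max(uv_lim[, 1]) + pad),
            by = ray_spacing_mm)
  vs <- seq(floor(min(uv_lim[, 2]) - pad), ceiling(max(uv_lim[, 2]) + pad),
            by = ray_spacing_mm)
  rays <- expand.grid(u = us, v = vs)
  starts <- bev_point(rays$u, rays$v, beam)

  prox <- rep(Inf, nrow(rays))
  dist <- rep(-Inf, nrow(rays))
  hit <- rep(FALSE, nrow(rays))
  for (p in phases) {
    res <- cpp_ray_mask_wepl(as.numeric(phantom$density[[p]]),
                             as.integer(ctv_masks[[p]]), geom$dim,
                             geom$spacing, geom$origin, starts, beam$dir)
    h <- res[, "hit"] > 0
    hit <- hit | h
    prox[h] <- pmin(prox[h], res[h, "wepl_in"])
    dist[h] <- pmax(dist[h], res[h, "wepl_out"])
  }
  if (!any(hit)) stop("beam port misses the CTV at all phases")
  rays$proximal_wepl <- ifelse(hit, prox, NA_real_)
  rays$distal_wepl <- ifelse(hit, dist, NA_real_)
  rays$hit <- hit

  # geometric mask on the reference phase
  ref <- "T50"
  wref <- wepl_grid(phantom$density[[ref]], geom, beam)
  pts_all <- grid_centers(geom)
  uv_all <- bev_coords(pts_all, beam)
  iu <- round((uv_all[, "u"] - us[1]) / ray_spacing_mm) + 1L
  iv <- round((uv_all[, "v"] - vs[1]) / ray_spacing_mm) + 1L
  ok <- iu >= 1L & iu <= length(us) & iv >= 1L & iv <= length(vs)
  ridx <- ifelse(ok, iu + (iv - 1L) * length(us), NA_integer_)
  inmask <- !is.na(ridx) & hit[ridx] &
    as.numeric(wref) >= prox[ridx] - 1e-9 &
    as.numeric(wref) <= dist[ridx] + 1e-9
  inmask[is.na(inmask)] <- FALSE

  structure(list(beam = beam, phases = phases,
                 rays = rays[rays$hit, c("u", "v", "proximal_wepl",
                                         "distal_wepl")],
                 ray_spacing_mm = ray_spacing_mm,
                 mask = grid_array(inmask, geom)),
            class = "field_target_volume")
}

#' @exportS3Method base::print
print.field_target_volume <- function(x, ...) {
  cat("field_target_volume:", nrow(x$rays), "rays, gantry",
      x$beam$gantry_angle_deg, "deg, phases",
      paste(x$phases, collapse = " "), "\n")
  cat("  WEPL envelope (mm):",
      signif(min(x$rays$proximal_wepl), 4), "-",
      signif(max(x$rays$distal_wepl), 4),
      "; mask voxels:", sum(x$mask), "\n")
  invisible(x)
}

#' FTV volume in cubic centimeters
#' @param ftv a [build_ftv()] result.
#' @param geom the phantom grid geometry.
#' @return volume of the geometric FTV mask, cc.
#' @export
ftv_volume_cc <- function(ftv, geom) {
  sum(ftv$mask) * prod(geom$spacing) / 1000
}
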