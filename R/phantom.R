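#' @section Respiratory phase convention:
#' Ten phases T00..T90 subdivide the breathing cycle; T00 is peak
#' inhalation and T50 peak exhalation.  T50 is the reference phase: the
#' phantom rest geometry, and the phase every dose is accumulated to.
NULL

#' Phase labels T00..T90
#' @return character vector of the ten phase labels.
#' @export
phase_labels <- function() sprintf("T%02d", seq(0, 90, by = 10))

#' Respiratory trace
#'
#' Periodic, time-binned respiration: the cycle is split into ten equal
#' phase bins.  The gating window defaults to peri-exhalation
#' (T40-T60).  Delivery starts at T00 when ungated and at T40 (the gate
#' opening) when gated.
#'
#' @param cycle_s breathing period in seconds.
#' @param gate_phases labels of phases in the gating window.
#' @return object of class `respiratory_trace`.
#' @export
respiratory_trace <- function(cycle_s, gate_phases = c("T40", "T50", "T60")) {
  stopifnot(is.numeric(cycle_s), cycle_s > 0)
  labels <- phase_labels()
  stopifnot(all(gate_phases %in% labels))
  structure(list(cycle_s = cycle_s, phase_count = 10L,
                 phase_labels = labels, gate_phases = gate_phases,
                 start_phase_ungated = "T00", start_phase_gated = "T40"),
            class = "respiratory_trace")
}

#' Phase label at a delivery time
#'
#' Time 0 maps to the strategy's start phase (T00 ungated, T40 gated);
#' phases advance cyclically every `cycle_s / 10` seconds.
#'
#' @param trace a [respiratory_trace()].
#' @param t time in seconds (scalar or vector), `t >= 0`.
#' @param strategy `"ungated"` or `"gated"`.
#' @return phase label(s).
#' @export
phase_at_time <- function(trace, t, strategy = c("ungated", "gated")) {
  strategy <- match.arg(strategy)
  if (any(t < 0)) stop("negative time")
  start <- if (strategy == "gated") trace$start_phase_gated else
    trace$start_phase_ungated
  i0 <- match(start, trace$phase_labels) - 1L
  idx <- (i0 + floor(10 * t / trace$cycle_s)) %% 10
  trace$phase_labels[idx + 1L]
}

#' Tumor motion model
#'
#' Peak displacement (exhale to inhale) of the tumor center per patient
#' axis, a periodic waveform, and the spatial extent of the surrounding
#' lung deformation.  The waveform w(phi) is parameterized by the phase
#' fraction phi from peak inhalation (phi = 0 at T00, 0.5 at T50);
#' displacement from the exhale rest position is `w(phi) * amplitude`,
#' so it is exactly zero at T50 and peaks at T00.
#'
#' @param amplitude_mm 3-vector (LR, AP, SI) of peak tumor-center
#'   displacement in mm.
#' @param cycle_s breathing period, seconds.
#' @param waveform `"cos4"` (long quiescent exhale, sharp inhale:
#'   w = cos^4(pi phi)) or `"sin"` (sinusoidal: w = (1+cos(2 pi phi))/2).
#' @param extent_mm ellipsoidal semi-axes (mm) of the deformation
#'   falloff region around the tumor; displacement is exactly zero on
#'   and beyond this ellipsoid.
#' @param rigid_core_mm radius (mm) of the rigid core around the tumor
#'   center that translates without deformation.
#' @return object of class `motion_model`.
#' @export
motion_model <- function(amplitude_mm, cycle_s, waveform = c("cos4", "sin"),
                         extent_mm = c(34, 34, 70), rigid_core_mm = 12) {
  waveform <- match.arg(waveform)
  stopifnot(length(amplitude_mm) == 3L, all(amplitude_mm >= 0), cycle_s > 0,
            length(extent_mm) == 3L, all(extent_mm > 0),
            rigid_core_mm > 0, rigid_core_mm < min(extent_mm))
  structure(list(amplitude_mm = as.numeric(amplitude_mm), cycle_s = cycle_s,
                 waveform = waveform, extent_mm = as.numeric(extent_mm),
                 rigid_core_mm = rigid_core_mm),
            class = "motion_model")
}

#' Waveform value at phase fraction from inhale
#' @param motion a [motion_model()].
#' @param phi phase fraction in [0, 1) measured from peak inhalation.
#' @return scalar weight in [0, 1]; 1 at inhale (phi = 0), 0 at exhale.
#' @export
waveform_value <- function(motion, phi) {
  phi <- phi %% 1
  switch(motion$waveform,
         cos4 = cos(pi * phi)^4,
         sin = (1 + cos(2 * pi * phi)) / 2)
}

phase_phi <- function(label) as.numeric(sub("T", "", label)) / 100

# Raised-cosine falloff window around the tumor rest center: 1 inside
# the rigid core, smooth taper to exactly 0 on the extent ellipsoid.
motion_window <- function(pts, center, motion) {
  s <- sweep(sweep(pts, 2, center), 2, motion$extent_mm, "/")
  rho <- sqrt(rowSums(s^2))
  rho0 <- motion$rigid_core_mm / min(motion$extent_mm)
  w <- numeric(length(rho))
  w[rho <= rho0] <- 1
  mid <- rho > rho0 & rho < 1
  w[mid] <- cos(pi / 2 * (rho[mid] - rho0) / (1 - rho0))^2
  w
}

# Forward displacement u_p(r) of rest points r at one phase (N x 3 mm).
forward_displacement <- function(pts, center, motion, phi) {
  wv <- waveform_value(motion, phi)
  if (wv == 0) return(matrix(0, nrow(pts), 3))
  win <- wv * motion_window(pts, center, motion)
  cbind(win * motion$amplitude_mm[1], win * motion$amplitude_mm[2],
        win * motion$amplitude_mm[3])
}

# Lipschitz bound of the fixed-point update for the forward map
# x = r + u(r); must stay < 1 for invertibility.
motion_contraction_bound <- function(motion) {
  rho0 <- motion$rigid_core_mm / min(motion$extent_mm)
  max_slope <- (pi / 2) / (1 - rho0)  # of cos^2 taper wrt rho
  max_slope * sqrt(sum((motion$amplitude_mm / motion$extent_mm)^2))
}

# Invert x = r + u_p(r) for given phase positions x (fixed point on the
# analytic displacement); returns rest coordinates r.
invert_forward_map <- function(pts, center, motion, phi, tol_mm = 1e-3,
                               maxit = 200L) {
  wv <- waveform_value(motion, phi)
  if (wv == 0) return(pts)
  r <- pts
  for (it in seq_len(maxit)) {
    u <- forward_displacement(r, center, motion, phi)
    rn <- pts - u
    delta <- max(abs(rn - r))
    r <- rn
    if (delta < tol_mm) break
  }
  r
}

#' Phantom configuration
#'
#' Desk-scale synthetic thorax: an elliptic-cylinder body of
#' water-equivalent density 1.0 containing two ellipsoidal lungs of
#' density 0.3, a spherical tumor (density 1.0) inside the right lung,
#' a heart ellipsoid and a spinal-cord cylinder (density 1.0).  The
#' tumor and surrounding lung move with the respiratory waveform; the
#' deformation is a windowed translation that is rigid across the
#' tumor, decays smoothly over `motion` extent, and vanishes at the
#' chest wall.
#'
#' @param grid_dim voxel counts, default 64 x 64 x 96.
#' @param spacing_mm voxel spacing, default 2 mm isotropic.
#' @param gtv_radius_mm tumor radius (mm).
#' @param tumor_center_mm rest (T50) tumor center, mm.
#' @param amplitude_mm,cycle_s,waveform passed to [motion_model()].
#' @param extent_mm,rigid_core_mm deformation falloff geometry; by
#'   default the rigid core is `gtv_radius_mm + 4` mm.
#' @param densities named list of relative stopping powers.
#' @param jitter_mm per-axis half-width of the seeded tumor-center
#'   jitter that differentiates phantom realizations.
#' @return a list of class `phantom_params`.
#' @export
phantom_params <- function(grid_dim = c(64, 64, 96), spacing_mm = c(2, 2, 2),
                           gtv_radius_mm = 10,
                           tumor_center_mm = c(22, 0, 0),
                           amplitude_mm = c(1.4, 2.2, 7.2), cycle_s = 3.8,
                           waveform = "cos4",
                           extent_mm = c(34, 34, 70),
                           rigid_core_mm = gtv_radius_mm + 4,
                           densities = list(air = 0.001, lung = 0.3,
                                            soft = 1.0),
                           jitter_mm = c(3, 3, 5)) {
  structure(list(
    grid_dim = as.integer(grid_dim), spacing_mm = as.numeric(spacing_mm),
    gtv_radius_mm = gtv_radius_mm, tumor_center_mm = as.numeric(tumor_center_mm),
    amplitude_mm = as.numeric(amplitude_mm), cycle_s = cycle_s,
    waveform = waveform, extent_mm = as.numeric(extent_mm),
    rigid_core_mm = rigid_core_mm, densities = densities,
    jitter_mm = as.numeric(jitter_mm),
    body_semi_mm = c(58, 50), lung_center_mm = c(30, -2, 0),
    lung_semi_mm = c(24, 36, 80), heart_center_mm = c(-10, 12, -25),
    heart_semi_mm = c(20, 18, 28), cord_center_mm = c(0, -40),
    cord_radius_mm = 5), class = "phantom_params")
}

in_ellipsoid <- function(pts, center, semi) {
  s <- sweep(sweep(pts, 2, center), 2, semi, "/")
  rowSums(s^2) <= 1
}

# Rest (T50) anatomy membership, evaluated analytically at world points.
rest_regions <- function(pts, pp, tumor_center) {
  body <- (pts[, 1] / pp$body_semi_mm[1])^2 +
    (pts[, 2] / pp$body_semi_mm[2])^2 <= 1
  lung_r <- in_ellipsoid(pts, pp$lung_center_mm, pp$lung_semi_mm)
  lung_l <- in_ellipsoid(pts, pp$lung_center_mm * c(-1, 1, 1),
                         pp$lung_semi_mm)
  heart <- in_ellipsoid(pts, pp$heart_center_mm, pp$heart_semi_mm)
  cord <- (pts[, 1] - pp$cord_center_mm[1])^2 +
    (pts[, 2] - pp$cord_center_mm[2])^2 <= pp$cord_radius_mm^2
  gtv <- sqrt(rowSums(sweep(pts, 2, tumor_center)^2)) <= pp$gtv_radius_mm
  lungs <- (lung_r | lung_l) & body & !heart & !cord
  list(body = body, lung = lungs & !gtv, heart = heart & body,
       cord = cord & body, gtv = gtv)
}

rest_density_values <- function(pts, pp, tumor_center) {
  reg <- rest_regions(pts, pp, tumor_center)
  dens <- rep(pp$densities$air, nrow(pts))
  dens[reg$body] <- pp$densities$soft
  dens[reg$lung] <- pp$densities$lung
  dens[reg$gtv] <- pp$densities$soft
  dens
}

#' Generate a synthetic 10-phase moving-lung phantom
#'
#' Builds per-phase water-equivalent density grids, structure masks
#' (GTV, CTV = GTV + 10 mm, bilateral lung excluding the GTV, heart,
#' spinal cord) and ground-truth phase-to-reference deformation fields.
#' Each phase's anatomy is the rest anatomy advected by an analytically
#' invertible windowed translation: voxel values at phase positions are
#' the rest values at the fixed-point-inverted rest coordinates, so T50
#' reproduces the rest geometry exactly and warping any phase back to
#' T50 recovers it up to interpolation.  The only randomness is a
#' seeded jitter of the tumor center.
#'
#' @param params a [phantom_params()].
#' @param seed integer seed (tumor-position jitter); the phantom is
#'   bit-identical for identical params + seed.
#' @param ctv_margin_mm margin added isotropically to the GTV, mm.
#' @return object of class `phantom4d`: fields `geom`, `phases`,
#'   `density` (list of arrays), `deformation_to_ref` (per phase, list
#'   of x/y/z mm arrays), `structures` (per structure, list of per-phase
#'   logical arrays), `trace`, `motion`, `tumor_center_mm`, `params`.
#' @export
generate_phantom <- function(params = phantom_params(), seed = 1L,
                             ctv_margin_mm = 10) {
  pp <- params
  geom <- grid_geometry(pp$grid_dim, pp$spacing_mm)
  set.seed(seed)
  jit <- runif(3, -pp$jitter_mm, pp$jitter_mm)
  center <- pp$tumor_center_mm + jit
  motion <- motion_model(pp$amplitude_mm, pp$cycle_s, pp$waveform,
                         pp$extent_mm, pp$rigid_core_mm)

  # -- validity checks ------------------------------------------------
  lb <- motion_contraction_bound(motion)
  if (lb >= 0.95)
    stop("motion amplitude too large for the deformation extent ",
         "(contraction bound ", signif(lb, 3), " >= 0.95)")
  lung_rho <- sqrt(sum(((center - pp$lung_center_mm) / pp$lung_semi_mm)^2))
  if (lung_rho + pp$gtv_radius_mm / min(pp$lung_semi_mm) > 1)
    stop("tumor outside lung volume")
  lim <- (geom$dim - 1) / 2 * geom$spacing
  if (any(abs(center) + pp$amplitude_mm + pp$gtv_radius_mm > lim))
    stop("amplitude moves tumor off-grid")

  pts <- grid_centers(geom)
  labels <- phase_labels()
  rest_reg <- rest_regions(pts, pp, center)
  ctv_rest <- sqrt(rowSums(sweep(pts, 2, center)^2)) <=
    pp$gtv_radius_mm + ctv_margin_mm

  density <- vector("list", 10L); names(density) <- labels
  def <- vector("list", 10L); names(def) <- labels
  structures <- list(gtv = list(), ctv = list(), lung = list(),
                     heart = list(), cord = list())
  for (p in seq_along(labels)) {
    phi <- phase_phi(labels[p])
    r <- invert_forward_map(pts, center, motion, phi)
    density[[p]] <- grid_array(rest_density_values(r, pp, center), geom)
    d <- r - pts
    def[[p]] <- list(x = grid_array(d[, 1], geom),
                     y = grid_array(d[, 2], geom),
                     z = grid_array(d[, 3], geom))
    reg <- rest_regions(r, pp, center)
    structures$gtv[[labels[p]]] <- grid_array(reg$gtv, geom)
    structures$ctv[[labels[p]]] <- grid_array(
      sqrt(rowSums(sweep(r, 2, center)^2)) <= pp$gtv_radius_mm +
        ctv_margin_mm, geom)
    structures$lung[[labels[p]]] <- grid_array(reg$lung, geom)
    structures$heart[[labels[p]]] <- grid_array(reg$heart, geom)
    structures$cord[[labels[p]]] <- grid_array(reg$cord, geom)
  }

  structure(list(geom = geom, phases = labels, density = density,
                 deformation_to_ref = def, structures = structures,
                 trace = respiratory_trace(pp$cycle_s), motion = motion,
                 tumor_center_mm = center, ctv_margin_mm = ctv_margin_mm,
                 seed = seed, params = pp),
            class = "phantom4d")
}

#' @exportS3Method base::print
print.phantom4d <- function(x, ...) {
  cat("phantom4d:", paste(x$geom$dim, collapse = " x "), "voxels @",
      paste(x$geom$spacing, collapse = " x "), "mm\n")
  cat("  tumor center (mm):", paste(signif(x$tumor_center_mm, 3),
                                    collapse = ", "),
      " radius:", x$params$gtv_radius_mm, "mm\n")
  cat("  motion amplitude LRxAPxSI (mm):",
      paste(x$motion$amplitude_mm, collapse = " x "),
      " cycle:", x$motion$cycle_s, "s\n")
  invisible(x)
}

#' Clinical target volume by isotropic dilation
#'
#' Morphological dilation of the GTV mask with a spherical structuring
#' element of radius `margin_mm` in physical units.
#'
#' @param gtv logical array (GTV mask).
#' @param margin_mm margin in mm, `>= 0`.
#' @param spacing_mm voxel spacing 3-vector.
#' @return logical array of the dilated mask.
#' @export
build_ctv <- function(gtv, margin_mm, spacing_mm) {
  stopifnot(margin_mm >= 0)
  if (margin_mm == 0 || !any(gtv)) return(gtv)
  d <- dim(gtv)
  noff <- floor(margin_mm / spacing_mm)
  off <- expand.grid(dx = -noff[1]:noff[1], dy = -noff[2]:noff[2],
                     dz = -noff[3]:noff[3])
  keep <- (off$dx * spacing_mm[1])^2 + (off$dy * spacing_mm[2])^2 +
    (off$dz * spacing_mm[3])^2 <= margin_mm^2
  off <- off[keep, , drop = FALSE]
  idx <- which(gtv, arr.ind = TRUE)
  out <- array(FALSE, d)
  for (r in seq_len(nrow(off))) {
    i <- idx[, 1] + off$dx[r]
    j <- idx[, 2] + off$dy[r]
    k <- idx[, 3] + off$dz[r]
    if (any(i < 1L | i > d[1] | j < 1L | j > d[2] | k < 1L | k > d[3]))
      stop("margin pushes CTV off-grid")
    out[cbind(i, j, k)] <- TRUE
  }
  out
}

#' Warp a phase mask or volume to the reference phase
#'
#' Pulls a per-phase volume back to T50 voxel centers through the stored
#' phase-to-reference deformation (fixed-point inversion + trilinear
#' sampling).  Masks are thresholded at 0.5.
#'
#' @param vol numeric or logical array on the phantom grid at `phase`.
#' @param phantom a `phantom4d`.
#' @param phase phase label.
#' @return array on the reference grid (logical input returns logical).
#' @export
warp_to_reference <- function(vol, phantom, phase) {
  def <- phantom$deformation_to_ref[[phase]]
  if (is.null(def)) stop("missing deformation for phase ", phase)
  was_logical <- is.logical(vol)
  g <- phantom$geom
  out <- cpp_pullback(as.numeric(vol), as.numeric(def$x), as.numeric(def$y),
                      as.numeric(def$z), g$dim, g$spacing, g$origin,
                      1e-3, 100L)
  out <- grid_array(out, g)
  if (was_logical) out >= 0.5 else out
}
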