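#' Voxel grid geometry
#'
#' Defines a regular voxel grid in patient coordinates: x = left-right
#' (LR), y = anterior-posterior (AP), z = superior-inferior (SI), all in
#' mm.  Voxel (1,1,1) has world coordinate `origin`; by default the grid
#' is centered on the isocenter (0,0,0).
#'
#' @param dim integer 3-vector of voxel counts (nx, ny, nz).
#' @param spacing_mm numeric 3-vector of voxel spacings in mm.
#' @param origin_mm world coordinate (mm) of the first voxel center, or
#'   `NULL` to center the grid on the origin.
#' @return an object of class `pcr_grid` with fields `dim`, `spacing`,
#'   `origin`.
#' @export
grid_geometry <- function(dim, spacing_mm, origin_mm = NULL) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim >= 1L),
            length(spacing_mm) == 3L, all(spacing_mm > 0))
  if (is.null(origin_mm)) origin_mm <- -(dim - 1) / 2 * spacing_mm
  structure(list(dim = dim, spacing = as.numeric(spacing_mm),
                 origin = as.numeric(origin_mm)),
            class = "pcr_grid")
}

#' World coordinates of all voxel centers
#'
#' @param geom a `pcr_grid`.
#' @return an N x 3 matrix (mm), rows in R array order (x fastest).
#' @export
grid_centers <- function(geom) {
  d <- geom$dim
  x <- geom$origin[1] + (seq_len(d[1]) - 1) * geom$spacing[1]
  y <- geom$origin[2] + (seq_len(d[2]) - 1) * geom$spacing[2]
  z <- geom$origin[3] + (seq_len(d[3]) - 1) * geom$spacing[3]
  cbind(rep(x, times = d[2] * d[3]),
        rep(rep(y, each = d[1]), times = d[3]),
        rep(z, each = d[1] * d[2]))
}

grid_array <- function(values, geom) {
  array(values, dim = geom$dim)
}

#' Dice overlap coefficient between two masks
#'
#' @param a,b logical arrays of identical shape.
#' @return 2|A∩B| / (|A|+|B|); 1 when both masks are empty.
#' @export
dice <- function(a, b) {
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) return(1)
  2 * sum(a & b) / (na + nb)
}

#' Trilinear interpolation of a grid at world points
#'
#' Edge-clamped trilinear sampling, used for deformation-field lookups
#' and test oracles.
#'
#' @param vol numeric array on `geom`.
#' @param geom a `pcr_grid`.
#' @param pts N x 3 matrix of world coordinates (mm).
#' @return numeric vector of sampled values.
#' @export
interp_trilinear <- function(vol, geom, pts) {
  cpp_trilinear(as.numeric(vol), geom$dim, geom$spacing, geom$origin,
                as.matrix(pts))
}
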