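# Shared fixtures.  Phantom generation and planning are the expensive
# steps, so commonly reused objects are built lazily and cached for the
# whole test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# small grids keep unit tests fast; the tumor stays at the default
# left-lung position, so the grid must span at least ~96 mm per axis
tiny_params <- function(amplitude_mm = c(0, 0, 0), cycle_s = 4,
                        jitter_mm = c(0, 0, 0), ...) {
  phantom_params(grid_dim = c(32, 32, 44), spacing_mm = c(3, 3, 3),
                 gtv_radius_mm = 6, amplitude_mm = amplitude_mm,
                 cycle_s = cycle_s, rigid_core_mm = 10,
                 jitter_mm = jitter_mm, ...)
}

# desk-scale cohort phantom used by the acceptance studies
cohort_params <- function(amplitude_mm, cycle_s) {
  phantom_params(grid_dim = c(40, 40, 56), spacing_mm = c(3, 3, 3),
                 gtv_radius_mm = 7, amplitude_mm = amplitude_mm,
                 cycle_s = cycle_s, rigid_core_mm = 11)
}

tiny_static <- function() fixture("tiny_static", function()
  generate_phantom(tiny_params(), seed = 1))

tiny_moving <- function() fixture("tiny_moving", function()
  generate_phantom(tiny_params(amplitude_mm = c(1.5, 3, 10),
                               jitter_mm = c(1, 1, 2)), seed = 2))

tiny_static_field <- function() fixture("tiny_static_field", function()
  plan_field(tiny_static(), 340, "ungated", 48))

ref_structures <- function(phantom) lapply(phantom$structures, `[[`, "T50")

# uniform-water geometry for beam-kernel tests
water_geometry <- function(dim = c(40, 40, 40), sp = 2) {
  geom <- grid_geometry(dim, rep(sp, 3))
  list(geom = geom, density = array(1, dim))
}

# independent midpoint-quadrature WEPL oracle (nearest-voxel density
# lookup at fine steps along the ray)
wepl_quadrature <- function(density, geom, beam, ray_uv, depth, step = 0.01) {
  p_entry <- NULL
  # march from far outside the grid to find the entry, then integrate
  start <- bev_point(ray_uv[1], ray_uv[2], beam) -
    matrix(beam$dir * 500, 1, 3)
  lo <- geom$origin - geom$spacing / 2
  hi <- geom$origin + (geom$dim - 0.5) * geom$spacing
  tt <- seq(0, 1000, by = step)
  pts <- cbind(start[1] + tt * beam$dir[1], start[2] + tt * beam$dir[2],
               start[3] + tt * beam$dir[3])
  inside <- pts[, 1] >= lo[1] & pts[, 1] <= hi[1] &
    pts[, 2] >= lo[2] & pts[, 2] <= hi[2] &
    pts[, 3] >= lo[3] & pts[, 3] <= hi[3]
  t_entry <- tt[which(inside)[1]]
  mid <- t_entry + seq(step / 2, depth - step / 2, by = step)
  pm <- cbind(start[1] + mid * beam$dir[1], start[2] + mid * beam$dir[2],
              start[3] + mid * beam$dir[3])
  idx <- sapply(1:3, function(a)
    pmin(pmax(round((pm[, a] - geom$origin[a]) / geom$spacing[a]), 0),
         geom$dim[a] - 1))
  sum(density[idx + 1]) * step
}

# independent phase-label -> phase-fraction mapping for oracles
phase_phi_oracle <- function(label) as.numeric(substring(label, 2, 3)) / 100
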