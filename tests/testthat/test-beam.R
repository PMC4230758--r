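test_that("penumbra/sigma conversion matches the Gaussian edge relation", {
  # 80-20% distance of a Gaussian-blurred edge = 2 qnorm(0.8) sigma
  expect_equal(penumbra_to_sigma(5.0), 5.0 / (2 * qnorm(0.8)))
  expect_equal(penumbra_to_sigma(5.0), 2.9704, tolerance = 1e-4)
  expect_equal(penumbra_to_sigma(2 * qnorm(0.8)), 1.0, tolerance = 1e-12)
  x <- c(0.7, 3.3, 5.0)
  expect_equal(sigma_to_penumbra(penumbra_to_sigma(x)), x, tolerance = 1e-12)
  expect_error(penumbra_to_sigma(-1))
})

test_that("depth profile has unit peak, the configured plateau, and a sharp distal fall", {
  m <- beam_line_model()
  expect_equal(depth_profile(0, m), 1)
  expect_equal(depth_profile(-50, m), m$depth_tail, tolerance = 1e-6)
  expect_equal(depth_profile(m$depth_fall_sigma_mm, m), exp(-0.5))
  expect_equal(depth_profile(100, m), 0)
  x <- seq(-30, 10, by = 0.1)
  expect_true(all(diff(depth_profile(x[x <= 0], m)) >= 0))
})

test_that("layer placement follows the WEPL pitch: single-ray example", {
  ftv <- structure(list(rays = data.frame(u = 0, v = 0,
                                          proximal_wepl = 50,
                                          distal_wepl = 59),
                        beam = beam_port(0)),
                   class = "field_target_volume")
  spots <- place_spots(ftv)
  expect_equal(length(unique(spots$layer)), 4)  # 59, 56, 53, 50
  expect_equal(sort(unique(spots$range_wepl_mm)), c(50, 53, 56, 59))
  expect_true(all(spots$weight == 1))
})

test_that("spot raster matches brute-force enumeration on a disc FTV", {
  # 0.25 mm raster offset avoids exact midpoints between 2 mm cells
  us <- seq(-13.75, 14.25, by = 1)
  rays <- expand.grid(u = us, v = us)
  rays <- rays[rays$u^2 + rays$v^2 <= 10^2, ]
  rays$proximal_wepl <- 40; rays$distal_wepl <- 46
  ftv <- structure(list(rays = rays, beam = beam_port(0)),
                   class = "field_target_volume")
  spots <- place_spots(ftv)
  lay <- spots[spots$layer == 1, ]
  # oracle: for every ray find its nearest 2 mm cell by explicit
  # minimization, then dilate the covered set by one raster ring
  cand <- -10:10
  nearest <- function(x) cand[which.min(abs(x - 2 * cand))]
  cov_idx <- unique(data.frame(iu = vapply(rays$u, nearest, 0),
                               iv = vapply(rays$v, nearest, 0)))
  ring <- expand.grid(du = -1:1, dv = -1:1)
  grown <- unique(do.call(rbind, lapply(seq_len(nrow(ring)), function(r)
    cbind(cov_idx$iu + ring$du[r], cov_idx$iv + ring$dv[r]))))
  expect_equal(nrow(lay), nrow(grown))
  expect_setequal(paste(lay$u_mm, lay$v_mm),
                  paste(grown[, 1] * 2, grown[, 2] * 2))
  # serpentine path: consecutive steps stay local
  for (l in unique(spots$layer)) {
    s <- spots[spots$layer == l, ]
    s <- s[order(s$path_order), ]
    d <- sqrt(diff(s$u_mm)^2 + diff(s$v_mm)^2)
    expect_true(all(d <= 2 * 2 * sqrt(2) + 1e-9))
  }
})

test_that("spot dose is linear in weight and reproduces the printed penumbra", {
  m <- beam_line_model()
  # half-plane field edge at u = 0, probed at the peak depth
  sp <- expand.grid(u = seq(-30, 0, by = 2), v = seq(-30, 30, by = 2))
  spots <- cbind(sp$u, sp$v, 50, 1)
  uq <- seq(-12, 12, by = 0.05)
  dose <- pcr4d:::cpp_spot_dose(rep(50, length(uq)), uq, rep(0, length(uq)),
                                spots, m$sigma_lat_mm, m$depth_tail,
                                m$depth_rise_sigma_mm, m$depth_fall_sigma_mm,
                                5.0)
  dose2 <- pcr4d:::cpp_spot_dose(rep(50, length(uq)), uq, rep(0, length(uq)),
                                 cbind(sp$u, sp$v, 50, 2), m$sigma_lat_mm,
                                 m$depth_tail, m$depth_rise_sigma_mm,
                                 m$depth_fall_sigma_mm, 5.0)
  expect_equal(dose2, 2 * dose, tolerance = 1e-12)
  rel <- dose / dose[1]  # plateau value deep inside the field
  u80 <- uq[which.min(abs(rel - 0.8))]
  u20 <- uq[which.min(abs(rel - 0.2))]
  expect_equal(u20 - u80, 5.0, tolerance = 0.2)
})

test_that("integral spot dose matches the separable analytic kernel integral", {
  geom <- grid_geometry(c(61, 80, 61), c(1, 1, 1))
  dens <- array(1, geom$dim)
  beam <- beam_port(0)
  fgeom <- list(u = NULL, v = NULL, wepl = NULL, geom = geom, beam = beam)
  pts <- grid_centers(geom)
  uv <- bev_coords(pts, beam)
  fgeom$u <- uv[, "u"]; fgeom$v <- uv[, "v"]
  fgeom$wepl <- list(T50 = as.numeric(wepl_grid(dens, geom, beam)))
  m <- beam_line_model()
  spots <- data.frame(layer = 1, range_wepl_mm = 40, u_mm = 0.5, v_mm = -0.5,
                      weight = 2.5, path_order = 1)
  dose <- spot_dose(spots, fgeom, "T50", model = m)
  xs <- seq(0, 80, by = 0.001)
  depth_int <- sum(depth_profile(xs - 40, m)) * 0.001
  analytic <- 2.5 * 2 * pi * m$sigma_lat_mm^2 * depth_int
  expect_equal(sum(dose) * prod(geom$spacing), analytic, tolerance = 0.01)
})

test_that("single spot, single-voxel target: weight is the scalar solve", {
  geom <- grid_geometry(c(9, 9, 9), c(2, 2, 2))
  beam <- beam_port(0)
  pts <- grid_centers(geom)
  uv <- bev_coords(pts, beam)
  dens <- array(1, geom$dim)
  wg <- as.numeric(wepl_grid(dens, geom, beam))
  fgeom <- list(u = uv[, "u"], v = uv[, "v"], wepl = list(T50 = wg),
                geom = geom, beam = beam)
  vox <- 5 + 9 * 4 + 81 * 4  # central voxel
  mask <- array(FALSE, geom$dim); mask[vox] <- TRUE
  ftv <- structure(list(mask = mask, beam = beam),
                   class = "field_target_volume")
  spots <- data.frame(layer = 1, range_wepl_mm = wg[vox] + 0.8,
                      u_mm = uv[vox, "u"] + 0.6, v_mm = uv[vox, "v"] - 0.3,
                      weight = 1, path_order = 1)
  opt <- optimize_weights(spots, ftv, fgeom, 48)
  m <- beam_line_model()
  # independent kernel evaluation at the voxel
  unit <- exp(-(0.6^2 + 0.3^2) / (2 * m$sigma_lat_mm^2)) *
    (m$depth_tail + (1 - m$depth_tail) *
       exp(-0.8^2 / (2 * m$depth_rise_sigma_mm^2)))
  expect_equal(opt$weight, 0.95 * 48 / unit, tolerance = 1e-9)
})

test_that("optimized static single field encloses the FTV at the 95% isodose with HI <= 2.5%", {
  f <- tiny_static_field()
  opt <- attr(f$spots, "optimization")
  expect_equal(opt$ftv_dmin, 0.95 * 48, tolerance = 1e-9)
  expect_lte(opt$ftv_hi_pct, 2.5)
  expect_true(all(f$spots$weight >= 0))
  # every FTV voxel at or above 95% of the prescription
  dose <- spot_dose(f$spots, f$fgeom, "T50")
  expect_true(all(dose[f$ftv$mask] >= 0.95 * 48 - 1e-9))
})

test_that("NNLS solver matches exhaustive search on a 2-spot/3-voxel toy", {
  A <- matrix(c(1.0, 0.8, 0.3,
                0.2, 0.9, 1.0), nrow = 3)
  p <- c(4, 5, 3)
  As <- methods::as(A, "CsparseMatrix")
  fit <- pcr4d:::cpp_nnls_cd(As@p, As@i, As@x, 3, p, 5000L, 1e-12)
  obj <- function(w1, w2) (A[1,1]*w1 + A[1,2]*w2 - p[1])^2 +
    (A[2,1]*w1 + A[2,2]*w2 - p[2])^2 + (A[3,1]*w1 + A[3,2]*w2 - p[3])^2
  # two-stage exhaustive grid search
  g <- expand.grid(w1 = seq(0, 10, by = 0.01), w2 = seq(0, 10, by = 0.01))
  o <- obj(g$w1, g$w2)
  best <- g[which.min(o), ]
  g2 <- expand.grid(w1 = seq(max(0, best$w1 - 0.02), best$w1 + 0.02,
                             by = 1e-4),
                    w2 = seq(max(0, best$w2 - 0.02), best$w2 + 0.02,
                             by = 1e-4))
  o2 <- obj(g2$w1, g2$w2)
  expect_equal(fit$residual^2, min(o2), tolerance = 1e-6)
  expect_true(all(fit$w >= 0))
})

test_that("planning dose on a static phantom equals the single-phase dose", {
  ph <- tiny_static()
  f <- tiny_static_field()
  pd <- planning_dose(f$spots, ph, f$fgeom)
  direct <- spot_dose(f$spots, f$fgeom, "T50")
  expect_equal(max(abs(pd - direct)) / max(direct), 0, tolerance = 1e-12)
  expect_error(planning_dose(f$spots, ph, f$fgeom, phases = character(0)),
               "empty")
})

test_that("dose superposition: concatenated spot maps sum voxelwise", {
  f <- tiny_static_field()
  s <- f$spots
  h1 <- s[seq_len(nrow(s)) %% 2 == 1, ]
  h2 <- s[seq_len(nrow(s)) %% 2 == 0, ]
  d <- spot_dose(s, f$fgeom, "T50")
  d1 <- spot_dose(h1, f$fgeom, "T50")
  d2 <- spot_dose(h2, f$fgeom, "T50")
  expect_equal(d, d1 + d2, tolerance = 1e-12)
})
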