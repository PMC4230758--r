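test_that("zero-amplitude phantom is static: identical densities, zero deformation", {
  ph <- tiny_static()
  for (p in ph$phases) {
    expect_identical(ph$density[[p]], ph$density$T50)
    expect_equal(max(abs(ph$deformation_to_ref[[p]]$x)), 0)
    expect_equal(max(abs(ph$deformation_to_ref[[p]]$z)), 0)
    expect_identical(ph$structures$gtv[[p]], ph$structures$gtv$T50)
  }
})

test_that("reference phase is the rest geometry and phantoms are deterministic", {
  ph <- tiny_moving()
  expect_equal(max(abs(ph$deformation_to_ref$T50$x)), 0)
  expect_equal(max(abs(ph$deformation_to_ref$T50$y)), 0)
  expect_equal(max(abs(ph$deformation_to_ref$T50$z)), 0)
  ph2 <- generate_phantom(tiny_params(amplitude_mm = c(1.5, 3, 10),
                                      jitter_mm = c(1, 1, 2)), seed = 2)
  expect_identical(ph2$density, ph$density)
  expect_identical(ph2$tumor_center_mm, ph$tumor_center_mm)
})

test_that("tumor center-of-mass excursion matches a requested clinical-scale amplitude", {
  # amplitudes of a large-excursion patient: 1.5 x 4.7 x 21.8 mm, 3.9 s;
  # the SI deformation extent is widened with the amplitude so the
  # forward map stays a fast-converging contraction
  pp <- phantom_params(amplitude_mm = c(1.5, 4.7, 21.8), cycle_s = 3.9,
                       extent_mm = c(34, 34, 80), jitter_mm = c(0, 0, 0))
  ph <- fixture("phantom_large_amp", function() generate_phantom(pp, seed = 1))
  com <- function(m) {
    idx <- which(m, arr.ind = TRUE)
    colMeans(idx) * ph$geom$spacing
  }
  excursion <- com(ph$structures$gtv$T00) - com(ph$structures$gtv$T50)
  expect_lt(max(abs(excursion - c(1.5, 4.7, 21.8))), max(ph$geom$spacing))
})

test_that("warping phase masks to T50 reproduces the reference masks (Dice >= 0.95)", {
  ph <- fixture("phantom_default", function()
    generate_phantom(phantom_params(), seed = 3))
  for (p in c("T00", "T20", "T80")) {
    for (s in c("gtv", "ctv", "lung")) {
      w <- warp_to_reference(ph$structures[[s]][[p]], ph, p)
      expect_gte(dice(w, ph$structures[[s]]$T50), 0.95)
    }
  }
})

test_that("advection is near mass-preserving and structures stay consistent", {
  for (ph in list(tiny_moving(),
                  fixture("phantom_default", function()
                    generate_phantom(phantom_params(), seed = 3)))) {
    tot <- sapply(ph$density, sum)
    expect_lt((max(tot) - min(tot)) / min(tot), 0.02)
    for (p in ph$phases) {
      expect_true(all(ph$structures$gtv[[p]][ph$structures$ctv[[p]] == FALSE]
                      == FALSE))  # GTV subset of CTV
      expect_false(any(ph$structures$lung[[p]] & ph$structures$gtv[[p]]))
      expect_true(all(ph$density[[p]] >= 0))
    }
  }
})

test_that("invalid phantom configurations are rejected", {
  bad <- tiny_params()
  bad$tumor_center_mm <- c(-30, 30, 0)  # outside both lungs
  expect_error(generate_phantom(bad, seed = 1), "outside lung")
  big <- tiny_params(amplitude_mm = c(0, 0, 60))
  expect_error(generate_phantom(big, seed = 1), "amplitude|contraction")
})

test_that("build_ctv is an isotropic physical-units dilation", {
  ph <- tiny_static()
  gtv <- ph$structures$gtv$T50
  expect_identical(build_ctv(gtv, 0, ph$geom$spacing), gtv)

  # spherical GTV + 10 mm margin equals the analytic sphere of summed
  # radius, within one voxel of boundary error
  geom <- grid_geometry(c(31, 31, 31), c(2, 2, 2))
  pts <- grid_centers(geom)
  rad <- sqrt(rowSums(pts^2))
  gtv10 <- array(rad <= 10, geom$dim)
  ctv <- build_ctv(gtv10, 10, geom$spacing)
  sphere20 <- array(rad <= 20, geom$dim)
  mismatch <- which(ctv != sphere20)
  if (length(mismatch))
    expect_lt(max(abs(rad[mismatch] - 20)), sqrt(sum(geom$spacing^2)))
  expect_gt(dice(ctv, sphere20), 0.95)

  # every CTV voxel lies within margin + one voxel diagonal of a GTV
  # voxel (brute-force distance oracle), and GTV stays inside
  geo2 <- grid_geometry(c(16, 16, 16), c(2, 2, 2))
  p2 <- grid_centers(geo2)
  g2 <- array(sqrt(rowSums(sweep(p2, 2, c(2, 0, -2))^2)) <= 5, geo2$dim)
  c2 <- build_ctv(g2, 7, geo2$spacing)
  expect_true(all(c2[g2]))
  gi <- p2[which(as.logical(g2)), , drop = FALSE]
  ci <- p2[which(as.logical(c2)), , drop = FALSE]
  dmin <- apply(ci, 1, function(x)
    sqrt(min(colSums((t(gi) - x)^2))))
  expect_true(all(dmin <= 7 + sqrt(sum(geo2$spacing^2))))

  # dilation running off the grid is an error
  edge <- array(FALSE, c(8, 8, 8)); edge[1, 4, 4] <- TRUE
  expect_error(build_ctv(edge, 5, c(2, 2, 2)), "off-grid")
})

test_that("phase_at_time follows the strategy start phase and cycles", {
  tr <- respiratory_trace(4.0)
  expect_identical(phase_at_time(tr, 0, "ungated"), "T00")
  expect_identical(phase_at_time(tr, 2.0, "ungated"), "T50")
  tr42 <- respiratory_trace(4.2)
  expect_identical(phase_at_time(tr42, 0, "gated"), "T40")
  expect_identical(phase_at_time(tr42, 4.2, "gated"), "T40")
  expect_identical(phase_at_time(tr42, 4.2 + 2 * 0.42, "gated"), "T60")
  expect_error(phase_at_time(tr, -1, "ungated"), "negative")
  # periodicity across many cycles
  tt <- seq(0, 40, by = 0.37)
  expect_identical(phase_at_time(tr, tt, "ungated"),
                   phase_at_time(tr, tt + 8, "ungated"))
})

test_that("waveform is periodic, zero at exhale, one at inhale", {
  m <- motion_model(c(1, 1, 1), 4)
  expect_equal(waveform_value(m, 0), 1)
  expect_equal(waveform_value(m, 0.5), 0)
  expect_equal(waveform_value(m, 1.3), waveform_value(m, 0.3))
  ms <- motion_model(c(1, 1, 1), 4, waveform = "sin")
  expect_equal(waveform_value(ms, 0), 1)
  expect_equal(waveform_value(ms, 0.5), 0)
})
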