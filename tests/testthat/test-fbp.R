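test_that("Ram-Lak taps have the closed-form structure and decaying DC leak", {
  taps <- ramlak_kernel(9, pitch = 1)
  expect_equal(taps[5], 0.25)
  expect_equal(taps[c(1, 3, 7, 9)], rep(0, 4))        # even offsets
  expect_equal(taps[4], -1 / pi^2)
  expect_equal(taps[2], -1 / (pi^2 * 9))
  expect_error(ramlak_kernel(8), "odd")
  taps_d <- ramlak_kernel(9, pitch = 2)
  expect_equal(taps_d, taps / 4)
  # DC response: sum of taps -> 0 like the analytic tail 1/(pi^2 L)
  dc <- vapply(c(64, 256, 1024) * 2 + 1,
               function(n) sum(ramlak_kernel(n, 1)), numeric(1))
  expect_true(all(diff(abs(dc)) < 0))
  expect_lt(abs(dc[3]), 1.1 / (pi^2 * 1024))
})

test_that("filtering is linear, kills zero input, and replicates on impulses", {
  geom <- scan_geometry(-50, 50, 25, detector_size = 64)
  zero <- sinogram(matrix(0, geom$n_angles, 64), geom)
  expect_true(all(filter_sinogram(zero)$values == 0))
  imp <- matrix(0, geom$n_angles, 64)
  imp[2, 30] <- 1
  q <- filter_sinogram(sinogram(imp, geom))$values
  taps <- ramlak_kernel(2 * 64 - 1, 1)
  expect_equal(q[2, ], taps[(64 - 29):(2 * 64 - 1 - 29)], tolerance = 1e-10)
  expect_true(all(q[-2, ] == 0))
})

test_that("filtering a constant row leaks only the analytic DC residue", {
  geom <- scan_geometry(-50, 50, 50, detector_size = 256)
  const <- sinogram(matrix(1, geom$n_angles, 256), geom)
  q <- filter_sinogram(const)$values
  # a centre pixel sees the kernel over a +/- (nu/2) window; the response
  # to a unit constant is the tap sum over that window (tail ~ 1/(pi^2 L))
  oracle <- sum(ramlak_kernel(255, 1))
  centre <- abs(q[, 100:156])
  expect_lt(max(centre), 2 * abs(oracle))
  expect_lt(max(centre) / 0.25, 5e-3)  # tiny next to the impulse response
})

test_that("single-view backprojection smears a constant row", {
  geom <- scan_geometry(0, 1, 10, detector_size = 64)  # one effective view pair
  grid <- fbp_grid(32, geom)
  vals <- matrix(3, geom$n_angles, 64)
  img <- backproject(sinogram(vals, geom), grid)
  dtheta <- geom$angular_step * pi / 180
  inside <- laxm:::fov_mask(32, 14)
  expect_equal(unclass(img)[inside],
               rep(3 * dtheta * geom$n_angles, sum(inside)),
               tolerance = 1e-10)
})

test_that("full-180 FBP recovers a disk and the limited window degrades it", {
  geom180 <- scan_geometry(0, 179, 1, detector_size = 512)
  geom100 <- scan_geometry(-50, 50, 1, detector_size = 512)
  sec <- disk_sections(100, 1)
  ref <- raster_sections(sec, 256, 2, ns = 4)
  r180 <- fbp_reconstruct(analytic_sinogram(sec, geom180), fbp_grid(256, geom180))
  r100 <- fbp_reconstruct(analytic_sinogram(sec, geom100), fbp_grid(256, geom100))
  e180 <- rmse_fov(r180, ref, 128)
  e100 <- rmse_fov(r100, ref, 128)
  expect_lt(e180, 0.03)        # < 3 percent of unit disk intensity
  expect_gt(e100, e180)
  # angular refinement converges
  errs <- vapply(c(4, 2, 1), function(st) {
    g <- scan_geometry(0, 180 - st, st, detector_size = 512)
    rmse_fov(fbp_reconstruct(analytic_sinogram(sec, g), fbp_grid(256, g)),
             ref, 128)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("missing wedge blurs the edges whose normals are unmeasured", {
  geom <- scan_geometry(-50, 50, 1, detector_size = 256)
  sec <- disk_sections(10, 1)
  rec <- unclass(fbp_reconstruct(analytic_sinogram(sec, geom),
                                 fbp_grid(256, geom)))
  # detector coordinate directions span +/-50 deg about x, so edges with
  # normals near x are visible singularities (sharp left/right boundary)
  # while the top/bottom edges fall in the missing wedge and smear along y
  xw <- sum(rec[, 128] > 0.5)
  yw <- sum(rec[128, ] > 0.5)
  expect_gte(xw, 16)            # visible edges near the true 20 px width
  expect_lte(xw, 22)
  expect_gt(yw, xw + 3)         # wedge elongation along y
})

test_that("reconstruction is linear in the projections", {
  geom <- scan_geometry(-50, 50, 5, detector_size = 64)
  grid <- fbp_grid(32, geom)
  set.seed(3)
  p1 <- sinogram(matrix(runif(geom$n_angles * 64), geom$n_angles, 64), geom)
  p2 <- sinogram(matrix(runif(geom$n_angles * 64), geom$n_angles, 64), geom)
  combo <- sinogram(1.5 * p1$values - 0.5 * p2$values, geom)
  expect_equal(unclass(fbp_reconstruct(combo, grid)),
               1.5 * unclass(fbp_reconstruct(p1, grid)) -
                 0.5 * unclass(fbp_reconstruct(p2, grid)),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("volumes reconstruct row-wise: identical rows, decoupling, symmetry", {
  geom <- scan_geometry(-50, 50, 10, detector_size = 32)
  grid <- fbp_grid(16, geom)
  sec <- disk_sections(8, 1)
  svals <- analytic_sinogram(sec, geom)$values
  stack <- array(0, c(geom$n_angles, 4, 32))
  for (v in 1:4) stack[, v, ] <- svals
  attr(stack, "geometry") <- geom
  attr(stack, "z_indices") <- 1:4
  vol <- reconstruct_volume(stack, grid)
  expect_equal(vol[, , 1], vol[, , 3])
  # single nonzero detector row -> single nonzero slice
  stack2 <- array(0, c(geom$n_angles, 4, 32))
  stack2[, 2, ] <- svals
  attr(stack2, "geometry") <- geom
  attr(stack2, "z_indices") <- 1:4
  vol2 <- reconstruct_volume(stack2, grid)
  expect_true(all(vol2[, , c(1, 3, 4)] == 0))
  expect_gt(max(abs(vol2[, , 2])), 0)
  # sphere: central-pixel z-profile symmetric about the equator
  ph <- single_ellipsoid_phantom(grid = 32, ax = 10, ay = 10, az = 10,
                                 intensity = 0.01)
  stack3 <- project_phantom(ph, geom, z_indices = 9:24)
  vol3 <- reconstruct_volume(stack3, grid)
  profile <- vol3[8, 8, ]
  expect_equal(profile, rev(profile), tolerance = 1e-8)
})

test_that("sagittal reslicing is a lossless involution", {
  set.seed(4)
  vol <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
  sag <- reslice_sagittal(vol)
  expect_equal(dim(sag), c(8, 16, 16))
  expect_equal(attr(sag, "sagittal_indices"), 1:16)
  back <- reslice_sagittal(sag)
  expect_identical(unclass(back)[, , ], vol[, , ])
  expect_equal(sort(as.vector(sag)), sort(as.vector(vol)))
  expect_error(reslice_sagittal(vol, 17), "exceeds")
  few <- reslice_sagittal(vol, 4)
  expect_equal(dim(few)[3], 4)
})
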