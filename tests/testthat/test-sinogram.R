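geom_small <- scan_geometry(-50, 50, 5, detector_size = 64)

test_that("analytic disk sinogram has the exact central chord and support", {
  geom <- scan_geometry(-50, 50, 10, detector_size = 129)
  sec <- disk_sections(r = 20, intensity = 0.5)
  sino <- analytic_sinogram(sec, geom)
  u <- laxm:::geom_u(geom)
  centre <- which(abs(u) < 1e-9)
  expect_equal(sino$values[, centre], rep(2 * 20 * 0.5, geom$n_angles))
  expect_true(all(sino$values[, abs(u) >= 20] == 0))
})

test_that("analytic ellipse values match dense numerical line integration", {
  geom <- scan_geometry(-50, 50, 25, detector_size = 32)
  sec <- data.frame(cx = 3.2, cy = -4.1, A = 11, B = 5, phi = 0.7,
                    intensity = 0.8)
  attr(sec, "voxel_pitch") <- 21.9
  sino <- analytic_sinogram(sec, geom)
  th <- laxm:::geom_angles_rad(geom)
  u <- laxm:::geom_u(geom)
  # midpoint-rule quadrature of the membership function along each ray
  tt <- seq(-16, 16, length.out = 2e5)
  dt <- tt[2] - tt[1]
  for (k in seq_along(th)) {
    for (m in seq(4, 28, by = 6)) {
      x <- u[m] * cos(th[k]) - tt * sin(th[k])
      y <- u[m] * sin(th[k]) + tt * cos(th[k])
      uu <- cos(sec$phi) * (x - sec$cx) + sin(sec$phi) * (y - sec$cy)
      vv <- -sin(sec$phi) * (x - sec$cx) + cos(sec$phi) * (y - sec$cy)
      oracle <- 0.8 * sum((uu / 11)^2 + (vv / 5)^2 <= 1) * dt
      if (oracle > 0.05 * max(sino$values))
        expect_lt(abs(sino$values[k, m] - oracle) / oracle, 1e-3)
      else
        expect_lt(abs(sino$values[k, m] - oracle), 1e-3 * max(sino$values))
    }
  }
})

test_that("analytic sinogram is linear in intensities and rejects degenerate ellipses", {
  geom <- geom_small
  s1 <- disk_sections(10, 0.3)
  s2 <- disk_sections(15, 0.2, cx = 5)
  both <- rbind(s1, s2)
  attr(both, "voxel_pitch") <- 21.9
  expect_equal(analytic_sinogram(both, geom)$values,
               analytic_sinogram(s1, geom)$values +
                 analytic_sinogram(s2, geom)$values)
  bad <- disk_sections(10, 1)
  bad$A <- 0
  expect_error(analytic_sinogram(bad, geom), "degenerate")
})

test_that("discrete projector is linear and vanishes on the zero image", {
  geom <- geom_small
  zero <- matrix(0, 64, 64)
  expect_true(all(discrete_sinogram(zero, geom)$values == 0))
  set.seed(2)
  a <- matrix(runif(64 * 64), 64, 64)
  b <- matrix(runif(64 * 64), 64, 64)
  lhs <- discrete_sinogram(2 * a - 3 * b, geom)$values
  rhs <- 2 * discrete_sinogram(a, geom)$values -
    3 * discrete_sinogram(b, geom)$values
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("discrete projector conserves mass across angles for interior objects", {
  geom <- geom_small
  sec <- disk_sections(12, 0.7, cx = 4, cy = -3)
  img <- raster_sections(sec, 64, 1)
  sino <- discrete_sinogram(img, geom)
  mass <- rowSums(sino$values)      # detector spacing is 1 pixel unit
  expect_lt(max(abs(mass - mean(mass))) / mean(mass), 1e-3)
})

test_that("discrete projector reproduces the analytic sinogram of a smooth ellipse", {
  # soft-edged rotated anisotropic ellipse: nested shells with a ramped edge
  geom <- scan_geometry(-50, 50, 2, detector_size = 128)
  K <- 12; w <- 6
  sec <- data.frame(cx = 5, cy = -3,
                    A = 38 + (seq_len(K) - (K + 1) / 2) / K * w,
                    B = 22 + (seq_len(K) - (K + 1) / 2) / K * w,
                    phi = 0.4, intensity = 1 / K)
  attr(sec, "voxel_pitch") <- 21.9
  ana <- analytic_sinogram(sec, geom)$values
  img <- raster_sections(sec, 128, 1)
  d <- discrete_sinogram(img, geom)$values
  expect_lt(max(abs(d - ana)) / max(ana), 0.01)
})

test_that("rotating the image shifts the angle grid by one step", {
  geom <- scan_geometry(-50, 50, 1, detector_size = 64)
  sec <- data.frame(cx = 4, cy = 2, A = 16, B = 9, phi = 0.9, intensity = 1)
  img <- raster_sections(sec, 64, 1)
  orig <- discrete_sinogram(img, geom)$values
  rot <- discrete_sinogram(rotate_image(img, 1), geom)$values
  # p_rot(theta) = p(theta - step): compare shifted interior rows
  diff <- rot[2:101, 10:55] - orig[1:100, 10:55]
  expect_lt(max(abs(diff)) / max(orig), 0.05)
})

test_that("Poisson corruption matches the delta-method mean and variance", {
  p <- matrix(0, 200, 500)
  noisy <- corrupt(p, noise_model(1e4, seed = 31))
  se <- sqrt(exp(0) / 1e4 / length(p))
  # second-order delta method: E[ln(N0/I)] - p ~ 1/(2 lambda)
  bias <- 1 / (2 * 1e4)
  expect_lt(abs(mean(noisy) - bias), 3 * se)
  p2 <- matrix(0.8, 200, 500)
  noisy2 <- corrupt(p2, noise_model(1e4, seed = 32))
  v_pred <- exp(0.8) / 1e4
  expect_lt(abs(var(as.vector(noisy2)) - v_pred) / v_pred, 0.1)
})

test_that("corruption is seeded, near-exact at huge dose, and rejects negatives", {
  p <- matrix(runif(512), 8, 64)
  a <- corrupt(p, noise_model(1e4, seed = 4))
  b <- corrupt(p, noise_model(1e4, seed = 4))
  c <- corrupt(p, noise_model(1e4, seed = 5))
  expect_identical(a, b)
  expect_false(identical(a, c))
  clean <- corrupt(p, noise_model(1e12, seed = 1))
  expect_lt(max(abs(clean - p)), 1e-4)
  expect_error(corrupt(p - 2, noise_model(1e4, 1)), "non-negative")
})

test_that("projection stacks hold one sinogram per slice with stable geometry", {
  ph <- generate_phantom(phantom_spec(grid_size = 32, seed = 21))
  geom <- scan_geometry(-50, 50, 10, detector_size = 32)
  stack <- project_phantom(ph, geom, z_indices = c(10, 16, 22))
  expect_equal(dim(stack), c(geom$n_angles, 3, 32))
  direct <- analytic_sinogram(ellipse_cross_sections(ph, 16), geom)
  expect_equal(stack[, 2, ], direct$values)
})
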