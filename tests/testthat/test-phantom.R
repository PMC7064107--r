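test_that("default spec draws the prescribed ellipsoid census", {
  spec <- phantom_spec(grid_size = 64, seed = 3)
  ph <- generate_phantom(spec)
  counts <- table(ph$ellipsoids$category)
  expect_equal(unname(counts[["outer"]]), 2)
  expect_equal(unname(counts[["chloroplast"]]), 2)
  expect_equal(unname(counts[["lipid"]]), 20)
  expect_equal(unname(counts[["gold"]]), 50)
  gold <- ph$ellipsoids$intensity[ph$ellipsoids$category == "gold"]
  rest <- ph$ellipsoids$intensity[ph$ellipsoids$category != "gold"]
  expect_gt(min(gold), max(rest))
  expect_true(all(ph$ellipsoids[, c("ax", "ay", "az")] > 0))
})

test_that("interior ellipsoids lie inside the outer boundary union", {
  ph <- generate_phantom(phantom_spec(grid_size = 128, seed = 5))
  es <- ph$ellipsoids
  outer <- es[es$category == "outer", ]
  inner <- es[es$category %in% c("lipid", "gold"), ]
  for (i in seq_len(nrow(inner))) {
    centre <- as.numeric(inner[i, c("cx", "cy", "cz")])
    inside <- FALSE
    for (j in seq_len(nrow(outer))) {
      M <- laxm:::ellipsoid_quadric(outer[j, ])
      d <- centre - as.numeric(outer[j, c("cx", "cy", "cz")])
      if (drop(t(d) %*% M %*% d) <= 1) inside <- TRUE
    }
    expect_true(inside, info = sprintf("ellipsoid %d centre outside", i))
  }
})

test_that("empty phantom evaluates to pure background inside the slab", {
  spec <- phantom_spec(grid_size = 64,
                       counts = c(outer = 0, chloroplast = 0, lipid = 0, gold = 0),
                       seed = 1)
  ph <- generate_phantom(spec)
  expect_equal(nrow(ph$ellipsoids), 0)
  inside <- rbind(c(0, 0, 0), c(20, -20, 10), c(-40, 40, -5))
  expect_equal(evaluate_phantom(ph, inside),
               rep(spec$background_intensity, 3))
  outside <- rbind(c(spec$background_extent + 1, 0, 0),
                   c(0, -(spec$background_extent + 1), 0))
  expect_equal(evaluate_phantom(ph, outside), c(0, 0))
})

test_that("phantom generation is a pure function of its seed", {
  a <- generate_phantom(phantom_spec(grid_size = 64, seed = 7))
  b <- generate_phantom(phantom_spec(grid_size = 64, seed = 7))
  c <- generate_phantom(phantom_spec(grid_size = 64, seed = 8))
  expect_identical(a$ellipsoids, b$ellipsoids)
  expect_false(isTRUE(all.equal(a$ellipsoids, c$ellipsoids)))
})

test_that("impossible interior placement fails naming the category", {
  spec <- phantom_spec(grid_size = 64,
                       counts = c(outer = 0, chloroplast = 0, lipid = 1, gold = 0),
                       seed = 1)
  expect_error(generate_phantom(spec), "lipid")
})

test_that("phantom evaluation is additive over containing ellipsoids", {
  ph <- generate_phantom(phantom_spec(grid_size = 64, seed = 12))
  set.seed(1)
  pts <- matrix(runif(300, -30, 30), ncol = 3)
  vals <- evaluate_phantom(ph, pts)
  manual <- rep(ph$spec$background_intensity, nrow(pts))
  for (i in seq_len(nrow(ph$ellipsoids))) {
    e <- ph$ellipsoids[i, ]
    M <- laxm:::ellipsoid_quadric(e)
    d <- sweep(pts, 2, c(e$cx, e$cy, e$cz))
    manual <- manual + e$intensity * (rowSums((d %*% M) * d) <= 1)
  }
  expect_equal(vals, manual)
})

test_that("slicing a sphere gives the analytic disk, and misses beyond it", {
  ph <- single_ellipsoid_phantom(grid = 64, ax = 10, ay = 10, az = 10,
                                 cz = 4, intensity = 0.01)
  z_centre <- 4 + (64 + 1) / 2          # z index whose plane passes the centre
  sl <- slice_phantom(ph, z_centre, 64)
  cc <- laxm:::centred_coords(64)
  rr <- outer(cc, cc, function(x, y) sqrt(x^2 + y^2))
  expect_equal(unclass(sl), 0.01 * (rr <= 10), ignore_attr = TRUE)
  empty <- slice_phantom(ph, z_centre + 11, 64)
  expect_true(all(empty == 0))
  expect_error(slice_phantom(ph, 0, 64), "out of range")
})

test_that("slices of a rotated ellipsoid match the 3D quadric membership", {
  ph <- single_ellipsoid_phantom(grid = 64, ax = 22, ay = 11, az = 7,
                                 cx = 3, cy = -5, cz = 2,
                                 rx = 0.4, ry = 1.1, rz = 2.2,
                                 intensity = 0.013)
  for (z_index in c(25, 33, 40)) {
    sl <- slice_phantom(ph, z_index, 64)
    z <- z_index - (64 + 1) / 2
    cc <- laxm:::centred_coords(64)
    pts <- cbind(rep(cc, times = 64), rep(cc, each = 64), z)
    oracle <- matrix(evaluate_phantom(ph, pts), 64, 64)
    expect_equal(unclass(sl), oracle, ignore_attr = TRUE)
  }
})

test_that("surrogate texture images honour count, range and seed", {
  imgs <- surrogate_texture_images(5, size = 32, seed = 9, range = c(0, 0.018))
  expect_length(imgs, 5)
  for (im in imgs) {
    expect_equal(dim(im), c(32, 32))
    expect_gte(min(im), 0)
    expect_lte(max(im), 0.018 + 1e-12)
  }
  expect_length(surrogate_texture_images(0, 32, 1), 0)
  again <- surrogate_texture_images(5, size = 32, seed = 9, range = c(0, 0.018))
  expect_identical(lapply(imgs, unclass), lapply(again, unclass))
  other <- surrogate_texture_images(5, size = 32, seed = 10, range = c(0, 0.018))
  expect_false(identical(unclass(imgs[[1]]), unclass(other[[1]])))
})

test_that("rotation augmentation is an exact, ordered pixel permutation", {
  imgs <- surrogate_texture_images(3, size = 16, seed = 2)
  aug <- augment_rotations(imgs)
  expect_length(aug, 12)
  expect_identical(unclass(aug[[1]]), unclass(imgs[[1]]))
  # rotating twice by 90 equals the 180 rotation
  r90_twice <- laxm:::rot90_ccw(laxm:::rot90_ccw(unclass(imgs[[2]])))
  r180 <- aug[[3 + 2 + 3]]
  attributes(r180) <- list(dim = dim(r180))
  expect_identical(r90_twice, r180)
  # pixel multiset conserved by every rotation
  for (k in 0:3)
    expect_equal(sort(as.vector(aug[[1 + 3 * k]])),
                 sort(as.vector(imgs[[1]])))
  expect_error(augment_rotations(list(matrix(0, 4, 5))), "square")
})
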