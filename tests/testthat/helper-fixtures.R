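# shared fixtures: all built in code, small enough for fast tests

# a single-ellipsoid phantom with explicit geometry (voxel units)
single_ellipsoid_phantom <- function(grid = 64, ax = 20, ay = 20, az = 20,
                                     cx = 0, cy = 0, cz = 0,
                                     rx = 0, ry = 0, rz = 0,
                                     intensity = 0.01, background = 0) {
  spec <- phantom_spec(grid_size = grid,
                       counts = c(outer = 0, chloroplast = 0, lipid = 0, gold = 0),
                       background_intensity = background, seed = 1)
  phantom_volume(data.frame(category = "outer", cx = cx, cy = cy, cz = cz,
                            ax = ax, ay = ay, az = az, rx = rx, ry = ry,
                            rz = rz, intensity = intensity), spec)
}

# analytic disk cross-section table (detector-pixel units, no background)
disk_sections <- function(r, intensity = 1, cx = 0, cy = 0, pitch = 21.9) {
  sec <- data.frame(cx = cx, cy = cy, A = r, B = r, phi = 0,
                    intensity = intensity)
  attr(sec, "voxel_pitch") <- pitch
  sec
}

# area-antialiased raster of a set of ellipse sections on an n x n grid
# with pixel pitch `pitch_px` detector pixels (supersampled coverage)
raster_sections <- function(sections, n, pitch_px, ns = 8) {
  px <- (seq_len(n) - (n + 1) / 2) * pitch_px
  sub <- (seq_len(ns) - (ns + 1) / 2) / ns * pitch_px
  img <- matrix(0, n, n)
  for (dxs in sub) for (dys in sub) {
    X <- matrix(px + dxs, n, n)
    Y <- matrix(px + dys, n, n, byrow = TRUE)
    for (k in seq_len(nrow(sections))) {
      s <- sections[k, ]
      u <- cos(s$phi) * (X - s$cx) + sin(s$phi) * (Y - s$cy)
      v <- -sin(s$phi) * (X - s$cx) + cos(s$phi) * (Y - s$cy)
      img <- img + s$intensity * ((u / s$A)^2 + (v / s$B)^2 <= 1)
    }
  }
  img <- img / ns^2
  attr(img, "pixel_pitch") <- 21.9 * pitch_px
  img
}

# small random training pairs from a seeded toy phantom pipeline
toy_training_pairs <- function(n_slices = 8, size = 32, seed = 11) {
  ph <- generate_phantom(phantom_spec(grid_size = size, seed = seed))
  geom <- scan_geometry(detector_size = size,
                        detector_pitch = 21.9 * 512 / size)
  grid <- fbp_grid(size, geom)
  zs <- phantom_slice_indices(size, n_slices)
  lapply(zs, function(z) {
    sec <- ellipse_cross_sections(ph, z)
    sino <- corrupt(analytic_sinogram(sec, geom), noise_model(1e4, seed + z))
    rec <- fbp_reconstruct(sino, grid)
    ref <- slice_phantom(ph, z, size)
    list(input = unclass(rec), target = unclass(rec) - unclass(ref))
  })
}
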