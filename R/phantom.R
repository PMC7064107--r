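#' Specification of a randomized ellipsoid cell phantom
#'
#' Describes a cryo-immobilized single-cell phantom: two large ellipsoids
#' forming the outer cell boundary, two middle-sized overlapping ellipsoids
#' emulating the cup-shaped chloroplast, small ellipsoids for lipid bodies,
#' and high-intensity small ellipsoids for gold fiducial nanoparticles, all
#' embedded in a constant-intensity "ice" slab wider than the detector
#' field of view (which makes simulated projections laterally truncated).
#'
#' @param grid_size Phantom grid size in voxels per axis.
#' @param counts Named integer vector with categories `outer`, `chloroplast`,
#'   `lipid`, `gold`.
#' @param background_intensity Constant ice background attenuation
#'   (1/micrometre).
#' @param background_extent Half-width of the square ice slab in voxels;
#'   defaults to 1.5x the half-width of the grid.
#' @param intensity_ranges Named list of `(low, high)` additive attenuation
#'   ranges per category (1/micrometre). The gold range must lie strictly
#'   above every other range so gold particles are the brightest features.
#' @param size_fractions Named list of `(low, high)` semi-axis ranges as
#'   fractions of `grid_size`.
#' @param voxel_pitch Voxel pitch in nanometres.
#' @param seed Integer seed controlling all random draws.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_size = 512L,
                         counts = c(outer = 2L, chloroplast = 2L,
                                    lipid = 20L, gold = 50L),
                         background_intensity = 0.002,
                         background_extent = NULL,
                         intensity_ranges = list(
                           outer = c(0.002, 0.005),
                           chloroplast = c(0.004, 0.008),
                           lipid = c(0.006, 0.012),
                           gold = c(0.015, 0.020)),
                         size_fractions = list(
                           outer = c(0.28, 0.42),
                           chloroplast = c(0.12, 0.20),
                           lipid = c(0.02, 0.05),
                           gold = c(0.004, 0.010)),
                         voxel_pitch = 21.9,
                         seed = 1L) {
  cats <- c("outer", "chloroplast", "lipid", "gold")
  if (!all(cats %in% names(counts))) stopf("counts must name %s",
                                           paste(cats, collapse = ", "))
  counts <- counts[cats]
  if (any(counts < 0)) stopf("counts must be non-negative")
  if (background_intensity < 0) stopf("background_intensity must be >= 0")
  for (cat in cats) {
    r <- intensity_ranges[[cat]]
    if (is.null(r) || length(r) != 2 || r[1] > r[2])
      stopf("intensity range for '%s' must be (low, high) with low <= high", cat)
    s <- size_fractions[[cat]]
    if (is.null(s) || length(s) != 2 || s[1] > s[2] || s[1] <= 0)
      stopf("size fractions for '%s' must be positive with low <= high", cat)
  }
  others <- vapply(cats[cats != "gold"], function(cat)
    intensity_ranges[[cat]][2], numeric(1))
  if (counts["gold"] > 0 && any(counts[cats != "gold"] > 0) &&
      intensity_ranges$gold[1] <= max(others))
    stopf("gold intensity range must lie strictly above all other ranges")
  structure(list(
    grid_size = as.integer(grid_size),
    counts = counts,
    background_intensity = background_intensity,
    background_extent = background_extent %||% (0.75 * grid_size),
    intensity_ranges = intensity_ranges,
    size_fractions = size_fractions,
    voxel_pitch = voxel_pitch,
    seed = as.integer(seed)), class = "phantom_spec")
}

# intrinsic rotation matrix Rz(rz) Ry(ry) Rx(rx)
rotation_matrix <- function(rx, ry, rz) {
  cx <- cos(rx); sx <- sin(rx)
  cy <- cos(ry); sy <- sin(ry)
  cz <- cos(rz); sz <- sin(rz)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

# quadric matrix M with membership (x - c)' M (x - c) <= 1
ellipsoid_quadric <- function(e) {
  R <- rotation_matrix(e$rx, e$ry, e$rz)
  R %*% diag(1 / c(e$ax, e$ay, e$az)^2) %*% t(R)
}

#' Construct a phantom volume from an explicit ellipsoid table
#'
#' Lower-level companion of [generate_phantom()] for hand-built phantoms
#' (single spheres, regression fixtures, ...). Ellipsoid geometry is given
#' in voxel units in a coordinate system centred on the grid.
#'
#' @param ellipsoids Data frame with columns `category`, `cx`, `cy`, `cz`,
#'   `ax`, `ay`, `az`, `rx`, `ry`, `rz`, `intensity`.
#' @param spec A [phantom_spec()] providing grid size and background.
#' @return An object of class `phantom_volume`.
#' @export
phantom_volume <- function(ellipsoids, spec) {
  needed <- c("category", "cx", "cy", "cz", "ax", "ay", "az",
              "rx", "ry", "rz", "intensity")
  if (!all(needed %in% names(ellipsoids)))
    stopf("ellipsoid table must have columns %s", paste(needed, collapse = ", "))
  if (nrow(ellipsoids) && any(ellipsoids$ax <= 0 | ellipsoids$ay <= 0 |
                              ellipsoids$az <= 0))
    stopf("all semi-axes must be strictly positive")
  if (nrow(ellipsoids)) check_finite(ellipsoids$intensity, "ellipsoid intensities")
  structure(list(ellipsoids = ellipsoids, spec = spec,
                 voxel_pitch = spec$voxel_pitch),
            class = "phantom_volume")
}

#' Generate a randomized ellipsoid cell phantom
#'
#' Draws ellipsoid locations, sizes, orientations and intensities from the
#' ranges in the spec. Lipid bodies and gold nanoparticles are placed by
#' rejection sampling so that they lie inside the union of the outer
#' boundary ellipsoids; the chloroplast is modelled as overlapping
#' middle-sized ellipsoids. The same seed always reproduces the identical
#' phantom.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_volume`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$grid_size
  with_seed(spec$seed, {
    rows <- list()
    draw <- function(category, center, frac) {
      r <- spec$intensity_ranges[[category]]
      data.frame(category = category,
                 cx = center[1], cy = center[2], cz = center[3],
                 ax = runif(1, frac[1], frac[2]) * g,
                 ay = runif(1, frac[1], frac[2]) * g,
                 az = runif(1, frac[1], frac[2]) * g,
                 rx = runif(1, 0, pi), ry = runif(1, 0, pi),
                 rz = runif(1, 0, pi),
                 intensity = runif(1, r[1], r[2]),
                 stringsAsFactors = FALSE)
    }
    # outer boundary ellipsoids, nearly concentric
    for (i in seq_len(spec$counts[["outer"]]))
      rows[[length(rows) + 1L]] <- draw("outer", runif(3, -0.05, 0.05) * g,
                                        spec$size_fractions$outer)
    outer_rows <- do.call(rbind, rows)
    outer_quadrics <- if (!is.null(outer_rows))
      lapply(seq_len(nrow(outer_rows)), function(i)
        list(M = ellipsoid_quadric(outer_rows[i, ]),
             c = unlist(outer_rows[i, c("cx", "cy", "cz")]),
             amin = min(unlist(outer_rows[i, c("ax", "ay", "az")]))))
    fits_inside <- function(center, radius) {
      if (is.null(outer_quadrics) || !length(outer_quadrics)) return(FALSE)
      for (q in outer_quadrics) {
        d <- center - q$c
        lev <- sqrt(drop(t(d) %*% q$M %*% d))
        if (lev <= max(0, 1 - radius / q$amin)) return(TRUE)
      }
      FALSE
    }
    place_inside <- function(category, frac, attempts = 1000L) {
      for (k in seq_len(attempts)) {
        center <- runif(3, -0.45, 0.45) * g
        e <- draw(category, center, frac)
        if (fits_inside(center, max(e$ax, e$ay, e$az))) return(e)
      }
      stopf("failed to place a '%s' ellipsoid inside the outer boundary after %d attempts",
            category, attempts)
    }
    # chloroplast: overlapping middle-sized pair(s) forming the cup
    prev <- NULL
    for (i in seq_len(spec$counts[["chloroplast"]])) {
      if (i %% 2L == 1L || is.null(prev)) {
        e <- place_inside("chloroplast", spec$size_fractions$chloroplast)
      } else {
        offset <- runif(3, -0.5, 0.5) * unlist(prev[c("ax", "ay", "az")])
        e <- draw("chloroplast",
                  unlist(prev[c("cx", "cy", "cz")]) + offset,
                  spec$size_fractions$chloroplast)
      }
      rows[[length(rows) + 1L]] <- e
      prev <- e
    }
    for (i in seq_len(spec$counts[["lipid"]]))
      rows[[length(rows) + 1L]] <- place_inside("lipid", spec$size_fractions$lipid)
    for (i in seq_len(spec$counts[["gold"]]))
      rows[[length(rows) + 1L]] <- place_inside("gold", spec$size_fractions$gold)
    ellipsoids <- if (length(rows)) do.call(rbind, rows) else
      data.frame(category = character(), cx = numeric(), cy = numeric(),
                 cz = numeric(), ax = numeric(), ay = numeric(),
                 az = numeric(), rx = numeric(), ry = numeric(),
                 rz = numeric(), intensity = numeric())
    phantom_volume(ellipsoids, spec)
  })
}

#' Evaluate the phantom attenuation function at arbitrary points
#'
#' Returns the analytic attenuation value at each point: the constant ice
#' background (inside the slab) plus the sum of the intensities of all
#' ellipsoids containing the point. Outside the slab the value is zero
#' except where an ellipsoid reaches.
#'
#' @param phantom A `phantom_volume`.
#' @param points Numeric matrix (n x 3) of voxel coordinates relative to the
#'   grid centre.
#' @return Numeric vector of attenuation values (1/micrometre).
#' @export
evaluate_phantom <- function(phantom, points) {
  stopifnot(inherits(phantom, "phantom_volume"))
  points <- matrix(points, ncol = 3)
  E <- phantom$spec$background_extent
  val <- phantom$spec$background_intensity *
    (abs(points[, 1]) <= E & abs(points[, 2]) <= E)
  es <- phantom$ellipsoids
  for (i in seq_len(nrow(es))) {
    e <- es[i, ]
    M <- ellipsoid_quadric(e)
    d <- sweep(points, 2, c(e$cx, e$cy, e$cz))
    q <- rowSums((d %*% M) * d)
    val <- val + e$intensity * (q <= 1)
  }
  val
}

#' Ellipse cross-sections of a phantom at one z-plane
#'
#' Intersects every ellipsoid with the horizontal plane of a given z index
#' and returns the resulting 2D ellipses (closed form, no voxelization).
#' Used by the analytic projector and the analytic slice renderer.
#'
#' @param phantom A `phantom_volume`.
#' @param z_index Slice index, 1-based in `1..grid_size`.
#' @return Data frame with columns `cx`, `cy` (voxel), `A`, `B` (semi-axes,
#'   voxel, `A` major), `phi` (major-axis angle, radians), `intensity`;
#'   attributes `background` (list with `intensity`, `extent`) and
#'   `voxel_pitch`.
#' @export
ellipse_cross_sections <- function(phantom, z_index) {
  stopifnot(inherits(phantom, "phantom_volume"))
  g <- phantom$spec$grid_size
  if (z_index < 1 || z_index > g) stopf("z_index %s out of range 1..%d", z_index, g)
  z <- z_index - (g + 1) / 2
  es <- phantom$ellipsoids
  out <- list()
  for (i in seq_len(nrow(es))) {
    e <- es[i, ]
    M <- ellipsoid_quadric(e)
    Q <- M[1:2, 1:2]
    m <- M[1:2, 3]
    mu <- M[3, 3]
    dz <- z - e$cz
    Qi <- solve(Q)
    k <- 1 - dz^2 * (mu - drop(t(m) %*% Qi %*% m))
    if (k <= 1e-12) next
    ctr <- c(e$cx, e$cy) - dz * drop(Qi %*% m)
    eg <- eigen(Q, symmetric = TRUE)
    out[[length(out) + 1L]] <- data.frame(
      cx = ctr[1], cy = ctr[2],
      A = sqrt(k / eg$values[2]), B = sqrt(k / eg$values[1]),
      phi = atan2(eg$vectors[2, 2], eg$vectors[1, 2]),
      intensity = e$intensity)
  }
  df <- if (length(out)) do.call(rbind, out) else
    data.frame(cx = numeric(), cy = numeric(), A = numeric(), B = numeric(),
               phi = numeric(), intensity = numeric())
  attr(df, "background") <- list(intensity = phantom$spec$background_intensity,
                                 extent = phantom$spec$background_extent)
  attr(df, "voxel_pitch") <- phantom$voxel_pitch
  df
}

#' Construct a slice image
#'
#' @param pixels Numeric matrix of attenuation values (1/micrometre).
#' @param pixel_pitch Pixel pitch in nanometres.
#' @param fov_radius Field-of-view radius in pixels.
#' @return The matrix with class `slice_image` and metadata attributes.
#' @export
slice_image <- function(pixels, pixel_pitch, fov_radius = min(dim(pixels)) / 2) {
  check_finite(pixels, "slice image")
  if (fov_radius > min(dim(pixels)) / 2 + 1e-9)
    stopf("fov_radius exceeds half the grid width")
  structure(pixels, pixel_pitch = pixel_pitch, fov_radius = fov_radius,
            class = c("slice_image", "matrix", "array"))
}

#' Analytic horizontal slice of a phantom
#'
#' Evaluates the phantom attenuation on the plane of `z_index`, sampled on
#' an `out_size` x `out_size` grid spanning the full phantom extent. The
#' evaluation is exact point-in-quadric arithmetic, not voxel interpolation.
#'
#' @param phantom A `phantom_volume`.
#' @param z_index Slice index, 1-based.
#' @param out_size Output grid size in pixels.
#' @return A [slice_image()].
#' @export
slice_phantom <- function(phantom, z_index, out_size = phantom$spec$grid_size) {
  sections <- ellipse_cross_sections(phantom, z_index)
  g <- phantom$spec$grid_size
  step <- g / out_size
  cc <- centred_coords(out_size, step)
  X <- matrix(cc, out_size, out_size)
  Y <- matrix(cc, out_size, out_size, byrow = TRUE)
  bg <- attr(sections, "background")
  img <- bg$intensity * ((abs(X) <= bg$extent) & (abs(Y) <= bg$extent))
  for (i in seq_len(nrow(sections))) {
    s <- sections[i, ]
    u <- cos(s$phi) * (X - s$cx) + sin(s$phi) * (Y - s$cy)
    v <- -sin(s$phi) * (X - s$cx) + cos(s$phi) * (Y - s$cy)
    img <- img + s$intensity * ((u / s$A)^2 + (v / s$B)^2 <= 1)
  }
  slice_image(img, pixel_pitch = phantom$voxel_pitch * step,
              fov_radius = out_size / 2)
}

#' Uniformly spaced training-slice indices
#'
#' Selects `n` z-indices uniformly over the central 80 percent of the grid,
#' avoiding near-empty top and bottom slabs.
#'
#' @param grid_size Phantom grid size.
#' @param n Number of slices.
#' @return Integer vector of z indices.
#' @export
phantom_slice_indices <- function(grid_size, n = 20L) {
  unique(round(seq(0.1 * grid_size, 0.9 * grid_size, length.out = n)))
}

#' Procedural stand-in for multi-category training images
#'
#' Generates structured grayscale images (smooth gradients, overlapping
#' random ellipses and rectangles, fine blurred-noise texture) rescaled to
#' an attenuation range. These act as generic structural content for
#' network training when no curated image collection is available; see
#' [load_gray_images()] for substituting real images.
#'
#' @param n Number of images.
#' @param size Image size in pixels.
#' @param seed Integer seed.
#' @param range Attenuation range `(low, high)` in 1/micrometre the images
#'   are rescaled to.
#' @param pixel_pitch Pixel pitch in nanometres recorded on each image.
#' @return List of [slice_image()]s.
#' @export
surrogate_texture_images <- function(n, size = 512L, seed = 1L,
                                     range = c(0, 0.018),
                                     pixel_pitch = 21.9) {
  if (n < 0) stopf("n must be >= 0")
  if (n == 0) return(list())
  cc <- seq(-1, 1, length.out = size)
  X <- matrix(cc, size, size)
  Y <- matrix(cc, size, size, byrow = TRUE)
  with_seed(seed, lapply(seq_len(n), function(i) {
    co <- rnorm(6)
    grad <- co[1] + co[2] * X + co[3] * Y + co[4] * X * Y +
      co[5] * X^2 + co[6] * Y^2
    shapes <- matrix(0, size, size)
    for (k in seq_len(sample(5:15, 1))) {
      ctr <- runif(2, -0.8, 0.8)
      ab <- runif(2, 0.05, 0.45)
      phi <- runif(1, 0, pi)
      u <- cos(phi) * (X - ctr[1]) + sin(phi) * (Y - ctr[2])
      v <- -sin(phi) * (X - ctr[1]) + cos(phi) * (Y - ctr[2])
      shapes <- shapes + runif(1, -1, 1) * ((u / ab[1])^2 + (v / ab[2])^2 <= 1)
    }
    for (k in seq_len(sample(3:8, 1))) {
      ctr <- runif(2, -0.8, 0.8)
      hw <- runif(2, 0.05, 0.35)
      shapes <- shapes + runif(1, -1, 1) *
        (abs(X - ctr[1]) <= hw[1]) * (abs(Y - ctr[2]) <= hw[2])
    }
    tex <- gaussian_blur(matrix(rnorm(size * size), size, size),
                         sigma = runif(1, 1, 3))
    img <- runif(1, 0.5, 1.5) * grad + runif(1, 0.5, 1.5) * shapes +
      runif(1, 2, 6) * tex
    lo <- min(img); hi <- max(img)
    img <- range[1] + (img - lo) / (hi - lo) * (range[2] - range[1])
    slice_image(img, pixel_pitch = pixel_pitch, fov_radius = size / 2)
  }))
}

#' Quarter-turn rotation augmentation
#'
#' Expands an image list with its 90, 180 and 270 degree rotations (exact
#' pixel permutations), ordered as originals, then 90, 180, 270.
#'
#' @param images List of square matrices / [slice_image()]s.
#' @return List of length `4 * length(images)`.
#' @export
augment_rotations <- function(images) {
  if (!length(images)) return(list())
  for (im in images) if (nrow(im) != ncol(im)) stopf("images must be square")
  rot_k <- function(im, k) {
    out <- unclass(im)
    for (i in seq_len(k)) out <- rot90_ccw(out)
    attributes(out) <- c(attributes(out),
                         attributes(im)[c("pixel_pitch", "fov_radius")])
    class(out) <- class(im)
    out
  }
  c(images,
    lapply(images, rot_k, k = 1L),
    lapply(images, rot_k, k = 2L),
    lapply(images, rot_k, k = 3L))
}

#' Load user-supplied grayscale images as attenuation maps
#'
#' Reads TIFF or PNG images, converts colour to luminance, and rescales each
#' image to the given attenuation range. This lets real image collections
#' (optical microscopy, CT, ...) take the role of the procedural surrogate
#' images in corpus building.
#'
#' @param paths Character vector of file paths (.tif/.tiff/.png).
#' @param range Attenuation range `(low, high)` in 1/micrometre.
#' @param pixel_pitch Pixel pitch in nanometres recorded on each image.
#' @return List of [slice_image()]s.
#' @export
load_gray_images <- function(paths, range = c(0, 0.018), pixel_pitch = 21.9) {
  lapply(paths, function(p) {
    ext <- tolower(tools::file_ext(p))
    img <- switch(ext,
                  tif = , tiff = tiff::readTIFF(p),
                  png = png::readPNG(p),
                  stopf("unsupported image format: %s", p))
    if (length(dim(img)) == 3)
      img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    lo <- min(img); hi <- max(img)
    if (hi > lo) img <- (img - lo) / (hi - lo)
    slice_image(range[1] + img * (range[2] - range[1]),
                pixel_pitch = pixel_pitch,
                fov_radius = min(dim(img)) / 2)
  })
}
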