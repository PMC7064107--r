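#' Parallel-beam scan geometry
#'
#' Limited-angle parallel-beam geometry: an inclusive arithmetic grid of
#' sample rotation angles and a centred linear detector. The rotation axis
#' is z, so the 3D scan decouples into independent 2D slice problems.
#'
#' @param theta_start,theta_end First and last rotation angle (degrees).
#' @param angular_step Angular step (degrees).
#' @param detector_size Number of detector pixels.
#' @param detector_pitch Detector pixel pitch (nanometres).
#' @return An object of class `scan_geometry`.
#' @export
scan_geometry <- function(theta_start = -50, theta_end = 50, angular_step = 1,
                          detector_size = 512L, detector_pitch = 21.9) {
  if (theta_start >= theta_end) stopf("theta_start must be < theta_end")
  if (angular_step <= 0) stopf("angular_step must be > 0")
  if (detector_size <= 0) stopf("detector_size must be > 0")
  angles <- seq(theta_start, theta_end, by = angular_step)
  structure(list(theta_start = theta_start, theta_end = theta_end,
                 angular_step = angular_step,
                 detector_size = as.integer(detector_size),
                 detector_pitch = detector_pitch,
                 angles_deg = angles, n_angles = length(angles)),
            class = "scan_geometry")
}

geom_angles_rad <- function(geometry) geometry$angles_deg * pi / 180

# detector coordinates in detector-pixel units, u = 0 on the rotation axis.
# All line integrals use the detector pitch as the unit of length, so p =
# integral of f (1/um) over length in pixel units; FBP with the same unit
# returns f in 1/um. (Physical micrometre lengths at nanometre pitches
# would make soft-matter phantoms nearly transparent; see the vignette.)
geom_u <- function(geometry) centred_coords(geometry$detector_size, 1)

#' Construct a sinogram
#'
#' @param values Matrix of log-transformed line integrals, shape
#'   `(n_angles, detector_size)`.
#' @param geometry A [scan_geometry()].
#' @param z_index Optional slice index the sinogram belongs to.
#' @return Object of class `sinogram`.
#' @export
sinogram <- function(values, geometry, z_index = NA_integer_) {
  if (nrow(values) != geometry$n_angles ||
      ncol(values) != geometry$detector_size)
    stopf("sinogram shape (%d, %d) does not match geometry (%d, %d)",
          nrow(values), ncol(values), geometry$n_angles, geometry$detector_size)
  check_finite(values, "sinogram")
  structure(list(values = values, geometry = geometry, z_index = z_index),
            class = "sinogram")
}

# chord length of the ray (theta, u) through the axis-aligned square
# [-E, E]^2; theta scalar (radians), u vector (same units as E)
square_chord <- function(theta, u, E) {
  c0 <- cos(theta); s0 <- sin(theta)
  lo <- rep(-Inf, length(u)); hi <- rep(Inf, length(u))
  # x(t) = u c - t s in [-E, E]
  if (abs(s0) > 1e-12) {
    t1 <- (u * c0 - E) / s0; t2 <- (u * c0 + E) / s0
    lo <- pmax(lo, pmin(t1, t2)); hi <- pmin(hi, pmax(t1, t2))
  } else {
    miss <- abs(u * c0) > E
    hi[miss] <- lo[miss]
  }
  # y(t) = u s + t c in [-E, E]
  if (abs(c0) > 1e-12) {
    t1 <- (-E - u * s0) / c0; t2 <- (E - u * s0) / c0
    lo <- pmax(lo, pmin(t1, t2)); hi <- pmin(hi, pmax(t1, t2))
  } else {
    miss <- abs(u * s0) > E
    hi[miss] <- lo[miss]
  }
  pmax(0, hi - lo)
}

#' Closed-form sinogram of the background ice slab
#'
#' Line integrals of a constant-intensity square slab of half-width
#' `halfwidth`, optionally with the central square of half-width
#' `inner_halfwidth` removed (used to add the part of the slab outside a
#' rendered image footprint to a discretely projected sinogram).
#'
#' @param geometry A [scan_geometry()].
#' @param halfwidth Outer half-width of the slab (detector-pixel units).
#' @param intensity Slab attenuation (1/micrometre).
#' @param inner_halfwidth Half-width of the removed core (detector pixels).
#' @return A [sinogram()].
#' @export
slab_sinogram <- function(geometry, halfwidth, intensity,
                          inner_halfwidth = 0) {
  th <- geom_angles_rad(geometry)
  u <- geom_u(geometry)
  vals <- t(vapply(th, function(a) {
    ch <- square_chord(a, u, halfwidth)
    if (inner_halfwidth > 0)
      ch <- ch - square_chord(a, u, inner_halfwidth)
    intensity * ch
  }, numeric(length(u))))
  sinogram(vals, geometry)
}

#' Analytic sinogram of ellipse cross-sections plus background slab
#'
#' Computes each line integral in closed form: the chord of the ray through
#' every ellipse (classic ellipse Radon transform) plus the chord through
#' the square ice slab, all scaled by the respective attenuation. The result
#' is exactly linear in the intensities.
#'
#' @param sections Ellipse table from [ellipse_cross_sections()], or any
#'   data frame with columns `cx`, `cy`, `A`, `B`, `phi`, `intensity` (voxel
#'   units) and attributes `voxel_pitch` (nm) and optionally `background`.
#' @param geometry A [scan_geometry()].
#' @param z_index Optional slice index stored on the result.
#' @return A [sinogram()].
#' @export
analytic_sinogram <- function(sections, geometry, z_index = NA_integer_) {
  pitch <- attr(sections, "voxel_pitch") %||% geometry$detector_pitch
  pitch_px <- pitch / geometry$detector_pitch
  if (nrow(sections) && any(sections$A <= 0 | sections$B <= 0))
    stopf("degenerate ellipse: semi-axes must be strictly positive")
  check_finite(as.matrix(sections[, c("cx", "cy", "A", "B", "phi",
                                      "intensity")]), "ellipse parameters")
  th <- geom_angles_rad(geometry)
  u <- geom_u(geometry)
  vals <- matrix(0, length(th), length(u))
  for (i in seq_len(nrow(sections))) {
    s <- sections[i, ]
    A <- s$A * pitch_px; B <- s$B * pitch_px
    cx <- s$cx * pitch_px; cy <- s$cy * pitch_px
    a2 <- A^2 * cos(th - s$phi)^2 + B^2 * sin(th - s$phi)^2
    sc <- outer(cos(th) * cx + sin(th) * cy, rep(1, length(u)))
    su <- outer(rep(1, length(th)), u) - sc
    vals <- vals + s$intensity * 2 * A * B *
      sqrt(pmax(0, a2 - su^2)) / a2
  }
  bg <- attr(sections, "background")
  if (!is.null(bg) && bg$intensity > 0) {
    E <- bg$extent * pitch_px
    for (k in seq_along(th))
      vals[k, ] <- vals[k, ] + bg$intensity * square_chord(th[k], u, E)
  }
  sinogram(vals, geometry, z_index)
}

#' Discrete sinogram of a slice image
#'
#' Ray-driven projection of a pixel image: each line integral is the sum of
#' bilinearly interpolated image samples along the ray, times the sampling
#' step. The operator is linear in the image.
#'
#' @param image Square matrix / [slice_image()]; attribute `pixel_pitch`
#'   (nm) defaults to the detector pitch.
#' @param geometry A [scan_geometry()].
#' @param z_index Optional slice index stored on the result.
#' @return A [sinogram()].
#' @export
discrete_sinogram <- function(image, geometry, z_index = NA_integer_) {
  if (nrow(image) != ncol(image)) stopf("image must be square")
  pitch_px <- (attr(image, "pixel_pitch") %||% geometry$detector_pitch) /
    geometry$detector_pitch
  vals <- cpp_forward_project(unclass(image), pitch_px,
                              geom_angles_rad(geometry), geom_u(geometry),
                              step = pitch_px)
  sinogram(vals, geometry, z_index)
}

#' Rotate an image about its centre (bilinear interpolation)
#'
#' Positive angles rotate the image content counter-clockwise in the (x, y)
#' frame, so the projection of the rotated image at angle `theta` equals
#' the original projection at `theta - angle`.
#'
#' @param image Matrix.
#' @param angle_deg Rotation angle in degrees.
#' @return Matrix of the same size.
#' @export
rotate_image <- function(image, angle_deg) {
  cpp_rotate_image(unclass(image), angle_deg * pi / 180)
}

#' Poisson noise model for transmission measurements
#'
#' @param n0 Incident photon count per detector pixel before attenuation.
#' @param seed Integer seed.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(n0 = 1e4, seed = 1L) {
  if (n0 <= 0) stopf("photon count must be > 0")
  structure(list(n0 = n0, seed = as.integer(seed)), class = "noise_model")
}

#' Corrupt line integrals with Poisson counting noise
#'
#' Simulates transmission counts `I ~ Poisson(N0 exp(-p))` for each ray and
#' returns the log-transformed measurement `log(N0 / max(I, 1))` (counts of
#' zero are clamped to one photon before the log). Deterministic under the
#' noise model's seed.
#'
#' @param x A [sinogram()], matrix or array of non-negative line integrals.
#' @param noise A [noise_model()].
#' @return Same type as `x`, with noisy values.
#' @export
corrupt <- function(x, noise) {
  stopifnot(inherits(noise, "noise_model"))
  vals <- if (inherits(x, "sinogram")) x$values else x
  if (any(vals < -1e-9)) stopf("line integrals must be non-negative")
  vals[vals < 0] <- 0
  noisy <- with_seed(noise$seed, {
    counts <- rpois(length(vals), noise$n0 * exp(-as.vector(vals)))
    log(noise$n0 / pmax(counts, 1))
  })
  out <- vals
  out[] <- noisy
  if (inherits(x, "sinogram")) sinogram(out, x$geometry, x$z_index) else out
}

#' Analytic projection stack of a phantom
#'
#' Simulates the full scan: one analytic sinogram per selected z slice,
#' assembled into an array shaped `(angle, v, u)` where the detector row v
#' corresponds to the slice.
#'
#' @param phantom A `phantom_volume`.
#' @param geometry A [scan_geometry()].
#' @param z_indices Slice indices (default: all rows of the grid).
#' @return Array of class `projection_stack` with attributes `geometry` and
#'   `z_indices`.
#' @export
project_phantom <- function(phantom, geometry,
                            z_indices = seq_len(phantom$spec$grid_size)) {
  stack <- array(0, c(geometry$n_angles, length(z_indices),
                      geometry$detector_size))
  for (j in seq_along(z_indices)) {
    sec <- ellipse_cross_sections(phantom, z_indices[j])
    stack[, j, ] <- analytic_sinogram(sec, geometry)$values
  }
  structure(stack, geometry = geometry, z_indices = z_indices,
            class = c("projection_stack", "array"))
}
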