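#' Reconstruction grid for filtered back-projection
#'
#' Output raster covering the same lateral extent as the detector: the
#' pixel pitch is `detector_pitch * detector_size / out_size`, and metrics
#' use the inscribed circle of radius `out_size / 2` as the field of view.
#'
#' @param out_size Output image size in pixels.
#' @param geometry A [scan_geometry()].
#' @return Object of class `fbp_grid`.
#' @export
fbp_grid <- function(out_size = 256L, geometry = scan_geometry()) {
  if (out_size <= 0) stopf("out_size must be > 0")
  structure(list(out_size = as.integer(out_size),
                 out_pitch = geometry$detector_pitch *
                   geometry$detector_size / out_size,
                 fov_radius = out_size / 2),
            class = "fbp_grid")
}

#' Spatial-domain Ram-Lak filter taps
#'
#' The standard discretization of the ramp filter: centre tap `1/(4 d^2)`,
#' odd offsets `-1/(pi^2 n^2 d^2)`, even non-zero offsets exactly zero,
#' where `d` is the detector pitch.
#'
#' @param n_taps Odd number of taps.
#' @param pitch Detector pitch `d` (any length unit; output scales as
#'   1/pitch^2).
#' @return Numeric vector of length `n_taps`, centre at `(n_taps + 1) / 2`.
#' @export
ramlak_kernel <- function(n_taps, pitch = 1) {
  if (n_taps %% 2 == 0) stopf("n_taps must be odd")
  half <- (n_taps - 1) / 2
  n <- seq(-half, half)
  taps <- numeric(n_taps)
  taps[n == 0] <- 1 / (4 * pitch^2)
  odd <- n %% 2 != 0
  taps[odd] <- -1 / (pi^2 * n[odd]^2 * pitch^2)
  taps
}

#' Ramp-filter a sinogram
#'
#' Convolves every detector row with the Ram-Lak kernel at native detector
#' resolution, zero-padding to the next power of two of at least twice the
#' row length to suppress circular wrap-around. The discrete convolution is
#' scaled by the detector pitch so it approximates the continuous filter.
#'
#' @param sino A [sinogram()] or plain matrix `(angle, u)`.
#' @param pitch Detector pitch in the working length unit; the package
#'   works in detector-pixel units, so the default `d = 1` applies to both
#'   sinogram objects and plain matrices.
#' @return Same type as input with filtered values.
#' @export
filter_sinogram <- function(sino, pitch = 1) {
  vals <- if (inherits(sino, "sinogram")) sino$values else sino
  d <- pitch
  nu <- ncol(vals)
  npad <- 2^ceiling(log2(2 * nu))
  h <- numeric(npad)
  h[1] <- 1 / (4 * d^2)
  ks <- seq(1, npad / 2)
  odd <- ks[ks %% 2 == 1]
  h[odd + 1] <- -1 / (pi^2 * odd^2 * d^2)
  h[npad - odd + 1] <- -1 / (pi^2 * odd^2 * d^2)
  H <- fft(h)
  P <- rbind(t(vals), matrix(0, npad - nu, nrow(vals)))
  Q <- Re(mvfft(mvfft(P) * H, inverse = TRUE)) / npad * d
  out <- t(Q[seq_len(nu), , drop = FALSE])
  if (inherits(sino, "sinogram")) sinogram(out, sino$geometry, sino$z_index)
  else out
}

#' Back-project filtered projections onto a slice grid
#'
#' Each output pixel accumulates the linearly interpolated filtered value
#' at detector coordinate `u = x cos(theta) + y sin(theta)` over all view
#' angles, weighted by the angular step in radians. With the Ram-Lak
#' filtering step this is the (limited-angle) FBP inversion.
#'
#' @param filtered A filtered [sinogram()].
#' @param grid An [fbp_grid()].
#' @return A [slice_image()] in 1/micrometre.
#' @export
backproject <- function(filtered, grid = fbp_grid(geometry = filtered$geometry)) {
  stopifnot(inherits(filtered, "sinogram"))
  check_finite(filtered$values, "filtered sinogram")
  g <- filtered$geometry
  img <- cpp_backproject(filtered$values, geom_angles_rad(g),
                         du = 1,
                         nout = grid$out_size,
                         dpix = g$detector_size / grid$out_size,
                         dtheta = g$angular_step * pi / 180)
  slice_image(img, pixel_pitch = grid$out_pitch, fov_radius = grid$fov_radius)
}

#' Filtered back-projection of one sinogram
#'
#' @param sino A [sinogram()].
#' @param grid An [fbp_grid()].
#' @return A [slice_image()].
#' @export
fbp_reconstruct <- function(sino, grid = fbp_grid(geometry = sino$geometry)) {
  backproject(filter_sinogram(sino), grid)
}

#' Reconstruct a volume slice by slice
#'
#' Parallel-beam geometry decouples detector rows, so each row v of the
#' projection stack is reconstructed independently and the slices stacked
#' along z.
#'
#' @param stack `projection_stack` array shaped `(angle, v, u)` with a
#'   `geometry` attribute, e.g. from [project_phantom()] or [corrupt()].
#' @param grid An [fbp_grid()].
#' @param pwls Optional [pwls_config()]; when given, the stack is denoised
#'   before reconstruction and the fact is recorded in the provenance.
#' @return Array of class `recon_volume`, dims `(x, y, slice)`, with
#'   attributes `grid`, `geometry`, `z_indices`, `pwls`.
#' @export
reconstruct_volume <- function(stack, grid = NULL, pwls = NULL) {
  geometry <- attr(stack, "geometry")
  if (is.null(geometry)) stopf("projection stack lacks a geometry attribute")
  grid <- grid %||% fbp_grid(geometry = geometry)
  if (!is.null(pwls)) stack <- pwls_denoise(stack, pwls)
  nv <- dim(stack)[2]
  vol <- array(0, c(grid$out_size, grid$out_size, nv))
  for (v in seq_len(nv)) {
    sino <- sinogram(stack[, v, ], geometry)
    vol[, , v] <- fbp_reconstruct(sino, grid)
  }
  structure(vol, grid = grid, geometry = geometry,
            z_indices = attr(stack, "z_indices"),
            pwls = !is.null(pwls),
            class = c("recon_volume", "array"))
}

#' Reslice a reconstructed volume into sagittal planes
#'
#' Pure axis re-indexing of the voxel array (no resampling): axes 1 and 3
#' are swapped, so sagittal planes (fixed x) become the slices of the
#' returned array. Applying the re-indexing twice returns the original
#' volume.
#'
#' @param volume `recon_volume` or plain 3D array, dims `(x, y, z)`.
#' @param n_slices Number of sagittal planes to keep (evenly spaced;
#'   default all). Must not exceed the x extent.
#' @return Array with dims `(z, y, n_slices)`; attribute `sagittal_indices`
#'   records which x planes were taken.
#' @export
reslice_sagittal <- function(volume, n_slices = dim(volume)[1]) {
  nx <- dim(volume)[1]
  if (n_slices > nx) stopf("n_slices (%d) exceeds volume width (%d)",
                           n_slices, nx)
  perm <- aperm(unclass(volume), c(3, 2, 1))
  idx <- unique(round(seq(1, nx, length.out = n_slices)))
  out <- perm[, , idx, drop = FALSE]
  attr(out, "sagittal_indices") <- idx
  out
}
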