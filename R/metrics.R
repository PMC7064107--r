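#' Root-mean-square error inside the field of view
#'
#' RMSE of `image - reference` over pixels whose centre lies within
#' `fov_radius` pixels of the grid centre; pixels outside the circular FOV
#' (including the truncation ring region) are ignored.
#'
#' @param image,reference Matrices of equal shape (1/micrometre).
#' @param fov_radius FOV radius in pixels; defaults to the image attribute
#'   or half the grid width.
#' @return Scalar RMSE (1/micrometre).
#' @export
rmse_fov <- function(image, reference,
                     fov_radius = attr(image, "fov_radius") %||%
                       (min(dim(image)) / 2)) {
  if (!all(dim(image) == dim(reference))) stopf("shape mismatch")
  mask <- fov_mask(nrow(image), fov_radius)
  sqrt(mean((unclass(image)[mask] - unclass(reference)[mask])^2))
}

#' Structural similarity index
#'
#' Mean SSIM over all fully contained Gaussian windows, with the standard
#' stabilization constants and the data range taken from the reference
#' image. Identical images score exactly 1.
#'
#' @param image,reference Matrices of equal shape.
#' @param window_size Side of the Gaussian window (odd).
#' @param sigma Gaussian window width in pixels.
#' @param K1,K2 Stabilization constants.
#' @param data_range Dynamic range; defaults to
#'   `max(reference) - min(reference)` and must be positive.
#' @return Scalar SSIM in \[-1, 1\].
#' @export
ssim_index <- function(image, reference, window_size = 11L, sigma = 1.5,
                       K1 = 0.01, K2 = 0.03, data_range = NULL) {
  if (!all(dim(image) == dim(reference))) stopf("shape mismatch")
  L <- data_range %||% (max(reference) - min(reference))
  if (L <= 0) stopf("degenerate data range: reference image is constant")
  n <- nrow(image); m <- ncol(image)
  if (window_size > n || window_size > m)
    stopf("window larger than the image")
  k <- gaussian_kernel(window_size, sigma)
  # valid-mode separable weighting matrices
  Fr <- matrix(0, n - window_size + 1, n)
  for (i in seq_len(nrow(Fr))) Fr[i, i:(i + window_size - 1)] <- k
  Fc <- matrix(0, m - window_size + 1, m)
  for (i in seq_len(nrow(Fc))) Fc[i, i:(i + window_size - 1)] <- k
  w2 <- function(z) Fr %*% z %*% t(Fc)
  x <- unclass(image); y <- unclass(reference)
  mx <- w2(x); my <- w2(y)
  sxx <- w2(x * x) - mx^2
  syy <- w2(y * y) - my^2
  sxy <- w2(x * y) - mx * my
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  s <- ((2 * mx * my + C1) * (2 * sxy + C2)) /
    ((mx^2 + my^2 + C1) * (sxx + syy + C2))
  mean(s)
}

#' Evaluate a reconstructed volume against its analytic phantom
#'
#' Computes RMSE-in-FOV and SSIM of every reconstructed slice against the
#' analytic reference slice of the phantom, plus per-volume means. Slices
#' whose reference is constant (pure background) get `NA` SSIM and are
#' excluded from the SSIM mean.
#'
#' @param volume `recon_volume` from [reconstruct_volume()].
#' @param phantom The `phantom_volume` the projections came from.
#' @param method Method label, one of `"FBP"`, `"FBP_PWLS"`, `"UNet"`,
#'   `"UNet_PWLS"`.
#' @param metrics Character subset of `c("rmse", "ssim")`.
#' @return Object of class `eval_report`: list with `per_slice` (data
#'   frame), `mean_rmse`, `mean_ssim`, `method`, `fov_radius`.
#' @export
evaluate_volume <- function(volume, phantom,
                            method = c("FBP", "FBP_PWLS", "UNet", "UNet_PWLS"),
                            metrics = c("rmse", "ssim")) {
  method <- match.arg(method)
  grid <- attr(volume, "grid")
  z_indices <- attr(volume, "z_indices")
  if (is.null(grid) || is.null(z_indices))
    stopf("volume lacks grid / z_indices provenance")
  nv <- dim(volume)[3]
  out_size <- dim(volume)[1]
  rmse <- rep(NA_real_, nv)
  ssim <- rep(NA_real_, nv)
  for (v in seq_len(nv)) {
    ref <- slice_phantom(phantom, z_indices[v], out_size)
    if ("rmse" %in% metrics)
      rmse[v] <- rmse_fov(volume[, , v], ref, grid$fov_radius)
    if ("ssim" %in% metrics && (max(ref) - min(ref)) > 0)
      ssim[v] <- ssim_index(volume[, , v], ref)
  }
  structure(list(
    per_slice = data.frame(slice = seq_len(nv), z_index = z_indices,
                           rmse = rmse, ssim = ssim),
    mean_rmse = if ("rmse" %in% metrics) mean(rmse) else NA_real_,
    mean_ssim = if ("ssim" %in% metrics) mean(ssim, na.rm = TRUE) else NA_real_,
    method = method, fov_radius = grid$fov_radius),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> method=%s slices=%d mean RMSE=%.4g mean SSIM=%.4g\n",
              x$method, nrow(x$per_slice), x$mean_rmse, x$mean_ssim))
  invisible(x)
}
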