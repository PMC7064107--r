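#' PWLS denoising configuration
#'
#' Parameters of the penalized weighted least-squares projection denoiser:
#' the data term weights each pixel by the inverse of an estimate of its
#' noise variance, and the penalty discourages differences between
#' 4-connected neighbours with Gaussian intensity-difference weights.
#'
#' @param beta Regularization relaxation parameter (> 0). The variance map
#'   is normalized to unit median internally, so `beta = 1` balances the
#'   data and penalty terms across photon levels.
#' @param sigma Weight-control parameter of the neighbour weights.
#' @param a Variance scale per pixel.
#' @param eta Variance shape parameter.
#' @param n_iterations Number of Gauss-Seidel sweeps.
#' @param variance_fn Optional function `(p_hat, config) -> variance map`
#'   replacing the default `a * exp(p_hat / eta)`.
#' @return Object of class `pwls_config`.
#' @export
pwls_config <- function(beta = 1, sigma = 2, a = 0.5, eta = 1,
                        n_iterations = 2L, variance_fn = NULL) {
  if (beta < 0) stopf("beta must be >= 0")
  if (sigma <= 0) stopf("sigma must be > 0")
  if (n_iterations < 0) stopf("n_iterations must be >= 0")
  structure(list(beta = beta, sigma = sigma, a = a, eta = eta,
                 n_iterations = as.integer(n_iterations),
                 variance_fn = variance_fn),
            class = "pwls_config")
}

#' Per-pixel variance estimate of log-transformed projections
#'
#' Default form `v_i = a * exp(p_hat_i / eta)`, the exponential
#' mean-variance relationship of log-transformed transmission data: rays
#' with larger attenuation see fewer photons and carry more noise. Only the
#' relative weighting matters downstream since the overall scale is
#' absorbed by `beta`.
#'
#' @param p_hat Matrix or array of measured log projections.
#' @param config A [pwls_config()].
#' @return Variance map, same shape, strictly positive.
#' @export
estimate_variance <- function(p_hat, config = pwls_config()) {
  vals <- if (inherits(p_hat, "sinogram")) p_hat$values else p_hat
  check_finite(vals, "p_hat")
  if (!is.null(config$variance_fn)) return(config$variance_fn(vals, config))
  config$a * exp(vals / config$eta)
}

#' Neighbour weights of the PWLS penalty
#'
#' Gaussian weights `w_ij = exp(-(p_i - p_j)^2 / sigma^2)` over the
#' 4-connectivity neighbourhood, returned once per unordered pair.
#'
#' @param p Matrix of projection values.
#' @param sigma Weight-control parameter (> 0).
#' @return List with `down` (pairs along rows, `(n-1) x m`) and `right`
#'   (pairs along columns, `n x (m-1)`).
#' @export
neighbor_weights <- function(p, sigma) {
  if (sigma <= 0) stopf("sigma must be > 0")
  p <- if (inherits(p, "sinogram")) p$values else unclass(p)
  n <- nrow(p); m <- ncol(p)
  list(down = exp(-(p[-n, , drop = FALSE] - p[-1, , drop = FALSE])^2 / sigma^2),
       right = exp(-(p[, -m, drop = FALSE] - p[, -1, drop = FALSE])^2 / sigma^2))
}

#' PWLS objective value
#'
#' `Phi(p) = sum_i (p_hat_i - p_i)^2 / v_i +
#'  beta * sum_i sum_{j in N_i} w_ij (p_i - p_j)^2`, with the neighbour sum
#' running over ordered pairs (each unordered pair counted from both sides).
#'
#' @param p Candidate projection matrix.
#' @param p_hat Measured projection matrix.
#' @param variance Variance map (diagonal of the weighting matrix).
#' @param config A [pwls_config()].
#' @param weights Optional frozen neighbour weights from
#'   [neighbor_weights()]; defaults to weights computed from `p`.
#' @return Scalar objective value (>= 0).
#' @export
pwls_objective <- function(p, p_hat, variance, config = pwls_config(),
                           weights = NULL) {
  p <- if (inherits(p, "sinogram")) p$values else p
  p_hat <- if (inherits(p_hat, "sinogram")) p_hat$values else p_hat
  if (!all(dim(p) == dim(p_hat)) || !all(dim(p) == dim(variance)))
    stopf("shape mismatch between p, p_hat and variance")
  w <- weights %||% neighbor_weights(p, config$sigma)
  n <- nrow(p); m <- ncol(p)
  data_term <- sum((p_hat - p)^2 / variance)
  dr <- (p[-n, , drop = FALSE] - p[-1, , drop = FALSE])^2
  dc <- (p[, -m, drop = FALSE] - p[, -1, drop = FALSE])^2
  # each unordered pair appears in the neighbourhood sum of both pixels
  penalty <- 2 * (sum(w$down * dr) + sum(w$right * dc))
  data_term + config$beta * penalty
}

# core denoiser for one 2D field
pwls_denoise_field <- function(p_hat, config, freeze_weights = FALSE) {
  check_finite(p_hat, "p_hat")
  if (config$n_iterations == 0L) return(p_hat)
  v <- estimate_variance(p_hat, config)
  v <- v / median(v)
  p <- p_hat
  for (it in seq_len(config$n_iterations)) {
    wsrc <- if (freeze_weights) p_hat else p
    p <- cpp_pwls_sweep(p, p_hat, v, wsrc, config$beta, config$sigma)
  }
  p
}

#' Denoise log-transformed projections by penalized weighted least squares
#'
#' Runs `n_iterations` full Gauss-Seidel sweeps of the PWLS quadratic; each
#' pixel is replaced by the closed-form minimizer
#' `p_i <- (p_hat_i / v_i + 2 beta sum_j w_ij p_j) /
#'         (1 / v_i + 2 beta sum_j w_ij)`
#' in raster order. Neighbour weights are recomputed from the current
#' estimate at the start of each sweep (or frozen at the measured data with
#' `freeze_weights = TRUE`, in which case the objective is non-increasing
#' across sweeps).
#'
#' The 2D denoising unit is the projection image at fixed angle: for a
#' projection stack each `(v, u)` image is processed with 4-connectivity;
#' for a single-slice sinogram each angle contributes a 1D detector row, so
#' the neighbourhood reduces to the two neighbours along u.
#'
#' @param p_hat A [sinogram()], `projection_stack` array `(angle, v, u)`,
#'   or plain matrix (treated as one 2D field).
#' @param config A [pwls_config()].
#' @param freeze_weights Freeze neighbour weights at the measured data.
#' @return Denoised object of the same type.
#' @export
pwls_denoise <- function(p_hat, config = pwls_config(),
                         freeze_weights = FALSE) {
  if (inherits(p_hat, "sinogram")) {
    vals <- p_hat$values
    for (k in seq_len(nrow(vals)))
      vals[k, ] <- pwls_denoise_field(vals[k, , drop = FALSE], config,
                                      freeze_weights)
    return(sinogram(vals, p_hat$geometry, p_hat$z_index))
  }
  if (is.array(p_hat) && length(dim(p_hat)) == 3) {
    out <- p_hat
    for (k in seq_len(dim(p_hat)[1]))
      out[k, , ] <- pwls_denoise_field(p_hat[k, , ], config, freeze_weights)
    return(out)
  }
  pwls_denoise_field(as.matrix(p_hat), config, freeze_weights)
}
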