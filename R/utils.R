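# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG state
#'
#' Sets the RNG seed for the duration of `code` and restores the caller's
#' RNG state afterwards, so that seeded package operations do not disturb
#' the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv), add = TRUE)
  }
  set.seed(seed)
  code
}

# n sub-seeds derived deterministically from one master seed
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_finite <- function(x, what) {
  if (!all(is.finite(x))) stopf("non-finite values in %s", what)
  invisible(x)
}

# centred pixel coordinates: index i (1-based) -> i - (n+1)/2
centred_coords <- function(n, pitch = 1) (seq_len(n) - (n + 1) / 2) * pitch

# circular field-of-view mask on an n x n grid, radius in pixels
fov_mask <- function(n, radius) {
  cc <- centred_coords(n)
  outer(cc, cc, function(x, y) sqrt(x^2 + y^2)) <= radius
}

# 2x2 (or general integer factor) block-mean downsampling
block_mean <- function(img, factor) {
  n <- nrow(img)
  m <- ncol(img)
  if (factor == 1) return(img)
  if (n %% factor || m %% factor) stopf("image size not divisible by %d", factor)
  no <- n / factor
  mo <- m / factor
  dim(img) <- c(factor, no, factor, mo)
  out <- apply(img, c(2, 4), mean)
  out
}

# exact counter-clockwise quarter-turn rotation (pixel permutation)
rot90_ccw <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]

# normalized 1-d Gaussian kernel
gaussian_kernel <- function(size, sigma) {
  x <- seq_len(size) - (size + 1) / 2
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# separable Gaussian blur with reflected edges (used by the texture generator)
gaussian_blur <- function(img, sigma) {
  size <- 2L * ceiling(3 * sigma) + 1L
  k <- gaussian_kernel(size, sigma)
  half <- (size - 1L) / 2L
  blur1 <- function(m) {
    n <- nrow(m)
    idx <- c(rev(seq_len(half)), seq_len(n), n + 1 - seq_len(half))
    padded <- m[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_len(size)) out <- out + k[j] * padded[(j - 1) + seq_len(n), , drop = FALSE]
    out
  }
  t(blur1(t(blur1(img))))
}
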