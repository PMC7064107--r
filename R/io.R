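#' Write an image or volume as 32-bit TIFF with a scale sidecar
#'
#' Slices are written as single-page, volumes as multi-page (one page per
#' slice along the third axis) 32-bit TIFF. TIFF storage here is
#' normalized to [0, 1]; the affine range of the original values is
#' recorded in a small JSON sidecar (`<path>.json`) so reading restores
#' physical attenuation values.
#'
#' @param x Matrix or 3D array.
#' @param path Output file.
#' @export
write_float_tiff <- function(x, path) {
  x <- unclass(x)
  lo <- min(x)
  hi <- max(x)
  scaled <- if (hi > lo) (x - lo) / (hi - lo) else x * 0
  pages <- if (length(dim(scaled)) == 3)
    lapply(seq_len(dim(scaled)[3]), function(i) scaled[, , i])
  else list(as.matrix(scaled))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  jsonlite::write_json(list(min = lo, max = hi), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a TIFF written by [write_float_tiff()]
#'
#' Restores physical values through the JSON scale sidecar when present;
#' plain TIFFs are returned in their stored [0, 1] range.
#'
#' @param path File path.
#' @return Matrix (single page) or 3D array (multi-page).
#' @export
read_float_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  out <- if (length(pages) == 1) pages[[1]] else {
    arr <- array(0, c(dim(pages[[1]]), length(pages)))
    for (i in seq_along(pages)) arr[, , i] <- pages[[i]]
    arr
  }
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    rng <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    out <- out * (rng$max - rng$min) + rng$min
  }
  out
}

#' Read a phantom spec from YAML or JSON
#'
#' The file may define any subset of the [phantom_spec()] arguments;
#' omitted fields keep their defaults.
#'
#' @param path Path to a .yaml/.yml/.json file.
#' @return A `phantom_spec`.
#' @export
read_phantom_spec <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lst <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else stopf("unsupported spec format: %s", path)
  if (!is.null(lst$counts)) lst$counts <- unlist(lst$counts)
  do.call(phantom_spec, lst)
}

#' Write an evaluation report as JSON
#'
#' @param report An `eval_report`.
#' @param path Output file.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(list(method = report$method,
                            mean_rmse = report$mean_rmse,
                            mean_ssim = report$mean_ssim,
                            fov_radius = report$fov_radius,
                            per_slice = report$per_slice),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
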