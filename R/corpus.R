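#' Build the synthetic training corpus
#'
#' Reproduces the data-preparation recipe end to end: randomized ellipsoid
#' phantoms contribute uniformly selected slices, procedural structured
#' images supply generic "multi-category" content, and the whole base set
#' is expanded by quarter-turn rotations. Each resulting image is projected
#' over the limited angular window (discrete projector plus the closed-form
#' chord of the ice slab outside the image footprint), corrupted with
#' Poisson noise at a photon level drawn from `noise_levels`, reconstructed
#' by FBP — directly for the originals and their 90 degree rotations, after
#' PWLS denoising for the 180 and 270 degree rotations — and paired with
#' its reference (the block-mean of the clean image on the reconstruction
#' grid) to form the artifact-image regression target.
#'
#' With the default counts this yields 10 x 20 + 400 = 600 base images and
#' 2400 training pairs, half of them PWLS-processed.
#'
#' @param n_phantoms Number of ellipsoid phantoms.
#' @param slices_per_phantom Slices selected per phantom.
#' @param n_surrogate Number of procedural structured images.
#' @param phantom_grid Phantom grid size (voxels); reduced sizes give a
#'   proportionally scaled geometry.
#' @param image_size Rendered image size (pixels); the detector has
#'   `image_size` pixels and reconstructions are `image_size / 2` unless
#'   `out_size` says otherwise.
#' @param out_size Reconstruction size (pixels).
#' @param theta_start,theta_end,angular_step Angular window (degrees).
#' @param noise_levels Photon counts sampled per training image.
#' @param pwls A [pwls_config()] used for the PWLS half of the corpus.
#' @param seed Master seed; the manifest and all pairs are reproducible.
#' @param keep_pairs Keep the pixel data (set `FALSE` for a manifest-only
#'   dry run, e.g. for corpus arithmetic checks).
#' @return Object of class `corpus`: list with `manifest` (data frame:
#'   `id`, `source`, `base`, `rotation`, `photon`, `pwls_flag`), `pairs`
#'   (list of `list(input, target, reference)`), `geometry`, `out_size`,
#'   `seed`.
#' @export
build_corpus <- function(n_phantoms = 10L, slices_per_phantom = 20L,
                         n_surrogate = 400L, phantom_grid = 512L,
                         image_size = 512L, out_size = image_size / 2L,
                         theta_start = -50, theta_end = 50, angular_step = 1,
                         noise_levels = c(1e4, 5e4, 1e5),
                         pwls = pwls_config(), seed = 1L,
                         keep_pairs = TRUE) {
  pitch <- 21.9 * 512 / image_size   # keep the physical FOV of the scan
  geometry <- scan_geometry(theta_start, theta_end, angular_step,
                            detector_size = image_size,
                            detector_pitch = pitch)
  grid <- fbp_grid(out_size, geometry)
  seeds <- derive_seeds(seed, 3L + n_phantoms)
  base <- list()
  source <- character()
  bg_intensity <- NULL
  for (i in seq_len(n_phantoms)) {
    spec <- phantom_spec(grid_size = phantom_grid, seed = seeds[3L + i])
    bg_intensity <- spec$background_intensity
    ph <- generate_phantom(spec)
    for (z in phantom_slice_indices(phantom_grid, slices_per_phantom)) {
      sl <- slice_phantom(ph, z, image_size)
      attr(sl, "pixel_pitch") <- pitch
      base[[length(base) + 1L]] <- sl
      source <- c(source, "phantom")
    }
  }
  if (n_surrogate > 0) {
    for (im in surrogate_texture_images(n_surrogate, image_size,
                                        seed = seeds[1], pixel_pitch = pitch)) {
      base[[length(base) + 1L]] <- im
      source <- c(source, "surrogate")
    }
  }
  n_base <- length(base)
  all_images <- augment_rotations(base)
  rotation <- rep(c(0L, 90L, 180L, 270L), each = n_base)
  photon <- with_seed(seeds[2], sample(noise_levels, length(all_images),
                                       replace = TRUE))
  pair_seeds <- derive_seeds(seeds[3], max(1L, length(all_images)))
  manifest <- data.frame(id = seq_along(all_images),
                         source = rep(source, 4),
                         base = rep(seq_len(n_base), 4),
                         rotation = rotation,
                         photon = photon,
                         pwls_flag = rotation %in% c(180L, 270L))
  pairs <- NULL
  if (keep_pairs) {
    half_px <- image_size / 2
    slab_extra <- if (!is.null(bg_intensity) && bg_intensity > 0)
      slab_sinogram(geometry, 1.5 * half_px, bg_intensity, half_px)$values
    else 0
    factor <- image_size / out_size
    pairs <- vector("list", length(all_images))
    for (k in seq_along(all_images)) {
      img <- all_images[[k]]
      sino <- discrete_sinogram(img, geometry)
      vals <- sino$values
      if (manifest$source[k] == "phantom") vals <- vals + slab_extra
      noisy <- corrupt(sinogram(vals, geometry),
                       noise_model(photon[k], pair_seeds[k]))
      if (manifest$pwls_flag[k]) noisy <- pwls_denoise(noisy, pwls)
      recon <- fbp_reconstruct(noisy, grid)
      reference <- block_mean(unclass(img), factor)
      pairs[[k]] <- list(input = recon, target = unclass(recon) - reference,
                         reference = reference)
    }
  }
  structure(list(manifest = manifest, pairs = pairs, geometry = geometry,
                 out_size = out_size, seed = seed),
            class = "corpus")
}

#' Training pairs (normalized view) from a corpus
#'
#' @param corpus A `corpus` with pixel data.
#' @return List of `list(input, target)` in physical units, ready for
#'   [train_unet()] (which computes and stores the shared normalization
#'   constant).
#' @export
corpus_training_pairs <- function(corpus) {
  if (is.null(corpus$pairs)) stopf("corpus was built without pixel data")
  lapply(corpus$pairs, function(p) list(input = unclass(p$input),
                                        target = p$target))
}
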