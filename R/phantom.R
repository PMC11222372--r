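#' Synthetic two-modality hippocampus phantom
#'
#' Deterministic generator of hippocampus-like test volumes: an ellipsoidal
#' "organ" partitioned into three contiguous bands along its long axis
#' (playing the roles of CA1-3, CA4/DG and SUB), imaged in two channels with
#' distinct per-label contrasts, corrupted by a smooth multiplicative bias
#' field and additive Gaussian noise, plus small bright distractor blobs away
#' from the organ to exercise false-positive removal. Identical config and
#' seed give bit-identical output.
#'
#' @param grid_shape integer triple (D, H, W).
#' @param spacing voxel size in mm.
#' @param organ_axes ellipsoid semi-axes in voxels, (D, H, W) order; the
#'   largest axis is the long (band-partition) axis.
#' @param contrast_t1,contrast_t2 length-4 mean intensities for labels
#'   0 (background), 1, 2, 3 in each modality; must be pairwise distinct
#'   within a modality.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param bias_amplitude amplitude `a` of the multiplicative bias field
#'   `1 + a * sin(pi u_D) sin(pi u_H) sin(pi u_W)` over normalized
#'   coordinates.
#' @param n_distractors number of distractor blobs.
#' @param distractor_size_range voxel-count interval for each blob.
#' @param distractor_intensity intensity of distractor voxels (both
#'   channels, before bias/noise).
#' @param center_jitter max uniform offset (voxels) of the organ centre.
#' @param axes_jitter max relative perturbation of the semi-axes.
#' @param seed RNG seed driving jitter, distractors and noise.
#' @return `phantom_config()` returns a config list; [generate_phantom()] the
#'   phantom itself.
#' @export
phantom_config <- function(grid_shape = c(64L, 64L, 64L),
                           spacing = c(0.4, 0.4, 0.4),
                           organ_axes = c(18, 11, 11),
                           contrast_t1 = c(0.2, 1.0, 0.7, 0.85),
                           contrast_t2 = c(0.3, 0.6, 1.0, 0.45),
                           noise_sd = 0.05,
                           bias_amplitude = 0.1,
                           n_distractors = 3L,
                           distractor_size_range = c(50L, 500L),
                           distractor_intensity = 1.3,
                           center_jitter = 0,
                           axes_jitter = 0,
                           seed = 0L) {
  cfg <- list(grid_shape = as.integer(grid_shape), spacing = spacing,
              organ_axes = organ_axes, contrast_t1 = contrast_t1,
              contrast_t2 = contrast_t2, noise_sd = noise_sd,
              bias_amplitude = bias_amplitude,
              n_distractors = as.integer(n_distractors),
              distractor_size_range = as.integer(distractor_size_range),
              distractor_intensity = distractor_intensity,
              center_jitter = center_jitter, axes_jitter = axes_jitter,
              seed = as.integer(seed))
  worst <- cfg$organ_axes * (1 + cfg$axes_jitter) + cfg$center_jitter
  if (any((cfg$grid_shape - 1) / 2 - worst < 4))
    stop("organ does not fit in the grid with a 4-voxel margin")
  if (anyDuplicated(contrast_t1) || anyDuplicated(contrast_t2))
    stop("per-label mean intensities must be distinct within each modality")
  class(cfg) <- "dsnet_phantom_config"
  cfg
}

#' Generate one phantom subject
#'
#' @param cfg a [phantom_config()].
#' @return list with `volume` (two-channel [new_volume()]), `labels`
#'   ([new_labelmap()]), `distractors` (integer mask array of the distractor
#'   blobs) and `cfg`.
#' @export
generate_phantom <- function(cfg = phantom_config()) {
  stopifnot(inherits(cfg, "dsnet_phantom_config"))
  set.seed(cfg$seed)
  g <- cfg$grid_shape
  center <- (g - 1) / 2 +
    runif(3, -cfg$center_jitter, cfg$center_jitter)
  axes <- cfg$organ_axes * runif(3, 1 - cfg$axes_jitter, 1 + cfg$axes_jitter)

  dd <- ((0:(g[1] - 1) - center[1]) / axes[1])^2
  hh <- ((0:(g[2] - 1) - center[2]) / axes[2])^2
  ww <- ((0:(g[3] - 1) - center[3]) / axes[3])^2
  E <- outer(outer(dd, hh, `+`), ww, `+`)
  organ <- E <= 1

  long <- which.max(axes)
  tcoord <- switch(long,
                   (slice.index(E, 1) - 1 - center[1]) / axes[1],
                   (slice.index(E, 2) - 1 - center[2]) / axes[2],
                   (slice.index(E, 3) - 1 - center[3]) / axes[3])
  labels <- array(0L, g)
  labels[organ & tcoord < -1 / 3] <- 1L
  labels[organ & tcoord >= -1 / 3 & tcoord < 1 / 3] <- 2L
  labels[organ & tcoord >= 1 / 3] <- 3L
  if (any(tabulate(labels[organ], 3L) == 0))
    stop("fewer than 3 non-empty subfields after rasterization; ",
         "enlarge organ_axes")

  distract <- array(0L, g)
  if (cfg$n_distractors > 0) {
    surf <- mask_surface_coords(organ, c(1, 1, 1))  # organ surface, voxels
    centers <- matrix(0, 0, 3); radii <- numeric(0)
    tries <- 0L
    while (length(radii) < cfg$n_distractors) {
      tries <- tries + 1L
      if (tries > 5000L) stop("could not place distractors; grid too crowded")
      v <- runif(1, cfg$distractor_size_range[1], cfg$distractor_size_range[2])
      r <- (3 * v / (4 * pi))^(1 / 3)
      ctr <- vapply(seq_len(3), function(a)
        sample(seq(ceiling(r) + 1, g[a] - ceiling(r) - 2), 1), 0)
      if (cpp_min_dists(matrix(ctr, 1), surf) < r + 8) next
      if (nrow(centers) &&
          any(sqrt(rowSums(sweep(centers, 2, ctr)^2)) < radii + r + 3)) next
      blob <- sphere_mask(g, ctr, r)
      n_vox <- sum(blob)
      if (n_vox < cfg$distractor_size_range[1] ||
          n_vox > cfg$distractor_size_range[2]) next
      distract[blob] <- 1L
      centers <- rbind(centers, ctr); radii <- c(radii, r)
    }
  }

  base1 <- cfg$contrast_t1[labels + 1L]
  base2 <- cfg$contrast_t2[labels + 1L]
  base1[distract == 1L] <- cfg$distractor_intensity
  base2[distract == 1L] <- cfg$distractor_intensity
  dim(base1) <- g; dim(base2) <- g

  bias <- 1
  if (cfg$bias_amplitude > 0) {
    sd_ <- sin(pi * (0:(g[1] - 1)) / (g[1] - 1))
    sh_ <- sin(pi * (0:(g[2] - 1)) / (g[2] - 1))
    sw_ <- sin(pi * (0:(g[3] - 1)) / (g[3] - 1))
    bias <- 1 + cfg$bias_amplitude * outer(outer(sd_, sh_), sw_)
  }
  arr <- array(0, c(g, 2L))
  arr[, , , 1] <- base1 * bias
  arr[, , , 2] <- base2 * bias
  if (cfg$noise_sd > 0)
    arr <- arr + rnorm(length(arr), sd = cfg$noise_sd)

  list(volume = new_volume(arr, channels = c("t1w", "t2w"),
                           spacing = cfg$spacing),
       labels = new_labelmap(labels, spacing = cfg$spacing),
       distractors = distract, cfg = cfg)
}

sphere_mask <- function(g, ctr, r) {
  dd <- (0:(g[1] - 1) - ctr[1])^2
  hh <- (0:(g[2] - 1) - ctr[2])^2
  ww <- (0:(g[3] - 1) - ctr[3])^2
  outer(outer(dd, hh, `+`), ww, `+`) <= r^2
}

#' Derive a per-subject seed from a cohort seed
#'
#' @param seed cohort-level seed.
#' @param i subject index (1-based).
#' @return an integer seed below 2^31.
#' @export
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 104729 + i * 7919) %% 2147483647)
}

#' Generate a cohort of distinct phantom subjects
#'
#' Subjects share the grid geometry but differ in organ pose and size
#' (per-subject jitter of centre and semi-axes), noise, bias sampling and
#' distractor placement, reproducibly derived from one cohort seed via
#' [derive_seed()].
#'
#' @param cfg base [phantom_config()].
#' @param n_subjects cohort size (>= 1).
#' @param seed cohort seed.
#' @param center_jitter,axes_jitter per-subject pose variability.
#' @return list of [generate_phantom()] results.
#' @export
generate_cohort <- function(cfg = phantom_config(), n_subjects, seed = 0L,
                            center_jitter = 2, axes_jitter = 0.08) {
  stopifnot(n_subjects >= 1)
  lapply(seq_len(n_subjects), function(i) {
    ci <- cfg
    ci$center_jitter <- center_jitter
    ci$axes_jitter <- axes_jitter
    ci$seed <- derive_seed(seed, i)
    ci <- do.call(phantom_config, unclass(ci)[names(formals(phantom_config))])
    generate_phantom(ci)
  })
}
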