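#' Phantom generator configuration
#'
#' Defines the synthetic two-channel volumes the package uses to exercise the
#' full saliency pipeline without external data. The phantom mimics the
#' statistical structure the saliency methods assume: blob lesions that are
#' hyperintense in channel 1 (FLAIR-like) and hypointense in channel 2
#' (MPRAGE/T1-like) on a noisy background, inside an ellipsoidal brain-shaped
#' support, with constant "air" outside the support. Intensities are z-score
#' normalized over the brain mask.
#'
#' @param dims integer vector of grid extents (default 64^3; use 32^3 for
#'   fast runs).
#' @param n_lesions number of lesions to place.
#' @param radius_range_mm lesion radius range in mm (uniformly sampled). The
#'   default lower bound of 1.5 mm guarantees every lesion survives a 5 mm^3
#'   volume filter at 1 mm isotropic spacing.
#' @param delta1 channel-1 lesion contrast (added above background, in
#'   background-noise SD units).
#' @param delta2 channel-2 lesion contrast (subtracted below background).
#'   Smaller than `delta1` by default, mirroring the weaker lesion conspicuity
#'   of T1-like contrast.
#' @param noise_sd background Gaussian noise SD (raw scale).
#' @param bias_sd SD of the smooth low-frequency background field added to
#'   each channel (raw scale). Real brain MRI keeps smooth regional intensity
#'   variation even after bias correction and z-scoring, so absolute
#'   intensity alone does not identify a lesion; the field forces detection
#'   to rely on local contrast against the perilesional neighbourhood, the
#'   structural premise of the context experiments. Set to 0 for a flat
#'   background.
#' @param bias_scale_vox correlation length of the background field in
#'   voxels.
#' @param semi_axes brain ellipsoid semi-axes in voxels; default 0.42 * dims.
#' @param air_value raw intensity outside the brain mask.
#' @param spacing voxel spacing in mm.
#' @param seed integer seed; every stochastic step derives from it.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(dims = c(64L, 64L, 64L), n_lesions = 5L,
                           radius_range_mm = c(1.5, 3.5), delta1 = 3,
                           delta2 = 1.5, noise_sd = 1, bias_sd = 1.5,
                           bias_scale_vox = 8, semi_axes = NULL,
                           air_value = -3, spacing = c(1, 1, 1), seed = 1L) {
  if (length(dims) == 2L) dims <- c(dims, 1L)
  if (is.null(semi_axes)) semi_axes <- 0.42 * dims
  stopifnot(all(radius_range_mm > 0), delta1 > 0, delta2 > 0, noise_sd >= 0,
            bias_sd >= 0, bias_scale_vox >= 2)
  structure(
    list(dims = as.integer(dims), n_lesions = as.integer(n_lesions),
         radius_range_mm = radius_range_mm, delta1 = delta1, delta2 = delta2,
         noise_sd = noise_sd, bias_sd = bias_sd,
         bias_scale_vox = bias_scale_vox, semi_axes = semi_axes,
         air_value = air_value, spacing = spacing, seed = as.integer(seed)),
    class = "phantom_config"
  )
}

#' Ellipsoidal brain support mask
#'
#' @param dims grid extents.
#' @param semi_axes semi-axes in voxels; clipped (with a warning) to fit the
#'   grid when too large.
#' @return integer 0/1 array.
#' @export
make_brain_mask <- function(dims, semi_axes) {
  if (length(dims) == 2L) dims <- c(dims, 1L)
  if (length(semi_axes) == 2L) semi_axes <- c(semi_axes, 0.5)
  max_axes <- (dims - 1) / 2
  max_axes[dims == 1L] <- 0.5
  if (any(semi_axes > max_axes + 1e-9)) {
    warning("semi-axes exceed the grid; clipping to fit")
    semi_axes <- pmin(semi_axes, max_axes)
  }
  ctr <- (dims + 1) / 2
  i1 <- (seq_len(dims[1]) - ctr[1]) / semi_axes[1]
  i2 <- (seq_len(dims[2]) - ctr[2]) / semi_axes[2]
  i3 <- (seq_len(dims[3]) - ctr[3]) / semi_axes[3]
  r2 <- outer(outer(i1^2, i2^2, `+`), i3^2, `+`)
  mask <- array(as.integer(r2 <= 1), dims)
  mask
}

#' Generate a two-channel phantom
#'
#' @param cfg a [phantom_config()].
#' @return a `sal_phantom` list with fields `volume` (z-scored
#'   [as_volume()]), `gt_mask`, `brain_mask`, `lesions` (data frame of
#'   centres and radii) and `config`.
#' @export
generate_phantom <- function(cfg = phantom_config()) {
  stopifnot(inherits(cfg, "phantom_config"))
  set.seed(cfg$seed)
  dims <- cfg$dims
  brain <- make_brain_mask(dims, cfg$semi_axes)
  ctr <- (dims + 1) / 2

  # --- place non-overlapping lesions fully inside the brain ellipsoid ---
  centers <- matrix(numeric(0), 0, 3)
  radii <- numeric(0)
  max_attempts <- 2000L * max(cfg$n_lesions, 1L)
  attempts <- 0L
  while (nrow(centers) < cfg$n_lesions) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop(sprintf(
        "phantom lesion placement exhausted after %d attempts (%d of %d placed)",
        max_attempts, nrow(centers), cfg$n_lesions
      ))
    }
    r <- stats::runif(1, cfg$radius_range_mm[1], cfg$radius_range_mm[2]) /
      min(cfg$spacing)
    eff_axes <- cfg$semi_axes
    eff_axes[dims == 1L] <- Inf  # singleton axes (2D phantoms) unconstrained
    cand <- ctr + (stats::runif(3) * 2 - 1) * pmax(ifelse(is.finite(eff_axes), eff_axes - r - 2, 0), 0)
    cand[dims == 1L] <- 1
    # entire taper footprint inside the ellipsoid
    margin <- max((r + 2) / eff_axes[is.finite(eff_axes)])
    if (sum(((cand - ctr) / eff_axes)^2) > max(0, 1 - margin)^2) next
    if (nrow(centers) > 0) {
      d <- sqrt(rowSums((centers - matrix(cand, nrow(centers), 3, byrow = TRUE))^2))
      if (any(d < radii + r + 3)) next  # keep instances separable
    }
    centers <- rbind(centers, cand)
    radii <- c(radii, r)
  }

  # --- intensity profile with a 1-voxel cosine taper at the lesion edge ---
  profile <- array(0, dims)
  gt <- array(0L, dims)
  for (l in seq_len(nrow(centers))) {
    r <- radii[l]
    lo <- pmax(floor(centers[l, ] - r - 1), 1)
    hi <- pmin(ceiling(centers[l, ] + r + 1), dims)
    ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
    dg <- expand.grid(i = ii, j = jj, k = kk)
    d <- sqrt((dg$i - centers[l, 1])^2 + (dg$j - centers[l, 2])^2 +
                (dg$k - centers[l, 3])^2)
    prof <- ifelse(d <= r - 1, 1,
                   ifelse(d <= r + 1, 0.5 * (1 + cos(pi * (d - (r - 1)) / 2)), 0))
    idx <- cbind(dg$i, dg$j, dg$k)
    profile[idx] <- pmax(profile[idx], prof)
    gt[idx[d <= r, , drop = FALSE]] <- 1L
  }

  smooth_field <- function() {
    if (cfg$bias_sd == 0) return(array(0, dims))
    coarse_dims <- pmax(ceiling(dims / cfg$bias_scale_vox) + 1L, 2L)
    coarse_dims[dims == 1L] <- 1L
    coarse <- array(stats::rnorm(prod(coarse_dims), sd = cfg$bias_sd), coarse_dims)
    upsample_linear(coarse, dims)
  }
  ch1 <- array(stats::rnorm(prod(dims), sd = cfg$noise_sd), dims) +
    smooth_field() + cfg$delta1 * profile
  ch2 <- array(stats::rnorm(prod(dims), sd = cfg$noise_sd), dims) +
    smooth_field() - cfg$delta2 * profile
  ch1[brain == 0L] <- cfg$air_value
  ch2[brain == 0L] <- cfg$air_value

  zscore <- function(x) {
    mu <- mean(x[brain == 1L]); sd <- stats::sd(x[brain == 1L])
    if (sd == 0) sd <- 1
    (x - mu) / sd
  }
  vol <- as_volume(
    array(c(zscore(ch1), zscore(ch2)), c(dims, 2L)),
    channels = c("flair", "mprage"), spacing = cfg$spacing
  )
  lesions <- data.frame(
    c1 = centers[, 1], c2 = centers[, 2], c3 = centers[, 3],
    radius_vox = radii
  )
  structure(
    list(volume = vol, gt_mask = gt, brain_mask = brain,
         lesions = lesions, config = cfg),
    class = "sal_phantom"
  )
}

#' @export
print.sal_phantom <- function(x, ...) {
  cat(sprintf(
    "<sal_phantom> %s, %d lesion(s), %d GT voxels, seed %d\n",
    paste(x$config$dims, collapse = "x"), nrow(x$lesions),
    sum(x$gt_mask), x$config$seed
  ))
  invisible(x)
}
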