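#' Noise configuration for SmoothGrad
#'
#' @param n number of noisy repetitions (N >= 1); default 50.
#' @param sigma Gaussian noise SD on the z-scored intensity scale; default
#'   0.05. Noise is drawn independently per repetition, channel and voxel.
#' @param seed base random seed.
#' @return a `noise_config` list.
#' @export
noise_config <- function(n = 50L, sigma = 0.05, seed = 1L) {
  if (n < 1) stop("noise configuration invalid: n must be >= 1")
  if (sigma < 0) stop("noise configuration invalid: sigma must be >= 0")
  structure(list(n = as.integer(n), sigma = sigma, seed = as.integer(seed)),
            class = "noise_config")
}

#' Signed-maximum aggregation of gradient candidates
#'
#' Returns the candidate of maximal absolute value, keeping its sign. Ties
#' are broken in favour of the earliest candidate (candidates are ordered by
#' the scan order of their source voxels).
#'
#' @param candidates numeric vector of gradient values at one voxel, one per
#'   source voxel of the lesion domain.
#' @return scalar.
#' @export
max_signed_aggregate <- function(candidates) {
  if (length(candidates) == 0L) stop("empty candidate set: the lesion domain is empty")
  candidates[which.max(abs(candidates))]
}

# Rows of the logit Jacobian: gradient maps of single output voxels, as a
# (n_voxels * n_channels) x m matrix, one column per requested output voxel.
# The default route is one backward pass per voxel; models with an expensive
# forward pass override this to share the forward cache.
jacobian_rows <- function(model, x, lins, ...) UseMethod("jacobian_rows")

#' @export
jacobian_rows.default <- function(model, x, lins, ...) {
  sdim <- vol_sdim(x)
  G <- matrix(0, prod(sdim) * vol_nchan(x), length(lins))
  w <- array(0, sdim)
  for (j in seq_along(lins)) {
    w[lins[j]] <- 1
    G[, j] <- as.numeric(input_gradient(model, x, w))
    w[lins[j]] <- 0
  }
  G
}

#' @export
jacobian_rows.sal_tiny_cnn <- function(model, x, lins, ...) {
  check_model_input(model, x, model$n_channels)
  sdim <- vol_sdim(x)
  cache <- cnn_forward_cache(model, x$data)
  pd <- dim(cache$x)[1:3]
  G <- matrix(0, prod(sdim) * model$n_channels, length(lins))
  w <- array(0, sdim)
  for (j in seq_along(lins)) {
    w[lins[j]] <- 1
    dy <- embed_padded(w, pd)
    dx <- cnn_backward(model, cache, dy)$dx
    G[, j] <- as.numeric(unpad(dx, cache$orig))
    w[lins[j]] <- 0
  }
  G
}

remap_lins <- function(lins, dims, win) {
  sub <- lin_to_sub(lins, dims)
  sub <- sweep(sub, 2, win$lo - 1L)
  cdim <- win$hi - win$lo + 1L
  sub_to_lin(sub, cdim)
}

#' Instance-level SmoothGrad saliency
#'
#' Computes per-channel instance saliency maps for a lesion domain Omega by
#' averaging input gradients of the logits over `cfg$n` noise-perturbed
#' copies of the input, with either of two aggregation rules over the source
#' voxels of Omega:
#'
#' * `"mean"` — the gradient maps of all output voxels in Omega are averaged
#'   (equivalently, a single backward pass on `sum(y[Omega]) / |Omega|` per
#'   repetition). Values scale inversely with lesion size.
#' * `"max_signed"` — per repetition and per voxel, the candidate gradient of
#'   largest absolute value across source voxels is kept with its sign, and
#'   the kept maps are averaged over repetitions. Values are comparable
#'   across lesions of different sizes ("quantitative" saliency).
#'
#' Computation is restricted to a crop around Omega (default margin: the
#' model's receptive-field radius, else 48 voxels) and re-embedded at the
#' original offset; gradients vanish beyond the receptive field, so the crop
#' is exact for models with a known radius.
#'
#' @param model a model implementing the [model-contract].
#' @param x input [as_volume()] volume.
#' @param omega a non-empty [new_instance()] on `x`'s grid.
#' @param cfg a [noise_config()].
#' @param aggregation `"max_signed"` or `"mean"`.
#' @param crop_margin integer margin in voxels, or `NULL` for the default.
#' @param full_volume set `TRUE` to skip cropping.
#' @return object of class `sal_saliency`: `values` (crop array, dims x
#'   channels), `channels`, `method`, `aggregation`, `label`, `cfg`,
#'   `offset` (1-based low corner of the crop) and `full_dims`.
#' @export
smoothgrad_instance <- function(model, x, omega, cfg = noise_config(),
                                aggregation = c("max_signed", "mean"),
                                crop_margin = NULL, full_volume = FALSE) {
  aggregation <- match.arg(aggregation)
  stopifnot(inherits(x, "sal_volume"), inherits(cfg, "noise_config"))
  if (!inherits(omega, "sal_instance") || omega$cardinality == 0L) {
    stop("empty lesion domain: omega must be a non-empty instance")
  }
  sdim <- vol_sdim(x)
  if (any(omega$dims != sdim)) stop("omega grid does not match the volume")
  if (full_volume) {
    win <- list(lo = c(1L, 1L, 1L), hi = sdim)
  } else {
    if (is.null(crop_margin)) {
      crop_margin <- tryCatch(receptive_field_radius(model), error = function(e) 48L)
    }
    win <- crop_window(omega$voxels, sdim, as.integer(crop_margin))
  }
  xc <- crop_volume(x, win)
  lins <- remap_lins(omega$lin, sdim, win)
  cdim <- vol_sdim(xc)
  nc <- vol_nchan(xc)

  set.seed(cfg$seed)
  acc <- array(0, c(cdim, nc))
  mean_w <- NULL
  if (aggregation == "mean") {
    mean_w <- array(0, cdim)
    mean_w[lins] <- 1 / omega$cardinality
  }
  for (rep in seq_len(cfg$n)) {
    xn <- xc
    if (cfg$sigma > 0) {
      xn$data <- xc$data + array(stats::rnorm(length(xc$data), sd = cfg$sigma),
                                 dim(xc$data))
    }
    if (aggregation == "mean") {
      acc <- acc + input_gradient(model, xn, mean_w)
    } else {
      G <- jacobian_rows(model, xn, lins)
      kept <- cpp_signed_absmax_rows(G)
      acc <- acc + array(kept, c(cdim, nc))
    }
  }
  structure(
    list(values = acc / cfg$n, channels = x$channels,
         method = if (cfg$n == 1L && cfg$sigma == 0) "vanilla" else "smoothgrad",
         aggregation = aggregation, label = omega$label, cfg = cfg,
         offset = win$lo, full_dims = sdim, spacing = x$spacing),
    class = "sal_saliency"
  )
}

#' Vanilla-gradient instance saliency
#'
#' Single unperturbed backward computation: identical to
#' [smoothgrad_instance()] with `n = 1`, `sigma = 0`.
#'
#' @inheritParams smoothgrad_instance
#' @export
vanilla_instance_map <- function(model, x, omega,
                                 aggregation = c("max_signed", "mean"),
                                 crop_margin = NULL, full_volume = FALSE) {
  smoothgrad_instance(model, x, omega, noise_config(n = 1L, sigma = 0),
                      aggregation = match.arg(aggregation),
                      crop_margin = crop_margin, full_volume = full_volume)
}

#' @export
print.sal_saliency <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<sal_saliency> %s (%s), label %s: crop %s in grid %s, range [%.4g, %.4g]\n",
    x$method, x$aggregation, x$label,
    paste(d[1:3], collapse = "x"), paste(x$full_dims, collapse = "x"),
    min(x$values), max(x$values)
  ))
  invisible(x)
}

#' Embed a saliency crop into the full grid
#' @param map a `sal_saliency`.
#' @return numeric array `(full_dims, channels)`, zero outside the crop.
#' @export
embed_saliency <- function(map) {
  d <- dim(map$values)
  out <- array(0, c(map$full_dims, d[4]))
  out[map$offset[1] + seq_len(d[1]) - 1L,
      map$offset[2] + seq_len(d[2]) - 1L,
      map$offset[3] + seq_len(d[3]) - 1L, ] <- map$values
  out
}

#' Discard low-attention saliency values
#'
#' Sets values strictly inside the open interval `(band[1], band[2])` to
#' zero; values on the boundary are kept.
#'
#' @param map a `sal_saliency` or a numeric array.
#' @param band numeric length-2 interval, default `c(-0.1, 0.1)`.
#' @return same type as `map`.
#' @export
saliency_band_filter <- function(map, band = c(-0.1, 0.1)) {
  if (band[1] >= band[2]) stop("band lower bound must be below upper bound")
  filt <- function(v) {
    v[v > band[1] & v < band[2]] <- 0
    v
  }
  if (inherits(map, "sal_saliency")) {
    map$values <- filt(map$values)
    map
  } else {
    filt(map)
  }
}

#' Per-channel saliency extrema
#' @param map a `sal_saliency`.
#' @param channel channel index or name.
#' @return named vector `c(max = ..., min = ...)`.
#' @export
saliency_peaks <- function(map, channel = 1L) {
  if (is.character(channel)) channel <- match(channel, map$channels)
  v <- map$values[, , , channel]
  c(max = max(v), min = min(v))
}
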