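#' Segmentation model contract
#'
#' Every model usable for saliency computation implements a small S3
#' contract:
#'
#' * [forward_logits()] — forward pass returning per-voxel logits and the
#'   companion Softmax probability map (binary task: sigmoid of the logit).
#' * [input_gradient()] — gradient of a weighted sum of output logits with
#'   respect to every input voxel, one map per input channel.
#' * [activation_names()], [get_activations()], [activation_gradient()] —
#'   access to named internal layers and derivatives of a weighted logit sum
#'   with respect to their activations, up to third order.
#' * [receptive_field_radius()] — analytic bound (in voxels, Chebyshev
#'   distance) on how far an input perturbation can reach a given output
#'   voxel, derived from layer hyperparameters.
#'
#' Gradients are taken with respect to raw (pre-Softmax) logits throughout;
#' probabilities are only used for thresholding and detection.
#'
#' @name model-contract
NULL

#' Logit map returned by a forward pass
#' @param y numeric 3D array of raw logits over the input grid.
#' @param t probability threshold associated with the map (may be `NA`).
#' @return object of class `sal_logits` with fields `y`, `p` (sigmoid of
#'   `y`, the two-class Softmax probability of the foreground class) and `t`.
#' @export
sal_logits <- function(y, t = NA_real_) {
  structure(list(y = y, p = stats::plogis(y), t = t), class = "sal_logits")
}

#' @rdname model-contract
#' @param model a segmentation model object.
#' @param x a [as_volume()] volume.
#' @param ... passed to methods.
#' @export
forward_logits <- function(model, x, ...) UseMethod("forward_logits")

#' @rdname model-contract
#' @param weights numeric 3D array over the output grid: the functional whose
#'   gradient is requested is `sum(weights * y)`.
#' @export
input_gradient <- function(model, x, weights, ...) UseMethod("input_gradient")

#' @rdname model-contract
#' @export
activation_names <- function(model) UseMethod("activation_names")

#' @rdname model-contract
#' @param layer name of an exposed layer.
#' @export
get_activations <- function(model, x, layer, ...) UseMethod("get_activations")

#' @rdname model-contract
#' @param order derivative order, 1, 2 or 3.
#' @export
activation_gradient <- function(model, x, layer, weights, order = 1L, ...) {
  UseMethod("activation_gradient")
}

#' @rdname model-contract
#' @export
receptive_field_radius <- function(model) UseMethod("receptive_field_radius")

#' @export
activation_names.default <- function(model) character(0)

check_model_input <- function(model, x, n_expected) {
  if (!inherits(x, "sal_volume")) stop("`x` must be a sal_volume")
  if (vol_nchan(x) != n_expected) {
    stop(sprintf(
      "model expects %d input channel(s) but volume has %d",
      n_expected, vol_nchan(x)
    ))
  }
  invisible(TRUE)
}

check_weights <- function(weights, sdim) {
  if (!is.numeric(weights) || !identical(as.integer(dim(weights)), as.integer(sdim))) {
    stop("functional weights must be a numeric array matching the spatial grid")
  }
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# Analytic per-voxel linear model: y[v] = sum_c w_c x_c[v] + b.
# No spatial mixing, receptive-field radius 0, gradients known in closed form.
# ---------------------------------------------------------------------------

#' Analytic per-voxel linear reference model
#'
#' `y[v] = sum_c w_c * x_c[v] + b`, applied voxel-wise with no spatial
#' mixing. Its input gradients are exact and input-independent, which makes
#' it the oracle for aggregation-rule algebra: signed-maximum aggregation
#' recovers `w` exactly for any lesion size while mean aggregation scales as
#' `w / |Omega|`.
#'
#' @param w numeric vector of per-channel weights.
#' @param b scalar bias.
#' @return a model implementing the [model-contract].
#' @export
linear_model <- function(w, b = 0) {
  structure(
    list(w = as.numeric(w), b = as.numeric(b)),
    class = c("sal_linear_model", "sal_model")
  )
}

#' @export
forward_logits.sal_linear_model <- function(model, x, ...) {
  check_model_input(model, x, length(model$w))
  sdim <- vol_sdim(x)
  y <- array(model$b, sdim)
  for (c in seq_along(model$w)) {
    y <- y + model$w[c] * vol_channel(x, c)
  }
  sal_logits(y)
}

#' @export
input_gradient.sal_linear_model <- function(model, x, weights, ...) {
  check_model_input(model, x, length(model$w))
  check_weights(weights, vol_sdim(x))
  g <- array(0, c(vol_sdim(x), length(model$w)))
  for (c in seq_along(model$w)) {
    g[, , , c] <- model$w[c] * weights
  }
  g
}

#' @export
receptive_field_radius.sal_linear_model <- function(model) 0L

#' @export
get_activations.sal_linear_model <- function(model, x, layer, ...) {
  stop("linear reference model exposes no internal layers")
}

#' @export
activation_gradient.sal_linear_model <- function(model, x, layer, weights, order = 1L, ...) {
  stop("linear reference model exposes no internal layers")
}

# ---------------------------------------------------------------------------
# Fixed single-kernel convolution model: y = K * x[, designated channel],
# linear, no nonlinearity. Receptive-field radius = kernel radius.
# ---------------------------------------------------------------------------

#' Fixed-convolution reference model
#'
#' A single known convolution kernel ("same" zero padding, odd extents)
#' applied to one designated input channel, with no nonlinearity. Because the
#' model is linear, gradients are input-independent and the gradient of a
#' single output voxel is the flipped kernel centred at that voxel — an exact
#' oracle for locality (zero saliency beyond the kernel radius).
#'
#' @param kernel numeric array with odd extents; a plain vector is read as a
#'   kernel along the first axis.
#' @param channel index of the input channel the kernel is applied to.
#' @param n_channels number of input channels the model expects.
#' @param bias scalar added to every output voxel.
#' @return a model implementing the [model-contract].
#' @export
conv_model <- function(kernel, channel = 1L, n_channels = 1L, bias = 0) {
  if (is.null(dim(kernel))) kernel <- array(kernel, c(length(kernel), 1L, 1L))
  kd <- dim(kernel)
  if (length(kd) == 2L) kernel <- array(kernel, c(kd, 1L))
  kd <- dim(kernel)
  if (length(kd) != 3L || any(kd %% 2L == 0L)) {
    stop("kernel must be a 1-3D array with odd extents")
  }
  if (channel < 1 || channel > n_channels) stop("designated channel out of range")
  structure(
    list(kernel = kernel, channel = as.integer(channel),
         n_channels = as.integer(n_channels), bias = as.numeric(bias)),
    class = c("sal_conv_model", "sal_model")
  )
}

#' @export
forward_logits.sal_conv_model <- function(model, x, ...) {
  check_model_input(model, x, model$n_channels)
  sdim <- vol_sdim(x)
  ch <- vol_channel(x, model$channel)
  w <- array(model$kernel, c(dim(model$kernel), 1L, 1L))
  y <- cpp_conv3d(
    as.numeric(ch), as.integer(c(sdim, 1L)),
    as.numeric(w), as.integer(dim(w)), model$bias
  )
  dim(y) <- sdim
  sal_logits(y)
}

#' @export
input_gradient.sal_conv_model <- function(model, x, weights, ...) {
  check_model_input(model, x, model$n_channels)
  sdim <- vol_sdim(x)
  check_weights(weights, sdim)
  w <- array(model$kernel, c(dim(model$kernel), 1L, 1L))
  dx <- cpp_conv3d_bwd_input(
    as.numeric(weights), as.integer(c(sdim, 1L)),
    as.numeric(w), as.integer(dim(w))
  )
  g <- array(0, c(sdim, model$n_channels))
  g[, , , model$channel] <- dx
  g
}

#' @export
receptive_field_radius.sal_conv_model <- function(model) {
  as.integer(max((dim(model$kernel) - 1L) / 2L))
}

#' @export
get_activations.sal_conv_model <- function(model, x, layer, ...) {
  stop("fixed-convolution reference model exposes no internal layers")
}

#' @export
activation_gradient.sal_conv_model <- function(model, x, layer, weights, order = 1L, ...) {
  stop("fixed-convolution reference model exposes no internal layers")
}

# ---------------------------------------------------------------------------
# Model registry
# ---------------------------------------------------------------------------

.model_registry <- new.env(parent = emptyenv())

#' Model plug-in registry
#'
#' Models are constructible by name from a plain configuration list (or JSON
#' file), so pipelines can be described entirely in configuration.
#'
#' @param name registry key.
#' @param constructor function taking a configuration list and returning a
#'   model implementing the [model-contract].
#' @export
register_model <- function(name, constructor) {
  stopifnot(is.character(name), is.function(constructor))
  assign(name, constructor, envir = .model_registry)
  invisible(name)
}

#' @rdname register_model
#' @param config a list (or path to a JSON file) with a `model` field naming
#'   the registered constructor; remaining fields are passed on.
#' @export
model_from_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  name <- config$model
  if (is.null(name) || !exists(name, envir = .model_registry)) {
    stop(sprintf("unknown model '%s'", if (is.null(name)) "<missing>" else name))
  }
  ctor <- get(name, envir = .model_registry)
  ctor(config[setdiff(names(config), "model")])
}

register_builtin_models <- function() {
  register_model("linear", function(cfg) {
    linear_model(w = unlist(cfg$w), b = if (is.null(cfg$b)) 0 else cfg$b)
  })
  register_model("fixed_conv", function(cfg) {
    k <- cfg$kernel
    if (!is.null(cfg$kernel_dim)) k <- array(unlist(k), unlist(cfg$kernel_dim))
    conv_model(
      kernel = if (is.array(k)) k else unlist(k),
      channel = if (is.null(cfg$channel)) 1L else cfg$channel,
      n_channels = if (is.null(cfg$n_channels)) 1L else cfg$n_channels,
      bias = if (is.null(cfg$bias)) 0 else cfg$bias
    )
  })
  register_model("tiny_cnn", function(cfg) {
    do.call(tiny_cnn, cfg)
  })
}
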