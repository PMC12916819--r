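#' Tiny trainable encoder-decoder CNN
#'
#' A small segmentation network with two resolution levels and a skip
#' connection, written directly on top of the package's convolution kernels
#' so that every derivative used for saliency is available without an
#' external autodiff framework:
#'
#' ```
#' x -> conv3 (Cin -> c1) -> ReLU ["enc_relu"]
#'   -> avgpool/2 -> conv3 (c1 -> c2) -> ReLU ["bottleneck_relu"]
#'   -> nearest-upsample x2 -> concat(skip) -> conv3 (c1+c2 -> c1) -> ReLU
#'   -> conv3 (c1 -> c1) -> ReLU ["dec_relu"] -> conv1 (c1 -> 1) = logit
#' ```
#'
#' With the default widths (`c1 = 6`, `c2 = 12`) the model has about 10k
#' parameters. The two decoder blocks give the gradient path enough ReLU
#' gating for input gradients to depend on image content rather than only on
#' the learned weights. The logit head is a 1x1x1 convolution, so the logits are
#' exactly linear in the `"dec_relu"` activations — the relevant degenerate
#' case for exact higher-order activation derivatives (see
#' [alpha_coefficients()]). The analytic receptive-field radius is 6 voxels
#' (Chebyshev): encoder conv(+1), pool+bottleneck conv(+3 after upsampling
#' alignment), two decoder convs(+2).
#'
#' Spatial extents may be odd: inputs are zero-padded to even extents
#' internally and outputs cropped back.
#'
#' @param n_channels number of input channels.
#' @param c1,c2 encoder/decoder and bottleneck widths.
#' @param seed integer seed for He-normal weight initialization.
#' @return a model implementing the [model-contract].
#' @export
tiny_cnn <- function(n_channels = 2L, c1 = 6L, c2 = 12L, seed = 1L) {
  rng <- local({
    set.seed(seed)
    function(n, fan_in) stats::rnorm(n, sd = sqrt(2 / fan_in))
  })
  he <- function(kd) {
    fan_in <- prod(kd[1:4])
    array(rng(prod(kd), fan_in), kd)
  }
  params <- list(
    w1 = he(c(3L, 3L, 3L, n_channels, c1)), b1 = rep(0.1, c1),
    w2 = he(c(3L, 3L, 3L, c1, c2)),         b2 = rep(0.1, c2),
    w3 = he(c(3L, 3L, 3L, c1 + c2, c1)),    b3 = rep(0.1, c1),
    w4 = he(c(3L, 3L, 3L, c1, c1)),         b4 = rep(0.1, c1),
    wh = he(c(1L, 1L, 1L, c1, 1L)),         bh = 0
  )
  structure(
    list(params = params, n_channels = as.integer(n_channels),
         c1 = as.integer(c1), c2 = as.integer(c2), seed = as.integer(seed),
         trained = FALSE),
    class = c("sal_tiny_cnn", "sal_model")
  )
}

conv_fwd <- function(x, w, b) {
  y <- cpp_conv3d(as.numeric(x), as.integer(dim(x)), as.numeric(w), as.integer(dim(w)), as.numeric(b))
  y
}
conv_bwd_x <- function(dy, w) {
  cpp_conv3d_bwd_input(as.numeric(dy), as.integer(dim(dy)), as.numeric(w), as.integer(dim(w)))
}
conv_bwd_w <- function(x, dy, kd) {
  cpp_conv3d_bwd_weights(as.numeric(x), as.integer(dim(x)),
                         as.numeric(dy), as.integer(dim(dy)), as.integer(kd))
}

# pad spatial extents (> 1) up to even numbers with zeros at the high end
pad_even <- function(a) {
  d <- dim(a)
  pad <- ifelse(d[1:3] > 1L, d[1:3] %% 2L, 0L)
  if (all(pad == 0L)) return(list(a = a, pad = pad))
  out <- array(0, c(d[1:3] + pad, d[4]))
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), ] <- a
  list(a = out, pad = pad)
}
unpad <- function(a, orig) {
  a[seq_len(orig[1]), seq_len(orig[2]), seq_len(orig[3]), , drop = FALSE]
}

cnn_forward_cache <- function(model, xarr) {
  orig <- dim(xarr)[1:3]
  pp <- pad_even(xarr)
  x <- pp$a
  p <- model$params
  z1 <- conv_fwd(x, p$w1, p$b1); a1 <- pmax(z1, 0); dim(a1) <- dim(z1)
  p1 <- cpp_avgpool3d(as.numeric(a1), as.integer(dim(a1)))
  z2 <- conv_fwd(p1, p$w2, p$b2); a2 <- pmax(z2, 0); dim(a2) <- dim(z2)
  u2 <- cpp_upsample_nearest(as.numeric(a2), as.integer(dim(a2)),
                             as.integer(c(dim(a1)[1:3], dim(a2)[4])))
  cat3 <- array(0, c(dim(a1)[1:3], model$c1 + model$c2))
  cat3[, , , seq_len(model$c1)] <- a1
  cat3[, , , model$c1 + seq_len(model$c2)] <- u2
  z3 <- conv_fwd(cat3, p$w3, p$b3); a3 <- pmax(z3, 0); dim(a3) <- dim(z3)
  z4 <- conv_fwd(a3, p$w4, p$b4); a4 <- pmax(z4, 0); dim(a4) <- dim(z4)
  y <- conv_fwd(a4, p$wh, p$bh)
  list(x = x, z1 = z1, a1 = a1, p1 = p1, z2 = z2, a2 = a2, u2 = u2,
       cat3 = cat3, z3 = z3, a3 = a3, z4 = z4, a4 = a4, y = y,
       orig = orig, pad = pp$pad)
}

# Backward pass from a gradient `dy` on the (padded) logit grid.
# Returns whatever of dx / parameter gradients / intermediate activation
# gradients is requested; activation gradients are reported on the padded
# grid and cropped by callers.
cnn_backward <- function(model, cache, dy, want_params = FALSE, upto_layer = NULL) {
  p <- model$params
  da4 <- conv_bwd_x(dy, p$wh)
  if (!is.null(upto_layer) && upto_layer == "dec_relu") {
    return(list(d_act = da4))
  }
  dz4 <- da4 * (cache$z4 > 0); dim(dz4) <- dim(da4)
  da3 <- conv_bwd_x(dz4, p$w4)
  dz3 <- da3 * (cache$z3 > 0); dim(dz3) <- dim(da3)
  dcat <- conv_bwd_x(dz3, p$w3)
  c1 <- model$c1; c2 <- model$c2
  da1_skip <- dcat[, , , seq_len(c1), drop = FALSE]
  du2 <- dcat[, , , c1 + seq_len(c2), drop = FALSE]
  da2 <- cpp_upsample_nearest_bwd(as.numeric(du2), as.integer(dim(du2)),
                                  as.integer(dim(cache$a2)))
  if (!is.null(upto_layer) && upto_layer == "bottleneck_relu") {
    return(list(d_act = da2))
  }
  dz2 <- da2 * (cache$z2 > 0); dim(dz2) <- dim(da2)
  dp1 <- conv_bwd_x(dz2, p$w2)
  da1_pool <- cpp_avgpool3d_bwd(as.numeric(dp1), as.integer(dim(dp1)),
                                as.integer(dim(cache$a1)))
  da1 <- da1_skip + da1_pool; dim(da1) <- dim(cache$a1)
  if (!is.null(upto_layer) && upto_layer == "enc_relu") {
    return(list(d_act = da1))
  }
  dz1 <- da1 * (cache$z1 > 0); dim(dz1) <- dim(da1)
  dx <- conv_bwd_x(dz1, p$w1)
  out <- list(dx = dx)
  if (want_params) {
    g4 <- conv_bwd_w(cache$a3, dz4, dim(p$w4)[1:3])
    g3 <- conv_bwd_w(cache$cat3, dz3, dim(p$w3)[1:3])
    g2 <- conv_bwd_w(cache$p1, dz2, dim(p$w2)[1:3])
    g1 <- conv_bwd_w(cache$x, dz1, dim(p$w1)[1:3])
    gh <- conv_bwd_w(cache$a4, dy, dim(p$wh)[1:3])
    out$grads <- list(w1 = g1$dw, b1 = g1$db, w2 = g2$dw, b2 = g2$db,
                      w3 = g3$dw, b3 = g3$db, w4 = g4$dw, b4 = g4$db,
                      wh = gh$dw, bh = gh$db)
  }
  out
}

embed_padded <- function(arr3, pad_dims) {
  out <- array(0, c(pad_dims, 1L))
  out[seq_len(dim(arr3)[1]), seq_len(dim(arr3)[2]), seq_len(dim(arr3)[3]), 1] <- arr3
  out
}

#' @export
forward_logits.sal_tiny_cnn <- function(model, x, ...) {
  check_model_input(model, x, model$n_channels)
  cache <- cnn_forward_cache(model, x$data)
  y <- unpad(cache$y, cache$orig)
  dim(y) <- cache$orig
  sal_logits(y)
}

#' @export
input_gradient.sal_tiny_cnn <- function(model, x, weights, ...) {
  check_model_input(model, x, model$n_channels)
  sdim <- vol_sdim(x)
  check_weights(weights, sdim)
  cache <- cnn_forward_cache(model, x$data)
  dy <- embed_padded(weights, dim(cache$x)[1:3])
  dx <- cnn_backward(model, cache, dy)$dx
  g <- unpad(dx, cache$orig)
  dim(g) <- c(sdim, model$n_channels)
  g
}

#' @export
receptive_field_radius.sal_tiny_cnn <- function(model) 6L

#' @export
activation_names.sal_tiny_cnn <- function(model) {
  c("enc_relu", "bottleneck_relu", "dec_relu")
}

#' @export
get_activations.sal_tiny_cnn <- function(model, x, layer = "dec_relu", ...) {
  check_model_input(model, x, model$n_channels)
  if (!layer %in% activation_names(model)) {
    stop(sprintf("layer '%s' is not exposed", layer))
  }
  cache <- cnn_forward_cache(model, x$data)
  a <- switch(layer, enc_relu = cache$a1, bottleneck_relu = cache$a2,
              dec_relu = cache$a4)
  if (layer != "bottleneck_relu") {
    a <- a[seq_len(cache$orig[1]), seq_len(cache$orig[2]), seq_len(cache$orig[3]), , drop = FALSE]
  }
  structure(a, layer = layer, input_dim = cache$orig)
}

#' @export
activation_gradient.sal_tiny_cnn <- function(model, x, layer, weights, order = 1L, ...) {
  check_model_input(model, x, model$n_channels)
  if (!layer %in% activation_names(model)) {
    stop(sprintf("layer '%s' is not exposed", layer))
  }
  if (!order %in% 1:3) stop("derivative order must be 1, 2 or 3")
  sdim <- vol_sdim(x)
  check_weights(weights, sdim)
  cache <- cnn_forward_cache(model, x$data)
  adim_full <- switch(layer, enc_relu = dim(cache$a1),
                      bottleneck_relu = dim(cache$a2), dec_relu = dim(cache$a4))
  if (order >= 2L) {
    # Downstream of every exposed layer is a composition of convolutions and
    # ReLUs: piecewise linear in the activations, so exact second and third
    # derivatives vanish (everywhere for "dec_relu", whose downstream is the
    # linear 1x1 head; almost everywhere for the deeper layers).
    g <- array(0, adim_full)
  } else {
    dy <- embed_padded(weights, dim(cache$x)[1:3])
    g <- cnn_backward(model, cache, dy, upto_layer = layer)$d_act
  }
  if (layer != "bottleneck_relu") {
    g <- g[seq_len(cache$orig[1]), seq_len(cache$orig[2]), seq_len(cache$orig[3]), , drop = FALSE]
  }
  attr(g, "method") <- if (order >= 2L) "exact_piecewise_linear" else "exact_backprop"
  g
}

# Re-run the network head from a replaced activation of an exposed layer
# (finite-difference support). Only layers at input resolution are supported.
cnn_forward_from <- function(model, cache, layer, a_new) {
  p <- model$params
  if (layer == "dec_relu") {
    return(conv_fwd(a_new, p$wh, p$bh))
  }
  if (layer == "enc_relu") {
    p1 <- cpp_avgpool3d(as.numeric(a_new), as.integer(dim(a_new)))
    z2 <- conv_fwd(p1, p$w2, p$b2); a2 <- pmax(z2, 0); dim(a2) <- dim(z2)
    u2 <- cpp_upsample_nearest(as.numeric(a2), as.integer(dim(a2)),
                               as.integer(c(dim(a_new)[1:3], dim(a2)[4])))
    cat3 <- array(0, c(dim(a_new)[1:3], model$c1 + model$c2))
    cat3[, , , seq_len(model$c1)] <- a_new
    cat3[, , , model$c1 + seq_len(model$c2)] <- u2
    z3 <- conv_fwd(cat3, p$w3, p$b3); a3 <- pmax(z3, 0); dim(a3) <- dim(z3)
    z4 <- conv_fwd(a3, p$w4, p$b4); a4 <- pmax(z4, 0); dim(a4) <- dim(z4)
    return(conv_fwd(a4, p$wh, p$bh))
  }
  stop("forward-from is supported for 'enc_relu' and 'dec_relu'")
}

#' Save / load a model as JSON
#'
#' Weights and hyperparameters are stored as plain JSON so model artifacts
#' are text files.
#'
#' @param model a `tiny_cnn` model.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "sal_tiny_cnn"))
  obj <- list(
    type = "tiny_cnn",
    n_channels = model$n_channels, c1 = model$c1, c2 = model$c2,
    seed = model$seed, trained = model$trained,
    params = lapply(model$params, function(p) {
      list(dim = if (is.null(dim(p))) length(p) else dim(p), values = as.numeric(p))
    })
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "tiny_cnn")) stop("unsupported model file")
  m <- tiny_cnn(n_channels = obj$n_channels, c1 = obj$c1, c2 = obj$c2, seed = obj$seed)
  m$params <- lapply(obj$params, function(p) {
    v <- as.numeric(p$values)
    if (length(p$dim) > 1L) dim(v) <- as.integer(p$dim)
    v
  })
  m$trained <- isTRUE(obj$trained)
  m
}
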