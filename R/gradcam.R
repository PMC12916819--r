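#' Aggregate logits for class-level Grad-CAM++
#'
#' `y' = sum of logits y[v] strictly greater than the threshold t`. Returns 0
#' with a warning when no voxel exceeds the threshold.
#'
#' @param logits a [sal_logits()] object or numeric array of logits.
#' @param t threshold applied to the raw logits.
#' @return scalar `y'` with attribute `selection` (logical array).
#' @export
aggregate_logits_class <- function(logits, t) {
  y <- if (inherits(logits, "sal_logits")) logits$y else logits
  sel <- y > t
  if (!any(sel)) {
    warning("no logit exceeds the threshold; y' = 0 over an empty selection")
    return(structure(0, selection = sel))
  }
  structure(sum(y[sel]), selection = sel)
}

#' Aggregate logits over an instance domain
#'
#' `y' = sum of y[v] for v in Omega`, signed and unthresholded.
#'
#' @param logits a [sal_logits()] object or numeric array.
#' @param omega a non-empty [new_instance()].
#' @return scalar `y'`.
#' @export
aggregate_logits_instance <- function(logits, omega) {
  if (!inherits(omega, "sal_instance") || omega$cardinality == 0L) {
    stop("empty lesion domain: omega must be a non-empty instance")
  }
  y <- if (inherits(logits, "sal_logits")) logits$y else logits
  sum(y[omega$lin])
}

#' Grad-CAM++ alpha coefficients
#'
#' `alpha^k[v] = d2 / (2 * d2 + S_A * d3)` where `d2`, `d3` are the second
#' and third derivatives of the aggregate `y'` with respect to `A^k[v]` and
#' `S_A` is the sum of the k-th activation map (the literal reading of the
#' published formula, where the activation sum runs over the whole domain
#' against the local third derivative). Where the denominator's magnitude is
#' below `eps`, alpha is set to 0: at such points the aggregate is (locally)
#' linear in the activation and the coefficient is degenerate.
#'
#' @param activations array `(dims..., K)` of activation maps.
#' @param d2,d3 derivative arrays of the same shape.
#' @param eps guard threshold for the denominator.
#' @param denominator `"global_sum"` for the literal form; `"per_location"`
#'   replaces `S_A` by the local activation `A^k[v]`.
#' @return alpha array of the activations' shape.
#' @export
alpha_coefficients <- function(activations, d2, d3, eps = 1e-8,
                               denominator = c("global_sum", "per_location")) {
  denominator <- match.arg(denominator)
  ad <- dim(activations)
  stopifnot(identical(dim(d2), ad), identical(dim(d3), ad))
  K <- ad[4]
  alpha <- array(0, ad)
  for (k in seq_len(K)) {
    Ak <- activations[, , , k]
    d2k <- d2[, , , k]; d3k <- d3[, , , k]
    SA <- if (denominator == "global_sum") sum(Ak) else Ak
    den <- 2 * d2k + SA * d3k
    a <- d2k / den
    a[abs(den) < eps] <- 0
    alpha[, , , k] <- a
  }
  alpha
}

relu <- function(v) pmax(v, 0)

# alpha via the power-of-first-gradient route used by the original
# Grad-CAM++ exponential formulation: substituting exp(y') for the score
# turns the higher-order derivatives into powers of the first gradient g,
# and the exponential factor cancels: alpha = g^2 / (2 g^2 + S_A g^3).
# This is the route of choice for piecewise-linear (ReLU) networks, whose
# exact second and third derivatives vanish almost everywhere.
alpha_expgrad <- function(activations, g1, eps = 1e-8,
                          denominator = "global_sum") {
  alpha_coefficients(activations, d2 = g1^2, d3 = g1^3, eps = eps,
                     denominator = denominator)
}

# interpolate a 3D array to new dims, linearly along each axis
upsample_linear <- function(a, outdims) {
  d <- dim(a)
  for (ax in 1:3) {
    if (d[ax] == outdims[ax]) next
    # voxel-centre alignment: target centre i maps to source coordinate
    src <- (seq_len(outdims[ax]) - 0.5) * d[ax] / outdims[ax] + 0.5
    a <- apply(a, setdiff(1:3, ax), function(v) {
      stats::approx(seq_along(v), v, xout = src, rule = 2)$y
    })
    # apply returns (outdims[ax], other dims); restore axis order
    perm <- order(c(ax, setdiff(1:3, ax)))
    a <- aperm(array(a, c(outdims[ax], d[setdiff(1:3, ax)])), perm)
    d <- dim(a)
  }
  a
}

upsample_heatmap <- function(m, outdims, method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  if (all(dim(m) == outdims)) return(m)
  if (method == "nearest") {
    m4 <- array(m, c(dim(m), 1L))
    out <- cpp_upsample_nearest(as.numeric(m4), as.integer(dim(m4)),
                                as.integer(c(outdims, 1L)))
    array(out, outdims)
  } else {
    upsample_linear(m, outdims)
  }
}

new_heatmap <- function(values, mode, label = NA_integer_, layer = NA_character_,
                        route = NA_character_) {
  structure(list(values = values, mode = mode, label = label, layer = layer,
                 route = route),
            class = "sal_heatmap")
}

#' @export
print.sal_heatmap <- function(x, ...) {
  cat(sprintf(
    "<sal_heatmap> %s-level (layer %s, route %s): dims %s, max %.4g\n",
    x$mode, x$layer, x$route, paste(dim(x$values), collapse = "x"),
    max(x$values)
  ))
  invisible(x)
}

gradcam_core <- function(model, x, layer, weights_on_logits, route, eps,
                         denominator, upsample, mode, label = NA_integer_) {
  A <- get_activations(model, x, layer)
  g1 <- activation_gradient(model, x, layer, weights_on_logits, order = 1L)
  if (route == "exact") {
    d2 <- activation_gradient(model, x, layer, weights_on_logits, order = 2L)
    d3 <- activation_gradient(model, x, layer, weights_on_logits, order = 3L)
    alpha <- alpha_coefficients(unclass_arr(A), unclass_arr(d2), unclass_arr(d3),
                                eps = eps, denominator = denominator)
  } else {
    alpha <- alpha_expgrad(unclass_arr(A), unclass_arr(g1), eps = eps,
                           denominator = denominator)
  }
  K <- dim(A)[4]
  adim <- dim(A)[1:3]
  M <- array(0, adim)
  rg <- relu(unclass_arr(g1))
  if (mode == "class") {
    for (k in seq_len(K)) {
      wk <- sum(alpha[, , , k] * rg[, , , k])  # scalar weight per map
      M <- M + wk * A[, , , k]
    }
  } else {
    for (k in seq_len(K)) {
      wkv <- alpha[, , , k] * rg[, , , k]      # per-voxel weight, no spatial sum
      M <- M + wkv * A[, , , k]
    }
  }
  M <- relu(M)
  dim(M) <- adim
  M <- upsample_heatmap(M, vol_sdim(x), method = upsample)
  new_heatmap(M, mode = mode, label = label, layer = layer, route = route)
}

unclass_arr <- function(a) {
  attributes(a) <- list(dim = dim(a))
  a
}

#' Class-level Grad-CAM++ heatmap for segmentation
#'
#' Aggregates all supra-threshold logits into `y'`, weights each activation
#' map of the chosen layer by a single rectified-gradient weight and returns
#' the rectified linear combination, upsampled to the input grid when the
#' layer's resolution differs. This is the class-level explanation: the
#' contributions of every instance of the class are merged in one map.
#'
#' @param model model implementing the [model-contract] with exposed layers.
#' @param x input volume.
#' @param layer exposed layer name (default `"dec_relu"`, the final
#'   activation layer before the logit head).
#' @param t logit threshold defining the aggregate `y'`.
#' @param route `"expgrad"` (default; power-of-first-gradient coefficients,
#'   the appropriate route for ReLU networks whose exact higher-order
#'   derivatives vanish) or `"exact"` (nested differentiation via
#'   [activation_gradient()]).
#' @param eps denominator guard for [alpha_coefficients()].
#' @param denominator see [alpha_coefficients()].
#' @param upsample `"trilinear"` or `"nearest"`.
#' @return a `sal_heatmap` (non-negative everywhere).
#' @export
gradcam_class_map <- function(model, x, layer = "dec_relu", t = 0.3,
                              route = c("expgrad", "exact"), eps = 1e-8,
                              denominator = "global_sum",
                              upsample = "trilinear") {
  route <- match.arg(route)
  yl <- forward_logits(model, x)
  yp <- aggregate_logits_class(yl, t)
  weights <- array(as.numeric(attr(yp, "selection")), vol_sdim(x))
  gradcam_core(model, x, layer, weights, route, eps, denominator, upsample,
               mode = "class")
}

#' Instance-level Grad-CAM++ heatmap
#'
#' The instance adaptation: `y'` is the (unthresholded, signed) sum of logits
#' over one lesion domain Omega, and the spatial summation in the class-level
#' weights is removed so each activation-map element keeps its own weight
#' `w^k[v] = alpha^k[v] * Relu(d y' / d A^k[v])`. The result
#' `Relu(sum_k w^k[v] A^k[v])` isolates the attribution of the single
#' instance instead of merging all instances of the class.
#'
#' @inheritParams gradcam_class_map
#' @param omega a non-empty [new_instance()] on `x`'s grid.
#' @return a `sal_heatmap` (non-negative everywhere).
#' @export
gradcam_instance_map <- function(model, x, layer = "dec_relu", omega,
                                 route = c("expgrad", "exact"), eps = 1e-8,
                                 denominator = "global_sum",
                                 upsample = "trilinear") {
  route <- match.arg(route)
  if (!inherits(omega, "sal_instance") || omega$cardinality == 0L) {
    stop("empty lesion domain: omega must be a non-empty instance")
  }
  weights <- array(0, vol_sdim(x))
  weights[omega$lin] <- 1
  gradcam_core(model, x, layer, weights, route, eps, denominator, upsample,
               mode = "instance", label = omega$label)
}

#' Finite-difference derivative of a logit aggregate w.r.t. one activation
#'
#' Central-difference check of the exact activation-derivative path: the
#' aggregate `sum(weights * y)` is re-evaluated with the activation map of
#' `layer` perturbed at a single location. Used to validate exact derivatives
#' on reference models.
#'
#' @param model a `tiny_cnn` model (layers `"enc_relu"`, `"dec_relu"`).
#' @param x input volume.
#' @param layer layer name.
#' @param weights functional weights over the logit grid.
#' @param at integer vector `c(i1, i2, i3, k)`: activation location.
#' @param order 1, 2 or 3.
#' @param step finite-difference step (default 1e-3).
#' @return scalar derivative estimate.
#' @export
fd_activation_derivative <- function(model, x, layer, weights, at,
                                     order = 1L, step = 1e-3) {
  stopifnot(inherits(model, "sal_tiny_cnn"))
  cache <- cnn_forward_cache(model, x$data)
  pd <- dim(cache$x)[1:3]
  wpad <- embed_padded(weights, pd)[, , , 1]
  A0 <- switch(layer, enc_relu = cache$a1, dec_relu = cache$a3,
               stop("finite differences support 'enc_relu' and 'dec_relu'"))
  f <- function(delta) {
    A <- A0
    A[at[1], at[2], at[3], at[4]] <- A[at[1], at[2], at[3], at[4]] + delta
    y <- cnn_forward_from(model, cache, layer, A)
    sum(wpad * y[, , , 1])
  }
  h <- step
  switch(as.character(order),
    "1" = (f(h) - f(-h)) / (2 * h),
    "2" = (f(h) - 2 * f(0) + f(-h)) / h^2,
    "3" = (f(2 * h) - 2 * f(h) + 2 * f(-h) - f(-2 * h)) / (2 * h^3),
    stop("order must be 1, 2 or 3")
  )
}
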