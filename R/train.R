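#' Train the tiny CNN on phantoms
#'
#' Full-volume Adam training with a plain overlap + cross-entropy objective:
#' voxel-wise binary cross-entropy with a positive-class weight (capped ratio
#' of background to lesion voxels) plus a soft-Dice term. Deterministic for a
#' fixed seed and thread count.
#'
#' @param phantoms list of at least 20 [generate_phantom()] phantoms.
#' @param epochs passes over the training set; `0` returns the untrained
#'   model with a warning.
#' @param seed seed controlling weight initialization and epoch shuffling.
#' @param lr Adam learning rate.
#' @param val_phantoms optional list of held-out phantoms for a lesion-wise
#'   validation summary.
#' @param model optionally continue training an existing [tiny_cnn()].
#' @param t probability threshold used for validation detection.
#' @param verbose print per-epoch losses.
#' @return list with `model`, `history` (mean loss per epoch) and
#'   `validation` (`NULL` or a list with lesion-wise TPR and counts).
#' @export
train_tiny_model <- function(phantoms, epochs = 8L, seed = 1L, lr = 0.01,
                             val_phantoms = NULL, model = NULL, t = 0.3,
                             verbose = FALSE) {
  if (length(phantoms) < 20L) {
    stop("training requires at least 20 phantoms")
  }
  if (is.null(model)) {
    model <- tiny_cnn(n_channels = vol_nchan(phantoms[[1]]$volume), seed = seed)
  }
  if (epochs == 0L) {
    warning("0 epochs requested: returning the untrained model")
    return(list(model = model, history = numeric(0),
                validation = validate_model(model, val_phantoms, t)))
  }
  p <- model$params
  m1 <- lapply(p, function(q) q * 0)
  m2 <- lapply(p, function(q) q * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  history <- numeric(epochs)
  set.seed(seed)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(length(phantoms))
    losses <- numeric(length(ord))
    for (ii in seq_along(ord)) {
      ph <- phantoms[[ord[ii]]]
      cache <- cnn_forward_cache(model, ph$volume$data)
      tgt <- embed_padded(array(as.numeric(ph$gt_mask), dim(ph$gt_mask)),
                          dim(cache$x)[1:3])
      y <- cache$y
      s <- stats::plogis(y)
      npos <- sum(tgt); nneg <- length(tgt) - npos
      pw <- if (npos > 0) min(nneg / npos, 50) else 1
      # weighted BCE
      bce <- -(pw * tgt * log(pmax(s, 1e-12)) +
                 (1 - tgt) * log(pmax(1 - s, 1e-12)))
      nvox <- length(tgt)
      dbce_dy <- (s * (pw * tgt + 1 - tgt) - pw * tgt) / nvox
      # soft Dice on probabilities
      inter <- sum(s * tgt); ssum <- sum(s) + sum(tgt) + 1e-6
      dice_loss <- 1 - 2 * inter / ssum
      ddice_ds <- -2 * (tgt * ssum - inter) / ssum^2
      dy <- dbce_dy + ddice_ds * s * (1 - s)
      dim(dy) <- dim(y)
      loss <- mean(bce) + dice_loss
      if (!is.finite(loss)) stop("training diverged: non-finite loss")
      losses[ii] <- loss
      grads <- cnn_backward(model, cache, dy, want_params = TRUE)$grads
      step <- step + 1L
      for (nm in names(p)) {
        m1[[nm]] <- b1 * m1[[nm]] + (1 - b1) * grads[[nm]]
        m2[[nm]] <- b2 * m2[[nm]] + (1 - b2) * grads[[nm]]^2
        mhat <- m1[[nm]] / (1 - b1^step)
        vhat <- m2[[nm]] / (1 - b2^step)
        p[[nm]] <- p[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
      model$params <- p
    }
    history[ep] <- mean(losses)
    if (verbose) message(sprintf("epoch %d: loss %.4f", ep, history[ep]))
  }
  model$trained <- TRUE
  list(model = model, history = history,
       validation = validate_model(model, val_phantoms, t))
}

validate_model <- function(model, val_phantoms, t = 0.3) {
  if (is.null(val_phantoms) || length(val_phantoms) == 0L) return(NULL)
  n_gt <- 0L; n_hit <- 0L; n_pred <- 0L; n_tp_pred <- 0L
  for (ph in val_phantoms) {
    lp <- forward_logits(model, ph$volume)
    pred_mask <- binarize_probability(lp$p, t)
    gt_inst <- label_instances(ph$gt_mask, 18L, 5, ph$volume$spacing,
                               origin = "ground_truth")
    pred_inst <- label_instances(pred_mask, 18L, 5, ph$volume$spacing)
    es <- classify_examples(pred_inst, gt_inst, pred_mask, ph$gt_mask)
    n_gt <- n_gt + length(gt_inst)
    n_hit <- n_hit + (length(gt_inst) - length(es$fn))
    n_pred <- n_pred + length(pred_inst)
    n_tp_pred <- n_tp_pred + length(es$tp)
  }
  list(
    lesion_tpr = if (n_gt > 0) n_hit / n_gt else NA_real_,
    lesion_fdr = if (n_pred > 0) 1 - n_tp_pred / n_pred else NA_real_,
    n_gt = n_gt, n_pred = n_pred
  )
}

#' Generate a stream of training phantoms
#'
#' Convenience wrapper producing `n` phantoms with derived seeds.
#'
#' @param n number of phantoms.
#' @param base_cfg template [phantom_config()]; each phantom gets seed
#'   `base_cfg$seed * 1000 + i`.
#' @return list of phantoms.
#' @export
phantom_stream <- function(n, base_cfg = phantom_config()) {
  lapply(seq_len(n), function(i) {
    cfg <- base_cfg
    cfg$seed <- as.integer((base_cfg$seed * 1000L + i) %% .Machine$integer.max)
    generate_phantom(cfg)
  })
}
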