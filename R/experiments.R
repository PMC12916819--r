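#' Two-sided Mann-Whitney U test with an exact small-sample path
#'
#' For group sizes both at most `exact_max` (default 8) the permutation null
#' is enumerated exactly over all assignments of the pooled mid-ranks to the
#' two groups (ties handled by mid-ranks), and the two-sided p-value is
#' `min(1, 2 * min(P(U <= u), P(U >= u)))`. Larger groups use the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y numeric samples.
#' @param exact_max largest group size for the exact path.
#' @return list with `U` (statistic for the first sample), `p`, `method`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 8L) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)  # mid-ranks under ties
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    combs <- utils::combn(n1 + n2, n1)
    us <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    tol <- 1e-9
    p <- min(1, 2 * min(mean(us <= u_obs + tol), mean(us >= u_obs - tol)))
    list(U = u_obs, p = p, method = "exact_enumeration")
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    )
    list(U = u_obs, p = wt$p.value, method = "normal_approx_tie_corrected")
  }
}

boot_ci_median <- function(v, n_boot = 1000L, seed = 1L, conf = 0.95) {
  set.seed(seed)
  meds <- replicate(n_boot, stats::median(sample(v, replace = TRUE)))
  a <- (1 - conf) / 2
  stats::quantile(meds, c(a, 1 - a), names = FALSE)
}

#' Peak-value distributions across example categories
#'
#' For each example's saliency map the maximum and minimum value of the
#' requested channel is taken; per category the median and a seeded bootstrap
#' 95% CI (1000 resamples) are reported for maxima and minima, together with
#' two-sided Mann-Whitney comparisons of all category pairs.
#'
#' @param maps named list with components among `tp`, `fp`, `fn`, `tn`, each
#'   a list of `sal_saliency` maps (for FN / TN examples the maps are
#'   computed with Omega set to the ground-truth instance / control sphere).
#' @param channel channel index or name used for the peaks.
#' @param n_boot bootstrap resamples for the CIs.
#' @param seed bootstrap seed.
#' @return list of data frames: `peaks` (per example), `summary` (per
#'   category medians and CIs), `tests` (pairwise Mann-Whitney on maxima and
#'   minima).
#' @export
peak_value_distributions <- function(maps, channel = 1L, n_boot = 1000L,
                                     seed = 1L) {
  cats <- intersect(c("tn", "fn", "fp", "tp"), names(maps))
  peaks <- do.call(rbind, lapply(cats, function(cat) {
    ms <- maps[[cat]]
    if (length(ms) == 0L) return(NULL)
    do.call(rbind, lapply(seq_along(ms), function(i) {
      pk <- saliency_peaks(ms[[i]], channel)
      data.frame(category = toupper(cat), example = i,
                 max = pk[["max"]], min = pk[["min"]])
    }))
  }))
  summ <- NULL; tests <- NULL
  have <- unique(peaks$category)
  for (cat in have) {
    sub <- peaks[peaks$category == cat, ]
    if (nrow(sub) < 2L) {
      warning(sprintf("category %s has fewer than 2 examples; statistics skipped", cat))
      next
    }
    for (stat in c("max", "min")) {
      v <- sub[[stat]]
      ci <- boot_ci_median(v, n_boot, seed)
      summ <- rbind(summ, data.frame(
        category = cat, stat = stat, n = length(v),
        median = stats::median(v), ci_lo = ci[1], ci_hi = ci[2]
      ))
    }
  }
  if (length(have) >= 2L) {
    prs <- utils::combn(have, 2)
    for (j in seq_len(ncol(prs))) {
      a <- prs[1, j]; b <- prs[2, j]
      for (stat in c("max", "min")) {
        va <- peaks[[stat]][peaks$category == a]
        vb <- peaks[[stat]][peaks$category == b]
        if (length(va) < 2L || length(vb) < 2L) next
        mw <- mann_whitney_u(va, vb)
        tests <- rbind(tests, data.frame(
          group1 = a, group2 = b, stat = stat, U = mw$U, p = mw$p,
          method = mw$method
        ))
      }
    }
  }
  list(peaks = peaks, summary = summ, tests = tests)
}

#' Compute instance saliency maps for every example of a set
#'
#' FN maps use the ground-truth instance as Omega; TN maps use the control
#' sphere ("some external input selects the domain" for undetected
#' examples).
#'
#' @param model,x model and input volume.
#' @param es an `example_set` from [extract_example_set()].
#' @param cfg a [noise_config()].
#' @param aggregation aggregation rule, default `"max_signed"`.
#' @param categories which categories to compute.
#' @return named list of lists of `sal_saliency` maps.
#' @export
example_saliency_maps <- function(model, x, es, cfg = noise_config(),
                                  aggregation = "max_signed",
                                  categories = c("tp", "fp", "fn", "tn")) {
  out <- list()
  for (cat in categories) {
    out[[cat]] <- lapply(es[[cat]], function(inst) {
      smoothgrad_instance(model, x, inst, cfg, aggregation = aggregation)
    })
  }
  out
}

#' Saliency sanity check on a lesion-free region
#'
#' Computes instance saliency for a probe domain placed in healthy tissue;
#' the probe must not intersect the ground-truth or prediction masks. The
#' resulting peaks are meant to be compared against the TP range: for a
#' spatially aware (trained) model they fall well below it, while for a
#' purely voxel-wise model they are identical by construction — the check is
#' only informative for models with spatial context.
#'
#' @param model,x model and input volume.
#' @param probe_omega probe instance.
#' @param gt_mask,pred_mask binary masks the probe must avoid.
#' @param cfg a [noise_config()].
#' @param aggregation aggregation rule.
#' @param channel channel for the reported peaks.
#' @return list with `map` (`sal_saliency`) and `peaks`.
#' @export
empty_region_check <- function(model, x, probe_omega, gt_mask, pred_mask,
                               cfg = noise_config(),
                               aggregation = "max_signed", channel = 1L) {
  if (length(dim(gt_mask)) == 2L) dim(gt_mask) <- c(dim(gt_mask), 1L)
  if (length(dim(pred_mask)) == 2L) dim(pred_mask) <- c(dim(pred_mask), 1L)
  if (any(gt_mask[probe_omega$lin] != 0) || any(pred_mask[probe_omega$lin] != 0)) {
    stop("probe domain intersects a lesion (ground truth or prediction)")
  }
  map <- smoothgrad_instance(model, x, probe_omega, cfg, aggregation = aggregation)
  list(map = map, peaks = saliency_peaks(map, channel))
}

#' Transplant a lesion to a new location
#'
#' Copies the intensities of a source instance (optionally together with a
#' shell of surrounding tissue, `context_margin_mm` from the lesion border)
#' onto a destination-centred footprint, per channel; all other voxels are
#' untouched. Used for the synthetic-lesion sanity checks: moving a lesion
#' into healthy tissue, outside the support, or outside with part of its
#' native context.
#'
#' @param x input volume.
#' @param source a [new_instance()] on `x`'s grid.
#' @param dest_center integer vector (length 3): destination centre voxel.
#' @param context_margin_mm shell width in mm (0 = lesion voxels only);
#'   converted to dilation steps at the volume's minimum spacing.
#' @return list with `volume` (modified copy) and `instance` (translated
#'   lesion domain, without the shell).
#' @export
transplant_lesion <- function(x, source, dest_center, context_margin_mm = 0) {
  sdim <- vol_sdim(x)
  steps <- round(context_margin_mm / min(x$spacing))
  foot <- instance_indicator(source)
  if (steps > 0) {
    for (i in seq_len(steps)) foot <- dilate_mask(foot, 6L)
  }
  foot_sub <- lin_to_sub(which(foot != 0), sdim)
  src_ctr <- round(colMeans(source$voxels))
  shift <- as.integer(round(dest_center)) - as.integer(src_ctr)
  dest_sub <- sweep(foot_sub, 2, -shift)
  if (any(dest_sub < 1) || any(dest_sub > matrix(sdim, nrow(dest_sub), 3, byrow = TRUE))) {
    stop("translated footprint falls outside the image grid")
  }
  src_lin <- sub_to_lin(foot_sub, sdim)
  dest_lin <- sub_to_lin(dest_sub, sdim)
  out <- x
  nvox <- prod(sdim)
  for (c in seq_len(vol_nchan(x))) {
    off <- (c - 1L) * nvox
    out$data[dest_lin + off] <- x$data[src_lin + off]
  }
  dest_omega <- new_instance(
    sweep(source$voxels, 2, -shift), label = source$label,
    spacing = x$spacing, origin = "manual", dims = sdim
  )
  list(volume = out, instance = dest_omega)
}

#' Contextual-information probe
#'
#' Measures how much perilesional context a model needs: at iteration 0 all
#' intensities are zeroed except the lesion domain Omega; each subsequent
#' iteration restores the original intensities on a one-step morphological
#' dilation of the visible region (face-connected element by default, one
#' step ~ 1 mm of context at 1 mm spacing). Per iteration the mean Softmax
#' score within Omega and the detection flag (any in-Omega score strictly
#' above `t`) are recorded. When the dilated region covers the whole
#' (cropped) volume the input equals the unmasked input, so the final scores
#' match plain inference.
#'
#' @param model,x model and input volume.
#' @param omega lesion domain.
#' @param iterations number of dilation iterations I (result covers 0..I).
#' @param t detection threshold on the Softmax score.
#' @param connectivity structuring element: 6 (face-connected, default) or
#'   26.
#' @param crop_margin crop margin around Omega; defaults to `iterations` so
#'   the final dilation can cover the crop.
#' @return data frame (iteration, mean_score, detected, coverage) with
#'   attribute `unmasked` (list: mean in-Omega score and detection of the
#'   unmasked input).
#' @export
context_probe <- function(model, x, omega, iterations = 35L, t = 0.3,
                          connectivity = 6L, crop_margin = NULL) {
  if (!inherits(omega, "sal_instance") || omega$cardinality == 0L) {
    stop("empty lesion domain")
  }
  if (is.null(crop_margin)) crop_margin <- iterations
  sdim <- vol_sdim(x)
  win <- crop_window(omega$voxels, sdim, as.integer(crop_margin))
  xc <- crop_volume(x, win)
  cdim <- vol_sdim(xc)
  lins <- remap_lins(omega$lin, sdim, win)
  mask <- array(0L, cdim)
  mask[lins] <- 1L
  res <- data.frame(iteration = integer(), mean_score = numeric(),
                    detected = logical(), coverage = numeric())
  for (i in 0:iterations) {
    xi <- xc
    xi$data <- xc$data * array(rep(as.numeric(mask), vol_nchan(xc)), dim(xc$data))
    p <- forward_logits(model, xi)$p
    res <- rbind(res, data.frame(
      iteration = i, mean_score = mean(p[lins]),
      detected = any(p[lins] > t), coverage = mean(mask)
    ))
    if (i < iterations) mask <- dilate_mask(mask, connectivity)
  }
  p_full <- forward_logits(model, xc)$p
  attr(res, "unmasked") <- list(mean_score = mean(p_full[lins]),
                                detected = any(p_full[lins] > t))
  res
}

#' Aggregate the context probe over several lesions
#'
#' @inheritParams context_probe
#' @param omegas list of lesion domains.
#' @return data frame (iteration, mean_score, sd_score, n_detected,
#'   n_lesions).
#' @export
context_probe_summary <- function(model, x, omegas, iterations = 35L, t = 0.3,
                                  connectivity = 6L, crop_margin = NULL) {
  runs <- lapply(omegas, function(om) {
    context_probe(model, x, om, iterations, t, connectivity, crop_margin)
  })
  scores <- sapply(runs, function(r) r$mean_score)
  det <- sapply(runs, function(r) r$detected)
  if (is.null(dim(scores))) {
    scores <- matrix(scores, ncol = length(runs))
    det <- matrix(det, ncol = length(runs))
  }
  data.frame(
    iteration = 0:iterations,
    mean_score = rowMeans(scores),
    sd_score = apply(scores, 1, stats::sd),
    n_detected = rowSums(det),
    n_lesions = length(runs)
  )
}

#' Select lesions of near-average size
#'
#' Keeps instances whose physical volume lies in the closed interval
#' `[low, high]` mm^3 (defaults 90-120, around the average lesion volume the
#' context experiment targets).
#'
#' @param instances list of [new_instance()] objects.
#' @param low,high interval bounds in mm^3 (inclusive).
#' @return filtered list.
#' @export
select_average_size_lesions <- function(instances, low = 90, high = 120) {
  Filter(function(i) i$physical_volume >= low && i$physical_volume <= high,
         instances)
}

#' Perilesional shell of an instance
#'
#' The voxels between `inner` and `inner + width` dilation steps of the
#' domain — the "neighbourhood" region where the sign structure of saliency
#' is examined. The default skips the first ring (`inner = 1`): the voxels
#' immediately adjacent to a segmented lesion still carry lesion-like
#' intensity (partial-volume edge), and saliency there behaves like the
#' lesion edge rather than like perilesional tissue.
#'
#' @param instance a [new_instance()].
#' @param width shell thickness in dilation steps.
#' @param inner rings to skip next to the domain.
#' @param connectivity structuring element connectivity.
#' @return a `sal_instance` with origin `"manual"`.
#' @export
instance_shell <- function(instance, width = 2L, inner = 1L,
                           connectivity = 6L) {
  m <- instance_indicator(instance)
  d <- m
  for (i in seq_len(inner)) d <- dilate_mask(d, connectivity)
  inner_mask <- d
  for (i in seq_len(width)) d <- dilate_mask(d, connectivity)
  shell <- which(d != 0 & inner_mask == 0)
  new_instance(lin_to_sub(shell, instance$dims), label = instance$label,
               spacing = instance$spacing, origin = "manual",
               dims = instance$dims)
}
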