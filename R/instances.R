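#' Lesion instance
#'
#' A lesion domain: the voxel-index set of one connected instance, with label
#' and physical volume. Voxel indices are 1-based array subscripts (first
#' axis fastest-varying), and all tie-breaks in the package follow that scan
#' order.
#'
#' @param voxels integer matrix (m x 3) of 1-based voxel subscripts.
#' @param label integer instance id.
#' @param spacing voxel spacing (mm).
#' @param origin one of `"prediction"`, `"ground_truth"`, `"tn_sphere"`,
#'   `"manual"`.
#' @param dims grid extents the indices refer to.
#' @return object of class `sal_instance` with fields `voxels`, `lin`
#'   (column-major linear indices, sorted: scan order), `label`,
#'   `cardinality`, `physical_volume` (mm^3), `origin`, `spacing`, `dims`.
#' @export
new_instance <- function(voxels, label = 1L, spacing = c(1, 1, 1),
                         origin = "manual", dims = NULL) {
  voxels <- matrix(as.integer(voxels), ncol = 3)
  if (is.null(dims)) dims <- apply(voxels, 2, max)
  lin <- sort(sub_to_lin(voxels, dims))
  voxels <- lin_to_sub(lin, dims)
  structure(
    list(voxels = voxels, lin = lin, label = as.integer(label),
         cardinality = nrow(voxels),
         physical_volume = nrow(voxels) * voxel_volume(spacing),
         origin = origin, spacing = spacing, dims = as.integer(dims)),
    class = "sal_instance"
  )
}

#' @export
print.sal_instance <- function(x, ...) {
  cat(sprintf(
    "<sal_instance> label %d (%s): |Omega| = %d, %.1f mm^3\n",
    x$label, x$origin, x$cardinality, x$physical_volume
  ))
  invisible(x)
}

#' Indicator array of an instance domain
#' @param instance a `sal_instance`.
#' @return numeric 0/1 array over the instance's grid.
#' @export
instance_indicator <- function(instance) {
  a <- array(0, instance$dims)
  a[instance$lin] <- 1
  a
}

#' Binarize a probability map
#'
#' `mask[v] = 1` iff `p[v] > t`, with a strict inequality.
#'
#' @param p numeric array of probabilities in `[0, 1]`.
#' @param t threshold in `(0, 1)`; the package default of 0.3 is the value
#'   used throughout the pipeline.
#' @return integer 0/1 array.
#' @export
binarize_probability <- function(p, t = 0.3) {
  if (t <= 0 || t >= 1) stop("threshold t must lie strictly inside (0, 1)")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("probabilities must lie in [0, 1]")
  m <- array(as.integer(p > t), dim(p))
  m
}

#' Label connected components and filter by physical volume
#'
#' Components are extracted under the requested connectivity (default 18:
#' face and edge neighbours, corners excluded) and components smaller than
#' `min_volume_mm3` (default 5 mm^3) are removed. Labels are assigned in the
#' order the first voxel of each surviving component appears in scan order.
#'
#' @param mask integer/logical 3D array (2D input gets a singleton axis).
#' @param connectivity 6, 18 or 26.
#' @param min_volume_mm3 minimum physical component volume; components with
#'   `volume < min_volume_mm3` are dropped (strict).
#' @param spacing voxel spacing in mm.
#' @param origin origin tag for the resulting instances.
#' @return list of [new_instance()] objects.
#' @export
label_instances <- function(mask, connectivity = 18L, min_volume_mm3 = 5,
                            spacing = c(1, 1, 1), origin = "prediction") {
  if (length(dim(mask)) == 2L) dim(mask) <- c(dim(mask), 1L)
  if (!connectivity %in% c(6L, 18L, 26L)) stop("connectivity must be 6, 18 or 26")
  dims <- dim(mask)
  lab <- cpp_label_components(as.integer(mask != 0), as.integer(dims),
                              as.integer(connectivity))
  n <- max(lab)
  if (n == 0L) return(list())
  vv <- voxel_volume(spacing)
  out <- list()
  next_label <- 0L
  for (k in seq_len(n)) {
    lin <- which(lab == k)
    if (length(lin) * vv < min_volume_mm3) next
    next_label <- next_label + 1L
    out[[next_label]] <- new_instance(
      lin_to_sub(lin, dims), label = next_label, spacing = spacing,
      origin = origin, dims = dims
    )
  }
  out
}

#' Classify prediction and ground-truth instances into TP / FP / FN
#'
#' A prediction instance is a true positive iff it overlaps the ground-truth
#' mask in at least one voxel, otherwise a false positive. A ground-truth
#' instance is a false negative iff it has zero overlap with the full
#' predicted mask. The matching is one-sided: no one-to-one assignment is
#' attempted.
#'
#' @param pred_instances,gt_instances lists of [new_instance()] objects.
#' @param pred_mask,gt_mask binary arrays on a common grid.
#' @return an `example_set` list with fields `tp`, `fp`, `fn` (instance
#'   lists).
#' @export
classify_examples <- function(pred_instances, gt_instances, pred_mask, gt_mask) {
  if (length(dim(pred_mask)) == 2L) dim(pred_mask) <- c(dim(pred_mask), 1L)
  if (length(dim(gt_mask)) == 2L) dim(gt_mask) <- c(dim(gt_mask), 1L)
  if (!identical(dim(pred_mask), dim(gt_mask))) {
    stop("prediction and ground-truth masks must share dimensions")
  }
  tp <- list(); fp <- list(); fn <- list()
  for (inst in pred_instances) {
    if (any(gt_mask[inst$lin] != 0)) tp[[length(tp) + 1L]] <- inst
    else fp[[length(fp) + 1L]] <- inst
  }
  for (inst in gt_instances) {
    if (all(pred_mask[inst$lin] == 0)) fn[[length(fn) + 1L]] <- inst
  }
  structure(list(tp = tp, fp = fp, fn = fn, tn = list()), class = "example_set")
}

#' Sample true-negative control spheres
#'
#' Draws `n` spheres of a target physical volume (default 93 mm^3, radius
#' about 2.81 mm) uniformly inside a support mask, rejecting spheres that
#' intersect the ground-truth or prediction masks. Spheres may overlap each
#' other. The discrete sphere is the set of voxels whose centre lies within
#' Euclidean distance r of the sampled centre; its discrete volume is carried
#' by the instance rather than being forced to the target exactly.
#'
#' @param brain_mask binary support mask.
#' @param gt_mask,pred_mask binary masks the spheres must not intersect.
#' @param n number of spheres.
#' @param target_volume_mm3 target sphere volume.
#' @param spacing voxel spacing (mm).
#' @param seed integer seed (required: sampling must be reproducible).
#' @param max_attempts rejection-sampling cap per sphere.
#' @return list of [new_instance()] objects with origin `"tn_sphere"`.
#' @export
sample_tn_spheres <- function(brain_mask, gt_mask, pred_mask, n = 10L,
                              target_volume_mm3 = 93, spacing = c(1, 1, 1),
                              seed, max_attempts = 10000L) {
  if (missing(seed)) stop("`seed` must be supplied")
  if (length(dim(brain_mask)) == 2L) dim(brain_mask) <- c(dim(brain_mask), 1L)
  if (sum(brain_mask) == 0) stop("brain mask is empty")
  dims <- dim(brain_mask)
  r_mm <- (3 * target_volume_mm3 / (4 * pi))^(1 / 3)
  set.seed(seed)
  support_lin <- which(brain_mask != 0)
  placed <- list()
  for (s in seq_len(n)) {
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      ctr_lin <- support_lin[sample.int(length(support_lin), 1L)]
      ctr <- lin_to_sub(ctr_lin, dims)[1, ]
      lo <- pmax(floor(ctr - r_mm / spacing), 1)
      hi <- pmin(ceiling(ctr + r_mm / spacing), dims)
      dg <- expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3])
      d2 <- ((dg$i - ctr[1]) * spacing[1])^2 + ((dg$j - ctr[2]) * spacing[2])^2 +
        ((dg$k - ctr[3]) * spacing[3])^2
      sub <- cbind(dg$i, dg$j, dg$k)[d2 <= r_mm^2, , drop = FALSE]
      if (nrow(sub) == 0L) next
      lin <- sub_to_lin(sub, dims)
      if (any(brain_mask[lin] == 0)) next
      if (any(gt_mask[lin] != 0) || any(pred_mask[lin] != 0)) next
      placed[[s]] <- new_instance(sub, label = s, spacing = spacing,
                                  origin = "tn_sphere", dims = dims)
      ok <- TRUE
      break
    }
    if (!ok) {
      stop(sprintf(
        "sphere sampling exhausted after %d attempts: placed %d of %d spheres",
        max_attempts, length(placed), n
      ))
    }
  }
  placed
}

#' Reduce an instance to its centre-of-mass voxel
#'
#' The single voxel nearest to the arithmetic mean of the instance's voxel
#' subscripts. When the rounded mean does not belong to the domain, the
#' domain member nearest (Euclidean) to the mean is chosen, ties broken by
#' scan order.
#'
#' @param instance a non-empty [new_instance()].
#' @return a `sal_instance` with a single voxel.
#' @export
center_of_mass_domain <- function(instance) {
  if (instance$cardinality == 0L) stop("instance domain is empty")
  mu <- colMeans(instance$voxels)
  cand <- round(mu)
  lin_cand <- sub_to_lin(matrix(as.integer(cand), 1), instance$dims)
  if (lin_cand %in% instance$lin) {
    vox <- matrix(as.integer(cand), 1)
  } else {
    d2 <- rowSums((instance$voxels - matrix(mu, instance$cardinality, 3, byrow = TRUE))^2)
    # instance voxels are stored in scan order, so which.min's first-minimum
    # rule is the scan-order tie-break
    vox <- instance$voxels[which.min(d2), , drop = FALSE]
  }
  new_instance(vox, label = instance$label, spacing = instance$spacing,
               origin = instance$origin, dims = instance$dims)
}

#' Build a full TP/FP/FN/TN example set from maps
#'
#' Convenience wrapper running [binarize_probability()], [label_instances()]
#' on prediction and ground truth, [classify_examples()] and
#' [sample_tn_spheres()].
#'
#' @param p probability map array.
#' @param gt_mask binary ground-truth mask.
#' @param brain_mask binary support mask for control spheres.
#' @param t probability threshold.
#' @param connectivity,min_volume_mm3 see [label_instances()].
#' @param filter_gt apply the volume filter to ground-truth instances too
#'   (default `TRUE`).
#' @param tn_n,tn_volume_mm3 control-sphere count and volume.
#' @param spacing voxel spacing.
#' @param seed seed for sphere sampling.
#' @return an `example_set` with fields `tp`, `fp`, `fn`, `tn`, `pred_mask`,
#'   `provenance`.
#' @export
extract_example_set <- function(p, gt_mask, brain_mask, t = 0.3,
                                connectivity = 18L, min_volume_mm3 = 5,
                                filter_gt = TRUE, tn_n = 10L,
                                tn_volume_mm3 = 93, spacing = c(1, 1, 1),
                                seed = 1L) {
  pred_mask <- binarize_probability(p, t)
  if (length(dim(pred_mask)) == 2L) dim(pred_mask) <- c(dim(pred_mask), 1L)
  if (length(dim(gt_mask)) == 2L) dim(gt_mask) <- c(dim(gt_mask), 1L)
  pred <- label_instances(pred_mask, connectivity, min_volume_mm3, spacing,
                          origin = "prediction")
  gt <- label_instances(gt_mask, connectivity,
                        if (filter_gt) min_volume_mm3 else 0, spacing,
                        origin = "ground_truth")
  es <- classify_examples(pred, gt, pred_mask, gt_mask)
  es$tn <- sample_tn_spheres(brain_mask, gt_mask, pred_mask, n = tn_n,
                             target_volume_mm3 = tn_volume_mm3,
                             spacing = spacing, seed = seed)
  es$pred_mask <- pred_mask
  es$gt_instances <- gt
  es$provenance <- list(t = t, connectivity = connectivity,
                        min_volume_mm3 = min_volume_mm3, tn_n = tn_n,
                        tn_volume_mm3 = tn_volume_mm3, seed = seed)
  es
}

#' Tabulate an example set
#' @param es an `example_set`.
#' @return data frame with label, category, cardinality, volume and centroid.
#' @export
example_table <- function(es) {
  rows <- list()
  for (cat in c("tp", "fp", "fn", "tn")) {
    for (inst in es[[cat]]) {
      ctr <- colMeans(inst$voxels)
      rows[[length(rows) + 1L]] <- data.frame(
        label = inst$label, category = toupper(cat),
        n_voxels = inst$cardinality, volume_mm3 = inst$physical_volume,
        centroid_1 = ctr[1], centroid_2 = ctr[2], centroid_3 = ctr[3]
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(label = integer(), category = character(),
                      n_voxels = integer(), volume_mm3 = numeric(),
                      centroid_1 = numeric(), centroid_2 = numeric(),
                      centroid_3 = numeric()))
  }
  do.call(rbind, rows)
}
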