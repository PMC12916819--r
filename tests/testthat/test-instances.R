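test_that("binarization is strictly greater-than the threshold", {
  p <- array(c(0.29, 0.30, 0.31), c(3, 1, 1))
  expect_equal(as.integer(binarize_probability(p, 0.3)), c(0L, 0L, 1L))
  expect_equal(sum(binarize_probability(array(0, c(4, 4, 4)), 0.3)), 0)
  expect_equal(sum(binarize_probability(array(1, c(4, 4, 4)), 0.3)), 64)
  expect_error(binarize_probability(p, 1.2), "threshold")
  expect_error(binarize_probability(array(2, c(2, 2, 2)), 0.3), "0, 1")
})

test_that("connectivity rules: faces join, corners split under 18-connectivity", {
  m <- array(0L, c(4, 4, 4))
  m[1, 1, 1] <- 1L; m[2, 1, 1] <- 1L          # face-adjacent pair
  expect_length(label_instances(m, 18, 0), 1L)
  m2 <- array(0L, c(4, 4, 4))
  m2[1, 1, 1] <- 1L; m2[2, 2, 2] <- 1L        # corner contact only
  expect_length(label_instances(m2, 18, 0), 2L)
  expect_length(label_instances(m2, 26, 0), 1L)
  m3 <- array(0L, c(4, 4, 4))
  m3[1, 1, 1] <- 1L; m3[2, 2, 1] <- 1L        # edge contact
  expect_length(label_instances(m3, 18, 0), 1L)
  expect_length(label_instances(m3, 6, 0), 2L)
})

test_that("the 5 mm^3 volume filter removes a 4-voxel but keeps a 6-voxel component", {
  m <- array(0L, c(12, 12, 12))
  m[1:4, 1, 1] <- 1L          # 4 mm^3 at 1 mm isotropic
  m[1:6, 6, 6] <- 1L          # 6 mm^3
  inst <- label_instances(m, 18, 5, spacing = c(1, 1, 1))
  expect_length(inst, 1L)
  expect_equal(inst[[1]]$cardinality, 6L)
  expect_equal(inst[[1]]$physical_volume, 6)
  # spacing-aware: same voxel counts at 1.25 mm isotropic keep both
  inst2 <- label_instances(m, 18, 5, spacing = rep(1.25, 3))
  expect_length(inst2, 2L)
})

test_that("component labelling agrees with an igraph oracle on random masks", {
  skip_if_not_installed("igraph")
  set.seed(99)
  for (conn in c(6L, 18L, 26L)) {
    m <- array(as.integer(runif(10^3) < 0.25), c(10, 10, 10))
    inst <- label_instances(m, conn, 0)
    # independent oracle: graph over foreground voxels, edges between
    # neighbours under the connectivity, count components
    fg <- which(m != 0)
    sub <- instasal:::lin_to_sub(fg, dim(m))
    offs <- instasal:::neighbourhood_offsets(conn)
    edges <- NULL
    idx <- integer(prod(dim(m))); idx[fg] <- seq_along(fg)
    for (r in seq_len(nrow(offs))) {
      nb <- sweep(sub, 2, -offs[r, ])
      ok <- nb[, 1] >= 1 & nb[, 1] <= 10 & nb[, 2] >= 1 & nb[, 2] <= 10 &
        nb[, 3] >= 1 & nb[, 3] <= 10
      nl <- instasal:::sub_to_lin(nb[ok, , drop = FALSE], dim(m))
      keep <- m[nl] != 0
      edges <- rbind(edges, cbind(idx[fg[ok][keep]], idx[nl[keep]]))
    }
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, length(fg) - igraph::vcount(g)))
    expect_equal(length(inst), igraph::count_components(g))
  }
})

test_that("component count never increases when connectivity grows", {
  set.seed(4)
  m <- array(as.integer(runif(12^3) < 0.2), c(12, 12, 12))
  n6 <- length(label_instances(m, 6, 0))
  n18 <- length(label_instances(m, 18, 0))
  n26 <- length(label_instances(m, 26, 0))
  expect_lte(n18, n6)
  expect_lte(n26, n18)
})

test_that("volume filtering is idempotent", {
  set.seed(12)
  m <- array(as.integer(runif(14^3) < 0.15), c(14, 14, 14))
  once <- label_instances(m, 18, 5)
  relab <- array(0L, dim(m))
  for (i in once) relab[i$lin] <- 1L
  twice <- label_instances(relab, 18, 5)
  expect_equal(lapply(twice, `[[`, "lin"), lapply(once, `[[`, "lin"))
})

test_that("TP/FP/FN classification follows the overlap definitions", {
  dims <- c(10, 10, 10)
  gt <- array(0L, dims); gt[2:4, 2:4, 2] <- 1L
  pred <- array(0L, dims)
  pred[4:6, 4:6, 2] <- 1L      # overlaps gt in exactly one voxel (4,4,2) -> TP
  pred[8:9, 8:9, 8] <- 1L      # zero overlap -> FP
  gt[8, 1, 1] <- 1L            # untouched GT voxel -> FN
  pi <- label_instances(pred, 18, 0)
  gi <- label_instances(gt, 18, 0, origin = "ground_truth")
  expect_equal(sum(pred * gt), 1)
  es <- classify_examples(pi, gi, pred, gt)
  expect_length(es$tp, 1L)
  expect_length(es$fp, 1L)
  expect_length(es$fn, 1L)
  expect_equal(length(es$tp) + length(es$fp), length(pi))
  expect_error(classify_examples(pi, gi, pred, array(0L, c(5, 5, 5))),
               "dimensions")
})

test_that("control spheres respect volume, purity and determinism", {
  ph <- small_phantom(seed = 21)
  pred <- array(0L, dim(ph$gt_mask))
  tn <- sample_tn_spheres(ph$brain_mask, ph$gt_mask, pred, n = 10,
                          target_volume_mm3 = 93, seed = 77)
  expect_length(tn, 10L)
  r <- (3 * 93 / (4 * pi))^(1 / 3)
  expect_equal(r, 2.8098, tolerance = 1e-3)
  for (s in tn) {
    expect_equal(s$origin, "tn_sphere")
    # discrete volume close to the 93 mm^3 target
    expect_gt(s$physical_volume, 60)
    expect_lt(s$physical_volume, 130)
    expect_true(all(ph$brain_mask[s$lin] == 1))
    expect_true(all(ph$gt_mask[s$lin] == 0))
  }
  tn2 <- sample_tn_spheres(ph$brain_mask, ph$gt_mask, pred, n = 10,
                           target_volume_mm3 = 93, seed = 77)
  expect_equal(lapply(tn2, `[[`, "lin"), lapply(tn, `[[`, "lin"))

  tiny_support <- array(0L, c(8, 8, 8)); tiny_support[4, 4, 4] <- 1L
  expect_error(
    sample_tn_spheres(tiny_support, array(0L, c(8, 8, 8)),
                      array(0L, c(8, 8, 8)), n = 1, seed = 1,
                      max_attempts = 50),
    "exhausted"
  )
  expect_error(sample_tn_spheres(ph$brain_mask, ph$gt_mask, pred, n = 1),
               "seed")
})

test_that("centre-of-mass domain picks the symmetric centre or nearest member", {
  dims <- c(8, 8, 8)
  collinear <- new_instance(cbind(1:3, 4, 4), dims = dims)
  com <- center_of_mass_domain(collinear)
  expect_equal(com$voxels, matrix(c(2L, 4L, 4L), 1))
  single <- new_instance(cbind(5, 5, 5), dims = dims)
  expect_equal(center_of_mass_domain(single)$voxels, single$voxels)
  # C-shape whose index mean falls outside the domain
  cshape <- rbind(c(2, 2, 1), c(2, 3, 1), c(2, 4, 1),
                  c(3, 2, 1), c(3, 4, 1),
                  c(4, 2, 1), c(4, 3, 1), c(4, 4, 1))
  inst <- new_instance(cshape, dims = dims)
  mu <- colMeans(inst$voxels)
  expect_false(instasal:::sub_to_lin(matrix(round(mu), 1), dims) %in% inst$lin)
  got <- center_of_mass_domain(inst)$voxels
  # brute-force nearest member with scan-order tie-break
  d2 <- rowSums(sweep(inst$voxels, 2, mu)^2)
  expect_equal(got, inst$voxels[which.min(d2), , drop = FALSE])
  expect_error(center_of_mass_domain(structure(list(cardinality = 0L),
                                               class = "sal_instance")),
               "empty")
})

test_that("full example-set extraction partitions predictions and keeps TN purity", {
  ph <- small_phantom(seed = 33)
  # synthetic probability map: high inside gt, plus one detached blob
  p <- array(0.01, dim(ph$gt_mask))
  p[ph$gt_mask == 1] <- 0.9
  p[2:4, 2:4, 16] <- 0.8   # false-positive blob outside the brain lesions
  es <- extract_example_set(p, ph$gt_mask, ph$brain_mask, seed = 3)
  n_pred <- length(label_instances(binarize_probability(p, 0.3), 18, 5))
  expect_equal(length(es$tp) + length(es$fp), n_pred)
  expect_length(es$tn, 10L)
  tn_lin <- unlist(lapply(es$tn, `[[`, "lin"))
  expect_true(all(ph$gt_mask[tn_lin] == 0))
  expect_true(all(es$pred_mask[tn_lin] == 0))
  tab <- example_table(es)
  expect_true(all(c("TP", "TN") %in% tab$category))
  expect_equal(nrow(tab),
               length(es$tp) + length(es$fp) + length(es$fn) + length(es$tn))
})
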