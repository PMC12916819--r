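test_that("Mann-Whitney exact path matches the stated small-sample cases", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p, 1.0)
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$p, 0.1)
  expect_equal(mw$U, 0)
  expect_equal(mw$method, "exact_enumeration")
})

test_that("Mann-Whitney exact path equals an independent enumeration oracle", {
  # oracle: enumerate group assignments and compute U by pair counting
  oracle_p <- function(x, y) {
    pooled <- c(x, y); n1 <- length(x)
    u_of <- function(xs, ys) {
      sum(outer(xs, ys, `>`)) + 0.5 * sum(outer(xs, ys, `==`))
    }
    u_obs <- u_of(x, y)
    combs <- utils::combn(length(pooled), n1)
    us <- apply(combs, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
    min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
  }
  set.seed(55)
  for (rep in 1:12) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    # half the cases with heavy ties
    if (rep %% 2 == 0) {
      x <- sample(1:4, n1, replace = TRUE); y <- sample(2:5, n2, replace = TRUE)
    } else {
      x <- rnorm(n1); y <- rnorm(n2, mean = 1)
    }
    got <- mann_whitney_u(x, y)
    expect_equal(got$p, oracle_p(x, y), tolerance = 1e-12)
  }
  # large groups take the normal-approximation path
  expect_equal(mann_whitney_u(rnorm(20), rnorm(20))$method,
               "normal_approx_tie_corrected")
})

test_that("peak distributions report extrema, medians with CIs and pairwise tests", {
  mk_map <- function(values) {
    structure(list(values = array(values, c(length(values), 1, 1, 1)),
                   channels = "ch1", full_dims = c(length(values), 1, 1),
                   offset = c(1, 1, 1)), class = "sal_saliency")
  }
  expect_equal(saliency_peaks(mk_map(c(-2, 0, 3))), c(max = 3, min = -2))
  maps <- list(
    tp = lapply(1:5, function(i) mk_map(c(-1, i))),
    tn = lapply(1:5, function(i) mk_map(c(-0.1, 0.1 * i)))
  )
  ps <- peak_value_distributions(maps, seed = 3)
  expect_equal(nrow(ps$peaks), 10)
  expect_true(all(ps$peaks$max >= ps$peaks$min))
  tp_max <- ps$summary[ps$summary$category == "TP" & ps$summary$stat == "max", ]
  expect_equal(tp_max$median, 3)
  expect_true(tp_max$ci_lo <= tp_max$median && tp_max$median <= tp_max$ci_hi)
  expect_equal(nrow(ps$tests), 2)  # one pair, max and min
  expect_warning(
    peak_value_distributions(list(tp = maps$tp, fn = maps$tn[1])),
    "fewer than 2"
  )
})

test_that("transplantation copies the footprint and conserves everything else", {
  dims <- c(16, 16, 16)
  set.seed(61)
  x <- as_volume(array(rnorm(2 * prod(dims)), c(dims, 2)))
  src <- cube_omega(c(3, 3, 3), 2, dims)
  tr <- transplant_lesion(x, src, dest_center = c(11, 11, 11))
  moved <- which(tr$volume$data != x$data)
  # margin 0: exactly |Omega| voxels per channel may change (generic values:
  # all change)
  expect_equal(length(moved), 2 * src$cardinality)
  expect_equal(tr$instance$cardinality, src$cardinality)
  # conservation outside the destination footprint
  out_mask <- array(TRUE, c(dims, 2))
  for (c in 1:2) out_mask[, , , c][tr$instance$lin] <- FALSE
  expect_identical(tr$volume$data[out_mask], x$data[out_mask])
  # copied intensities equal the source intensities
  expect_equal(tr$volume$data[, , , 1][tr$instance$lin],
               x$data[, , , 1][src$lin])

  # 3 mm margin at 1 mm spacing dilates the footprint by 3 steps
  tr3 <- transplant_lesion(x, src, dest_center = c(11, 11, 11),
                           context_margin_mm = 3)
  foot <- instance_indicator(src)
  for (i in 1:3) foot <- instasal:::dilate_mask(foot, 6)
  expect_equal(sum(tr3$volume$data[, , , 1] != x$data[, , , 1] |
                     tr3$volume$data[, , , 2] != x$data[, , , 2]) /
                 1, sum(foot))
  expect_error(transplant_lesion(x, src, dest_center = c(1, 1, 1)),
               "outside")
})

test_that("context probe on a voxel-wise model is flat and decided at iteration 0", {
  dims <- c(12, 12, 12)
  m <- linear_model(w = c(2, 0), b = -1)
  set.seed(67)
  x <- as_volume(array(rnorm(2 * prod(dims), mean = 0.5), c(dims, 2)))
  om <- cube_omega(c(5, 5, 5), 2, dims)
  res <- context_probe(m, x, om, iterations = 10, t = 0.3, crop_margin = 3)
  expect_equal(length(unique(round(res$mean_score, 12))), 1L)
  expect_equal(res$detected, rep(res$detected[1], 11))
  # final iteration covers the crop -> equals unmasked inference
  expect_equal(res$coverage[11], 1)
  expect_equal(res$mean_score[11], attr(res, "unmasked")$mean_score,
               tolerance = 1e-6)
})

test_that("detection uses a strict threshold on the Softmax score", {
  # logit chosen so the sigmoid score is just below / above t = 0.3
  dims <- c(5, 5, 5)
  om <- new_instance(cbind(3, 3, 3), dims = dims)
  for (target in c(0.29, 0.31)) {
    b <- stats::qlogis(target)
    m <- linear_model(w = 0, b = b)
    x <- as_volume(array(0, dims))
    res <- context_probe(m, x, om, iterations = 0, t = 0.3, crop_margin = 1)
    expect_equal(res$detected[1], target > 0.3)
  }
})

test_that("context probe on the trained model saturates to unmasked inference", {
  fit <- trained_fixture()
  ph <- fit$val_phantoms[[2]]
  gt_inst <- label_instances(ph$gt_mask, 18, 5, origin = "ground_truth")
  om <- gt_inst[[1]]
  res <- context_probe(fit$model, ph$volume, om, iterations = 12, t = 0.3,
                       crop_margin = 2)
  expect_equal(res$coverage[13], 1)
  expect_equal(res$mean_score[13], attr(res, "unmasked")$mean_score,
               tolerance = 1e-6)
  # once enough context is restored the lesion is detected
  expect_true(res$detected[13])
  summ <- context_probe_summary(fit$model, ph$volume, gt_inst[1:2],
                                iterations = 6, crop_margin = 4)
  expect_equal(nrow(summ), 7)
  expect_true(all(summ$n_detected <= summ$n_lesions))
})

test_that("near-average lesion-size selection uses a closed interval", {
  dims <- c(40, 12, 12)
  mk <- function(n) new_instance(cbind(seq_len(n), 1, 1), dims = dims)
  insts <- lapply(c(89, 90, 100, 120, 121), mk)
  # fake physical volumes via spacing 1: cardinality = volume
  sel <- select_average_size_lesions(insts, 90, 120)
  expect_equal(sapply(sel, `[[`, "cardinality"), c(90, 100, 120))
  expect_length(select_average_size_lesions(list(), 90, 120), 0L)
  same <- lapply(rep(100, 3), mk)
  expect_length(select_average_size_lesions(same), 3L)
})

test_that("healthy-region probe requires a lesion-free domain", {
  dims <- c(10, 10, 10)
  m <- linear_model(w = c(1, -0.2))
  set.seed(71)
  x <- as_volume(array(rnorm(2 * prod(dims)), c(dims, 2)))
  gt <- array(0L, dims); gt[2:3, 2:3, 2:3] <- 1L
  pred <- array(0L, dims)
  bad <- cube_omega(c(2, 2, 2), 2, dims)
  expect_error(empty_region_check(m, x, bad, gt, pred), "intersects")
  ok <- cube_omega(c(7, 7, 7), 2, dims)
  res <- empty_region_check(m, x, ok, gt, pred,
                            cfg = noise_config(n = 1, sigma = 0))
  # for a voxel-wise model the healthy-region magnitudes equal the lesion
  # ones: the check is only informative for spatially aware models
  gt_omega <- new_instance(instasal:::lin_to_sub(which(gt == 1L), dims),
                           dims = dims)
  lesion_map <- vanilla_instance_map(m, x, gt_omega, aggregation = "max_signed")
  expect_equal(res$peaks[["max"]], saliency_peaks(lesion_map)[["max"]],
               tolerance = 1e-12)
})
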