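test_that("signed-maximum aggregation keeps the largest-magnitude candidate with sign", {
  expect_equal(max_signed_aggregate(c(0.2, -0.5, 0.4)), -0.5)
  expect_equal(max_signed_aggregate(c(0.3, -0.3)), 0.3)  # tie: earliest wins
  expect_equal(max_signed_aggregate(7), 7)
  expect_error(max_signed_aggregate(numeric(0)), "empty")
})

test_that("per-voxel linear model: mean aggregation scales as w/|Omega|, max recovers w", {
  dims <- c(12, 12, 12)
  m <- linear_model(w = c(2, -0.5))
  set.seed(3)
  x <- as_volume(array(rnorm(2 * prod(dims)), c(dims, 2)),
                 channels = c("flair", "mprage"))
  om <- cube_omega(c(4, 4, 4), 2, dims)  # |Omega| = 8
  mn <- vanilla_instance_map(m, x, om, aggregation = "mean")
  full <- embed_saliency(mn)
  expect_equal(unique(full[, , , 1][om$lin]), 2 / 8)
  expect_equal(unique(full[, , , 2][om$lin]), -0.5 / 8)
  full[, , , 1][om$lin] <- 0; full[, , , 2][om$lin] <- 0
  expect_equal(max(abs(full)), 0)

  mx <- vanilla_instance_map(m, x, om, aggregation = "max_signed")
  fullx <- embed_saliency(mx)
  expect_equal(unique(fullx[, , , 1][om$lin]), 2)
  expect_equal(unique(fullx[, , , 2][om$lin]), -0.5)

  # zero-weight model gives a zero map
  z <- vanilla_instance_map(linear_model(c(0, 0)), x, om, aggregation = "mean")
  expect_equal(max(abs(z$values)), 0)
})

test_that("SmoothGrad on a linear model is noise-invariant and reduces to vanilla", {
  dims <- c(10, 10, 10)
  m <- linear_model(w = c(1.5, 0.5))
  set.seed(6)
  x <- as_volume(array(rnorm(2 * prod(dims)), c(dims, 2)))
  om <- scatter_omega(dims, 5, seed = 4)
  v <- vanilla_instance_map(m, x, om, aggregation = "max_signed")
  sg <- smoothgrad_instance(m, x, om, noise_config(n = 5, sigma = 0.3, seed = 2),
                            aggregation = "max_signed")
  expect_equal(sg$values, v$values)
  sg1 <- smoothgrad_instance(m, x, om, noise_config(n = 1, sigma = 0),
                             aggregation = "max_signed")
  expect_identical(sg1$values, v$values)
  expect_equal(sg1$method, "vanilla")
  expect_error(smoothgrad_instance(m, x, om, noise_config(n = 0)), "n must be")
  expect_error(noise_config(sigma = -0.1), "sigma")
})

test_that("conv model, Omega = one voxel: max_signed map is the flipped kernel footprint", {
  dims <- c(9, 9, 9)
  m <- conv_model(c(1, 2, 1))
  set.seed(10)
  x <- as_volume(array(rnorm(prod(dims)), dims))
  om <- new_instance(cbind(5, 5, 5), dims = dims)
  mp <- smoothgrad_instance(m, x, om, noise_config(n = 1, sigma = 0),
                            aggregation = "max_signed")
  full <- embed_saliency(mp)[, , , 1]
  expect_equal(full[5, 5, 5], 2)
  expect_equal(full[4, 5, 5], 1)
  expect_equal(full[6, 5, 5], 1)
  full[4:6, 5, 5] <- 0
  expect_equal(max(abs(full)), 0)
})

test_that("mean aggregation via one backward equals brute-force per-voxel averaging", {
  dims <- c(16, 16, 16)
  set.seed(17)
  m <- conv_model(array(rnorm(27), c(3, 3, 3)))
  x <- as_volume(array(rnorm(prod(dims)), dims))
  om <- scatter_omega(dims, 20, seed = 8)
  mp <- smoothgrad_instance(m, x, om, noise_config(n = 1, sigma = 0),
                            aggregation = "mean", full_volume = TRUE)
  # brute force: average the |Omega| single-voxel gradient maps
  acc <- array(0, c(dims, 1))
  for (l in om$lin) {
    w <- array(0, dims); w[l] <- 1
    acc <- acc + input_gradient(m, x, w)
  }
  acc <- acc / om$cardinality
  expect_lt(max(abs(mp$values - acc)), 1e-5)
})

test_that("cropped computation matches the full-volume map for reference models", {
  dims <- c(14, 14, 14)
  set.seed(23)
  m <- conv_model(array(rnorm(27), c(3, 3, 3)))
  x <- as_volume(array(rnorm(prod(dims)), dims))
  om <- cube_omega(c(6, 6, 6), 2, dims)
  for (agg in c("mean", "max_signed")) {
    crop <- smoothgrad_instance(m, x, om, noise_config(n = 1, sigma = 0), agg)
    full <- smoothgrad_instance(m, x, om, noise_config(n = 1, sigma = 0), agg,
                                full_volume = TRUE)
    expect_equal(embed_saliency(crop), full$values, tolerance = 1e-12)
  }
})

test_that("saliency is exactly zero beyond the receptive field of the conv model", {
  dims <- c(15, 15, 15)
  set.seed(29)
  m <- conv_model(array(rnorm(27), c(3, 3, 3)))
  x <- as_volume(array(rnorm(prod(dims)), dims))
  om <- cube_omega(c(7, 7, 7), 2, dims)
  for (agg in c("mean", "max_signed")) {
    mp <- smoothgrad_instance(m, x, om, noise_config(n = 2, sigma = 0.05, seed = 3),
                              agg, full_volume = TRUE)
    sup <- which(abs(mp$values[, , , 1]) > 0, arr.ind = TRUE)
    # Chebyshev distance to the Omega cube must be <= kernel radius 1
    dcheb <- apply(sup, 1, function(v) {
      max(pmax(c(7, 7, 7) - v, v - c(8, 8, 8), 0))
    })
    expect_true(all(dcheb <= receptive_field_radius(m)))
  }
})

test_that("seeded SmoothGrad is bit-reproducible and variance shrinks with N", {
  cnn <- tiny_cnn(n_channels = 2, seed = 41)
  set.seed(41)
  dims <- c(12, 12, 12)
  x <- as_volume(array(rnorm(2 * prod(dims)), c(dims, 2)))
  om <- cube_omega(c(6, 6, 6), 2, dims)
  a <- smoothgrad_instance(cnn, x, om, noise_config(n = 50, sigma = 0.05, seed = 5),
                           "max_signed")
  b <- smoothgrad_instance(cnn, x, om, noise_config(n = 50, sigma = 0.05, seed = 5),
                           "max_signed")
  expect_identical(a$values, b$values)
  var_over_seeds <- function(n_rep) {
    maps <- lapply(1:6, function(s) {
      smoothgrad_instance(cnn, x, om, noise_config(n = n_rep, sigma = 0.05,
                                                   seed = 100 + s),
                          "max_signed")$values
    })
    arr <- simplify2array(maps)
    mean(apply(arr, 1:4, stats::var))
  }
  expect_lt(var_over_seeds(50), var_over_seeds(5))
})

test_that("band filter zeroes the open interval and keeps boundary values", {
  v <- array(c(0.05, -0.09, 0.11, 0.1, -0.1, 0), c(6, 1, 1, 1))
  map <- structure(list(values = v, channels = "ch1", full_dims = c(6, 1, 1),
                        offset = c(1, 1, 1)), class = "sal_saliency")
  out <- saliency_band_filter(map)
  expect_equal(as.numeric(out$values), c(0, 0, 0.11, 0.1, -0.1, 0))
  z <- array(0, c(3, 3, 1, 1))
  expect_equal(saliency_band_filter(z), z)
  expect_error(saliency_band_filter(z, band = c(0.2, 0.1)), "band")
})
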