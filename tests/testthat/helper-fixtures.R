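# Shared fixtures. The trained phantom model is expensive (a few minutes of
# CPU), so it is trained once per session and reused by every test that
# needs a spatially aware model.

.fixture_cache <- new.env(parent = emptyenv())

small_phantom <- function(seed = 7, n_lesions = 3, dims = c(32, 32, 32)) {
  generate_phantom(phantom_config(dims = dims, n_lesions = n_lesions,
                                  seed = seed))
}

trained_fixture <- function() {
  if (!is.null(.fixture_cache$fit)) return(.fixture_cache$fit)
  base <- phantom_config(dims = c(32, 32, 32), n_lesions = 4, seed = 100)
  train <- phantom_stream(24, base)
  val <- lapply(1:8, function(i) {
    generate_phantom(phantom_config(dims = c(32, 32, 32), n_lesions = 4,
                                    seed = 9000 + i))
  })
  fit <- train_tiny_model(train, epochs = 25, seed = 11, val_phantoms = val)
  fit$val_phantoms <- val
  .fixture_cache$fit <- fit
  fit
}

# deterministic scattered voxel set inside a grid
scatter_omega <- function(dims, n, seed, spacing = c(1, 1, 1)) {
  set.seed(seed)
  lin <- sample.int(prod(dims), n)
  sub <- cbind(
    (lin - 1L) %% dims[1] + 1L,
    ((lin - 1L) %/% dims[1]) %% dims[2] + 1L,
    (lin - 1L) %/% (dims[1] * dims[2]) + 1L
  )
  new_instance(sub, label = 1L, spacing = spacing, dims = dims)
}

cube_omega <- function(lo, side, dims, spacing = c(1, 1, 1)) {
  g <- expand.grid(i = lo[1] + seq_len(side) - 1L,
                   j = lo[2] + seq_len(side) - 1L,
                   k = lo[3] + seq_len(side) - 1L)
  new_instance(cbind(g$i, g$j, g$k), label = 1L, spacing = spacing,
               dims = dims)
}
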