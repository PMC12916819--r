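#' Multi-channel volumetric image
#'
#' Container for a multi-channel image over a rectangular voxel grid. Data are
#' stored as a 4-dimensional array with dims `(n1, n2, n3, n_channels)`;
#' two-dimensional images are supported by a singleton third axis, so every
#' formula in the package is dimension-agnostic. Channels typically stand for
#' MRI contrasts ("flair", "mprage"), on a z-score normalized intensity scale.
#'
#' @param data numeric array: `(n1, n2, n3, C)`, `(n1, n2, C)` for 2D images,
#'   or `(n1, n2, n3)` / `(n1, n2)` for a single channel.
#' @param channels character vector of channel names; length must equal the
#'   channel count. Defaults to `"ch1"`, `"ch2"`, ...
#' @param spacing positive numeric vector of voxel spacing in mm per axis
#'   (length 3, or 2 for 2D input; recycled scalar allowed).
#' @param twod logical; set `TRUE` to force interpretation of a 3D array as
#'   `(n1, n2, C)`. By default a 3D array is read as a single-channel volume.
#' @return an object of class `sal_volume`.
#' @export
as_volume <- function(data, channels = NULL, spacing = c(1, 1, 1), twod = FALSE) {
  if (!is.array(data) && is.matrix(data)) data <- array(data, c(dim(data)))
  if (is.null(dim(data))) stop("`data` must be an array")
  d <- dim(data)
  if (length(d) == 2L) {
    data <- array(data, c(d, 1L, 1L))
  } else if (length(d) == 3L) {
    if (twod) {
      # (n1, n2, C) -> (n1, n2, 1, C): pure reshape, singleton third axis
      dim(data) <- c(d[1], d[2], 1L, d[3])
    } else {
      dim(data) <- c(d, 1L)
    }
  } else if (length(d) != 4L) {
    stop("`data` must have 2, 3 or 4 dimensions")
  }
  d <- dim(data)
  nc <- d[4]
  if (is.null(channels)) channels <- paste0("ch", seq_len(nc))
  if (length(channels) != nc) stop("channel names do not match channel count")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  if (length(spacing) == 2L) spacing <- c(spacing, 1)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("`spacing` must be strictly positive, length 3 (or 2 for 2D)")
  }
  structure(
    list(data = data, channels = channels, spacing = as.numeric(spacing)),
    class = "sal_volume"
  )
}

#' @export
print.sal_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<sal_volume> %s voxels, %d channel(s) [%s], spacing %s mm\n",
    paste(d[1:3], collapse = "x"), d[4],
    paste(x$channels, collapse = ", "),
    paste(format(x$spacing), collapse = "x")
  ))
  invisible(x)
}

vol_sdim <- function(x) dim(x$data)[1:3]
vol_nchan <- function(x) dim(x$data)[4]
voxel_volume <- function(spacing) prod(spacing)

#' Extract one channel as a plain 3D array
#' @param x a `sal_volume`
#' @param channel channel index or name
#' @return numeric 3D array
#' @export
vol_channel <- function(x, channel) {
  if (is.character(channel)) channel <- match(channel, x$channels)
  if (is.na(channel) || channel < 1 || channel > vol_nchan(x)) {
    stop("unknown channel")
  }
  arr <- x$data[, , , channel]
  dim(arr) <- vol_sdim(x)
  arr
}

# ---- voxel indexing helpers (1-based, column-major: first axis fastest) ----

lin_to_sub <- function(lin, dims) {
  lin0 <- lin - 1L
  cbind(
    lin0 %% dims[1] + 1L,
    (lin0 %/% dims[1]) %% dims[2] + 1L,
    lin0 %/% (dims[1] * dims[2]) + 1L
  )
}

sub_to_lin <- function(sub, dims) {
  (sub[, 1] - 1L) + dims[1] * ((sub[, 2] - 1L) + dims[2] * (sub[, 3] - 1L)) + 1L
}

# Crop window [lo, hi] (inclusive, 1-based) per axis around a voxel set, with
# an integer margin, clipped to the grid.
crop_window <- function(sub, dims, margin) {
  lo <- pmax(apply(sub, 2, min) - margin, 1L)
  hi <- pmin(apply(sub, 2, max) + margin, dims)
  list(lo = as.integer(lo), hi = as.integer(hi))
}

crop_volume <- function(x, win) {
  data <- x$data[win$lo[1]:win$hi[1], win$lo[2]:win$hi[2], win$lo[3]:win$hi[3], , drop = FALSE]
  as_volume(data, channels = x$channels, spacing = x$spacing)
}

# Binary 6/18/26-neighbourhood dilation by one step, in R via shifted copies.
dilate_mask <- function(mask, connectivity = 6L) {
  d <- dim(mask)
  out <- mask
  offs <- neighbourhood_offsets(connectivity)
  for (i in seq_len(nrow(offs))) {
    sh <- shift_array(mask, offs[i, ])
    out <- out | sh
  }
  storage.mode(out) <- "integer"
  dim(out) <- d
  out
}

neighbourhood_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(d1 = -1:1, d2 = -1:1, d3 = -1:1))
  nz <- rowSums(g != 0)
  keep <- switch(as.character(connectivity),
    "6" = nz == 1, "18" = nz >= 1 & nz <= 2, "26" = nz >= 1,
    stop("connectivity must be 6, 18 or 26")
  )
  g[keep, , drop = FALSE]
}

shift_array <- function(a, off) {
  d <- dim(a)
  out <- array(0L, d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    o <- off[ax]
    if (o >= 0) {
      src[[ax]] <- seq_len(d[ax] - o)
      dst[[ax]] <- seq_len(d[ax] - o) + o
    } else {
      src[[ax]] <- seq_len(d[ax] + o) - o
      dst[[ax]] <- seq_len(d[ax] + o)
    }
    if (length(src[[ax]]) == 0) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}
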