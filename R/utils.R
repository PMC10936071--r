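# Internal helpers shared across modules.

# Derive a reproducible substream seed from a master seed and integer ids.
# Counter-based LCG walk so per-patient / per-lesion streams are independent
# of generation order and stay inside the 32-bit integer range.
substream_seed <- function(seed, ...) {
  ids <- c(...)
  val <- as.double(seed) %% 2147483647
  for (i in ids) {
    val <- (val * 69069 + as.double(i) + 1) %% 2147483647
  }
  as.integer(val)
}

# Evaluate expr with a local RNG state seeded at `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Shift a 3-D array by an integer voxel offset, zero-filling exposed planes.
shift_array <- function(a, off) {
  d <- dim(a)
  out <- array(0, dim = d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    o <- off[ax]
    if (abs(o) >= d[ax]) return(out)
    if (o >= 0) {
      src[[ax]] <- seq_len(d[ax] - o)
      dst[[ax]] <- seq_len(d[ax] - o) + o
    } else {
      src[[ax]] <- seq_len(d[ax] + o) - o
      dst[[ax]] <- seq_len(d[ax] + o)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Sum of neighbour values over a set of voxel offsets, for every voxel.
# Used for local means/SDs and sphere averages; `a` is zero outside the mask.
neighbourhood_sum <- function(a, offsets) {
  out <- array(0, dim = dim(a))
  for (i in seq_len(nrow(offsets))) {
    out <- out + shift_array(a, offsets[i, ])
  }
  out
}

# Separable Gaussian smoothing of a 3-D array (reflecting boundaries).
gaussian_smooth3d <- function(a, sigma_vox) {
  d <- dim(a)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-(seq(-r, r))^2 / (2 * s^2))
    k <- k / sum(k)
    a <- apply_kernel_axis(a, k, ax)
  }
  a
}

apply_kernel_axis <- function(a, k, ax) {
  d <- dim(a)
  r <- (length(k) - 1L) / 2L
  out <- array(0, dim = d)
  n <- d[ax]
  for (j in seq_along(k)) {
    off <- j - r - 1L
    idx <- seq_len(n) + off
    idx <- pmin(pmax(idx, 1L), n)  # replicate edges
    sl <- switch(ax,
      a[idx, , , drop = FALSE],
      a[, idx, , drop = FALSE],
      a[, , idx, drop = FALSE])
    out <- out + k[j] * sl
  }
  out
}

# Voxel offsets (as integer matrix) whose physical distance is <= radius_mm.
sphere_offsets <- function(spacing, radius_mm, exclude_origin = FALSE) {
  r <- floor(radius_mm / spacing)
  g <- as.matrix(expand.grid(x = -r[1]:r[1], y = -r[2]:r[2], z = -r[3]:r[3]))
  dist <- sqrt((g[, 1] * spacing[1])^2 + (g[, 2] * spacing[2])^2 +
               (g[, 3] * spacing[3])^2)
  keep <- dist <= radius_mm
  if (exclude_origin) keep <- keep & rowSums(abs(g)) > 0
  unname(g[keep, , drop = FALSE])
}

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
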