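# Internal array helpers shared by the simulator and the texture engine.

# The 13 unique 3D directions (half of the 26-neighbourhood): first non-zero
# component positive, so that each opposed pair is represented once.
direction_offsets_13 <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  keep <- g$dx > 0 | (g$dx == 0 & g$dy > 0) | (g$dx == 0 & g$dy == 0 & g$dz > 0)
  as.matrix(g[keep, , drop = FALSE])
}

# All 26 neighbour offsets.
neighbour_offsets_26 <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), , drop = FALSE])
}

# Index ranges for the overlap of an array with itself shifted by `off`.
# Returns NULL when the overlap is empty.
shift_overlap <- function(dims, off) {
  src <- vector("list", 3L)
  dst <- vector("list", 3L)
  for (a in 1:3) {
    d <- off[a]
    lo <- max(1L, 1L - d)
    hi <- min(dims[a], dims[a] - d)
    if (lo > hi) return(NULL)
    src[[a]] <- lo:hi          # voxel position
    dst[[a]] <- (lo + d):(hi + d)  # its neighbour at position + off
  }
  list(src = src, dst = dst)
}

slice3 <- function(arr, idx) arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]

# Population central moments; returns list(mean, var, skew, kurt).
# skew/kurt are NA for constant input (variance zero).
population_moments <- function(x) {
  n <- length(x)
  m <- mean(x)
  d <- x - m
  m2 <- sum(d^2) / n
  if (m2 <= 0) {
    return(list(mean = m, var = 0, skew = NA_real_, kurt = NA_real_))
  }
  m3 <- sum(d^3) / n
  m4 <- sum(d^4) / n
  list(mean = m, var = m2, skew = m3 / m2^1.5, kurt = m4 / m2^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
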