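# Independent brute-force oracles for the texture families and the mesh
# surface. Plain nested loops over voxels/pairs/runs/zones — no pooling
# shortcuts, no code shared with the package implementation.

oracle_random_levels <- function(dims = c(5, 5, 5), n_levels = 4L,
                                 p_mask = 0.7) {
  lev <- array(sample.int(n_levels, prod(dims), replace = TRUE), dims)
  msk <- array(stats::runif(prod(dims)) < p_mask, dims)
  if (!any(msk)) msk[sample(prod(dims), 3L)] <- TRUE
  lev[!msk] <- NA_integer_
  lev
}

oracle_dirs13 <- function() {
  out <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    if (dx > 0 || (dx == 0 && dy > 0) || (dx == 0 && dy == 0 && dz > 0))
      out[[length(out) + 1L]] <- c(dx, dy, dz)
  }
  out
}

in_grid <- function(p, dims) all(p >= 1L) && all(p <= dims)

oracle_glcm <- function(lev, n_levels, dirs = oracle_dirs13()) {
  dims <- dim(lev)
  cnt <- matrix(0, n_levels, n_levels)
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    a <- lev[x, y, z]
    if (is.na(a)) next
    for (d in dirs) {
      q <- c(x, y, z) + d
      if (!in_grid(q, dims)) next
      b <- lev[q[1], q[2], q[3]]
      if (is.na(b)) next
      cnt[a, b] <- cnt[a, b] + 1
      cnt[b, a] <- cnt[b, a] + 1
    }
  }
  p <- cnt / sum(cnt)
  i <- row(p); j <- col(p)
  mu <- sum(i * p); sig2 <- sum((i - mu)^2 * p)
  pp <- p[p > 0]
  c(GLCM_Homogeneity = sum(p / (1 + (i - j)^2)),
    GLCM_Energy = sum(p^2),
    GLCM_Contrast = sum(p * (i - j)^2),
    GLCM_Correlation = if (sig2 > 0) (sum(i * j * p) - mu^2) / sig2 else NA_real_,
    GLCM_Entropy_log10 = -sum(pp * log10(pp)),
    GLCM_Entropy_log2 = -sum(pp * log2(pp)),
    GLCM_Dissimilarity = sum(p * abs(i - j)))
}

# Enumerate maximal runs along one direction by walking each line from its
# entry voxel.
oracle_runs <- function(lev, dirs = oracle_dirs13()) {
  dims <- dim(lev)
  runs <- list()
  for (d in dirs) {
    visited <- array(FALSE, dims)
    for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
      p <- c(x, y, z)
      prev <- p - d
      if (in_grid(prev, dims)) next   # not a line entry point
      # walk the whole line
      cur_lev <- NA_integer_; cur_len <- 0L
      q <- p
      while (in_grid(q, dims)) {
        v <- lev[q[1], q[2], q[3]]
        if (!is.na(v) && !is.na(cur_lev) && v == cur_lev) {
          cur_len <- cur_len + 1L
        } else {
          if (!is.na(cur_lev))
            runs[[length(runs) + 1L]] <- c(cur_lev, cur_len)
          cur_lev <- v; cur_len <- if (is.na(v)) 0L else 1L
        }
        q <- q + d
      }
      if (!is.na(cur_lev)) runs[[length(runs) + 1L]] <- c(cur_lev, cur_len)
    }
  }
  do.call(rbind, runs)
}

oracle_rl_feats <- function(mat_rows, n_voxels, n_chains_norm, prefix,
                            zone = FALSE) {
  i <- mat_rows[, 1]; j <- mat_rows[, 2]    # one row per run/zone
  nr <- nrow(mat_rows)
  gl <- tapply(rep(1, nr), i, sum)
  ln <- tapply(rep(1, nr), j, sum)
  vals <- c(sum(1 / j^2) / nr, sum(j^2) / nr, sum(1 / i^2) / nr,
            sum(i^2) / nr, sum(1 / (i^2 * j^2)) / nr, sum(i^2 / j^2) / nr,
            sum(j^2 / i^2) / nr, sum(i^2 * j^2) / nr,
            sum(gl^2) / nr, sum(ln^2) / nr, nr / n_chains_norm)
  nms <- if (zone) c("SZE", "LZE", "LGZE", "HGZE", "SZLGE", "SZHGE",
                     "LZLGE", "LZHGE", "GLNU", "ZLNU", "ZP")
         else c("SRE", "LRE", "LGRE", "HGRE", "SRLGE", "SRHGE", "LRLGE",
                "LRHGE", "GLNU", "RLNU", "RP")
  stats::setNames(vals, paste0(prefix, nms))
}

oracle_glrlm <- function(lev, dirs = oracle_dirs13()) {
  runs <- oracle_runs(lev, dirs)
  n_vox <- sum(!is.na(lev))
  oracle_rl_feats(runs, n_vox, n_vox * length(dirs), "GLRLM_")
}

# Recursive 26-connected flood fill per zone.
oracle_zones <- function(lev) {
  dims <- dim(lev)
  lab <- array(0L, dims)
  zones <- list()
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    if (is.na(lev[x, y, z]) || lab[x, y, z] > 0L) next
    id <- length(zones) + 1L
    level <- lev[x, y, z]
    stack <- list(c(x, y, z)); lab[x, y, z] <- id; size <- 0L
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (k in seq_len(nrow(nb))) {
        q <- p + nb[k, ]
        if (!in_grid(q, dims)) next
        if (is.na(lev[q[1], q[2], q[3]]) || lab[q[1], q[2], q[3]] > 0L) next
        if (lev[q[1], q[2], q[3]] == level) {
          lab[q[1], q[2], q[3]] <- id
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
    zones[[id]] <- c(level, size)
  }
  do.call(rbind, zones)
}

oracle_glzlm <- function(lev) {
  zs <- oracle_zones(lev)
  n_vox <- sum(!is.na(lev))
  oracle_rl_feats(zs, n_vox, n_vox, "GLZLM_", zone = TRUE)
}

oracle_ngldm <- function(lev, n_levels) {
  dims <- dim(lev)
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  s <- numeric(n_levels); ni <- numeric(n_levels); n <- 0L
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    v <- lev[x, y, z]
    if (is.na(v)) next
    nbv <- c()
    for (k in seq_len(nrow(nb))) {
      q <- c(x, y, z) + nb[k, ]
      if (!in_grid(q, dims)) next
      w <- lev[q[1], q[2], q[3]]
      if (!is.na(w)) nbv <- c(nbv, w)
    }
    if (!length(nbv)) next
    n <- n + 1L
    ni[v] <- ni[v] + 1
    s[v] <- s[v] + abs(v - mean(nbv))
  }
  p <- ni / n
  pres <- which(p > 0); ngp <- length(pres)
  den <- sum(p * s)
  coarseness <- if (den > 0) min(1 / den, 1e6) else 1e6
  contrast <- if (ngp > 1) {
    acc <- 0
    for (a in pres) for (b in pres) acc <- acc + p[a] * p[b] * (a - b)^2
    acc / (ngp * (ngp - 1)) * sum(s) / n
  } else 0
  bden <- 0
  if (ngp > 1) for (a in pres) for (b in pres)
    bden <- bden + abs(a * p[a] - b * p[b])
  busyness <- if (bden > 0) sum(p * s) / bden else 0
  c(NGLDM_Coarseness = coarseness, NGLDM_Contrast = contrast,
    NGLDM_Busyness = busyness)
}

# Independent mesh-surface oracle: walks every grid cell and tetrahedron,
# builds the midpoint triangles explicitly and sums their areas.
oracle_surface_area <- function(mask_arr, s) {
  dims <- dim(mask_arr)
  pad <- array(0L, dims + 2L)
  pad[2:(dims[1] + 1), 2:(dims[2] + 1), 2:(dims[3] + 1)] <- mask_arr
  tri_area <- function(a, b, c) {
    u <- b - a; v <- c - a
    w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
    sqrt(sum(w^2)) / 2
  }
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  ey <- diag(3)
  total <- 0
  for (cx in 1:(dims[1] + 1)) for (cy in 1:(dims[2] + 1))
    for (cz in 1:(dims[3] + 1)) {
      corner_val <- function(p) pad[cx + p[1], cy + p[2], cz + p[3]]
      for (pm in perms) {
        vs <- rbind(c(0, 0, 0), ey[pm[1], ], ey[pm[1], ] + ey[pm[2], ],
                    c(1, 1, 1))
        b <- apply(vs, 1, corner_val)
        ins <- which(b == 1L)
        k <- length(ins)
        if (k == 0 || k == 4) next
        if (k == 1 || k == 3) {
          lone <- if (k == 1) ins else setdiff(1:4, ins)
          rest <- setdiff(1:4, lone)
          m <- lapply(rest, function(r) (vs[lone, ] + vs[r, ]) / 2)
          total <- total + tri_area(m[[1]], m[[2]], m[[3]])
        } else {
          o <- setdiff(1:4, ins)
          mac <- (vs[ins[1], ] + vs[o[1], ]) / 2
          mad <- (vs[ins[1], ] + vs[o[2], ]) / 2
          mbc <- (vs[ins[2], ] + vs[o[1], ]) / 2
          mbd <- (vs[ins[2], ] + vs[o[2], ]) / 2
          total <- total + tri_area(mac, mad, mbd) + tri_area(mac, mbd, mbc)
        }
      }
    }
  total * s^2
}
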