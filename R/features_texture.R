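# Texture families on discretised grey levels: GLCM, GLRLM, GLZLM, NGLDM.
# All operate on a 3D integer level array with NA outside the mask.
# Directions: distance 1, the 13 unique 3D directions, occurrences pooled
# into a single matrix before normalisation (merged strategy).

#' Grey-level co-occurrence matrix
#'
#' Symmetric joint probability matrix of level pairs at distance 1, pooled
#' over the given directions before normalisation. Both voxels of a pair
#' must lie in the mask.
#'
#' @param levels 3D integer array of levels (NA outside the mask).
#' @param n_levels number of grey levels.
#' @param directions integer matrix of direction offsets (rows), default the
#'   13 unique 3D directions.
#' @return `n_levels x n_levels` probability matrix (sums to 1).
#' @export
glcm_matrix <- function(levels, n_levels = 64L,
                        directions = direction_offsets_13()) {
  dims <- dim(levels)
  counts <- numeric(n_levels * n_levels)
  for (i in seq_len(nrow(directions))) {
    ov <- shift_overlap(dims, directions[i, ])
    if (is.null(ov)) next
    a <- slice3(levels, ov$src); b <- slice3(levels, ov$dst)
    keep <- !is.na(a) & !is.na(b)
    if (!any(keep)) next
    a <- a[keep]; b <- b[keep]
    tab <- tabulate((a - 1L) * n_levels + b, n_levels * n_levels)
    counts <- counts + tab
    counts <- counts + tabulate((b - 1L) * n_levels + a, n_levels * n_levels)
  }
  tot <- sum(counts)
  if (tot == 0) stopf("GLCM needs at least one in-mask voxel pair")
  matrix(counts / tot, n_levels, n_levels)
}

#' GLCM features
#'
#' Homogeneity `sum p/(1+(i-j)^2)`, contrast `sum p (i-j)^2`, dissimilarity
#' `sum p |i-j|`, energy `sum p^2`, correlation, and entropy in log2/log10.
#' Correlation of a single-level region is degenerate (0/0) and returned as
#' `NA`.
#'
#' @inheritParams glcm_matrix
#' @return named numeric vector over the GLCM family.
#' @export
glcm_features <- function(levels, n_levels = 64L,
                          directions = direction_offsets_13()) {
  p <- glcm_matrix(levels, n_levels, directions)
  i <- row(p); j <- col(p)
  mu <- sum(i * p)                 # marginals identical by symmetry
  sig2 <- sum((i - mu)^2 * p)
  corr <- if (sig2 > 0) (sum(i * j * p) - mu^2) / sig2 else NA_real_
  pp <- p[p > 0]
  c(GLCM_Homogeneity = sum(p / (1 + (i - j)^2)),
    GLCM_Energy = sum(p^2),
    GLCM_Contrast = sum(p * (i - j)^2),
    GLCM_Correlation = corr,
    GLCM_Entropy_log10 = -sum(pp * log10(pp)),
    GLCM_Entropy_log2 = -sum(pp * log2(pp)),
    GLCM_Dissimilarity = sum(p * abs(i - j)))
}

#' Grey-level run-length matrix
#'
#' Counts of maximal collinear constant-level runs, by level (rows) and run
#' length (columns), pooled over the given directions. Out-of-mask voxels
#' break runs.
#'
#' @inheritParams glcm_matrix
#' @return integer matrix `n_levels x max_run_length`.
#' @export
glrlm_matrix <- function(levels, n_levels = 64L,
                         directions = direction_offsets_13()) {
  dims <- dim(levels)
  nmax <- max(dims)
  base <- 2 * nmax + 2
  ix <- slice.index(levels, 1L); iy <- slice.index(levels, 2L)
  iz <- slice.index(levels, 3L)
  w0 <- levels; w0[is.na(w0)] <- 0L
  counts <- list()
  maxlen <- 1L
  for (d in seq_len(nrow(directions))) {
    dd <- directions[d, ]
    a <- which(dd != 0)[1]
    t <- switch(a, ix, iy, iz)            # dd[a] == +1 by construction
    k1 <- ix - t * dd[1]; k2 <- iy - t * dd[2]; k3 <- iz - t * dd[3]
    code <- ((k1 + nmax) * base + (k2 + nmax)) * base + (k3 + nmax)
    ord <- order(code, t, method = "radix")
    co <- code[ord]; w <- as.integer(w0)[ord]
    n <- length(w)
    starts <- c(TRUE, co[-1] != co[-n] | w[-1] != w[-n])
    si <- which(starts)
    lens <- diff(c(si, n + 1L))
    levs <- w[si]
    keep <- levs > 0L
    lens <- lens[keep]; levs <- levs[keep]
    if (length(lens)) {
      maxlen <- max(maxlen, max(lens))
      counts[[d]] <- cbind(levs, lens)
    }
  }
  rl <- do.call(rbind, counts)
  out <- matrix(0, n_levels, maxlen)
  if (!is.null(rl)) {
    tab <- tabulate((rl[, 2] - 1L) * n_levels + rl[, 1], n_levels * maxlen)
    out[] <- tab
  }
  out
}

# Shared level/size-weighted statistics for run-length and zone matrices.
rl_stats <- function(m, prefix, n_voxels, n_chains_norm) {
  nr <- sum(m)
  i <- row(m); j <- col(m)
  ri <- rowSums(m); rj <- colSums(m)
  out <- c(
    sum(m / j^2) / nr,            # short emphasis
    sum(m * j^2) / nr,            # long emphasis
    sum(m / i^2) / nr,            # low grey-level
    sum(m * i^2) / nr,            # high grey-level
    sum(m / (i^2 * j^2)) / nr,    # short low
    sum(m * i^2 / j^2) / nr,      # short high
    sum(m * j^2 / i^2) / nr,      # long low
    sum(m * i^2 * j^2) / nr,      # long high
    sum(ri^2) / nr,               # grey-level non-uniformity
    sum(rj^2) / nr,               # length non-uniformity
    nr / n_chains_norm            # percentage
  )
  stats::setNames(out, paste0(prefix, c("SRE", "LRE", "LGRE", "HGRE",
                                        "SRLGE", "SRHGE", "LRLGE", "LRHGE",
                                        "GLNU", "RLNU", "RP")))
}

#' GLRLM features
#'
#' Standard run-length statistics (SRE, LRE, LGRE, HGRE, SRLGE, SRHGE,
#' LRLGE, LRHGE, GLNU, RLNU, RP) from the pooled matrix. RP is the run count
#' divided by `voxels x directions`, so it stays in (0, 1].
#'
#' @inheritParams glcm_matrix
#' @return named numeric vector over the GLRLM family.
#' @export
glrlm_features <- function(levels, n_levels = 64L,
                           directions = direction_offsets_13()) {
  m <- glrlm_matrix(levels, n_levels, directions)
  n_vox <- sum(!is.na(levels))
  rl_stats(m, "GLRLM_", n_vox, n_vox * nrow(directions))
}

#' Grey-level zone matrix
#'
#' Counts of 26-connected constant-level zones by level (rows) and zone size
#' (columns). Zone sizes partition the mask.
#'
#' @inheritParams glcm_matrix
#' @return integer matrix `n_levels x max_zone_size`.
#' @export
glzlm_matrix <- function(levels, n_levels = 64L) {
  dims <- dim(levels)
  idx <- which(!is.na(levels))
  if (!length(idx)) stopf("empty mask")
  vid <- array(0L, dims)
  vid[idx] <- seq_along(idx)
  offs <- direction_offsets_13()
  edges <- vector("list", nrow(offs))
  for (i in seq_len(nrow(offs))) {
    ov <- shift_overlap(dims, offs[i, ])
    if (is.null(ov)) next
    a <- slice3(vid, ov$src); b <- slice3(vid, ov$dst)
    la <- slice3(levels, ov$src); lb <- slice3(levels, ov$dst)
    keep <- a > 0L & b > 0L & !is.na(la) & !is.na(lb) & la == lb
    if (any(keep)) edges[[i]] <- cbind(a[keep], b[keep])
  }
  em <- do.call(rbind, edges)
  if (is.null(em)) {
    memb <- seq_along(idx)
  } else {
    g <- igraph::make_graph(as.vector(t(em)), n = length(idx),
                            directed = FALSE)
    memb <- igraph::components(g)$membership
  }
  sizes <- tabulate(memb)
  # level of each zone, aligned with component id 1..n_zones
  zl <- integer(length(sizes))
  zl[memb[!duplicated(memb)]] <- levels[idx][!duplicated(memb)]
  maxsz <- max(sizes)
  out <- matrix(0, n_levels, maxsz)
  tab <- tabulate((sizes - 1L) * n_levels + zl, n_levels * maxsz)
  out[] <- tab
  out
}

#' GLZLM features
#'
#' Zone-size statistics (SZE, LZE, LGZE, HGZE, SZLGE, SZHGE, LZLGE, LZHGE,
#' GLNU, ZLNU) and zone percentage `ZP = zones / voxels`.
#'
#' @inheritParams glcm_matrix
#' @return named numeric vector over the GLZLM family.
#' @export
glzlm_features <- function(levels, n_levels = 64L) {
  m <- glzlm_matrix(levels, n_levels)
  n_vox <- sum(!is.na(levels))
  out <- rl_stats(m, "GLZLM_", n_vox, n_vox)
  names(out) <- sub("SRE$", "SZE", names(out))
  names(out) <- sub("^GLZLM_LRE$", "GLZLM_LZE", names(out))
  names(out) <- sub("GRE$", "GZE", names(out))
  names(out) <- sub("SRLGE$", "SZLGE", names(out))
  names(out) <- sub("SRHGE$", "SZHGE", names(out))
  names(out) <- sub("LRLGE$", "LZLGE", names(out))
  names(out) <- sub("LRHGE$", "LZHGE", names(out))
  names(out) <- sub("RLNU$", "ZLNU", names(out))
  names(out) <- sub("RP$", "ZP", names(out))
  out
}

#' NGLDM features
#'
#' Neighbourhood grey-level difference aggregates over the 26-neighbourhood
#' restricted to the mask: for each level i, `s_i` is the summed absolute
#' difference between voxel level and the mean level of its in-mask
#' neighbours, and `p_i` the level probability. Coarseness
#' `1 / sum p_i s_i` (capped at 1e6 for uniform regions), contrast and
#' busyness follow the standard definitions; both are 0 for a single-level
#' region.
#'
#' @inheritParams glcm_matrix
#' @return named numeric vector over the NGLDM family.
#' @export
ngldm_features <- function(levels, n_levels = 64L) {
  dims <- dim(levels)
  msk <- !is.na(levels)
  if (sum(msk) < 2L) stopf("NGLDM needs at least 2 in-mask voxels")
  val <- levels; val[!msk] <- 0L
  val <- array(as.numeric(val), dims)
  cnt <- array(0, dims); acc <- array(0, dims)
  for (off in asplit(neighbour_offsets_26(), 1L)) {
    ov <- shift_overlap(dims, off)
    if (is.null(ov)) next
    acc[ov$src[[1]], ov$src[[2]], ov$src[[3]]] <-
      slice3(acc, ov$src) + slice3(val, ov$dst)
    cnt[ov$src[[1]], ov$src[[2]], ov$src[[3]]] <-
      slice3(cnt, ov$src) + slice3(msk, ov$dst)
  }
  use <- msk & cnt > 0
  lev <- levels[use]
  dif <- abs(lev - acc[use] / cnt[use])
  n <- sum(use)
  s <- numeric(n_levels)
  rs <- rowsum(dif, lev)
  s[as.integer(rownames(rs))] <- rs[, 1]
  ni <- tabulate(lev, n_levels)
  p <- ni / n
  present <- which(p > 0)
  ngp <- length(present)
  denom_coarse <- sum(p * s)
  coarseness <- if (denom_coarse > 0) min(1 / denom_coarse, 1e6) else 1e6
  contrast <- if (ngp > 1) {
    ii <- present
    sum(outer(p[ii], p[ii]) * outer(ii, ii, `-`)^2) /
      (ngp * (ngp - 1)) * sum(s) / n
  } else 0
  busy_den <- if (ngp > 1) {
    ii <- present
    sum(abs(outer(ii * p[ii], ii * p[ii], `-`)))
  } else 0
  busyness <- if (busy_den > 0) sum(p * s) / busy_den else 0
  c(NGLDM_Coarseness = coarseness,
    NGLDM_Contrast = contrast,
    NGLDM_Busyness = busyness)
}
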