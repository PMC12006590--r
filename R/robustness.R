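# Robustness screens: test-retest CoV and volume-dependency classification,
# combined into the two-stage feature reduction.

#' Coefficient of variation (percent)
#'
#' `100 * sample sd / |mean|` across repeat measurements. A zero mean makes
#' the CoV undefined; `NA` is returned (flag, not an exception). Values
#' flagged degenerate upstream (`NA`) make the CoV unevaluable (`NA`).
#'
#' @param values numeric vector, length >= 2.
#' @return CoV in percent, or `NA`.
#' @export
cov_percent <- function(values) {
  if (length(values) < 2L) stopf("CoV needs at least 2 values")
  if (anyNA(values)) return(NA_real_)
  m <- mean(values)
  if (m == 0) return(NA_real_)
  100 * stats::sd(values) / abs(m)
}

#' Repeatability screen over repeat-scan feature tables
#'
#' Computes the per-feature, per-insert CoV across repeat scans and flags
#' features whose CoV exceeds the threshold in at least one insert. Features
#' with degenerate (NA) values in any repeat are reported as unevaluable
#' rather than passed or failed.
#'
#' @param repeats data.frame with columns `insert` (insert label), `scan`
#'   (repeat id) and one column per feature.
#' @param threshold CoV threshold in percent (default 10, the guideline
#'   screen).
#' @return list with `cov` (data.frame feature x insert CoV%), `fail_any`
#'   (named logical), `n_inserts_failing` (named integer) and `unevaluable`
#'   (character).
#' @export
repeatability_flags <- function(repeats, threshold = 10) {
  feats <- setdiff(names(repeats), c("insert", "scan"))
  inserts <- unique(repeats$insert)
  cov <- sapply(inserts, function(ins) {
    sub <- repeats[repeats$insert == ins, feats, drop = FALSE]
    if (nrow(sub) < 2L) return(stats::setNames(rep(NA_real_, length(feats)),
                                               feats))
    vapply(sub, cov_percent, numeric(1))
  })
  cov <- matrix(cov, nrow = length(feats),
                dimnames = list(feats, as.character(inserts)))
  unevaluable <- feats[apply(cov, 1L, function(r) anyNA(r))]
  nfail <- apply(cov, 1L, function(r) sum(r > threshold, na.rm = TRUE))
  fail_any <- nfail > 0L
  fail_any[feats %in% unevaluable] <- NA
  list(cov = as.data.frame(cov), fail_any = fail_any,
       n_inserts_failing = nfail, unevaluable = unevaluable,
       threshold = threshold)
}

#' Volume curves from a per-VOI feature table
#'
#' One (volume, value) curve per feature, ordered by VOI volume regardless
#' of input row order.
#'
#' @param tbl data.frame with a `volume_ml` column and feature columns (as
#'   from [extract_series()]); provenance columns other than `volume_ml`
#'   are ignored.
#' @return named list of data.frames `(volume_ml, value)`.
#' @export
volume_curves <- function(tbl) {
  if (nrow(tbl) < 3L) stopf("volume curves need at least 3 VOIs")
  ord <- order(tbl$volume_ml)
  feats <- setdiff(names(tbl), c("volume_ml", "diameter_mm"))
  out <- lapply(feats, function(f)
    data.frame(volume_ml = tbl$volume_ml[ord], value = tbl[[f]][ord]))
  stats::setNames(out, feats)
}

#' Classify the volume dependency of one feature curve
#'
#' Algorithmic version of the three published dependency patterns. With
#' curve range `R = max - min` over the whole curve:
#' * **converging**: every value at volumes >= `v_conv` lies within
#'   `tail_tol * R` of the tail median; `convergence_volume` is the smallest
#'   curve volume from which that tail condition holds.
#' * **correlated**: not converging, and the tail has a monotone trend
#'   (Spearman |rho| >= `rho_threshold`).
#' * **random**: neither.
#' A flat curve is trivially converging from its first volume.
#'
#' @param curve data.frame `(volume_ml, value)` spanning volumes below and
#'   above `v_conv`.
#' @param v_conv convergence volume threshold (ml); default 25, the volume
#'   below which converging features were observed to vary.
#' @param tail_tol tail tolerance as a fraction of the curve range.
#' @param rho_threshold Spearman threshold for the correlated label.
#' @return list with `label` (`"converging"`, `"correlated"`, `"random"`)
#'   and `convergence_volume` (ml, or `NA`).
#' @export
classify_dependency <- function(curve, v_conv = 25, tail_tol = 0.10,
                                rho_threshold = 0.8) {
  ok <- is.finite(curve$value)
  v <- curve$volume_ml[ok]; y <- curve$value[ok]
  if (length(v) < 3L) {
    return(list(label = "unevaluable", convergence_volume = NA_real_))
  }
  if (!any(v < v_conv) || !any(v >= v_conv))
    stopf("curve must span volumes below and above v_conv = %g ml", v_conv)
  rng <- max(y) - min(y)
  if (rng == 0) return(list(label = "converging", convergence_volume = v[1]))
  tail_ok_from <- function(k) {
    yy <- y[k:length(y)]
    all(abs(yy - stats::median(yy)) <= tail_tol * rng)
  }
  k_conv <- which(v >= v_conv)[1]
  if (tail_ok_from(k_conv)) {
    flags <- vapply(seq_along(v), tail_ok_from, logical(1))
    suffix_all <- rev(cumprod(rev(flags))) > 0  # all(flags[k:n]) per k
    k_star <- which(suffix_all)[1]
    # smallest curve volume BEYOND which the condition holds: the last
    # volume at which it still fails (or the first volume for a curve
    # stable from the start)
    return(list(label = "converging",
                convergence_volume = v[max(k_star - 1L, 1L)]))
  }
  tail_idx <- k_conv:length(v)
  rho <- suppressWarnings(stats::cor(v[tail_idx], y[tail_idx],
                                     method = "spearman"))
  if (!is.na(rho) && abs(rho) >= rho_threshold) {
    list(label = "correlated", convergence_volume = NA_real_)
  } else {
    list(label = "random", convergence_volume = NA_real_)
  }
}

#' Two-stage feature reduction
#'
#' Combines the volume-dependency and repeatability screens: a feature is
#' excluded when its dependency label is not `"converging"` or when it fails
#' the CoV screen, unless it appears in `keep_exceptions` (features with a
#' known or intrinsic volume dependence, or judged clinically valuable,
#' retained despite a flag). Labels and flags must cover the whole
#' catalogue.
#'
#' @param catalog character vector of feature names (default the shipped
#'   67-name catalogue).
#' @param dependency named character vector of dependency labels, or a named
#'   list as returned by [classify_dependency()]; may also be a plain
#'   character vector of volume-excluded feature names.
#' @param cov_fail either the list from [repeatability_flags()] or a
#'   character vector of CoV-failing feature names.
#' @param keep_exceptions character vector of exception feature names.
#' @return list of class `reduction_result`: `retained`, `excluded_by`
#'   (named: `"volume"`, `"cov"`, `"both"`, `"none"`),
#'   `keep_list_exception` (named logical), `unevaluable`.
#' @export
reduce_features <- function(catalog = feature_names(), dependency = NULL,
                            cov_fail = NULL, keep_exceptions = character()) {
  vol_excl <- character()
  if (!is.null(dependency)) {
    if (is.list(dependency)) {
      dependency <- vapply(dependency, function(d)
        if (is.list(d)) d$label else as.character(d), character(1))
    }
    if (!is.null(names(dependency))) {
      missing <- setdiff(catalog, names(dependency))
      if (length(missing))
        stopf("dependency labels missing for: %s",
              paste(missing, collapse = ", "))
      vol_excl <- names(dependency)[!dependency %in%
                                      c("converging", "unevaluable")]
    } else {
      vol_excl <- as.character(dependency)   # plain excluded-name vector
    }
  }
  unevaluable <- character()
  if (!is.null(cov_fail)) {
    if (is.list(cov_fail)) {
      missing <- setdiff(catalog, names(cov_fail$fail_any))
      if (length(missing))
        stopf("CoV flags missing for: %s", paste(missing, collapse = ", "))
      unevaluable <- cov_fail$unevaluable
      cov_fail <- names(cov_fail$fail_any)[isTRUE_vec(cov_fail$fail_any)]
    }
    cov_fail <- as.character(cov_fail)
  } else {
    cov_fail <- character()
  }
  vol_excl <- intersect(vol_excl, catalog)
  cov_fail <- intersect(cov_fail, catalog)
  exc <- intersect(keep_exceptions, catalog)
  status <- stats::setNames(rep("none", length(catalog)), catalog)
  status[catalog %in% vol_excl] <- "volume"
  status[catalog %in% cov_fail] <-
    ifelse(status[catalog %in% cov_fail] == "volume", "both", "cov")
  rescued <- status != "none" & catalog %in% exc
  status[rescued] <- "none"
  structure(
    list(retained = catalog[status == "none"],
         excluded_by = status,
         keep_list_exception = stats::setNames(rescued, catalog),
         unevaluable = intersect(unevaluable, catalog)),
    class = "reduction_result"
  )
}

isTRUE_vec <- function(x) !is.na(x) & x

#' @export
print.reduction_result <- function(x, ...) {
  cat(sprintf("<reduction_result> %d retained / %d features\n",
              length(x$retained), length(x$excluded_by)))
  tb <- table(x$excluded_by)
  for (nm in setdiff(names(tb), "none"))
    cat(sprintf("  excluded by %s: %d\n", nm, tb[[nm]]))
  invisible(x)
}
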