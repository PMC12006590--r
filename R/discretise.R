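#' Fixed-bin-width SUV discretisation scheme
#'
#' The analysis protocol: 64 bins over the SUV range 0-20, giving a bin
#' width of 0.3125 SUV (printed as 0.3 SUV/bin at one decimal).
#'
#' @param n_bins number of grey levels.
#' @param lower,upper SUV range covered by the bins.
#' @return An object of class `discretisation_scheme` with fields `n_bins`,
#'   `lower`, `upper`, `bin_width`.
#' @export
discretisation_scheme <- function(n_bins = 64L, lower = 0, upper = 20) {
  if (n_bins < 2L || upper <= lower) stopf("invalid discretisation scheme")
  structure(list(n_bins = as.integer(n_bins), lower = lower, upper = upper,
                 bin_width = (upper - lower) / n_bins),
            class = "discretisation_scheme")
}

#' Discretise SUVs to grey levels
#'
#' `level = floor((x - lower) / bin_width) + 1`, clamped to `[1, n_bins]`;
#' `x = upper` maps to the top level.
#'
#' @param x numeric SUV values (finite).
#' @param scheme a [discretisation_scheme()].
#' @return integer levels in `1..n_bins`.
#' @export
discretise <- function(x, scheme = discretisation_scheme()) {
  if (any(!is.finite(x))) stopf("values must be finite")
  lev <- floor((x - scheme$lower) / scheme$bin_width) + 1
  as.integer(pmin(pmax(lev, 1), scheme$n_bins))
}

#' Grey-level bin centres
#'
#' SUV value at the centre of each level's bin,
#' `lower + (level - 1/2) * bin_width`; used for the discretised SUV
#' statistics so they stay in SUV units.
#'
#' @param levels integer levels.
#' @param scheme a [discretisation_scheme()].
#' @return numeric SUVs.
#' @export
bin_centres <- function(levels, scheme = discretisation_scheme()) {
  scheme$lower + (levels - 0.5) * scheme$bin_width
}
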