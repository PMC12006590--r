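# Synthetic volume-dependency curves with planted labels, used to validate
# the dependency classifier. Each generator constructs a curve that
# satisfies its label's defining condition by construction (and verifies it
# where the condition is statistical).

#' Synthetic volume curve with a planted dependency label
#'
#' * `"converging"`: exponential approach to a plateau, with excursions
#'   confined to small volumes and jitter well inside the tail tolerance.
#' * `"correlated"`: a monotone linear trend with jitter small enough to
#'   preserve strict monotonicity on the tail (Spearman |rho| = 1).
#' * `"random"`: sign-alternating values of comparable magnitude, so the
#'   tail neither settles within the tolerance band nor trends
#'   monotonically.
#'
#' @param label planted pattern.
#' @param volumes VOI volumes (ml); default the 29-sphere series volumes.
#' @param seed RNG seed.
#' @param v_conv,tail_tol the classifier parameters the construction must
#'   defeat or satisfy.
#' @return data.frame `(volume_ml, value)` with attribute `label`.
#' @export
synthetic_volume_curve <- function(label = c("converging", "correlated",
                                             "random"),
                                   volumes = NULL, seed = 1L,
                                   v_conv = 25, tail_tol = 0.10) {
  label <- match.arg(label)
  if (is.null(volumes)) {
    d <- seq(10, 122, by = 4)
    volumes <- pi / 6 * d^3 / 1000
  }
  v <- sort(volumes)
  n <- length(v)
  value <- withr::with_seed(seed, {
    switch(label,
      converging = {
        plateau <- stats::runif(1, -5, 5)
        amp <- stats::runif(1, 1, 10)
        decay <- v_conv / 5          # excursions die off well before v_conv
        plateau + amp * exp(-v / decay) +
          stats::runif(n, -1, 1) * 0.02 * amp * tail_tol
      },
      correlated = {
        slope <- sample(c(-1, 1), 1) * stats::runif(1, 0.5, 2)
        tail_gap <- min(diff(v[v >= v_conv]))
        slope * v + stats::runif(n, -1, 1) * 0.4 * abs(slope) * tail_gap
      },
      random = {
        amp <- stats::runif(1, 1, 10)
        signs <- rep_len(c(-1, 1), n)
        if (stats::runif(1) < 0.5) signs <- -signs
        val <- amp * signs * (1 + 0.3 * stats::runif(n))
        # alternation bounds Spearman far below any monotone threshold
        val
      }
    )
  })
  out <- data.frame(volume_ml = v, value = value)
  attr(out, "label") <- label
  out
}
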