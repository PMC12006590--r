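# Catalogue access and feature-name normalisation.

the_cache <- new.env(parent = emptyenv())

#' The 67-feature catalogue
#'
#' Returns the versioned feature catalogue shipped with the package: the 67
#' textural-analysis features (LIFEx v6.3-style naming) grouped into the
#' conventional SUV, discretised SUV, histogram, shape, GLCM, GLRLM, NGLDM
#' and GLZLM families. The catalogue was assembled by reconciling the
#' published exclusion/retention tables; see
#' `system.file("extdata", "feature_catalog.json", package = "spectrad")`
#' for the provenance note.
#'
#' @return data.frame with columns `name`, `display`, `family` (67 rows).
#' @export
feature_catalog <- function() {
  if (is.null(the_cache$catalog)) {
    path <- system.file("extdata", "feature_catalog.json", package = "spectrad")
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    the_cache$catalog <- j$features
  }
  the_cache$catalog
}

#' Catalogue feature names
#' @return character vector of the 67 canonical feature names, in catalogue
#'   order.
#' @export
feature_names <- function() feature_catalog()$name

# Collapse a printed or canonical feature name to a bare lookup key.
feature_key <- function(x) {
  k <- tolower(x)
  k <- gsub("[^a-z0-9]", "", k)
  k <- gsub("discretized", "discretised", k, fixed = TRUE)
  k <- gsub("glzcm", "glcm", k, fixed = TRUE)          # printed typo
  k <- sub("^discretisedhistogram", "histogram", k)
  k <- sub("peak1ml$", "peak10ml", k)
  k <- sub("peak5ml$", "peak05ml", k)
  # bare "Discretised <moment>" means the discretised-SUV moment
  k <- sub("^discretised(skewness|kurtosis|excesskurtosis)$",
           "discretisedsuv\\1", k)
  k
}

#' Normalise printed feature names to catalogue names
#'
#' Maps table spellings (case, spacing, `0.5 ml` vs `0.5ml`, the printed
#' `GLZCM` typo, `Discretised Skewness` shorthand, ...) onto the canonical
#' catalogue names. Names that match no catalogue entry map to `NA`.
#'
#' @param x character vector of feature names as printed or canonical.
#' @return character vector of canonical names (`NA` where unmatched).
#' @export
normalize_feature_name <- function(x) {
  cat <- feature_catalog()
  lut <- stats::setNames(rep(cat$name, 2L),
                         c(feature_key(cat$name), feature_key(cat$display)))
  unname(lut[feature_key(x)])
}
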