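#' Communalities (common factor variance)
#'
#' The communality of an indicator is the fraction of its variance
#' explained by the retained components: the sum of its squared loadings
#' over those components. With all components retained it equals 1 for
#' every indicator.
#'
#' @param pca A `pca_result`.
#' @param retained Integer vector of retained component indices.
#' @return Named numeric vector of communalities.
#' @export
communalities <- function(pca, retained) {
  if (length(retained) == 0) {
    stop_mdsqi("retained component set is empty",
               class = "validation_error")
  }
  U <- pca$loadings[, retained, drop = FALSE]
  rowSums(U^2)
}

#' Weights from communalities
#'
#' Indicator weights are each communality divided by the total communality
#' of the indicator set, so weights are non-negative and sum to 1.
#'
#' @param communality Named numeric vector of positive communalities.
#' @param label Indicator-set label, `"TDS"` or `"MDS"` (metadata).
#' @return A `weight_vector`: data frame with `indicator`, `communality`,
#'   `weight`; the set label is stored in attribute `"set"`.
#' @examples
#' weights_from_communalities(c(pH = 0.702, SOM = 0.826, BD = 0.540),
#'                            label = "MDS")
#' @export
weights_from_communalities <- function(communality, label = "TDS") {
  communality <- unlist(communality)
  if (any(!is.finite(communality)) || any(communality <= 0)) {
    stop_mdsqi("communalities must all be positive and finite",
               class = "validation_error")
  }
  w <- communality / sum(communality)
  out <- data.frame(indicator = names(communality),
                    communality = as.numeric(communality),
                    weight = as.numeric(w),
                    stringsAsFactors = FALSE)
  attr(out, "set") <- label
  class(out) <- c("weight_vector", "data.frame")
  out
}

#' @export
print.weight_vector <- function(x, ...) {
  cat(sprintf("<weight_vector> set = %s\n", attr(x, "set")))
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Indicator weights from a sample table
#'
#' From-data weighting path: runs a correlation PCA on the given indicator
#' subset, retains components by the configured eigenvalue/variance rules,
#' and converts the resulting communalities to weights. Used both for the
#' full TDS panel and for a freshly selected MDS subset.
#'
#' @param samples A [sample_table].
#' @param indicators Character vector of indicator names (default: all).
#' @param config An `mdsqi_config`.
#' @param label Set label recorded on the result.
#' @return A `weight_vector`.
#' @export
indicator_weights <- function(samples, indicators = NULL,
                              config = default_config(),
                              label = if (is.null(indicators)) "TDS"
                                      else "MDS") {
  m <- indicator_matrix(samples)
  if (!is.null(indicators)) {
    missing <- setdiff(indicators, colnames(m))
    if (length(missing) > 0) {
      stop_mdsqi("unknown indicator(s): ",
                 paste(missing, collapse = ", "), class = "config_error")
    }
    m <- m[, indicators, drop = FALSE]
  }
  pca <- pca_correlation(standardize(m))
  retained <- retain_components(pca, config$eigen_floor,
                                config$variance_floor)
  weights_from_communalities(communalities(pca, retained), label = label)
}
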