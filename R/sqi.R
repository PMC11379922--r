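#' Weighted-additive soil quality index
#'
#' The weighted-additive index of a sample is the dot product of the
#' indicator weights with the sample's membership scores. With weights
#' summing to 1 and memberships in \[0.1, 1\] the index lies in
#' \[0.1, 1\]. Per-plot values are the mean over the plot's samples.
#'
#' @param memberships A `membership_table` (see [score_table()]).
#' @param weights A `weight_vector`; its indicator set must be a subset of
#'   the membership columns. Weights are used as given (not renormalised),
#'   so published rounded weights reproduce published index values.
#' @return An `sqi_result`: list with `method`, `per_sample` (plot_id,
#'   sample_id, sqi), `per_plot` (plot_id, sqi, class).
#' @export
wdsqi_weighted_additive <- function(memberships, weights) {
  ind <- weights$indicator
  missing <- setdiff(ind, names(memberships))
  if (length(missing) > 0) {
    stop_mdsqi("membership table lacks weighted indicator(s): ",
               paste(missing, collapse = ", "), class = "config_error")
  }
  s <- sum(weights$weight)
  if (abs(s - 1) > 0.01) {
    stop_mdsqi("weights must sum to 1 (got ", signif(s, 6), ")",
               class = "config_error")
  }
  m <- as.matrix(as.data.frame(memberships)[, ind, drop = FALSE])
  sqi <- as.numeric(m %*% weights$weight)
  per_sample <- data.frame(plot_id = memberships$plot_id,
                           sample_id = memberships$sample_id,
                           sqi = sqi, stringsAsFactors = FALSE)
  sqi_result(paste0("weighted_additive_", attr(weights, "set")),
             per_sample)
}

#' Improved Nemerow soil quality index of one membership vector
#'
#' Pessimistic composite that couples the mean membership with the single
#' worst ("barrel theory") membership:
#' `sqrt((mean^2 + min^2) / 2) * (n - 1) / n`.
#' For memberships in \[0.1, 1\] the result lies in
#' \[0.1 (n-1)/n, (n-1)/n\], and it never exceeds `mean * (n-1)/n`.
#'
#' @param memberships Numeric vector of membership scores (one sample's
#'   scores across indicators), each in \[0.1, 1\]; length >= 2.
#' @return The index value (scalar).
#' @examples
#' nemerow_improved(rep(1, 9))  # 8/9
#' @export
nemerow_improved <- function(memberships) {
  if (length(memberships) == 0) {
    stop_mdsqi("empty membership vector", class = "validation_error")
  }
  if (length(memberships) < 2) {
    stop_mdsqi("improved Nemerow index needs n >= 2 indicators",
               class = "validation_error")
  }
  n <- length(memberships)
  f_bar <- mean(memberships)
  f_min <- min(memberships)
  sqrt((f_bar^2 + f_min^2) / 2) * (n - 1) / n
}

#' Improved Nemerow index of a membership table
#'
#' Applies [nemerow_improved()] across the indicator columns of every
#' sample, then aggregates to plots either by averaging the per-sample
#' indices (`"mean_of_samples"`, the default) or by applying the index to
#' the plot-mean membership vector (`"plot_mean_membership"`).
#'
#' @param memberships A `membership_table`.
#' @param aggregate Plot aggregation rule, see above.
#' @return An `sqi_result` with method `"nemerow_improved"`.
#' @export
wdsqin <- function(memberships,
                   aggregate = c("mean_of_samples",
                                 "plot_mean_membership")) {
  aggregate <- match.arg(aggregate)
  ind <- setdiff(names(memberships), c("plot_id", "sample_id"))
  m <- as.matrix(as.data.frame(memberships)[, ind, drop = FALSE])
  per_sample <- data.frame(plot_id = memberships$plot_id,
                           sample_id = memberships$sample_id,
                           sqi = apply(m, 1, nemerow_improved),
                           stringsAsFactors = FALSE)
  res <- sqi_result("nemerow_improved", per_sample)
  if (aggregate == "plot_mean_membership") {
    pm <- plot_mean_membership(memberships)
    sqi <- apply(as.matrix(pm[, ind, drop = FALSE]), 1, nemerow_improved)
    res$per_plot <- data.frame(plot_id = pm$plot_id, sqi = sqi,
                               class = classify(sqi),
                               stringsAsFactors = FALSE)
  }
  res$aggregate <- aggregate
  res
}

#' Legacy Nemerow composites
#'
#' The two historical forms of the Nemerow composite over a vector of
#' per-indicator quality indices:
#' * `eq4_min` — the minimum-factor form
#'   `sqrt((mean^2 + min^2) / 2) * (n - 1) / n` (identical to
#'   [nemerow_improved()]);
#' * `eq3_max` — the classical maximum-factor form, implemented as the
#'   symmetric quadratic mean `sqrt((mean^2 + max^2) / 2)` with no
#'   `(n - 1)/n` factor. Published statements of this form place the
#'   un-squared mean under the root (`sqrt(mean + max^2 / 2)`), which is
#'   dimensionally inconsistent and treated here as a typesetting error;
#'   set `literal = TRUE` to evaluate that printed form for auditing.
#'
#' @param values Non-empty numeric vector of quality indices.
#' @param variant `"eq4_min"` or `"eq3_max"`.
#' @param literal For `eq3_max` only: evaluate the literal printed form.
#' @return The composite index (scalar).
#' @export
nemerow_legacy <- function(values, variant = c("eq4_min", "eq3_max"),
                           literal = FALSE) {
  variant <- match.arg(variant)
  if (length(values) == 0) {
    stop_mdsqi("empty value vector", class = "validation_error")
  }
  n <- length(values)
  if (variant == "eq4_min") {
    sqrt((mean(values)^2 + min(values)^2) / 2) * (n - 1) / n
  } else if (literal) {
    sqrt(mean(values) + max(values)^2 / 2)
  } else {
    sqrt((mean(values)^2 + max(values)^2) / 2)
  }
}

#' Fertility classification
#'
#' Maps index values to the five fertility classes. Intervals are closed
#' on the upper end: > 0.8 Excellent, (0.7, 0.8] Good, (0.6, 0.7] Medium,
#' (0.4, 0.6] Deficient, <= 0.4 Destitute (with the default bounds).
#'
#' @param index Numeric vector of index values.
#' @param bounds Strictly increasing class bounds (default
#'   0.4/0.6/0.7/0.8).
#' @param labels Class labels from worst to best.
#' @return Character vector of class labels.
#' @examples
#' classify(c(0.634, 0.85, 0.4))  # Medium, Excellent, Destitute
#' @export
classify <- function(index, bounds = c(0.4, 0.6, 0.7, 0.8),
                     labels = c("Destitute", "Deficient", "Medium",
                                "Good", "Excellent")) {
  stopifnot(all(is.finite(index)), length(labels) == length(bounds) + 1L)
  # left.open makes each interval (lower, upper], so exact boundary
  # values fall in the lower class
  idx <- findInterval(index, bounds, left.open = TRUE)
  labels[idx + 1L]
}

#' Coefficient of variation and sensitivity class
#'
#' CV = 100 * sample SD / mean (n - 1 denominator), pooled over all
#' samples given. Sensitivity bands: CV < 10% insensitive, 10-50% low,
#' 50-100% moderate, >= 100% strong.
#'
#' @param values Numeric vector with at least 2 values and nonzero mean.
#' @return List with `cv` (percent) and `class`.
#' @examples
#' cv_sensitivity(c(1, 3))  # 70.71%, Moderate sensitivity
#' @export
cv_sensitivity <- function(values) {
  if (length(values) < 2) {
    stop_mdsqi("need at least 2 values for a CV", class = "validation_error")
  }
  m <- mean(values)
  if (m == 0) {
    stop_mdsqi("CV undefined for zero mean", class = "validation_error")
  }
  cv <- 100 * stats::sd(values) / m
  cls <- if (cv < 10) "Insensitive"
         else if (cv < 50) "Low sensitivity"
         else if (cv < 100) "Moderate sensitivity"
         else "Strong sensitivity"
  list(cv = cv, class = cls)
}

#' Regression validation of MDS against TDS indices
#'
#' Ordinary least-squares fit of the MDS-based index on the TDS-based
#' index over samples, quantifying how well the reduced indicator set
#' reproduces the full panel's assessment.
#'
#' @param tds_sqi,mds_sqi Equal-length numeric vectors (length >= 3) of
#'   per-sample index values.
#' @return List with `slope`, `intercept`, `r_squared` and the `lm` fit.
#' @export
validate_mds_vs_tds <- function(tds_sqi, mds_sqi) {
  if (length(tds_sqi) != length(mds_sqi) || length(tds_sqi) < 3) {
    stop_mdsqi("need equal-length vectors with at least 3 samples",
               class = "validation_error")
  }
  if (stats::sd(tds_sqi) == 0) {
    stop_mdsqi("TDS index has zero variance; regression undefined",
               class = "degenerate_input")
  }
  fit <- stats::lm(mds_sqi ~ tds_sqi)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       fit = fit)
}

# shared constructor: per-plot aggregate = mean of per-sample indices
sqi_result <- function(method, per_sample) {
  agg <- tapply(per_sample$sqi, per_sample$plot_id, mean)
  plots <- unique(per_sample$plot_id)
  per_plot <- data.frame(plot_id = plots,
                         sqi = as.numeric(agg[plots]),
                         stringsAsFactors = FALSE)
  per_plot$class <- classify(per_plot$sqi)
  structure(list(method = method, per_sample = per_sample,
                 per_plot = per_plot),
            class = "sqi_result")
}

#' @export
print.sqi_result <- function(x, ...) {
  cat(sprintf("<sqi_result> method = %s\n", x$method))
  print.data.frame(x$per_plot, digits = 3, row.names = FALSE)
  invisible(x)
}
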