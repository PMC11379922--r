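#' S-type membership score
#'
#' Monotone rising membership function used for nutrient indicators whose
#' effect on yield saturates: scores 0.1 below `m1`, rises linearly from
#' 0.1 to 1 on \[m1, m2), and is 1 at and above `m2`.
#'
#' @param value Measured value(s), in the indicator's units.
#' @param m1,m2 Lower and upper breakpoints, `m1 < m2`.
#' @return Score(s) in \[0.1, 1\].
#' @examples
#' score_s_type(8.5, 4, 13)  # 0.55
#' @export
score_s_type <- function(value, m1, m2) {
  if (!is.finite(m1) || !is.finite(m2) || m1 >= m2) {
    stop_mdsqi("score_s_type requires m1 < m2", class = "parameter_error")
  }
  stopifnot(all(is.finite(value)))
  ifelse(value >= m2, 1.0,
         ifelse(value < m1, 0.1,
                0.9 * (value - m1) / (m2 - m1) + 0.1))
}

#' Parabolic membership score
#'
#' Optimum-plateau membership function used for indicators with a critical
#' range (pH, moisture, bulk density): 0.1 below `x1`, rises linearly on
#' \[x1, x2), is 1 on the plateau \[x2, x3), falls linearly on \[x3, x4),
#' and is 0.1 at and above `x4`.
#'
#' @param value Measured value(s), in the indicator's units.
#' @param x1,x2,x3,x4 Breakpoints, `x1 < x2 <= x3 < x4`.
#' @return Score(s) in \[0.1, 1\].
#' @examples
#' score_parabolic(8.0, 5.5, 6.5, 7.5, 8.5)  # 0.55
#' @export
score_parabolic <- function(value, x1, x2, x3, x4) {
  ok <- all(is.finite(c(x1, x2, x3, x4))) && x1 < x2 && x2 <= x3 && x3 < x4
  if (!ok) {
    stop_mdsqi("score_parabolic requires x1 < x2 <= x3 < x4",
               class = "parameter_error")
  }
  stopifnot(all(is.finite(value)))
  out <- rep(0.1, length(value))
  rising <- value >= x1 & value < x2
  plateau <- value >= x2 & value < x3
  falling <- value >= x3 & value < x4
  out[rising] <- 0.9 * (value[rising] - x1) / (x2 - x1) + 0.1
  out[plateau] <- 1.0
  out[falling] <- 0.9 * (x4 - value[falling]) / (x4 - x3) + 0.1
  # degenerate plateau x2 == x3: the value x2 itself scores 1
  if (x2 == x3) out[value == x2] <- 1.0
  out
}

# score one indicator column through its spec
score_indicator <- function(value, spec) {
  p <- spec$params
  if (spec$fn_kind == "s_type") {
    score_s_type(value, p[["m1"]], p[["m2"]])
  } else {
    score_parabolic(value, p[["x1"]], p[["x2"]], p[["x3"]], p[["x4"]])
  }
}

#' Score a sample table to a membership table
#'
#' Applies each indicator's membership function elementwise, preserving
#' the (plot_id, sample_id) keys and table shape.
#'
#' @param samples A [sample_table].
#' @param specs Named list of [indicator_spec]; must cover every indicator
#'   column of `samples`.
#' @return A `membership_table`: same keys, scores in \[0.1, 1\].
#' @export
score_table <- function(samples, specs = default_indicator_specs()) {
  ind <- setdiff(names(samples), c("plot_id", "sample_id"))
  missing <- setdiff(ind, names(specs))
  if (length(missing) > 0) {
    stop_mdsqi("no indicator_spec for: ", paste(missing, collapse = ", "),
               class = "config_error")
  }
  out <- as.data.frame(samples)[, c("plot_id", "sample_id")]
  for (j in ind) out[[j]] <- score_indicator(samples[[j]], specs[[j]])
  class(out) <- c("membership_table", "data.frame")
  out
}

#' Per-plot mean membership
#'
#' Arithmetic mean of the sample membership scores within each plot, per
#' indicator — the per-plot summary used for radar charts and plot-level
#' indices.
#'
#' @param memberships A `membership_table`.
#' @return Data frame with one row per plot (plots in order of first
#'   appearance) and one column per indicator.
#' @export
plot_mean_membership <- function(memberships) {
  ind <- setdiff(names(memberships), c("plot_id", "sample_id"))
  plots <- unique(memberships$plot_id)
  if (length(plots) == 0 || nrow(memberships) == 0) {
    stop_mdsqi("membership table has no samples",
               class = "validation_error")
  }
  out <- data.frame(plot_id = plots, stringsAsFactors = FALSE)
  for (j in ind) {
    means <- tapply(memberships[[j]], memberships$plot_id, mean)
    out[[j]] <- as.numeric(means[plots])
  }
  out
}

#' @export
print.membership_table <- function(x, ...) {
  cat(sprintf("<membership_table> %d samples, %d plots\n",
              nrow(x), length(unique(x$plot_id))))
  print.data.frame(utils::head(x, 10), digits = 3)
  if (nrow(x) > 10) cat("... (", nrow(x) - 10, " more rows)\n", sep = "")
  invisible(x)
}
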