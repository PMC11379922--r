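#' Canonical indicator order
#'
#' The nine physicochemical indicators of the total data set (TDS), in the
#' fixed order used for every table produced by this package: pH, soil
#' organic matter (SOM), available nitrogen (AN), available phosphorus (AP),
#' available potassium (AK), total phosphorus (TP), total nitrogen (TN),
#' surface moisture content (SMC) and bulk density (BD). Fixing the order
#' makes all outputs deterministic regardless of input column order and
#' provides the tie-break order for selection rules.
#'
#' @format Character vector of length 9.
#' @export
INDICATOR_ORDER <- c("pH", "SOM", "AN", "AP", "AK", "TP", "TN", "SMC", "BD")

#' Create an indicator specification
#'
#' An indicator specification records an indicator's identity, units, and
#' the membership function used to rescale measured values to \[0.1, 1\]:
#' either an S-type (monotone rising) function with breakpoints `m1 < m2`,
#' or a parabolic (optimum plateau) function with breakpoints
#' `x1 < x2 <= x3 < x4`.
#'
#' @param name Indicator identifier (e.g. `"SOM"`).
#' @param units Free-text units; metadata only, never used in computation.
#' @param fn_kind `"s_type"` or `"parabolic"`.
#' @param params Named numeric vector: `c(m1=, m2=)` for S-type or
#'   `c(x1=, x2=, x3=, x4=)` for parabolic.
#' @return An object of class `indicator_spec`.
#' @examples
#' indicator_spec("SOM", "g/kg", "s_type", c(m1 = 4, m2 = 13))
#' @export
indicator_spec <- function(name, units, fn_kind = c("s_type", "parabolic"),
                           params) {
  fn_kind <- match.arg(fn_kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  params <- unlist(params)
  if (fn_kind == "s_type") {
    if (!all(c("m1", "m2") %in% names(params))) {
      stop_mdsqi("s_type spec for '", name, "' needs params m1 and m2",
                 class = "parameter_error")
    }
    params <- params[c("m1", "m2")]
    if (!all(is.finite(params)) || params[["m1"]] >= params[["m2"]]) {
      stop_mdsqi("s_type spec for '", name, "' requires finite m1 < m2",
                 class = "parameter_error")
    }
  } else {
    if (!all(c("x1", "x2", "x3", "x4") %in% names(params))) {
      stop_mdsqi("parabolic spec for '", name, "' needs params x1..x4",
                 class = "parameter_error")
    }
    params <- params[c("x1", "x2", "x3", "x4")]
    ok <- all(is.finite(params)) &&
      params[["x1"]] < params[["x2"]] &&
      params[["x2"]] <= params[["x3"]] &&
      params[["x3"]] < params[["x4"]]
    if (!ok) {
      stop_mdsqi("parabolic spec for '", name,
                 "' requires x1 < x2 <= x3 < x4",
                 class = "parameter_error")
    }
  }
  structure(list(name = name, units = units, fn_kind = fn_kind,
                 params = params),
            class = "indicator_spec")
}

#' @export
print.indicator_spec <- function(x, ...) {
  cat(sprintf("<indicator_spec> %s [%s], %s(%s)\n", x$name, x$units,
              x$fn_kind,
              paste(sprintf("%s=%g", names(x$params), x$params),
                    collapse = ", ")))
  invisible(x)
}

#' Default indicator specifications
#'
#' The published membership-function breakpoints for the nine waste-dump
#' soil indicators. SOM, AN, AP, AK, TP and TN use S-type functions whose
#' breakpoints are the agronomic deficiency/sufficiency limits; pH, SMC and
#' BD use parabolic functions with an optimum plateau.
#'
#' @return Named list of [indicator_spec] objects in canonical order.
#' @export
default_indicator_specs <- function() {
  load_fixture("membership_params")
}

#' Analysis configuration
#'
#' Bundles the indicator specifications and all tunable thresholds of the
#' minimum-data-set pipeline. Defaults are the published values: component
#' retention at eigenvalue >= 1 carrying >= 5% of total variance, loading
#' cutoff 0.6 for grouping, shortlist within 10% of the group's top
#' loading, redundancy filtering at |r| > 0.5, and the five fertility
#' classes bounded at 0.4/0.6/0.7/0.8.
#'
#' @param specs Named list of [indicator_spec] objects.
#' @param eigen_floor Minimum eigenvalue for a component to be retained.
#' @param variance_floor Minimum variance share (percent) for retention.
#' @param loading_cutoff Absolute loading at or above which an indicator is
#'   considered highly loaded on a component; in (0, 1].
#' @param shortlist_tol Multiplicative tolerance for the per-group
#'   shortlist: indicators with |loading| >= (1 - shortlist_tol) * max are
#'   kept; in (0, 1).
#' @param redundancy_r Absolute Pearson correlation above which two
#'   shortlisted indicators are considered redundant.
#' @param class_bounds Strictly increasing upper bounds of the four lower
#'   fertility classes.
#' @param class_labels Labels from worst to best class.
#' @param seed Optional integer seed recorded for reproducibility.
#' @return An object of class `mdsqi_config`.
#' @export
default_config <- function(specs = default_indicator_specs(),
                           eigen_floor = 1, variance_floor = 5,
                           loading_cutoff = 0.6, shortlist_tol = 0.1,
                           redundancy_r = 0.5,
                           class_bounds = c(0.4, 0.6, 0.7, 0.8),
                           class_labels = c("Destitute", "Deficient",
                                            "Medium", "Good", "Excellent"),
                           seed = NULL) {
  cfg <- structure(list(specs = specs, eigen_floor = eigen_floor,
                        variance_floor = variance_floor,
                        loading_cutoff = loading_cutoff,
                        shortlist_tol = shortlist_tol,
                        redundancy_r = redundancy_r,
                        class_bounds = class_bounds,
                        class_labels = class_labels, seed = seed),
                   class = "mdsqi_config")
  validate_config(cfg)
  cfg
}

#' Validate a configuration
#'
#' @param config An `mdsqi_config` object.
#' @return The config, invisibly, if valid; otherwise an error.
#' @export
validate_config <- function(config) {
  ok <- is.list(config$specs) && length(config$specs) > 0 &&
    all(vapply(config$specs, inherits, logical(1), "indicator_spec"))
  if (!ok) stop_mdsqi("config$specs must be a list of indicator_spec",
                      class = "config_error")
  if (!(config$loading_cutoff > 0 && config$loading_cutoff <= 1)) {
    stop_mdsqi("loading_cutoff must lie in (0, 1]", class = "config_error")
  }
  if (!(config$shortlist_tol > 0 && config$shortlist_tol < 1)) {
    stop_mdsqi("shortlist_tol must lie in (0, 1)", class = "config_error")
  }
  if (!(config$redundancy_r > 0)) {
    stop_mdsqi("redundancy_r must be positive", class = "config_error")
  }
  if (!(config$eigen_floor >= 0) || !(config$variance_floor >= 0)) {
    stop_mdsqi("retention floors must be non-negative",
               class = "config_error")
  }
  b <- config$class_bounds
  if (length(b) != length(config$class_labels) - 1L || any(diff(b) <= 0)) {
    stop_mdsqi("class_bounds must be strictly increasing with one fewer ",
               "entry than class_labels", class = "config_error")
  }
  invisible(config)
}

#' @export
print.mdsqi_config <- function(x, ...) {
  cat("<mdsqi_config>\n")
  cat("  indicators:    ", paste(names(x$specs), collapse = ", "), "\n")
  cat(sprintf("  retention:      eigenvalue >= %g and >= %g%% variance\n",
              x$eigen_floor, x$variance_floor))
  cat(sprintf("  grouping:       |loading| >= %g; shortlist within %g%%\n",
              x$loading_cutoff, 100 * x$shortlist_tol))
  cat(sprintf("  redundancy:     |r| > %g\n", x$redundancy_r))
  cat("  class bounds:  ", paste(x$class_bounds, collapse = " / "), "\n")
  invisible(x)
}

# classed conditions so callers can distinguish validation failures
stop_mdsqi <- function(..., class) {
  stop(errorCondition(paste0(...),
                      class = c(paste0("mdsqi_", class), "mdsqi_error")))
}

# info-level logging to stderr, toggled by options(mdsqi.verbose = TRUE)
log_info <- function(...) {
  if (isTRUE(getOption("mdsqi.verbose", FALSE))) {
    message("[mdsqi] ", ...)
  }
  invisible(NULL)
}
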