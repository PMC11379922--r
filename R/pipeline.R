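#' Run the full soil-quality evaluation pipeline
#'
#' Chains every stage on a raw sample table: membership scoring, MDS
#' selection (standardize, correlation PCA, retention, Norm scores,
#' grouping, shortlist/redundancy filtering), communality weighting for
#' both the full panel (TDS) and the selected subset (MDS, via a fresh
#' PCA on the selected indicators), weighted-additive indices under both
#' weight sets, the improved Nemerow index, fertility classification,
#' CV sensitivity, and the MDS-vs-TDS validation regression.
#'
#' @param samples A [sample_table].
#' @param config An `mdsqi_config` (see [default_config()]).
#' @return A `pipeline_report`: list with `memberships`,
#'   `plot_memberships`, `mds` (selection with audit), `weights_tds`,
#'   `weights_mds`, `sqi_tds`, `sqi_mds`, `sqi_nemerow`, `cv`,
#'   `validation` (slope/intercept/R^2 of MDS on TDS per-sample indices)
#'   and `meta` (config digest, input digest, seed, timestamp).
#' @export
run_pipeline <- function(samples, config = default_config()) {
  validate_config(config)
  log_info("scoring ", nrow(samples), " samples")
  memberships <- score_table(samples, config$specs)
  plot_memberships <- plot_mean_membership(memberships)

  log_info("selecting MDS")
  mds <- select_mds_from_samples(samples, config)

  weights_tds <- indicator_weights(samples, NULL, config, label = "TDS")
  weights_mds <- indicator_weights(samples, mds$selected, config,
                                   label = "MDS")

  sqi_tds <- wdsqi_weighted_additive(memberships, weights_tds)
  sqi_mds <- wdsqi_weighted_additive(memberships, weights_mds)
  sqi_nem <- wdsqin(memberships)

  ind <- setdiff(names(samples), c("plot_id", "sample_id"))
  cv <- do.call(rbind, lapply(ind, function(j) {
    s <- cv_sensitivity(samples[[j]])
    data.frame(indicator = j, cv_pct = s$cv, sensitivity = s$class,
               stringsAsFactors = FALSE)
  }))

  validation <- validate_mds_vs_tds(sqi_tds$per_sample$sqi,
                                    sqi_mds$per_sample$sqi)
  validation$fit <- NULL

  meta <- list(config_digest = value_digest(config),
               input_digest = value_digest(as.data.frame(samples)),
               seed = config$seed,
               timestamp = format(Sys.time(), tz = "UTC"))
  structure(list(memberships = memberships,
                 plot_memberships = plot_memberships,
                 mds = mds,
                 weights_tds = weights_tds, weights_mds = weights_mds,
                 sqi_tds = sqi_tds, sqi_mds = sqi_mds,
                 sqi_nemerow = sqi_nem,
                 cv = cv, validation = validation, meta = meta),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat("  MDS:", paste(x$mds$selected, collapse = ", "), "\n")
  tab <- data.frame(plot_id = x$sqi_nemerow$per_plot$plot_id,
                    WDSQI_TDS = x$sqi_tds$per_plot$sqi,
                    WDSQI_MDS = x$sqi_mds$per_plot$sqi,
                    WDSQIN = x$sqi_nemerow$per_plot$sqi,
                    class = x$sqi_nemerow$per_plot$class)
  print.data.frame(tab, digits = 3, row.names = FALSE)
  cat(sprintf("  MDS vs TDS: R^2 = %.3f, slope = %.3f\n",
              x$validation$r_squared, x$validation$slope))
  invisible(x)
}

#' Export radar-chart data
#'
#' Per-plot polygons of mean membership, one vertex per indicator in
#' canonical order — the plot-ready form of the membership summary for
#' external radar/spider charts. No figure is drawn.
#'
#' @param memberships A `membership_table`.
#' @return Long data frame with `plot_id`, `indicator` (ordered factor)
#'   and `mean_membership`.
#' @export
export_radar_data <- function(memberships) {
  pm <- plot_mean_membership(memberships)
  ind <- setdiff(names(pm), "plot_id")
  out <- do.call(rbind, lapply(seq_len(nrow(pm)), function(i) {
    data.frame(plot_id = pm$plot_id[i],
               indicator = ind,
               mean_membership = as.numeric(pm[i, ind]),
               stringsAsFactors = FALSE)
  }))
  out$indicator <- factor(out$indicator, levels = ind, ordered = TRUE)
  rownames(out) <- NULL
  out
}

# deterministic content digest (base R; order-sensitive 31-bit FNV-style
# hash over the serialized value, excluding environments)
value_digest <- function(x) {
  b <- serialize(x, NULL, version = 2)
  h <- 2166136261
  for (chunk in split(as.integer(b),
                      ceiling(seq_along(b) / 4096))) {
    h <- (h * 16777619 + sum(chunk * seq_along(chunk))) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}
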