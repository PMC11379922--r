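#' Nearest positive-semidefinite correlation matrix
#'
#' Published correlation tables are rounded to 2-3 decimals and can be
#' slightly indefinite. Repair is by eigenvalue clipping at zero,
#' reconstruction, and renormalisation to unit diagonal. Already-PSD
#' matrices are returned unchanged (to machine precision).
#'
#' @param matrix Symmetric matrix with unit diagonal.
#' @return A positive-semidefinite correlation matrix.
#' @export
repair_correlation <- function(matrix) {
  m <- as.matrix(matrix)
  if (!isSymmetric(unname(m))) {
    stop_mdsqi("correlation matrix must be symmetric",
               class = "validation_error")
  }
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= 0) return(m)
  lam <- pmax(e$values, 0)
  s <- e$vectors %*% (lam * t(e$vectors))
  d <- sqrt(diag(s))
  out <- s / tcrossprod(d)
  diag(out) <- 1
  dimnames(out) <- dimnames(m)
  out
}

#' Synthetic study configuration
#'
#' Describes a multi-plot soil sampling design to emulate: per-plot
#' indicator means and SDs, a shared inter-indicator correlation matrix,
#' samples per plot, truncation bounds, and a mandatory seed. The
#' defaults are the published study conditions — five waste-dump plots
#' with the published per-plot means/SDs, the published (PSD-repaired)
#' correlation structure, and five samples per plot.
#'
#' @param plot_summaries Long data frame with `plot_id`, `indicator`,
#'   `mean`, `sd` (default: the packaged published table).
#' @param correlation Indicator correlation matrix shared by all plots
#'   (default: the packaged published matrix, PSD-repaired).
#' @param n_per_plot Samples per plot (>= 1).
#' @param seed Integer seed; mandatory.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(plot_summaries = load_fixture("plot_summaries"),
                             correlation =
                               repair_correlation(load_fixture("correlations")),
                             n_per_plot = 5, seed) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop_mdsqi("a seed is mandatory for synthetic generation",
               class = "config_error")
  }
  if (n_per_plot < 1) {
    stop_mdsqi("n_per_plot must be >= 1", class = "config_error")
  }
  if (any(plot_summaries$sd < 0)) {
    stop_mdsqi("SDs must be non-negative", class = "config_error")
  }
  correlation <- as.matrix(correlation)
  if (!isSymmetric(unname(correlation)) ||
      any(abs(diag(correlation) - 1) > 1e-8)) {
    stop_mdsqi("correlation must be symmetric with unit diagonal",
               class = "config_error")
  }
  if (min(eigen(correlation, symmetric = TRUE,
                only.values = TRUE)$values) < -1e-8) {
    stop_mdsqi("correlation matrix is not positive semidefinite; ",
               "repair_correlation() it first", class = "config_error")
  }
  ind <- intersect(INDICATOR_ORDER, unique(plot_summaries$indicator))
  if (is.null(dimnames(correlation))) {
    if (nrow(correlation) != length(ind)) {
      stop_mdsqi("correlation dimension does not match the indicator set",
                 class = "config_error")
    }
    dimnames(correlation) <- list(ind, ind)
  }
  structure(list(plot_summaries = plot_summaries,
                 correlation = correlation[ind, ind],
                 indicators = ind,
                 n_per_plot = as.integer(n_per_plot),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# deterministic 31-bit sub-seed from a master seed and a string label,
# so per-plot streams are invariant to plot ordering
derive_seed <- function(seed, label) {
  h <- as.double(seed) %% 2147483647
  for (b in utf8ToInt(label)) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

#' Generate a synthetic sample table
#'
#' Draws each plot's samples from a multivariate normal with the plot's
#' mean vector, diagonal SD scaling and the shared correlation matrix.
#' Draws outside the physical bounds (pH in (0, 14); all other indicators
#' strictly positive) are rejected and redrawn, so marginals are
#' truncated without point masses at the bounds. Fully reproducible from
#' the config seed; each plot has its own deterministic sub-stream.
#'
#' @param config A [synthetic_config()].
#' @return A [sample_table] with `n_per_plot` rows per plot.
#' @export
generate_samples <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  ind <- config$indicators
  plots <- unique(config$plot_summaries$plot_id)
  lower <- rep(0, length(ind))          # all indicators strictly positive
  upper <- ifelse(ind == "pH", 14, Inf) # pH bounded above as well
  rows <- lapply(plots, function(p) {
    ps <- config$plot_summaries[config$plot_summaries$plot_id == p, ]
    mu <- stats::setNames(ps$mean, ps$indicator)[ind]
    sd <- stats::setNames(ps$sd, ps$indicator)[ind]
    sigma <- diag(sd) %*% config$correlation %*% diag(sd)
    n <- config$n_per_plot
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(derive_seed(config$seed, p))
    kept <- matrix(NA_real_, 0, length(ind))
    drawn <- 0
    while (nrow(kept) < n) {
      batch <- max(2 * (n - nrow(kept)), 16L)
      x <- MASS::mvrnorm(batch, mu = mu, Sigma = sigma)
      if (batch == 1) x <- matrix(x, nrow = 1)
      drawn <- drawn + batch
      ok <- apply(x, 1, function(r) all(r > lower & r < upper))
      kept <- rbind(kept, x[ok, , drop = FALSE])
      if (drawn > 100 * n && nrow(kept) < drawn / 100) {
        stop_mdsqi("rejection rate above 99% for plot '", p,
                   "'; truncation bounds incompatible with moments",
                   class = "config_error")
      }
    }
    kept <- kept[seq_len(n), , drop = FALSE]
    df <- data.frame(plot_id = p,
                     sample_id = sprintf("%s-%d", p, seq_len(n)),
                     stringsAsFactors = FALSE)
    for (j in seq_along(ind)) df[[ind[j]]] <- kept[, j]
    df
  })
  df <- do.call(rbind, rows)
  specs <- default_indicator_specs()[ind]
  sample_table(df, specs)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Replicated end-to-end MDS recovery
#'
#' Runs the full selection pipeline (standardize, correlation PCA,
#' component retention, Norm scores, grouping, MDS selection) on
#' `replicates` fresh synthetic studies drawn under `config`'s moment and
#' correlation structure, and summarises how often each indicator enters
#' the MDS, the MDS size distribution, and the leading eigenvalues.
#'
#' @param config A [synthetic_config()]; its seed seeds replicate 1, and
#'   further replicates use deterministic sub-seeds.
#' @param replicates Number of replicate studies (>= 10).
#' @param seed Optional master seed overriding `config$seed`.
#' @param mds_config An `mdsqi_config` with the selection thresholds.
#' @return List with `inclusion_freq` (named, descending), `sizes`
#'   (integer vector per replicate), `eigen_summary` (mean of the two
#'   leading eigenvalues), and `replicates`.
#' @export
end_to_end_recovery <- function(config, replicates = 100,
                                seed = config$seed,
                                mds_config = default_config()) {
  if (replicates < 10) {
    stop_mdsqi("need at least 10 replicates", class = "config_error")
  }
  counts <- stats::setNames(numeric(length(config$indicators)),
                            config$indicators)
  sizes <- integer(replicates)
  lead1 <- lead2 <- numeric(replicates)
  for (r in seq_len(replicates)) {
    cfg_r <- config
    cfg_r$seed <- derive_seed(seed, paste0("replicate-", r))
    samples <- generate_samples(cfg_r)
    sel <- select_mds_from_samples(samples, mds_config)
    counts[sel$selected] <- counts[sel$selected] + 1
    sizes[r] <- length(sel$selected)
    lead1[r] <- sel$pca$eigenvalues[1]
    lead2[r] <- sel$pca$eigenvalues[2]
  }
  list(inclusion_freq = sort(counts / replicates, decreasing = TRUE),
       sizes = sizes,
       eigen_summary = c(lambda1_mean = mean(lead1),
                         lambda2_mean = mean(lead2)),
       replicates = replicates)
}
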