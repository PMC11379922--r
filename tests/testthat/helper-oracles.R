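# Shared helpers: small deterministic inputs and a pca_result built from
# the packaged published loadings, used by several test files.

# pca_result carrying the published two-component loading matrix
published_pca <- function() {
  L <- load_fixture("loadings")
  structure(list(eigenvalues = L$eigenvalues,
                 variance_pct = L$variance_pct,
                 cumulative_pct = L$cumulative_pct,
                 loadings = L$loadings,
                 p = nrow(L$loadings)),
            class = "pca_result")
}

# small valid sample table with values inside every membership window
tiny_samples <- function(n_per_plot = 4, plots = c("A", "B"), seed = 42) {
  set.seed(seed)
  rows <- lapply(plots, function(p) {
    df <- data.frame(plot_id = p,
                     sample_id = paste0(p, seq_len(n_per_plot)),
                     stringsAsFactors = FALSE)
    df$pH <- runif(n_per_plot, 6, 9)
    df$SOM <- runif(n_per_plot, 2, 15)
    df$AN <- runif(n_per_plot, 3, 18)
    df$AP <- runif(n_per_plot, 2, 12)
    df$AK <- runif(n_per_plot, 80, 420)
    df$TP <- runif(n_per_plot, 0.5, 2.5)
    df$TN <- runif(n_per_plot, 0.5, 3)
    df$SMC <- runif(n_per_plot, 4, 18)
    df$BD <- runif(n_per_plot, 0.4, 1.4)
    df
  })
  sample_table(do.call(rbind, rows))
}

# random full-rank correlation matrix via random data
random_corr <- function(p, n = 50, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("v", seq_len(p))))
  stats::cor(m)
}

# full MDS selection from a numeric sample matrix (no sample_table
# validation), used for sign-flip invariance checks
select_from_matrix <- function(m, config = default_config()) {
  pca <- pca_correlation(m)
  retained <- retain_components(pca, config$eigen_floor,
                                config$variance_floor)
  norms <- norm_scores(pca, retained)
  groups <- group_indicators(pca, retained, pca$correlation,
                             config$loading_cutoff)
  select_mds(pca, pca$correlation, norms, groups,
             config$shortlist_tol, config$redundancy_r)
}
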