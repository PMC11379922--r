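#' Load a packaged reference table
#'
#' The package ships plain-text transcriptions of the published reference
#' tables for the Hequ open-pit mine waste-dump study, so the whole
#' pipeline can be exercised without any external data:
#'
#' * `membership_params` — membership-function breakpoints for the nine
#'   indicators (returned as a named list of [indicator_spec]).
#' * `plot_summaries` — per-plot mean and standard deviation of every
#'   indicator over the five field samples (long data frame).
#' * `loadings` — the published two-component PCA of the nine-indicator
#'   panel: loading matrix, eigenvalues, variance percentages and printed
#'   Norm values (a list).
#' * `correlations` — the 9x9 Pearson correlation matrix of the indicator
#'   panel (symmetric, unit diagonal).
#' * `communalities` — published communalities ("common factor variance")
#'   and weights for the TDS and MDS indicator sets (data frame).
#' * `memberships` — the published per-sample membership scores, 25 samples
#'   by 9 indicators (a `membership_table`).
#'
#' Note on `memberships`: the published table prints its TN and TP columns
#' in the order TN, TP, while other tables order TP before TN; the
#' transcription keeps the printed column order and labels. Which of the
#' two columns is truly which cannot be resolved from the source, and no
#' computation in this package depends on the distinction.
#'
#' @param table_id One of `"membership_params"`, `"plot_summaries"`,
#'   `"loadings"`, `"correlations"`, `"communalities"`, `"memberships"`.
#' @return A typed table as described above.
#' @examples
#' specs <- load_fixture("membership_params")
#' specs$SOM$params  # m1 = 4, m2 = 13
#' @export
load_fixture <- function(table_id) {
  valid <- c("membership_params", "plot_summaries", "loadings",
             "correlations", "communalities", "memberships")
  if (!is.character(table_id) || length(table_id) != 1L ||
      !(table_id %in% valid)) {
    stop_mdsqi("unknown table_id; expected one of: ",
               paste(valid, collapse = ", "), class = "lookup_error")
  }
  path <- function(f) system.file("extdata", f, package = "mdsqi",
                                  mustWork = TRUE)
  switch(table_id,
    membership_params = {
      df <- utils::read.csv(path("membership_params.csv"))
      specs <- lapply(seq_len(nrow(df)), function(i) {
        r <- df[i, ]
        if (r$fn_kind == "s_type") {
          indicator_spec(r$indicator, r$units, "s_type",
                         c(m1 = r$m1, m2 = r$m2))
        } else {
          indicator_spec(r$indicator, r$units, "parabolic",
                         c(x1 = r$x1, x2 = r$x2, x3 = r$x3, x4 = r$x4))
        }
      })
      names(specs) <- df$indicator
      specs[INDICATOR_ORDER]
    },
    plot_summaries = {
      df <- utils::read.csv(path("plot_summaries.csv"))
      class(df) <- c("plot_summary", "data.frame")
      df
    },
    loadings = {
      ld <- utils::read.csv(path("pca_loadings.csv"))
      sm <- utils::read.csv(path("pca_summary.csv"))
      U <- as.matrix(ld[, c("pc1", "pc2")])
      dimnames(U) <- list(ld$indicator, c("PC1", "PC2"))
      list(loadings = U,
           eigenvalues = sm$eigenvalue,
           variance_pct = sm$variance_pct,
           cumulative_pct = sm$cumulative_pct,
           group = stats::setNames(ld$group, ld$indicator),
           norm_printed = stats::setNames(ld$norm, ld$indicator))
    },
    correlations = {
      df <- utils::read.csv(path("correlations.csv"))
      m <- as.matrix(df[, -1])
      dimnames(m) <- list(df$indicator, df$indicator)
      stopifnot(isSymmetric(m), all(diag(m) == 1))
      m
    },
    communalities = utils::read.csv(path("communalities.csv")),
    memberships = {
      df <- utils::read.csv(path("memberships.csv"))
      class(df) <- c("membership_table", "data.frame")
      df
    }
  )
}
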