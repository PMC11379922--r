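#' Standardize a sample table
#'
#' Centers each indicator column to mean 0 and scales to unit sample
#' variance (n - 1 denominator) — the input expected by the
#' correlation-matrix PCA.
#'
#' @param samples A [sample_table], or a numeric matrix/data frame of
#'   samples by indicators.
#' @return Numeric matrix of standardized values.
#' @export
standardize <- function(samples) {
  m <- if (inherits(samples, "sample_table")) indicator_matrix(samples)
       else as.matrix(samples)
  if (nrow(m) < 3) {
    stop_mdsqi("need at least 3 samples to standardize",
               class = "degenerate_input")
  }
  sds <- apply(m, 2, stats::sd)
  zero <- which(sds == 0 | !is.finite(sds))
  if (length(zero) > 0) {
    stop_mdsqi("zero variance in indicator '", colnames(m)[zero[1]], "'",
               class = "degenerate_input")
  }
  scale(m, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Correlation-matrix principal component analysis
#'
#' Eigendecomposition of the Pearson correlation matrix. Loadings are
#' eigenvectors scaled by the square root of their eigenvalue, so that the
#' loading of indicator i on component k is its correlation with the
#' component. Components are ordered by descending eigenvalue; the sign of
#' each component is fixed so its largest-magnitude loading is positive.
#'
#' @param x Either a standardized (or raw) samples-by-indicators matrix /
#'   [sample_table], or an already-computed symmetric correlation matrix
#'   with unit diagonal.
#' @return A `pca_result`: list with `eigenvalues`, `variance_pct`
#'   (eigenvalue / p, in percent), `cumulative_pct`, `loadings` (p x p
#'   matrix), `correlation` (the matrix decomposed), `p` and `n_samples`
#'   (NA when called on a correlation matrix).
#' @examples
#' pca_correlation(matrix(c(1, 0.6, 0.6, 1), 2,
#'                        dimnames = list(c("a", "b"), c("a", "b"))))
#' @export
pca_correlation <- function(x) {
  if (inherits(x, "sample_table")) x <- indicator_matrix(x)
  x <- as.matrix(x)
  if (!all(is.finite(x))) {
    stop_mdsqi("input contains non-finite values",
               class = "validation_error")
  }
  is_cor <- nrow(x) == ncol(x) && isSymmetric(unname(x)) &&
    all(abs(diag(x) - 1) < 1e-8)
  if (is_cor) {
    R <- x
    n_samples <- NA_integer_
  } else {
    if (nrow(x) < ncol(x) + 1) {
      stop_mdsqi("need at least p + 1 samples for a full-rank ",
                 "correlation PCA", class = "validation_error")
    }
    R <- stats::cor(x)
    n_samples <- nrow(x)
  }
  p <- ncol(R)
  e <- eigen(R, symmetric = TRUE)
  lambda <- e$values
  U <- e$vectors %*% diag(sqrt(pmax(lambda, 0)), p)
  dimnames(U) <- list(colnames(R), paste0("PC", seq_len(p)))
  for (k in seq_len(p)) {
    if (U[which.max(abs(U[, k])), k] < 0) U[, k] <- -U[, k]
  }
  structure(list(eigenvalues = lambda,
                 variance_pct = 100 * lambda / p,
                 cumulative_pct = cumsum(100 * lambda / p),
                 loadings = U,
                 correlation = R,
                 p = p,
                 n_samples = n_samples),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> p = %d indicators%s\n", x$p,
              if (is.na(x$n_samples)) " (from correlation matrix)"
              else sprintf(", n = %d samples", x$n_samples)))
  k <- min(x$p, 4L)
  tab <- rbind(eigenvalue = x$eigenvalues[1:k],
               `variance %` = x$variance_pct[1:k],
               `cumulative %` = x$cumulative_pct[1:k])
  colnames(tab) <- paste0("PC", 1:k)
  print(round(tab, 3))
  invisible(x)
}

#' Retain principal components
#'
#' Keeps components whose eigenvalue is at least `eigen_floor` and whose
#' variance share is at least `variance_floor` percent. The first
#' component is always retained (with a warning if it fails the rule), so
#' downstream Norm and grouping computations are defined.
#'
#' @param pca A `pca_result`.
#' @param eigen_floor Minimum eigenvalue (default 1, the Kaiser rule).
#' @param variance_floor Minimum variance share in percent (default 5).
#' @return Integer vector of retained component indices.
#' @export
retain_components <- function(pca, eigen_floor = 1, variance_floor = 5) {
  keep <- which(pca$eigenvalues >= eigen_floor &
                pca$variance_pct >= variance_floor)
  if (length(keep) == 0) {
    warning("no component meets the retention rule; keeping PC1")
    keep <- 1L
  }
  sort(keep)
}

#' Norm scores of indicators
#'
#' The Norm value summarises how much of the retained components'
#' information an indicator carries: the comprehensive load of indicator i
#' is the eigenvalue-weighted sum of its squared loadings over the
#' retained components, and the Norm score is its square root. Both are
#' returned; they induce the same ranking, and published tables report the
#' comprehensive load.
#'
#' @param pca A `pca_result`.
#' @param retained Integer vector of retained component indices.
#' @return Data frame with `indicator`, `comprehensive_load`, `norm`.
#' @export
norm_scores <- function(pca, retained) {
  if (length(retained) == 0) {
    stop_mdsqi("retained component set is empty",
               class = "validation_error")
  }
  U <- pca$loadings[, retained, drop = FALSE]
  lam <- pca$eigenvalues[retained]
  cl <- as.numeric(U^2 %*% lam)
  data.frame(indicator = rownames(pca$loadings),
             comprehensive_load = cl,
             norm = sqrt(cl),
             stringsAsFactors = FALSE)
}

#' Group indicators by principal component
#'
#' Assigns every indicator to one retained component:
#' * |loading| at or above `loading_cutoff` on exactly one retained
#'   component — that component's group;
#' * high loading on two or more components (cross-loading) — the group
#'   whose already-assigned members have the smallest mean absolute
#'   Pearson correlation with the indicator;
#' * high loading on none — the component where its |loading| is largest.
#'
#' @param pca A `pca_result`.
#' @param retained Integer vector of retained component indices.
#' @param correlations Symmetric indicator correlation matrix (used only
#'   for the cross-loading rule).
#' @param loading_cutoff Absolute loading threshold (default 0.6).
#' @return List with `assignment` (named integer vector of component
#'   indices) and `rule` (named character vector recording which rule
#'   placed each indicator).
#' @export
group_indicators <- function(pca, retained, correlations,
                             loading_cutoff = 0.6) {
  if (!(loading_cutoff > 0 && loading_cutoff < 1)) {
    stop_mdsqi("loading_cutoff must lie in (0, 1)",
               class = "config_error")
  }
  U <- abs(pca$loadings[, retained, drop = FALSE])
  ind <- rownames(pca$loadings)
  assignment <- stats::setNames(rep(NA_integer_, length(ind)), ind)
  rule <- stats::setNames(rep(NA_character_, length(ind)), ind)

  high <- U >= loading_cutoff
  n_high <- rowSums(high)
  # pass 1: unambiguous assignments anchor the groups
  for (i in which(n_high == 1)) {
    assignment[i] <- retained[which(high[i, ])]
    rule[i] <- "single_high_loading"
  }
  for (i in which(n_high == 0)) {
    assignment[i] <- retained[which.max(U[i, ])]
    rule[i] <- "max_loading"
  }
  # pass 2: cross-loading indicators go to the least-correlated group
  for (i in which(n_high >= 2)) {
    cand <- retained[which(high[i, ])]
    mean_r <- vapply(cand, function(k) {
      members <- names(assignment)[!is.na(assignment) & assignment == k]
      members <- setdiff(members, ind[i])
      if (length(members) == 0) return(Inf)
      mean(abs(correlations[ind[i], members]))
    }, numeric(1))
    assignment[i] <- cand[which.min(mean_r)]
    rule[i] <- "cross_loading_least_correlated"
  }
  list(assignment = assignment, rule = rule)
}

#' Select the minimum data set
#'
#' Executes the published shortlist-and-redundancy procedure on grouped
#' indicators. Per group: the shortlist keeps indicators whose absolute
#' loading on the group's component is within `shortlist_tol` (multiplic-
#' ative) of the group maximum; if all pairwise absolute correlations in
#' the shortlist are below `redundancy_r` every shortlisted indicator is
#' kept, otherwise the indicator with the highest comprehensive load is
#' kept and shortlisted indicators correlated with it above `redundancy_r`
#' are dropped, repeating on the remainder. The union of survivors over
#' groups is the MDS. All loading comparisons use absolute values; ties
#' are broken by the canonical indicator order.
#'
#' @param pca A `pca_result`.
#' @param correlations Symmetric indicator correlation matrix.
#' @param norms Data frame from [norm_scores()].
#' @param groups List from [group_indicators()].
#' @param shortlist_tol Multiplicative shortlist tolerance (default 0.1,
#'   i.e. within 10% of the top loading).
#' @param redundancy_r Absolute correlation above which shortlisted
#'   indicators are redundant (default 0.5).
#' @return An `mds_selection`: list with `selected` (character vector in
#'   canonical order), `groups`, `shortlists`, `norms` and `audit` (a
#'   character vector tracing every rule applied).
#' @export
select_mds <- function(pca, correlations, norms, groups,
                       shortlist_tol = 0.1, redundancy_r = 0.5) {
  if (!(shortlist_tol > 0 && shortlist_tol < 1)) {
    stop_mdsqi("shortlist_tol must lie in (0, 1)", class = "config_error")
  }
  ind <- rownames(pca$loadings)
  canon <- order(match(ind, INDICATOR_ORDER), ind)
  cl <- stats::setNames(norms$comprehensive_load, norms$indicator)
  assignment <- groups$assignment
  audit <- character(0)
  say <- function(...) audit <<- c(audit, paste0(...))

  for (i in ind) {
    say("group: ", i, " -> PC", assignment[i], " (", groups$rule[i], ")")
  }

  selected <- character(0)
  shortlists <- list()
  for (k in sort(unique(assignment))) {
    members <- ind[canon][ind[canon] %in% names(assignment)[assignment == k]]
    absload <- abs(pca$loadings[members, k])
    top <- max(absload)
    short <- members[absload >= (1 - shortlist_tol) * top]
    shortlists[[paste0("PC", k)]] <- short
    say("shortlist PC", k, ": {", paste(short, collapse = ", "),
        "} (|loading| >= ", signif((1 - shortlist_tol) * top, 4), ")")

    # iterative redundancy filter ordered by comprehensive load
    pool <- short[order(-cl[short], match(short, INDICATOR_ORDER))]
    survivors <- character(0)
    while (length(pool) > 0) {
      best <- pool[1]
      survivors <- c(survivors, best)
      rest <- pool[-1]
      if (length(rest) == 0) break
      r <- abs(correlations[best, rest])
      drop <- rest[r > redundancy_r]
      keep <- rest[r <= redundancy_r]
      for (d in drop) {
        say("redundancy PC", k, ": drop ", d, " (|r(", d, ",", best,
            ")| = ", signif(abs(correlations[best, d]), 3), " > ",
            redundancy_r, ")")
      }
      for (q in keep) {
        say("redundancy PC", k, ": keep ", q, " with ", best, " (|r| = ",
            signif(abs(correlations[best, q]), 3), " <= ", redundancy_r,
            ")")
      }
      pool <- keep
    }
    say("group PC", k, " survivors: {",
        paste(survivors, collapse = ", "), "}")
    selected <- c(selected, survivors)
  }
  selected <- selected[order(match(selected, INDICATOR_ORDER), selected)]
  say("MDS: {", paste(selected, collapse = ", "), "} (",
      length(selected), " of ", length(ind), " indicators)")
  log_info("selected MDS: ", paste(selected, collapse = ", "))
  structure(list(selected = selected, groups = groups,
                 shortlists = shortlists, norms = norms, audit = audit),
            class = "mds_selection")
}

#' @export
print.mds_selection <- function(x, ...) {
  cat("<mds_selection>\n")
  cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  for (g in names(x$shortlists)) {
    cat("  shortlist ", g, ": ",
        paste(x$shortlists[[g]], collapse = ", "), "\n", sep = "")
  }
  cat("  (", length(x$audit), " audit entries; see $audit)\n", sep = "")
  invisible(x)
}

#' Select an MDS directly from a sample table
#'
#' Convenience wrapper chaining [standardize()], [pca_correlation()],
#' [retain_components()], [norm_scores()], [group_indicators()] and
#' [select_mds()] under one configuration.
#'
#' @param samples A [sample_table].
#' @param config An `mdsqi_config` (see [default_config()]).
#' @return An `mds_selection` with the intermediate `pca_result` attached
#'   as `$pca` and retained components as `$retained`.
#' @export
select_mds_from_samples <- function(samples, config = default_config()) {
  z <- standardize(samples)
  pca <- pca_correlation(z)
  retained <- retain_components(pca, config$eigen_floor,
                                config$variance_floor)
  norms <- norm_scores(pca, retained)
  groups <- group_indicators(pca, retained, pca$correlation,
                             config$loading_cutoff)
  sel <- select_mds(pca, pca$correlation, norms, groups,
                    config$shortlist_tol, config$redundancy_r)
  sel$pca <- pca
  sel$retained <- retained
  sel
}
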