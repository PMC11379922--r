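test_that("standardize centers, scales, and is idempotent", {
  s <- generate_samples(synthetic_config(seed = 1))
  z <- standardize(s)
  expect_equal(unname(colMeans(z)), rep(0, 9), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, stats::var)), rep(1, 9),
               tolerance = 1e-12)
  expect_equal(unname(standardize(z)), unname(z), tolerance = 1e-12)

  const <- as.data.frame(tiny_samples())
  const$BD <- 0.8
  expect_error(standardize(sample_table(const)), "BD",
               class = "mdsqi_degenerate_input")
})

test_that("correlation PCA matches closed forms and external oracles", {
  # identity: all eigenvalues 1, equal variance shares
  id <- diag(9)
  dimnames(id) <- list(INDICATOR_ORDER, INDICATOR_ORDER)
  p_id <- pca_correlation(id)
  expect_equal(p_id$eigenvalues, rep(1, 9))
  expect_equal(p_id$variance_pct, rep(100 / 9, 9))

  # 2x2 closed form: eigenvalues 1 +/- r
  two <- matrix(c(1, 0.6, 0.6, 1), 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(pca_correlation(two)$eigenvalues, c(1.6, 0.4))

  # independent oracle: princomp loadings on random data
  set.seed(3)
  m <- matrix(rnorm(200), 40, 5, dimnames = list(NULL, paste0("v", 1:5)))
  ours <- pca_correlation(m)
  ref <- stats::princomp(covmat = stats::cor(m))
  ref_load <- unclass(ref$loadings) %*% diag(ref$sdev)
  expect_equal(abs(unname(ours$loadings)), abs(unname(ref_load)),
               tolerance = 1e-8)
  expect_equal(ours$eigenvalues, unname(ref$sdev^2), tolerance = 1e-8)

  expect_error(pca_correlation(matrix(c(1, NA, NA, 1), 2)),
               class = "mdsqi_validation_error")
})

test_that("PCA conserves trace and reconstructs the correlation matrix", {
  for (seed in 1:4) {
    p <- sample(4:6, 1)
    R <- random_corr(p, seed = seed)
    pca <- pca_correlation(R)
    expect_equal(sum(pca$eigenvalues), p, tolerance = 1e-8)
    expect_equal(tcrossprod(pca$loadings), R, tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_true(all(abs(pca$loadings) <= 1 + 1e-8))
  }
})

test_that("component retention applies the eigenvalue and variance floors", {
  fake <- function(lam) {
    structure(list(eigenvalues = lam, variance_pct = 100 * lam / sum(lam),
                   p = length(lam)), class = "pca_result")
  }
  expect_equal(retain_components(fake(c(5.435, 1.204, 0.8, 0.5, 0.4,
                                        0.3, 0.2, 0.1, 0.061))), c(1, 2))
  expect_equal(retain_components(fake(rep(1, 9))), 1:9)
  expect_equal(retain_components(fake(c(8.9, 0.05, 0.05))), 1L)
})

test_that("Norm scores equal the eigenvalue-weighted squared loadings", {
  ns <- norm_scores(published_pca(), 1:2)
  cl <- setNames(ns$comprehensive_load, ns$indicator)
  expect_equal(unname(round(cl[c("SOM", "AN", "BD")], 3)),
               c(4.520, 3.691, 2.392))
  expect_equal(ns$norm, sqrt(ns$comprehensive_load))

  single <- structure(list(eigenvalues = 1,
                           loadings = matrix(1, 1, 1,
                                             dimnames = list("x", "PC1")),
                           p = 1), class = "pca_result")
  ns1 <- norm_scores(single, 1)
  expect_equal(ns1$comprehensive_load, 1)
  expect_equal(ns1$norm, 1)
})

test_that("grouping follows the loading-cutoff and cross-loading rules", {
  pca <- published_pca()
  R <- load_fixture("correlations")
  gr <- group_indicators(pca, 1:2, R, 0.6)
  expect_equal(unname(gr$assignment["pH"]), 1L)
  expect_equal(unname(gr$assignment["BD"]), 2L)
  expect_true(all(gr$assignment[setdiff(INDICATOR_ORDER,
                                        c("pH", "BD"))] == 1L))
  expect_equal(unname(gr$rule["pH"]), "cross_loading_least_correlated")

  # single retained component: everything lands in group 1
  gr1 <- group_indicators(pca, 1, R, 0.6)
  expect_true(all(gr1$assignment == 1L))

  # no high loading anywhere: largest |loading| wins
  lowpca <- structure(list(
    eigenvalues = c(1.2, 1.1),
    loadings = matrix(c(0.3, 0.5), 1, 2,
                      dimnames = list("v", c("PC1", "PC2"))),
    p = 1), class = "pca_result")
  grl <- group_indicators(lowpca, 1:2, matrix(1, 1, 1,
                                              dimnames = list("v", "v")),
                          0.6)
  expect_equal(unname(grl$assignment["v"]), 2L)
})

test_that("MDS selection reproduces the published subset with audit", {
  pca <- published_pca()
  R <- load_fixture("correlations")
  ns <- norm_scores(pca, 1:2)
  gr <- group_indicators(pca, 1:2, R, 0.6)
  sel <- select_mds(pca, R, ns, gr)
  expect_setequal(sel$selected, c("SOM", "pH", "BD"))
  expect_length(sel$selected, 3)
  expect_true(any(grepl("pH -> PC1 (cross_loading", sel$audit,
                        fixed = TRUE)))
  expect_true(any(grepl("keep SOM with pH", sel$audit) |
                  grepl("keep pH with SOM", sel$audit)))

  # determinism including the audit trail
  sel2 <- select_mds(pca, R, ns, gr)
  expect_identical(sel, sel2)
})

test_that("selection is invariant to monotone Norm transforms", {
  pca <- published_pca()
  R <- load_fixture("correlations")
  ns <- norm_scores(pca, 1:2)
  gr <- group_indicators(pca, 1:2, R, 0.6)
  base <- select_mds(pca, R, ns, gr)$selected
  # replacing the comprehensive load by its square root (the Norm value)
  # preserves the ranking, hence the selection
  ns_sqrt <- ns
  ns_sqrt$comprehensive_load <- sqrt(ns$comprehensive_load)
  expect_equal(select_mds(pca, R, ns_sqrt, gr)$selected, base)
})

test_that("selection is invariant to indicator sign flips", {
  s <- generate_samples(synthetic_config(n_per_plot = 10, seed = 5))
  m <- standardize(s)
  base <- select_from_matrix(m)$selected
  for (j in c("SOM", "pH", "AK")) {
    flipped <- m
    flipped[, j] <- -flipped[, j]
    expect_equal(select_from_matrix(flipped)$selected, base,
                 label = paste("flip", j))
  }
})

test_that("one indicator per group passes selection unfiltered", {
  R <- diag(3)
  dimnames(R) <- list(c("a", "b", "c"), c("a", "b", "c"))
  U <- matrix(c(0.9, 0.1, 0.1,
                0.1, 0.9, 0.1,
                0.1, 0.1, 0.9), 3, 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), paste0("PC", 1:3)))
  pca <- structure(list(eigenvalues = c(1.2, 1.1, 0.7),
                        loadings = U, p = 3), class = "pca_result")
  ns <- norm_scores(pca, 1:3)
  gr <- group_indicators(pca, 1:3, R, 0.6)
  sel <- select_mds(pca, R, ns, gr)
  expect_setequal(sel$selected, c("a", "b", "c"))
})
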