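test_that("weighted-additive index is the weight/membership dot product", {
  mem <- load_fixture("memberships")
  com <- load_fixture("communalities")
  tds_w <- weights_from_communalities(
    setNames(com$tds_communality, com$indicator), label = "TDS")

  all_one <- mem
  for (j in setdiff(names(mem), c("plot_id", "sample_id"))) all_one[[j]] <- 1
  r1 <- wdsqi_weighted_additive(all_one, tds_w)
  expect_equal(r1$per_sample$sqi, rep(1, 25))

  # constant memberships with the published (rounded) MDS weights: the
  # rounded weights sum to 0.999, so 0.5 * 0.999 = 0.4995
  mds_printed <- data.frame(indicator = c("pH", "SOM", "BD"),
                            communality = c(0.702, 0.826, 0.540),
                            weight = c(0.339, 0.399, 0.261))
  attr(mds_printed, "set") <- "MDS"
  class(mds_printed) <- c("weight_vector", "data.frame")
  half <- mem
  for (j in c("pH", "SOM", "BD")) half[[j]] <- 0.5
  r2 <- wdsqi_weighted_additive(half, mds_printed)
  expect_equal(r2$per_sample$sqi, rep(0.4995, 25))

  # published No.1 plot-mean memberships under published TDS weights
  pm1 <- data.frame(plot_id = "No.1", sample_id = "mean",
                    pH = 0.28, SOM = 0.85, AN = 0.80, AP = 0.78,
                    AK = 0.98, TN = 0.91, TP = 0.78, SMC = 0.78,
                    BD = 0.73)
  printed_w <- data.frame(
    indicator = c("pH", "SOM", "AP", "AN", "AK", "BD", "SMC", "TP", "TN"),
    weight = c(0.101, 0.138, 0.122, 0.093, 0.125, 0.118, 0.090, 0.094,
               0.118))
  class(printed_w) <- c("weight_vector", "data.frame")
  attr(printed_w, "set") <- "TDS"
  r3 <- wdsqi_weighted_additive(pm1, printed_w)
  expect_equal(r3$per_sample$sqi, 0.77468, tolerance = 1e-9)

  bad_w <- printed_w
  bad_w$weight <- bad_w$weight * 2
  expect_error(wdsqi_weighted_additive(pm1, bad_w),
               class = "mdsqi_config_error")
  expect_error(wdsqi_weighted_additive(pm1[, 1:5], printed_w),
               class = "mdsqi_config_error")
})

test_that("improved Nemerow index matches direct evaluation and bounds", {
  expect_equal(nemerow_improved(rep(1, 9)), 8 / 9)
  expect_equal(nemerow_improved(rep(0.1, 9)), 0.1 * 8 / 9)
  f11 <- c(0.24, 1, 1, 1, 1, 1, 1, 0.27, 0.71)
  expect_equal(nemerow_improved(f11), 0.5263, tolerance = 1e-4)
  expect_error(nemerow_improved(numeric(0)),
               class = "mdsqi_validation_error")
  expect_error(nemerow_improved(0.5), class = "mdsqi_validation_error")

  set.seed(13)
  for (i in 1:25) {
    n <- sample(2:12, 1)
    f <- runif(n, 0.1, 1)
    v <- nemerow_improved(f)
    expect_gte(v, 0.1 * (n - 1) / n)
    expect_lte(v, (n - 1) / n)
    # pessimism: never above the scaled mean, equal iff min == mean
    expect_lte(v, mean(f) * (n - 1) / n + 1e-12)
  }
  const <- rep(0.6, 5)
  expect_equal(nemerow_improved(const), 0.6 * 4 / 5)

  # monotonicity: raising one membership never lowers the index
  f <- c(0.3, 0.5, 0.9, 0.2)
  for (i in seq_along(f)) {
    up <- f; up[i] <- up[i] + 0.05
    expect_gte(nemerow_improved(up), nemerow_improved(f))
  }
})

test_that("legacy Nemerow variants agree with their formulas", {
  expect_equal(nemerow_legacy(rep(0.7, 9), "eq4_min"), 0.7 * 8 / 9)
  v <- c(1, 0.1, runif(7, 0.1, 1))
  expect_equal(nemerow_legacy(v, "eq4_min"), nemerow_improved(v))
  expect_equal(nemerow_legacy(c(0.5, 1.0), "eq3_max"),
               sqrt((0.75^2 + 1) / 2))
  expect_equal(nemerow_legacy(c(0.5, 1.0), "eq3_max", literal = TRUE),
               sqrt(0.75 + 1 / 2))
})

test_that("fertility classification uses upper-closed intervals", {
  expect_equal(classify(0.634), "Medium")
  expect_equal(classify(0.85), "Excellent")
  expect_equal(classify(c(0.4, 0.6, 0.7, 0.8)),
               c("Destitute", "Deficient", "Medium", "Good"))
  expect_equal(classify(0.8 + 1e-9), "Excellent")
  expect_equal(classify(0.05), "Destitute")
})

test_that("CV sensitivity bands match the published classification", {
  r <- cv_sensitivity(c(1, 3))
  expect_equal(r$cv, 100 * sqrt(2) / 2, tolerance = 1e-9)  # 70.71%
  expect_equal(r$class, "Moderate sensitivity")
  expect_equal(cv_sensitivity(rep(2, 4))$class, "Insensitive")
  expect_equal(cv_sensitivity(c(9.6, 10.4))$class, "Insensitive")
  expect_error(cv_sensitivity(c(-1, 1)), class = "mdsqi_validation_error")
  expect_error(cv_sensitivity(3), class = "mdsqi_validation_error")
})

test_that("MDS-vs-TDS regression recovers exact linear relations", {
  x <- c(0.1, 0.3, 0.5, 0.7)
  # exact fits make summary.lm warn about perfect residuals; harmless here
  r <- suppressWarnings(validate_mds_vs_tds(x, x))
  expect_equal(r$slope, 1)
  expect_equal(r$intercept, 0)
  expect_equal(r$r_squared, 1)
  r2 <- suppressWarnings(validate_mds_vs_tds(x, 2 * x + 1))
  expect_equal(r2$slope, 2)
  expect_equal(r2$r_squared, 1)
  expect_error(validate_mds_vs_tds(rep(0.5, 4), x),
               class = "mdsqi_degenerate_input")
  expect_error(validate_mds_vs_tds(x[1:2], x[1:2]),
               class = "mdsqi_validation_error")
})

test_that("synthetic study indices correlate across TDS and MDS", {
  s <- generate_samples(synthetic_config(n_per_plot = 5, seed = 1))
  report <- run_pipeline(s)
  expect_gt(report$validation$r_squared, 0.5)
})

test_that("published memberships reproduce the published plot ordering", {
  mem <- load_fixture("memberships")
  want <- c("No.4_lower", "No.1", "No.2", "No.3", "No.4_upper")

  nem <- wdsqin(mem)
  got <- nem$per_plot$plot_id[order(-nem$per_plot$sqi)]
  expect_equal(got, want)
  # the alternative plot-level aggregation preserves the same ordering
  nem2 <- wdsqin(mem, aggregate = "plot_mean_membership")
  expect_equal(nem2$per_plot$plot_id[order(-nem2$per_plot$sqi)], want)

  com <- load_fixture("communalities")
  tds_w <- weights_from_communalities(
    setNames(com$tds_communality, com$indicator), label = "TDS")
  wa <- wdsqi_weighted_additive(mem, tds_w)
  expect_equal(wa$per_plot$plot_id[order(-wa$per_plot$sqi)], want)
})
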