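test_that("one-way ANOVA matches hand-computed sums of squares", {
  g <- list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5))
  a <- anova_oneway(g)
  expect_equal(a$F, 3, tolerance = 1e-10)
  expect_identical(a$df_between, 2)
  expect_identical(a$df_within, 6)
  expect_equal(a$p, stats::pf(3, 2, 6, lower.tail = FALSE), tolerance = 1e-12)
  # identical groups with internal variance: F = 0
  a0 <- anova_oneway(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(a0$F, 0, tolerance = 1e-12)
  # location invariance
  a_shift <- anova_oneway(lapply(g, `+`, 100))
  expect_equal(a_shift$F, a$F, tolerance = 1e-9)
  # degenerate and malformed inputs
  expect_error(anova_oneway(list(c(1, 1), c(1, 1))), "undefined")
  expect_error(anova_oneway(list(c(1, 2))), "two groups")
  expect_error(anova_oneway(list(1, c(1, 2))), "at least two values")
})

test_that("ANOVA agrees with the brute-force decomposition on random data", {
  set.seed(42)
  for (rep in 1:10) {
    k <- sample(2:5, 1)
    groups <- lapply(seq_len(k), function(i)
      stats::rnorm(sample(3:10, 1), mean = stats::runif(1, -2, 2)))
    a <- anova_oneway(groups)
    y <- unlist(groups); gm <- mean(y)
    ni <- lengths(groups); mi <- vapply(groups, mean, numeric(1))
    ssb <- sum(ni * (mi - gm)^2)
    ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1)))
    F_bf <- (ssb / (k - 1)) / (ssw / (length(y) - k))
    expect_equal(a$F, F_bf, tolerance = 1e-10)
  }
})

test_that("Tukey HSD reduces to the t-test and matches ptukey", {
  set.seed(7)
  g2 <- list(a = stats::rnorm(8), b = stats::rnorm(8, 0.5))
  th <- tukey_hsd(g2)
  tt <- stats::t.test(g2$b, g2$a, var.equal = TRUE)
  expect_equal(th$p_adjusted, tt$p.value, tolerance = 1e-6)
  expect_equal(th$difference, mean(g2$b) - mean(g2$a), tolerance = 1e-12)
  # identical groups: adjusted p = 1
  gi <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  expect_true(all(tukey_hsd(gi)$p_adjusted > 1 - 1e-8))
  # adjusted p from the studentized range distribution, computed directly
  g3 <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5))
  th3 <- tukey_hsd(g3)
  msw <- mean(vapply(g3, stats::var, numeric(1)))
  q_obs <- abs(c(1, 2, 1)) / sqrt(msw / 3)     # pairwise mean differences
  p_ref <- stats::ptukey(q_obs, nmeans = 3, df = 6, lower.tail = FALSE)
  expect_equal(sort(th3$p_adjusted), sort(p_ref), tolerance = 1e-4)
  # adjusted p never below the unadjusted pairwise t-test p
  for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    pt <- stats::t.test(g3[[pair[1]]], g3[[pair[2]]], var.equal = TRUE)$p.value
    row <- grepl(pair[1], th3$pair) & grepl(pair[2], th3$pair)
    expect_gte(th3$p_adjusted[row] + 1e-12, pt)
  }
})

test_that("Shapiro-Wilk wrapper is calibrated and rejects degenerate input", {
  expect_error(test_normality(c(1, 1, 1, 1)), "constant")
  expect_error(test_normality(c(1, 2)), "3 <= n")
  # power sanity: strongly bimodal sample
  set.seed(11)
  bim <- c(stats::rnorm(25, 0, 0.05), stats::rnorm(25, 10, 0.05))
  expect_lt(test_normality(bim)$p, 0.01)
  # null calibration: p-values uniform over repeated normal samples
  set.seed(12)
  ps <- vapply(1:200, function(i) test_normality(stats::rnorm(50))$p, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("summary tables are complete, permutation-invariant and exact", {
  set.seed(3)
  grid <- expand.grid(knee_id = 1:4, model_type = c("sample_fea", "ssam_fea"),
                      varus_level = c(0, 50, 100),
                      compartment = c("medial", "lateral"),
                      stringsAsFactors = FALSE)
  grid$peak_pressure <- stats::runif(nrow(grid), 1, 3)
  grid$contact_area <- stats::runif(nrow(grid), 4, 9)
  t1 <- make_summary_tables(grid)
  t2 <- make_summary_tables(grid[sample(nrow(grid)), ])
  expect_equal(t1, t2)
  # delta = rounded mean difference to the neutral level, exactly
  pt <- t1$pressure_table
  m50 <- pt$mean_rounded[pt$model_type == "sample_fea" &
                           pt$varus_level == 50 & pt$compartment == "medial"]
  m0 <- pt$mean_rounded[pt$model_type == "sample_fea" &
                          pt$varus_level == 0 & pt$compartment == "medial"]
  d <- t1$delta_table
  expect_identical(d$delta[d$outcome == "peak_pressure" &
                             d$model_type == "sample_fea" &
                             d$compartment == "medial" & d$varus_level == 50],
                   m50 - m0)
  # missing cells are named in the error
  expect_error(make_summary_tables(grid[grid$varus_level != 50 |
                                          grid$model_type != "ssam_fea", ]),
               "ssam_fea 50")
  expect_error(study_record(1, "sample_fea", 30, "medial", 1, 1), "varus_level")
  expect_error(study_record(1, "sample_fea", 0, "medial", -1, 1), "finite")
})
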