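test_that("Welch from raw vectors equals Welch from exact summaries and base t.test", {
  withr::with_seed(31, {
    x <- rnorm(16, 1.1, 0.6)
    y <- rnorm(36, 0.55, 0.6)
  })
  from_vec <- welch_t(x, y)
  from_sum <- welch_t(mean(x), sd(x), 16, mean(y), sd(y), 36)
  expect_equal(from_vec, from_sum, tolerance = 1e-14)
  tt <- t.test(x, y, var.equal = FALSE)
  expect_equal(from_vec$statistic, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(from_vec$df, unname(tt$parameter), tolerance = 1e-12)
  expect_equal(from_vec$p, tt$p.value, tolerance = 1e-12)
})

test_that("Welch edge cases: equal means, degenerate variance, tiny groups", {
  eq <- welch_t(5, 1, 10, 5, 2, 12)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p, 1)
  expect_error(welch_t(1, 0, 10, 2, 0, 10), class = "dvr_degenerate_variance")
  expect_error(welch_t(1, 1, 1, 2, 1, 10), class = "dvr_bad_n")
})

test_that("two-sided p-values agree with adaptive-quadrature CDF evaluation", {
  cases <- list(c(1.1546, 0.6461, 16, 0.5449, 0.6031, 36),
                c(0.5950, 0.0283, 16, 0.5772, 0.0327, 36),
                c(12.0, 2.5298, 16, 9.4444, 2.3354, 36))
  for (cs in cases) {
    r <- welch_t(cs[1], cs[2], cs[3], cs[4], cs[5], cs[6])
    quad <- 2 * stats::integrate(function(t) stats::dt(t, df = r$df),
                                 abs(r$statistic), Inf,
                                 rel.tol = 1e-12)$value
    expect_equal(r$p, quad, tolerance = 1e-8)
  }
})

test_that("2x2 chi-square matches the closed-form statistic and handles degeneracy", {
  r <- chi2_2x2(9, 7, 14, 22)
  a <- 9; b <- 7; c <- 14; d <- 22; n <- a + b + c + d
  closed <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  expect_equal(r$statistic, closed, tolerance = 1e-12)
  expect_equal(r$p, stats::pchisq(closed, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  # proportional rows: no association
  prop <- chi2_2x2(10, 20, 5, 10)
  expect_equal(prop$statistic, 0)
  expect_equal(prop$p, 1)
  expect_error(chi2_2x2(0, 0, 5, 10), class = "dvr_zero_margin")
  expect_error(chi2_2x2(1.5, 2, 3, 4), class = "dvr_bad_counts")
})

test_that("covariate adjustment is orthogonal to covariates and anchors the control mean", {
  co <- generate_cohort(cohort_spec(), seed = 41)
  adj <- covariate_adjust(co, "DVR")
  is_cs <- co$group == "CS"
  # control-group mean preserved by construction
  expect_equal(mean(adj[is_cs]), mean(co$DVR[is_cs]), tolerance = 1e-10)
  # adjusted values are residuals plus a constant, so their centered dot
  # product with every covariate must vanish
  for (cv in c("age", "gender", "education")) {
    x <- co[[cv]] - mean(co[[cv]])
    rel <- abs(sum(x * (adj - mean(adj)))) /
      (sqrt(sum(x^2)) * sqrt(sum((adj - mean(adj))^2)))
    expect_lt(rel, 1e-8)
  }
  expect_error(covariate_adjust(co, "DVR", covariates = c("age", "age2")),
               class = "dvr_bad_table")
  co$age2 <- co$age * 2
  expect_error(covariate_adjust(co, "DVR", covariates = c("age", "age2")),
               class = "dvr_collinear")
})

test_that("adjustment with unrelated covariates is a pure recentering at large n", {
  sp <- cohort_spec(n_cs = 1000, n_mp = 1000)
  co <- generate_cohort(sp, seed = 42)
  adj <- covariate_adjust(co, "DVR")
  diffs <- adj - co$DVR
  expect_lt(sd(diffs) / sd(co$DVR), 0.1)
})

test_that("a constructed age confound is removed by adjustment", {
  withr::with_seed(43, {
    n <- 400
    group <- rep(c("CS", "MP"), each = n / 2)
    age <- rnorm(n, 65, 7)
    signal <- ifelse(group == "CS", 1, 0.4)
    d <- tibble::tibble(
      group = group, age = age,
      gender = stats::rbinom(n, 1, 0.5),
      education = rnorm(n, 16, 2),
      marker = signal + 0.1 * age + rnorm(n, sd = 0.3))
  })
  adj <- covariate_adjust(d, "marker")
  gap <- mean(adj[d$group == "CS"]) - mean(adj[d$group == "MP"])
  expect_equal(gap, 0.6, tolerance = 0.12)
})

test_that("Pearson test honours its identities and sampling behaviour", {
  withr::with_seed(44, x <- rnorm(30))
  expect_equal(pearson(x, x)$estimate, 1)
  expect_equal(pearson(x, -x)$estimate, -1)
  expect_error(pearson(x, rep(1, 30)), class = "dvr_degenerate_variance")
  expect_error(pearson(x[1:3], x[1:3]), class = "dvr_too_few_cases")
  # population r = 0.6107 at n = 1000
  withr::with_seed(45, {
    z <- MASS::mvrnorm(1000, c(0, 0),
                       matrix(c(1, 0.6107, 0.6107, 1), 2))
  })
  r <- pearson(z[, 1], z[, 2])
  expect_lt(abs(r$estimate - 0.6107), 0.05)
  expect_lt(r$p, 0.001)
  # pairwise-complete n reported
  z[1:10, 1] <- NA
  expect_equal(pearson(z[, 1], z[, 2])$n, 990)
})

test_that("simple regression matches hand computation and recovers a generating line", {
  r <- simple_regression(c(0, 1, 2, 3), c(1, 3, 5, 7))
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 1)
  expect_equal(r$r_squared, 1)
  # 5-point hand oracle: slope = cov/var computed directly
  x <- c(1, 2, 4, 5, 7); y <- c(2.1, 2.9, 5.2, 5.8, 8.1)
  hand_slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  hand_int <- mean(y) - hand_slope * mean(x)
  h <- simple_regression(x, y)
  expect_equal(h$slope, hand_slope, tolerance = 1e-12)
  expect_equal(h$intercept, hand_int, tolerance = 1e-12)
  expect_error(simple_regression(rep(1, 5), y), class = "dvr_degenerate_variance")
  # generated relation FA = 0.025 * DVR + 0.564 (the generator's default
  # DVR-FA regression target) is recovered within its standard error
  tg <- default_regression_targets()
  sl <- tg$slope[tg$response == "FA"]; ic <- tg$intercept[tg$response == "FA"]
  withr::with_seed(46, {
    dvr <- rnorm(4000, 0.8, 0.65)
    fa <- sl * dvr + ic + rnorm(4000, sd = 0.02)
  })
  fit <- simple_regression(dvr, fa)
  expect_lt(abs(fit$slope - sl), 0.002)
  expect_lt(abs(fit$intercept - ic), 0.005)
})

test_that("the group table reports both adjusted and unadjusted comparisons", {
  co <- generate_cohort(cohort_spec(), seed = 47)
  gt <- group_table(co)
  expect_equal(nrow(gt), 11)
  expect_true(all(c("p_before", "p_after", "sig_before", "sig_after")
                  %in% names(gt)))
  # control means preserved by the adjustment (column equality)
  expect_equal(gt$mean_cs, gt$mean_cs_adj, tolerance = 1e-10)
  expect_true(all(gt$p_before >= 0 & gt$p_before <= 1))
  # a variable entirely missing in one group is excluded with a warning
  co$extra <- ifelse(co$group == "CS", NA_real_, 1.0)
  expect_warning(gt2 <- group_table(co), class = "dvr_variable_excluded")
  expect_false("extra" %in% gt2$variable)
  # single subject in a group is a precondition error
  expect_error(group_table(co[c(1, 17:52), ]), class = "dvr_bad_n")
})

test_that("group separation at the default targets yields mostly p < 0.01 calls", {
  counts <- vapply(1:20, function(s) {
    gt <- group_table(generate_cohort(cohort_spec(), seed = 1000 + s))
    sum(gt$p_before < 0.01)
  }, numeric(1))
  # the default effect sizes put roughly half the 11 markers below 0.01;
  # allow generous Monte-Carlo spread around that expectation
  expect_gte(median(counts), 4)
  expect_lte(median(counts), 9)
})

test_that("the correlation matrix is symmetric, robust per cell, and null p-values are uniform", {
  co <- generate_cohort(cohort_spec(), seed = 48)
  co$DVR_copy <- co$DVR
  cm <- correlation_matrix(co, variables = c("DVR", "DVR_copy", "FA", "MD"))
  expect_equal(cm$r["DVR", "DVR_copy"], 1)
  expect_equal(cm$r, t(cm$r))
  expect_true(all(diag(cm$r) == 1))
  # a constant column degrades only its own cells
  co$flat <- 1
  cm2 <- correlation_matrix(co, variables = c("DVR", "FA", "flat"))
  expect_true(is.na(cm2$r["DVR", "flat"]))
  expect_false(is.na(cm2$r["DVR", "FA"]))
  td <- tidy(cm)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 6)

  # permutation-null p-values are uniform (KS at the 1% level)
  withr::with_seed(49, x <- rnorm(40))
  pvals <- vapply(1:200, function(s) {
    withr::with_seed(500 + s, y <- sample(x))
    pearson(x, y)$p
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})
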