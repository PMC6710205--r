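test_that("zeroth-order basis matches its closed form and alpha = 0 gives shifted impulses", {
  for (alpha in c(0, 0.2, 0.5, 0.8)) {
    b <- laguerre_basis(alpha, L = 1, M = 80)
    expect_equal(b$values[1, ], sqrt(1 - alpha^2) * alpha^(0:79),
                 tolerance = 1e-14)
    expect_equal(sum(b$values[1, ]^2), 1, tolerance = 1e-10)
  }
  b0 <- laguerre_basis(0, L = 4, M = 10)
  expect_equal(b0$values, diag(10)[1:4, ])
  expect_error(laguerre_basis(1, 2, 10), class = "dvr_bad_alpha")
  expect_error(laguerre_basis(-0.1, 2, 10), class = "dvr_bad_alpha")
})

test_that("basis rows are orthonormal by direct summation, with error shrinking in M", {
  b <- laguerre_basis(0.5, L = 5, M = 200)
  gram <- tcrossprod(b$values)
  expect_lt(max(abs(gram - diag(5))), 1e-8)
  err_m <- vapply(c(20, 60, 200), function(M) {
    g <- tcrossprod(laguerre_basis(0.7, 4, M)$values)
    max(abs(g - diag(4)))
  }, numeric(1))
  expect_true(all(diff(err_m) < 0))
})

test_that("regressor construction matches impulse sifting, constants and the double-loop oracle", {
  b <- laguerre_basis(0.4, L = 3, M = 20)
  imp <- c(1, rep(0, 59))
  V <- convolve_basis(imp, b)
  # impulse sifting: past the burn-in, column j reads back b_j(n) (zero
  # beyond the memory)
  expect_equal(V[20, ], b$values[, 20], ignore_attr = TRUE)
  expect_true(all(V[21:60, ] == 0))

  b0 <- laguerre_basis(0, L = 1, M = 5)
  V0 <- convolve_basis(rep(3, 30), b0)
  expect_true(all(V0[5:30, 1] == 3))

  withr::with_seed(1, x <- rnorm(80))
  V1 <- convolve_basis(x, b)
  V2 <- brute_regressor(x, b$values)
  expect_lt(max(abs(V1[20:80, ] - V2[20:80, ])), 1e-12)
  expect_true(all(is.na(V1[1:19, ])))
  expect_error(convolve_basis(rnorm(10), b), class = "dvr_series_too_short")
})

test_that("noise-free data from a matching-structure system is recovered exactly", {
  for (seed in 1:5) {
    sys <- random_sys(seed)
    u <- simulate_subject(sys, duration_s = 330, noise_sd = 0, seed = seed + 100)
    fit <- fit_two_input_model(u, sys$basis_p, sys$basis_c)
    expect_lt(max(abs(fit$a_p - sys$coeff_p)), 1e-6)
    expect_lt(max(abs(fit$a_c - sys$coeff_c)), 1e-6)
    expect_lt(fit$fit_nmse, 1e-10)
  }
})

test_that("duplicate input channels are rejected as rank-deficient unless ridged", {
  sys <- random_sys(3)
  u <- simulate_subject(sys, 330, noise_sd = 0.1, seed = 9)
  u2 <- u
  u2$etco2 <- u2$abp  # collinear branches
  b <- laguerre_basis(0.5, 3, 50)
  expect_error(fit_two_input_model(u2, b, b, ridge = 0),
               class = "dvr_rank_deficient")
  fit <- fit_two_input_model(u2, b, b, ridge = 1e-6)
  expect_s3_class(fit, "two_input_model")
})

test_that("training NMSE is non-decreasing in the ridge penalty", {
  sys <- random_sys(4)
  u <- simulate_subject(sys, 330, noise_frac = 0.1, seed = 12)
  b <- laguerre_basis(0.5, 3, 50)
  nmse <- vapply(c(0, 1e-4, 1e-2, 1, 100),
                 function(l) fit_two_input_model(u, b, b, ridge = l)$fit_nmse,
                 numeric(1))
  expect_true(all(diff(nmse) >= -1e-12))
})

test_that("output unrelated to the inputs yields NMSE near 1 and near-zero kernels", {
  withr::with_seed(21, {
    n <- 3000
    u <- uniform_series(abp = rnorm(n), etco2 = rnorm(n), cbfv = rnorm(n),
                        dt = 1)
  })
  b <- laguerre_basis(0.5, 3, 50)
  fit <- fit_two_input_model(u, b, b)
  expect_gt(fit$fit_nmse, 0.95)
  expect_lt(max(abs(c(fit$a_p, fit$a_c))), 0.1)
})

test_that("kernel reconstruction matches direct basis expansion", {
  b <- laguerre_basis(0.6, 4, 50)
  sys <- true_model(alpha_p = 0.6, alpha_c = 0.6,
                    coeff_p = c(1, 0, 0, 0), coeff_c = rep(0, 4), M = 50)
  expect_equal(kernel_of(sys, "abp")$kernel, b$values[1, ],
               tolerance = 1e-14)
  expect_true(all(kernel_of(sys, "etco2")$kernel == 0))
  withr::with_seed(5, a <- rnorm(4))
  sys2 <- true_model(alpha_p = 0.6, alpha_c = 0.6, coeff_p = a,
                     coeff_c = a, M = 50)
  direct <- colSums(a * b$values)  # sum_j a_j b_j(m) by direct summation
  expect_equal(kernel_of(sys2, "abp")$kernel, direct, tolerance = 1e-12)
  expect_error(kernel_of(sys2, "pressure"), class = "dvr_bad_branch")
})

test_that("prediction agrees with the regressor-times-coefficients path and is linear", {
  sys <- random_sys(6)
  u <- simulate_subject(sys, 330, noise_frac = 0.1, seed = 13)
  fit <- fit_two_input_model(u, sys$basis_p, sys$basis_c)
  pred <- predict(fit, newdata = u)
  # reproduces its own training NMSE by definition
  expect_equal(attr(pred, "nmse"), fit$fit_nmse, tolerance = 1e-12)
  # equivalence with explicit regressor algebra
  Vp <- convolve_basis(u$abp, fit$basis_p)
  Vc <- convolve_basis(u$etco2, fit$basis_c)
  manual <- fit$intercept + drop(Vp %*% fit$a_p) + drop(Vc %*% fit$a_c)
  ok <- !is.na(manual)
  expect_lt(max(abs(pred$prediction[ok] - manual[ok])), 1e-12)
  # zero inputs -> intercept everywhere past the burn-in
  z <- rep(0, 200)
  pz <- predict(fit, abp = z, etco2 = z)$prediction
  expect_true(all(pz[50:200] == fit$intercept))
  # additivity and homogeneity
  p1 <- predict(fit, abp = u$abp, etco2 = rep(0, nrow(u)))$prediction
  p2 <- predict(fit, abp = rep(0, nrow(u)), etco2 = u$etco2)$prediction
  p12 <- predict(fit, abp = u$abp, etco2 = u$etco2)$prediction
  expect_equal(p12[ok], (p1 + p2 - fit$intercept)[ok], tolerance = 1e-10)
  p3 <- predict(fit, abp = 3 * u$abp, etco2 = 3 * u$etco2)$prediction
  expect_equal((p3 - fit$intercept)[ok], 3 * (p12 - fit$intercept)[ok],
               tolerance = 1e-9)
  expect_error(predict(fit, abp = z, etco2 = z[-1]),
               class = "dvr_length_mismatch")
})

test_that("structure search recovers the generating structure and honours tie-breaks", {
  sys <- random_sys(7)  # alpha 0.5, L 3 per branch
  u <- simulate_subject(sys, 400, noise_sd = 0, seed = 14)
  sel <- select_structure(u, alpha_grid = c(0.3, 0.5, 0.7), L_grid = c(2, 3),
                          M = 50)
  g <- glance(sel)
  expect_equal(c(g$alpha_p, g$L_p, g$alpha_c, g$L_c), c(0.5, 3, 0.5, 3))

  single <- select_structure(u, alpha_grid = 0.4, L_grid = 2, M = 50)
  gs <- glance(single)
  expect_equal(c(gs$alpha_p, gs$L_p, gs$alpha_c, gs$L_c), c(0.4, 2, 0.4, 2))
})

test_that("pure-noise output biases structure search toward smaller orders", {
  picks <- vapply(1:12, function(s) {
    withr::with_seed(s, {
      n <- 500
      u <- uniform_series(abp = rnorm(n), etco2 = rnorm(n),
                          cbfv = rnorm(n), dt = 1)
    })
    sel <- select_structure(u, alpha_grid = 0.5, L_grid = c(1, 3, 5), M = 30)
    g <- glance(sel)
    g$L_p + g$L_c
  }, numeric(1))
  # with nothing to model, validation NMSE penalises extra coefficients, so
  # selected total order must fall below the uniform-choice mean (6)
  expect_lt(mean(picks), 6)
})
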