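make_toy <- function(seed = 61, n_subj = 24, noise_sd = 0.5, slope = 2,
                     frac = c(`1` = 1, `2` = 0.5, `3` = 0)) {
  lab <- toy_label_volume(c(12, 12, 6), 3)
  withr::with_seed(seed, dvr <- rnorm(n_subj, 0.8, 0.6))
  ds <- generate_voxel_dataset(dvr, lab, frac_assoc = frac, slope = slope,
                               noise_sd = noise_sd, seed = seed + 1)
  list(lab = lab, dvr = dvr, ds = ds)
}

test_that("the r map equals per-voxel Pearson calls exactly", {
  toy <- make_toy()
  cm <- voxel_corr_map(toy$ds)
  idx <- which(toy$ds$mask & !is.na(cm$r))
  check <- withr::with_seed(60, sample(idx, 40))
  for (v in check) {
    coords <- arrayInd(v, dim(toy$ds$mask))
    vals <- toy$ds$volumes[coords[1], coords[2], coords[3], ]
    ref <- pearson(vals, toy$ds$dvr)
    expect_equal(cm$r[v], ref$estimate, tolerance = 1e-12)
    expect_equal(cm$p[v], ref$p, tolerance = 1e-12)
  }
})

test_that("degenerate and mismatched voxel inputs are refused or excluded", {
  toy <- make_toy()
  expect_error(voxel_corr_map(toy$dvr[1:5], toy$ds$volumes),
               class = "dvr_length_mismatch")
  # volumes identical across subjects: every voxel excluded
  const <- toy$ds$volumes
  for (s in seq_len(dim(const)[4])) const[, , , s] <- const[, , , 1]
  cm <- voxel_corr_map(toy$dvr, const, toy$ds$mask)
  expect_true(all(is.na(cm$r[toy$ds$mask])))
  expect_equal(cm$n_excluded, sum(toy$ds$mask))
})

test_that("significance masks behave under trivial, null and FDR regimes", {
  toy <- make_toy()
  cm <- voxel_corr_map(toy$ds)
  # all p = 1 -> empty mask
  ones <- cm$p
  ones[!is.na(ones)] <- 1
  expect_equal(sum(significant_mask(ones, 0.05)), 0)
  expect_error(significant_mask(array(NA_real_, c(2, 2, 2))),
               class = "dvr_empty_map")

  # null generator: uncorrected significant fraction near alpha
  lab1 <- array(1L, c(20, 20, 10))
  withr::with_seed(62, dvr <- rnorm(20))
  null_ds <- generate_voxel_dataset(dvr, lab1, frac_assoc = 0, seed = 63)
  null_p <- voxel_corr_map(null_ds)$p
  frac <- mean(significant_mask(null_p, 0.05)[null_ds$mask])
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)

  # BH-FDR on a half-true map controls the empirical false-discovery rate
  fdrs <- vapply(1:5, function(s) {
    t2 <- make_toy(seed = 70 + s, noise_sd = 0.8,
                   frac = c(`1` = 0.5, `2` = 0.5, `3` = 0.5))
    m <- significant_mask(voxel_corr_map(t2$ds), 0.05, "bh_fdr")
    n_sig <- sum(m)
    if (n_sig == 0) return(0)
    sum(m & !t2$ds$truth) / n_sig
  }, numeric(1))
  expect_lt(mean(fdrs), 0.05 + 0.03)
  m <- significant_mask(cm, 0.05, "bh_fdr")
  expect_identical(attr(m, "method"), "bh_fdr")
})

test_that("region tables match hand counts, tile the mask, and flag >30% regions", {
  lab <- toy_label_volume(c(6, 2, 1), 3)  # regions of 4 voxels each
  mask <- array(FALSE, c(6, 2, 1))
  mask[1, 1, 1] <- TRUE; mask[1, 2, 1] <- TRUE   # 2 of 4 in region 1
  mask[3, 1, 1] <- TRUE                          # 1 of 4 in region 2
  rt <- region_table(mask, lab)
  expect_equal(rt$n_significant, c(2, 1, 0, 3))
  expect_equal(rt$pct, c(50, 25, 0, 25))
  expect_equal(rt$highlight, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(rt$region[4], "Whole mask")
  # counts conservation: labels tile the mask, so regions sum to the total
  expect_equal(sum(rt$n_significant[1:3]), rt$n_significant[4])

  empty <- region_table(array(FALSE, dim(lab)), lab)
  expect_true(all(empty$n_significant == 0))
  expect_true(all(empty$pct == 0))
  full <- region_table(array(TRUE, dim(lab)), lab)
  expect_true(all(full$pct == 100))
  expect_error(
    region_table(mask, lab, region_names = tibble::tibble(label = 1L,
                                                          region = "only one")),
    class = "dvr_unknown_label")
})

test_that("the toy generator's region fractions are recovered at high signal", {
  toy <- make_toy(seed = 80, noise_sd = 0.1, slope = 3)
  m <- significant_mask(voxel_corr_map(toy$ds), 0.05)
  rt <- region_table(m, toy$lab, toy$ds$region_names)
  expect_equal(rt$pct[1], 100, tolerance = 0.02)
  expect_equal(rt$pct[2], 50, tolerance = 0.15)
  expect_lt(rt$pct[3], 10)
})

test_that("subject means over masks reduce correctly and sharpen group contrasts", {
  toy <- make_toy()
  one <- array(FALSE, dim(toy$ds$mask)); one[2, 3, 1] <- TRUE
  expect_equal(subject_mean_over_mask(toy$ds$volumes, one),
               toy$ds$volumes[2, 3, 1, ])
  const <- toy$ds$volumes; const[] <- 7
  expect_true(all(subject_mean_over_mask(const, toy$ds$mask) == 7))
  expect_error(subject_mean_over_mask(toy$ds$volumes,
                                      array(FALSE, dim(toy$ds$mask))),
               class = "dvr_empty_mask")

  # metric shifted between groups only inside associated voxels: restricting
  # to the recovered significant mask strengthens the Welch contrast
  wins <- vapply(1:7, function(s) {
    lab <- toy_label_volume(c(10, 10, 5), 2)
    withr::with_seed(90 + s, {
      group <- rep(c(0, 1), each = 12)
      dvr <- rnorm(24, 0.8, 0.5) - 0.6 * group
    })
    ds <- generate_voxel_dataset(dvr, lab, frac_assoc = c(`1` = 1, `2` = 0),
                                 slope = 1.5, noise_sd = 1.2, seed = 190 + s)
    m <- significant_mask(voxel_corr_map(ds), 0.05)
    if (!any(m)) return(NA)
    masked <- subject_mean_over_mask(ds$volumes, m)
    whole <- subject_mean_over_mask(ds$volumes, ds$mask)
    welch_t(masked[group == 0], masked[group == 1])$p <
      welch_t(whole[group == 0], whole[group == 1])$p
  }, logical(1))
  expect_gt(mean(wins, na.rm = TRUE), 0.5)
})

test_that("outputs are invariant to a common permutation of subjects", {
  toy <- make_toy()
  perm <- withr::with_seed(95, sample(length(toy$dvr)))
  cm1 <- voxel_corr_map(toy$dvr, toy$ds$volumes, toy$ds$mask)
  cm2 <- voxel_corr_map(toy$dvr[perm],
                        toy$ds$volumes[, , , perm, drop = FALSE],
                        toy$ds$mask)
  expect_equal(cm1$r, cm2$r, tolerance = 1e-12)
  expect_equal(cm1$p, cm2$p, tolerance = 1e-12)
})

test_that("recovered masks converge to the ground truth as noise vanishes", {
  # FDR control keeps the false-positive floor shrinking with the noise, so
  # the overlap can actually approach 1 (uncorrected thresholding plateaus
  # at the alpha-level false-positive rate)
  jacc <- vapply(c(8, 2, 0.1), function(ns) {
    toy <- make_toy(seed = 85, noise_sd = ns, slope = 2,
                    frac = c(`1` = 0.6, `2` = 0.4, `3` = 0.2))
    m <- significant_mask(voxel_corr_map(toy$ds), 0.01, "bh_fdr")
    sum(m & toy$ds$truth) / sum(m | toy$ds$truth)
  }, numeric(1))
  expect_true(all(diff(jacc) > 0))
  expect_gt(jacc[3], 0.95)
})

test_that("voxel datasets round-trip through NIfTI plus sidecar", {
  toy <- make_toy(seed = 87, n_subj = 6)
  dir <- withr::local_tempdir()
  paths <- write_voxel_dataset(toy$ds, dir)
  back <- read_voxel_dataset(paths)
  expect_equal(back$volumes, toy$ds$volumes, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_identical(back$truth, toy$ds$truth)
  expect_equal(back$dvr, toy$ds$dvr, tolerance = 1e-12)
  expect_identical(array(back$labels, dim(toy$lab)), toy$lab)
})
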