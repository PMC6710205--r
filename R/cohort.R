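#' Default marker/score targets for the synthetic cohort
#'
#' Per-group means and SDs of the 11 markers/scores the synthetic cohort
#' generator reproduces by default: the DVR physiomarker, three DTI
#' metrics over significant voxels (FA unitless; MD and RD in
#' 10^-3 mm^2/s), four attention-executive scores (Trails-B, WAIS digit
#' span backward, WCST perseverative responses, letter fluency F+A+S) and
#' three episodic-memory scores (CVLT long-delay free recall, CVLT total,
#' visual reproduction t-score). The values emulate a published
#' MCI-versus-control cohort of 16 controls and 36 patients.
#'
#' @return A tibble with columns `marker`, `mean_cs`, `sd_cs`, `mean_mp`,
#'   `sd_mp`.
#' @export
default_marker_targets <- function() {
  tibble::tribble(
    ~marker,      ~mean_cs, ~sd_cs,  ~mean_mp, ~sd_mp,
    "DVR",        1.1546,   0.6461,  0.5449,   0.6031,
    "FA",         0.5950,   0.0283,  0.5772,   0.0327,
    "MD",         0.7190,   0.0219,  0.7420,   0.0279,
    "RD",         0.4630,   0.0263,  0.4880,   0.0316,
    "TrailsB",    56.9375,  15.0575, 77.1389,  30.9222,
    "WAISdig",    7.3125,   1.8154,  5.7500,   1.9030,
    "WCSTper",    55.3125,  11.9372, 55.7941,  22.9502,
    "LF_FAS",     39.6875,  7.5694,  36.3056,  11.2016,
    "CVLT_LDFR",  12.0000,  2.5298,  9.4444,   2.3354,
    "CVLT_total", 53.3750,  10.0391, 45.2778,  11.2596,
    "VRT",        51.0000,  15.8661, 41.9714,  15.5137)
}

#' Default inter-marker correlation targets
#'
#' Target pairwise Pearson correlation matrix among the 11 markers/scores
#' (same emulated cohort as [default_marker_targets()]); used as the
#' Gaussian-copula correlation of the synthetic cohort. Notable entries:
#' DVR correlates ~0.61 with FA and ~-0.6 with MD/RD.
#'
#' @return An 11 x 11 symmetric correlation matrix (positive definite).
#' @export
default_marker_correlations <- function() {
  v <- default_marker_targets()$marker
  R <- diag(length(v))
  dimnames(R) <- list(v, v)
  lower <- list(
    FA         = c(DVR = 0.6107),
    MD         = c(DVR = -0.6197, FA = -0.6545),
    RD         = c(DVR = -0.6045, FA = -0.8188, MD = 0.8744),
    TrailsB    = c(DVR = -0.2270, FA = -0.4601, MD = 0.5217, RD = 0.5450),
    WAISdig    = c(DVR = 0.2104, FA = 0.1147, MD = -0.1803, RD = -0.1670,
                   TrailsB = -0.3288),
    WCSTper    = c(DVR = 0.0025, FA = -0.0682, MD = 0.1553, RD = 0.0712,
                   TrailsB = 0.2312, WAISdig = -0.2492),
    LF_FAS     = c(DVR = 0.2105, FA = 0.1455, MD = -0.3402, RD = -0.2475,
                   TrailsB = -0.3092, WAISdig = 0.2805, WCSTper = -0.4673),
    CVLT_LDFR  = c(DVR = 0.2826, FA = 0.0629, MD = -0.3605, RD = -0.2302,
                   TrailsB = -0.1536, WAISdig = 0.1540, WCSTper = -0.1971,
                   LF_FAS = 0.2541),
    CVLT_total = c(DVR = 0.1904, FA = -0.0071, MD = -0.3506, RD = -0.1515,
                   TrailsB = -0.2193, WAISdig = 0.2130, WCSTper = -0.1220,
                   LF_FAS = 0.3292, CVLT_LDFR = 0.7265),
    VRT        = c(DVR = -0.0762, FA = 0.0850, MD = -0.0371, RD = -0.0493,
                   TrailsB = -0.2526, WAISdig = 0.3745, WCSTper = -0.0934,
                   LF_FAS = -0.0366, CVLT_LDFR = 0.1831, CVLT_total = 0.0812))
  for (row in names(lower)) {
    for (col in names(lower[[row]])) {
      R[row, col] <- R[col, row] <- lower[[row]][[col]]
    }
  }
  R
}

#' Default DVR-DTI regression-line targets
#'
#' Linear relations between DVR and the DTI metrics (and the CVLT
#' long-delay recall score) that the synthetic generators reproduce by
#' default, as `metric = slope * DVR + intercept` (MD and RD in 10^-3
#' mm^2/s units).
#'
#' @return A tibble with columns `response`, `slope`, `intercept`.
#' @export
default_regression_targets <- function() {
  tibble::tribble(
    ~response,   ~slope, ~intercept,
    "FA",         0.025,  0.564,
    "MD",        -0.022,  0.751,
    "RD",        -0.025,  0.499,
    "CVLT_LDFR",  1.15,   9.338)
}

#' Specification of a synthetic cohort
#'
#' Collects everything [generate_cohort()] needs: group sizes, per-marker
#' group means/SDs, the target inter-marker correlation matrix (Gaussian
#' copula), and covariate distributions. Defaults reproduce the emulated
#' MCI cohort of [default_marker_targets()].
#'
#' @param n_cs,n_mp Numbers of control subjects and patients (`>= 2`).
#' @param markers Tibble like [default_marker_targets()].
#' @param corr Target correlation matrix over `markers$marker` (symmetric,
#'   unit diagonal, positive semi-definite).
#' @param null_effect If `TRUE`, patient means/SDs are set equal to the
#'   control values (no group effect) — used for type-I-error calibration.
#' @param age_mean,age_sd Age distribution, years.
#' @param edu_mean,edu_sd,edu_range Education distribution, years
#'   (truncated normal).
#' @param seed Default seed for [generate_cohort()].
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cs = 16, n_mp = 36,
                        markers = default_marker_targets(),
                        corr = default_marker_correlations(),
                        null_effect = FALSE,
                        age_mean = 65, age_sd = 7,
                        edu_mean = 16, edu_sd = 2, edu_range = c(10, 22),
                        seed = NULL) {
  if (n_cs < 2 || n_mp < 2) dvr_abort("Need n >= 2 per group.", "dvr_bad_n")
  if (any(markers$sd_cs < 0) || any(markers$sd_mp < 0)) {
    dvr_abort("SDs must be >= 0.", "dvr_bad_sd")
  }
  if (isTRUE(null_effect)) {
    markers$mean_mp <- markers$mean_cs
    markers$sd_mp <- markers$sd_cs
  }
  k <- nrow(markers)
  if (!is.matrix(corr) || any(dim(corr) != k) ||
      max(abs(corr - t(corr))) > 1e-8 || max(abs(diag(corr) - 1)) > 1e-8) {
    dvr_abort("`corr` must be symmetric with unit diagonal over the markers.",
              "dvr_bad_corr")
  }
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    dvr_abort(paste0("Correlation target is not positive semi-definite ",
                     "(min eigenvalue ", signif(min(ev), 3), ")."),
              "dvr_not_psd")
  }
  structure(list(n_cs = n_cs, n_mp = n_mp, markers = markers, corr = corr,
                 age_mean = age_mean, age_sd = age_sd,
                 edu_mean = edu_mean, edu_sd = edu_sd, edu_range = edu_range,
                 seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic subject table
#'
#' Draws a cohort with the statistical structure the analysis layer
#' assumes: marker/score vectors from a Gaussian copula with the spec's
#' correlation target, rescaled per group to the requested means and SDs;
#' covariates age ~ Normal, gender ~ Bernoulli(0.5), education ~ truncated
#' Normal, independent of the markers.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed (overrides `spec$seed`); same seed, same
#'   table.
#' @return A tibble of class `subject_table`: columns `id`, `group`
#'   (`"CS"`/`"MP"`), `age`, `gender` (0/1), `education`, then one column
#'   per marker.
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  seed <- seed %||% spec$seed
  with_seed_if(seed, {
    n <- spec$n_cs + spec$n_mp
    group <- rep(c("CS", "MP"), c(spec$n_cs, spec$n_mp))
    k <- nrow(spec$markers)
    Z <- MASS::mvrnorm(n, mu = rep(0, k), Sigma = spec$corr)
    if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1L)
    X <- matrix(NA_real_, n, k, dimnames = list(NULL, spec$markers$marker))
    for (j in seq_len(k)) {
      mj <- ifelse(group == "CS", spec$markers$mean_cs[j],
                   spec$markers$mean_mp[j])
      sj <- ifelse(group == "CS", spec$markers$sd_cs[j],
                   spec$markers$sd_mp[j])
      X[, j] <- mj + sj * Z[, j]
    }
    # truncated-normal education via the probability-integral transform
    p_lo <- stats::pnorm(spec$edu_range[1L], spec$edu_mean, spec$edu_sd)
    p_hi <- stats::pnorm(spec$edu_range[2L], spec$edu_mean, spec$edu_sd)
    edu <- stats::qnorm(stats::runif(n, p_lo, p_hi), spec$edu_mean,
                        spec$edu_sd)
    out <- tibble(
      id = sprintf("S%03d", seq_len(n)),
      group = group,
      age = rnorm(n, spec$age_mean, spec$age_sd),
      gender = stats::rbinom(n, 1L, 0.5),
      education = edu)
    out <- dplyr::bind_cols(out, as_tibble(X))
    structure(out, spec = spec, class = c("subject_table", class(out)))
  })
}
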