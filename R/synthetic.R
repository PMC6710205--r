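#' Ground-truth two-input hemodynamic system
#'
#' Defines a known linear two-input system mapping ABP and ETCO2 deviations
#' to CBFV deviations, with each branch's first-order kernel given as a
#' Laguerre expansion. Used as the generator-side truth against which the
#' model-fitting and DVR pipeline are validated.
#'
#' @param alpha_p,alpha_c Laguerre decay parameters in `[0, 1)` for the ABP
#'   and ETCO2 branches.
#' @param coeff_p,coeff_c Nonempty coefficient vectors (one per basis
#'   function) for the two branches.
#' @param baseline_cbfv,baseline_abp,baseline_etco2 Channel baselines
#'   (cm/s, mmHg, mmHg).
#' @param dt Sampling step of the beat-to-beat grid, seconds (`> 0`).
#' @param M Kernel memory in samples.
#' @return An object of class `true_model`; [kernel_of()] and [true_dvr()]
#'   work on it directly.
#' @examples
#' sys <- true_model(coeff_c = c(0.8, 0.3))
#' true_dvr(sys)
#' @export
true_model <- function(alpha_p = 0.4, alpha_c = 0.5,
                       coeff_p = c(0.6, -0.2, 0.1),
                       coeff_c = c(0.8, 0.3, -0.1),
                       baseline_cbfv = 60, baseline_abp = 90,
                       baseline_etco2 = 40, dt = 1, M = 50L) {
  for (a in c(alpha_p, alpha_c)) {
    if (!is.finite(a) || a < 0 || a >= 1) {
      dvr_abort("Laguerre decays must lie in [0, 1).", "dvr_bad_alpha")
    }
  }
  if (length(coeff_p) < 1L || length(coeff_c) < 1L ||
      !all(is.finite(coeff_p)) || !all(is.finite(coeff_c))) {
    dvr_abort("Coefficient vectors must be nonempty and finite.",
              "dvr_bad_coeff")
  }
  if (dt <= 0) dvr_abort("`dt` must be > 0.", "dvr_bad_dt")
  M <- max(as.integer(M), length(coeff_p), length(coeff_c))
  structure(
    list(alpha_p = alpha_p, alpha_c = alpha_c,
         coeff_p = as.numeric(coeff_p), coeff_c = as.numeric(coeff_c),
         basis_p = laguerre_basis(alpha_p, length(coeff_p), M),
         basis_c = laguerre_basis(alpha_c, length(coeff_c), M),
         a_p = as.numeric(coeff_p), a_c = as.numeric(coeff_c),
         intercept = 0,
         baseline_cbfv = baseline_cbfv, baseline_abp = baseline_abp,
         baseline_etco2 = baseline_etco2, dt = dt, M = M),
    class = c("true_model", "two_input_model"))
}

#' @export
print.true_model <- function(x, ...) {
  cat(sprintf(paste0("<true_model> dt = %g s, M = %d\n",
                     "  ABP kernel:   alpha = %.3g, L = %d\n",
                     "  ETCO2 kernel: alpha = %.3g, L = %d\n",
                     "  closed-form DVR = %.4f per mmHg\n"),
              x$dt, x$M, x$alpha_p, length(x$coeff_p),
              x$alpha_c, length(x$coeff_c), true_dvr(x)))
  invisible(x)
}

# internal: band-limited stationary fluctuation around zero. Second-order
# Butterworth low-pass at `cutoff_hz` keeps the input persistently exciting
# (nonzero energy at all frequencies) while concentrating power in the slow
# vasomotor band.
lowpass_noise <- function(n, sd_target, dt, cutoff_hz = 0.1) {
  w <- min(2 * cutoff_hz * dt, 0.99)  # normalized cutoff (Nyquist = 1)
  bf <- signal::butter(2, w, type = "low")
  pad <- ceiling(10 / max(w, 1e-3))
  x <- signal::filtfilt(bf, rnorm(n + 2L * pad))
  x <- x[(pad + 1L):(pad + n)]
  x <- x - mean(x)
  if (sd(x) > 0) x <- x * sd_target / sd(x)
  x
}

#' Simulate one subject's beat-to-beat record from a known system
#'
#' ABP and ETCO2 deviations are generated as independent band-limited
#' Gaussian fluctuations (low-pass below 0.1 Hz, the resting vasomotor
#' band); CBFV deviations are the sum of the two kernel convolutions plus
#' white observation noise. An initial stretch of one kernel memory is
#' simulated and discarded so the returned record has no convolution
#' transient.
#'
#' @param model A [true_model()].
#' @param duration_s Record length in seconds; must cover at least the
#'   kernel memory.
#' @param noise_sd SD of additive white observation noise on CBFV (cm/s).
#'   Alternatively give `noise_frac`.
#' @param noise_frac If non-`NULL`, sets the noise power as a fraction of
#'   the clean CBFV deviation power (`noise_sd = sqrt(noise_frac) *
#'   sd(clean)`), overriding `noise_sd`.
#' @param abp_sd,etco2_sd SDs of the input fluctuations (mmHg).
#' @param seed Integer seed; identical arguments give bitwise-identical
#'   output. `NULL` uses (and advances) the session RNG.
#' @return A [uniform_series()] with the generating baselines stored;
#'   `attr(, "clean_sd")` is the SD of the noise-free CBFV deviations and
#'   `attr(, "true_model")` the generator.
#' @export
simulate_subject <- function(model, duration_s = 330, noise_sd = 0,
                             noise_frac = NULL, abp_sd = 3, etco2_sd = 1.5,
                             seed = NULL) {
  stopifnot(inherits(model, "true_model"))
  if (noise_sd < 0) dvr_abort("`noise_sd` must be >= 0.", "dvr_bad_noise")
  n <- floor(duration_s / model$dt)
  if (n < model$M) {
    dvr_abort("`duration_s` must cover at least the kernel memory.",
              "dvr_series_too_short")
  }
  with_seed_if(seed, {
    n_ext <- n + model$M  # transient burn, discarded below
    abp <- lowpass_noise(n_ext, abp_sd, model$dt)
    etco2 <- lowpass_noise(n_ext, etco2_sd, model$dt)
    kp <- drop(crossprod(model$basis_p$values, model$coeff_p))
    kc <- drop(crossprod(model$basis_c$values, model$coeff_c))
    clean <- as.numeric(stats::filter(abp, kp, method = "convolution", sides = 1)) +
      as.numeric(stats::filter(etco2, kc, method = "convolution", sides = 1))
    keep <- (model$M + 1L):n_ext
    abp <- abp[keep]; etco2 <- etco2[keep]; clean <- clean[keep]
    clean_sd <- sd(clean)
    if (!is.null(noise_frac)) noise_sd <- sqrt(noise_frac) * clean_sd
    cbfv <- clean + rnorm(n, sd = noise_sd)
    u <- uniform_series(
      abp = abp + model$baseline_abp,
      etco2 = etco2 + model$baseline_etco2,
      cbfv = cbfv + model$baseline_cbfv,
      dt = model$dt)
    attr(u, "clean_sd") <- clean_sd
    attr(u, "noise_sd") <- noise_sd
    attr(u, "true_model") <- model
    u
  })
}

# internal: systolic pulse contour on beat phase tau in [0, 1); centred so
# scaling it never shifts the per-beat mean. The phase average of
# sin^2(pi*tau) exp(-3*tau) is (1 - e^-3)/6 - 3(1 - e^-3)/(2(9 + 4*pi^2)).
pulse_contour <- function(tau) {
  s <- sin(pi * tau)^2 * exp(-3 * tau)
  m <- (1 - exp(-3)) / 6 - 3 * (1 - exp(-3)) / (2 * (9 + 4 * pi^2))
  s - m
}

# internal: capnogram contour — inspiration low, sigmoid rise, flat
# alveolar plateau, sharp fall; returns values in [0, 1] of plateau height
co2_contour <- function(tau) {
  rise <- stats::plogis((tau - 0.40) / 0.03)
  fall <- stats::plogis((0.96 - tau) / 0.008)
  pmin(rise, fall)
}

#' Simulate raw multichannel waveforms with ground-truth events
#'
#' Generates pulsatile ABP and CBFV waveforms and a breath-wise CO2
#' (capnogram) waveform at sampling rate `fs`, around beat-to-beat means
#' driven by a [true_model()]. Beats repeat a systolic/diastolic contour
#' whose per-beat mean follows slow ABP fluctuations; CBFV is the pulsatile
#' analog of the model-predicted flow; the CO2 channel rises to an
#' end-tidal plateau once per breath. Ground-truth beat onsets and
#' end-tidal sample times are returned for validating the preprocessing
#' stage.
#'
#' @param model A [true_model()].
#' @param heart_rate_bpm,resp_rate_bpm Heart and breathing rates
#'   (physiological ranges 30–180 and 6–30 bpm are enforced).
#' @param fs Sampling rate in Hz, at least 50 (beats are unresolvable
#'   below that).
#' @param duration_s Record length in seconds.
#' @param pulse_mmhg,pulse_cms Peak-to-trough amplitudes of the ABP and
#'   CBFV pulsatile contours.
#' @param seed Integer seed for the slow fluctuations.
#' @return An object of class `waveform_record`: a tibble with columns
#'   `time_s`, `abp_mmHg`, `cbfv_cms`, `co2_mmHg` and attributes `fs`,
#'   `beat_onsets_s` (true beat onset times) and `etco2_events` (tibble of
#'   per-breath end-tidal time and value).
#' @export
simulate_waveforms <- function(model, heart_rate_bpm = 60,
                               resp_rate_bpm = 15, fs = 100,
                               duration_s = 300, pulse_mmhg = 40,
                               pulse_cms = 30, seed = NULL) {
  stopifnot(inherits(model, "true_model"))
  if (fs < 50) dvr_abort("`fs` must be >= 50 Hz to resolve beats.",
                         "dvr_fs_too_low")
  if (heart_rate_bpm < 30 || heart_rate_bpm > 180) {
    dvr_abort("`heart_rate_bpm` outside physiological range 30-180.",
              "dvr_bad_rate")
  }
  if (resp_rate_bpm < 6 || resp_rate_bpm > 30) {
    dvr_abort("`resp_rate_bpm` outside physiological range 6-30.",
              "dvr_bad_rate")
  }
  with_seed_if(seed, {
    n <- floor(duration_s * fs)
    t <- (seq_len(n) - 1) / fs
    beat_period <- 60 / heart_rate_bpm
    breath_period <- 60 / resp_rate_bpm

    # slow beat-to-beat dynamics on the model's dt grid with one kernel
    # memory of pre-record history (grid index i <-> time (i - M - 1) * dt)
    dt <- model$dt
    M <- model$M
    n_grid <- ceiling(duration_s / dt) + M + 2L
    grid_t <- (seq_len(n_grid) - M - 1L) * dt
    abp_dev <- lowpass_noise(n_grid, 3, dt)
    etco2_slow <- lowpass_noise(n_grid, 1.5, dt)

    # breath-wise end-tidal values: arterial CO2 is sampled once per breath
    # at the end-tidal instant, and the effective model input holds that
    # value until the next end-tidal measurement
    breath_onsets <- seq(0, duration_s - 1e-9, by = breath_period)
    plateau_dev <- approx(grid_t, etco2_slow, xout = breath_onsets,
                          rule = 2)$y
    et_times <- breath_onsets + 0.95 * breath_period
    held_dev <- approx(et_times, plateau_dev, xout = grid_t,
                       method = "constant", rule = 2, f = 0)$y

    kp <- drop(crossprod(model$basis_p$values, model$coeff_p))
    kc <- drop(crossprod(model$basis_c$values, model$coeff_c))
    cbfv_dev <- as.numeric(stats::filter(abp_dev, kp, "convolution", sides = 1)) +
      as.numeric(stats::filter(held_dev, kc, "convolution", sides = 1))
    at <- function(dev, times) {
      ok <- !is.na(dev)
      approx(grid_t[ok], dev[ok], xout = times, rule = 2)$y
    }

    beat_onsets <- seq(0, duration_s - 1e-9, by = beat_period)
    beat_idx <- pmin(floor(t / beat_period) + 1L, length(beat_onsets))
    tau <- (t - beat_onsets[beat_idx]) / beat_period

    abp_mean_t <- model$baseline_abp + at(abp_dev, beat_onsets[beat_idx])
    cbfv_mean_t <- model$baseline_cbfv + at(cbfv_dev, beat_onsets[beat_idx])
    abp <- abp_mean_t + pulse_mmhg * pulse_contour(tau)
    cbfv <- cbfv_mean_t + pulse_cms * pulse_contour(tau)

    breath_idx <- pmin(floor(t / breath_period) + 1L, length(breath_onsets))
    tau_b <- (t - breath_onsets[breath_idx]) / breath_period
    plateau <- model$baseline_etco2 + plateau_dev
    co2_low <- 2  # inspired CO2, mmHg
    co2 <- co2_low + (plateau[breath_idx] - co2_low) * co2_contour(tau_b)

    # ground-truth end-tidal instants (0.95 of each breath period)
    in_rec <- et_times < duration_s
    etco2_events <- tibble(time_s = et_times[in_rec],
                           etco2_mmHg = plateau[in_rec])

    rec <- tibble(time_s = t, abp_mmHg = abp, cbfv_cms = cbfv,
                  co2_mmHg = co2)
    structure(rec, fs = fs, beat_onsets_s = beat_onsets,
              etco2_events = etco2_events,
              true_model = model,
              class = c("waveform_record", class(rec)))
  })
}

#' @export
print.waveform_record <- function(x, ...) {
  cat(sprintf("<waveform_record> fs = %g Hz, %.1f s, %d samples\n",
              attr(x, "fs"), nrow(x) / attr(x, "fs"), nrow(x)))
  NextMethod()
}

#' Closed-form DVR of a known system
#'
#' For a linear system the response to a rectangular ETCO2 pulse of
#' duration `w` is the running sum of the CO2 kernel, so the DVR index has
#' the closed form \eqn{\mathrm{DVR} = \frac{1}{N}\sum_{n=0}^{N-1}
#' \sum_{m=0}^{n} k_c(m)} with `N = w / dt` samples. Computed here directly
#' from the generating kernel, independently of the pulse-response code
#' path.
#'
#' @param model A [true_model()] (or any `two_input_model`).
#' @param window_s Pulse duration and averaging window, seconds.
#' @return The scalar DVR in cm/s per mmHg.
#' @export
true_dvr <- function(model, window_s = 5) {
  kc <- kernel_of(model, "etco2")$kernel
  n_win <- round(window_s / model$dt)
  if (n_win < 1) dvr_abort("window shorter than dt", "dvr_bad_window")
  run <- cumsum(c(kc, rep(0, max(0, n_win - length(kc)))))
  mean(run[seq_len(n_win)])
}
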