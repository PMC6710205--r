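#' Rectangular ETCO2 pulse input
#'
#' Builds the probing input for the DVR index: a rectangular ETCO2
#' deviation of the given amplitude and duration, zero afterwards, long
#' enough to cover the model memory.
#'
#' @param dt Sample step, seconds.
#' @param duration_s Pulse duration, seconds (default 5 s); must be at
#'   least `dt`.
#' @param amplitude Pulse height, mmHg.
#' @param length_out Total sequence length in samples; defaults to the
#'   pulse plus `tail_samples`.
#' @param tail_samples Zero samples appended after the pulse when
#'   `length_out` is not given.
#' @return Numeric sequence: `amplitude` for samples with time in
#'   `[0, duration_s)`, `0` elsewhere.
#' @export
pulse_input <- function(dt, duration_s = 5, amplitude = 1,
                        length_out = NULL, tail_samples = 50L) {
  if (dt <= 0) dvr_abort("`dt` must be > 0.", "dvr_bad_dt")
  if (duration_s < dt) {
    dvr_abort("`duration_s` must be at least `dt`.", "dvr_bad_pulse")
  }
  n_on <- round(duration_s / dt)
  n <- length_out %||% (n_on + tail_samples)
  if (n < n_on) dvr_abort("`length_out` shorter than the pulse.",
                          "dvr_bad_pulse")
  c(rep(amplitude, n_on), rep(0, n - n_on))
}

#' Model-predicted CBFV response to an ETCO2 pulse
#'
#' Convolves the model's first-order CO2 kernel with the pulse while the
#' ABP input is held at baseline (zero deviation), so only the CO2 branch
#' contributes; the intercept is excluded because the response is a
#' deviation from baseline flow.
#'
#' @param model A `two_input_model` or [true_model()].
#' @param pulse Input sequence from [pulse_input()], at least as long as
#'   the model memory.
#' @return A tibble with columns `time_s` and `response` (cm/s deviation),
#'   same length as `pulse`.
#' @export
pulse_response <- function(model, pulse) {
  M <- model$basis_c$M
  if (length(pulse) < M) {
    dvr_abort("`pulse` must be at least as long as the model memory.",
              "dvr_series_too_short")
  }
  kc <- kernel_of(model, "etco2")$kernel
  # zero-pad the past: the pulse starts from rest, so pre-pulse input is 0
  xp <- c(rep(0, M - 1L), pulse)
  r <- as.numeric(stats::filter(xp, kc, method = "convolution", sides = 1))
  r <- r[M:length(xp)]
  tibble(time_s = (seq_along(pulse) - 1) * model$dt, response = r)
}

#' DVR index from a pulse response
#'
#' The Dynamic Vasomotor Reactivity index: the arithmetic mean of the
#' predicted CBFV response over the evaluation window (default the 5-s
#' pulse duration), divided by the pulse amplitude, so the index is in
#' cm/s per mmHg and amplitude-invariant for a linear model.
#'
#' @param response Tibble from [pulse_response()] (columns `time_s`,
#'   `response`), or a numeric response vector (then `dt` is required).
#' @param dt Sample step, seconds (taken from `response$time_s` when a
#'   tibble is given).
#' @param window_s Averaging window from pulse onset, seconds.
#' @param amplitude Pulse amplitude the response was computed with, mmHg.
#' @return Scalar DVR (cm/s per mmHg).
#' @export
dvr_index <- function(response, dt = NULL, window_s = 5, amplitude = 1) {
  if (is.data.frame(response)) {
    t <- response$time_s
    r <- response$response
  } else {
    if (is.null(dt)) dvr_abort("`dt` required for a bare response vector.",
                               "dvr_bad_dt")
    r <- as.numeric(response)
    t <- (seq_along(r) - 1) * dt
  }
  in_win <- t >= 0 & t < window_s
  step <- if (length(t) > 1) t[2L] - t[1L] else window_s
  if (max(t) + step < window_s) {
    dvr_abort("Averaging window extends beyond the response trace.",
              "dvr_bad_window")
  }
  mean(r[in_win]) / amplitude
}

#' Pipeline configuration
#'
#' Central, validated bundle of every tunable in the pipeline; unknown
#' keys are rejected so a config file cannot silently misspell an option.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A named list of class `dvr_config`.
#' @section Defaults:
#' * `dt = 1` s beat-to-beat grid; `refractory_s = 0.3`,
#'   `breath_min_sep_s = 1.5`, `artifact_sd = 4`, `max_reject_frac = 0.2`
#'   (preprocessing);
#' * `M = 50` samples kernel memory, `alpha_grid = seq(0.2, 0.8, 0.1)`,
#'   `L_grid = 1:4`, `ridge = 0` (model structure search; singleton grids
#'   skip the search);
#' * `pulse_duration_s = 5`, `pulse_amplitude = 1` mmHg, `window_s = 5`,
#'   `normalize = FALSE` (DVR; when `normalize` the index is % of baseline
#'   CBFV per mmHg).
#' @export
dvr_config <- function(...) {
  defaults <- list(
    dt = 1, refractory_s = 0.3, breath_min_sep_s = 1.5,
    artifact_sd = 4, max_reject_frac = 0.2,
    M = 50L, alpha_grid = seq(0.2, 0.8, by = 0.1), L_grid = 1:4,
    ridge = 0,
    pulse_duration_s = 5, pulse_amplitude = 1, window_s = 5,
    normalize = FALSE)
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1L]]) && is.null(names(over))) {
    over <- over[[1L]]
  }
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0L) {
    dvr_abort(paste0("Unknown config key(s): ",
                     paste(unknown, collapse = ", ")), "dvr_bad_config")
  }
  structure(modifyList(defaults, over), class = "dvr_config")
}

#' End-to-end DVR estimation for one subject
#'
#' Chains the full pipeline: beat reduction and cleaning of the raw
#' waveforms (skipped when a [uniform_series()] is supplied), Laguerre
#' model structure search and least-squares fit, pulse response, and the
#' DVR index. Deterministic given the input and config.
#'
#' @param x A `waveform_record` or a [uniform_series()].
#' @param config A [dvr_config()].
#' @param subject_id Optional label carried into the result.
#' @return An object of class `dvr_result`: a list with `subject_id`,
#'   `dvr`, `response` (tibble trace), `model`, `pulse_amplitude`,
#'   `pulse_duration`, `window`, `normalized`.
#' @export
dvr_pipeline <- function(x, config = dvr_config(), subject_id = NA_character_) {
  stopifnot(inherits(config, "dvr_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      dvr_abort(paste0("[stage ", name, "] ", conditionMessage(e)),
                "dvr_stage_error", parent = e)
    })
  }
  if (inherits(x, "uniform_series")) {
    u <- x
  } else {
    beats <- stage("preprocess", {
      b <- beat_reduce(x, refractory_s = config$refractory_s,
                       min_sep_s = config$breath_min_sep_s)
      clean_beats(b, artifact_sd = config$artifact_sd,
                  max_reject_frac = config$max_reject_frac)
    })
    if (max(beats$beat_time_s) - min(beats$beat_time_s) < 180) {
      dvr_abort("Recording shorter than 3 usable minutes.",
                "dvr_series_too_short")
    }
    u <- stage("to_uniform", to_uniform(beats, dt = config$dt))
  }
  model <- stage("model", {
    if (length(config$alpha_grid) == 1L && length(config$L_grid) == 1L) {
      fit_two_input_model(
        u,
        laguerre_basis(config$alpha_grid, config$L_grid, config$M),
        laguerre_basis(config$alpha_grid, config$L_grid, config$M),
        ridge = config$ridge)
    } else {
      select_structure(u, alpha_grid = config$alpha_grid,
                       L_grid = config$L_grid, M = config$M,
                       ridge = config$ridge)
    }
  })
  pulse <- pulse_input(model$dt, duration_s = config$pulse_duration_s,
                       amplitude = config$pulse_amplitude,
                       tail_samples = config$M)
  resp <- stage("dvr", pulse_response(model, pulse))
  dvr <- dvr_index(resp, window_s = config$window_s,
                   amplitude = config$pulse_amplitude)
  if (isTRUE(config$normalize)) {
    base <- attr(u, "baselines")[["cbfv"]]
    if (!is.finite(base) || base == 0) {
      dvr_abort("Cannot normalize: baseline CBFV is zero or unknown.",
                "dvr_bad_baseline")
    }
    dvr <- 100 * dvr / base
  }
  structure(
    list(subject_id = subject_id, dvr = dvr, response = resp,
         model = model, pulse_amplitude = config$pulse_amplitude,
         pulse_duration = config$pulse_duration_s,
         window = config$window_s, normalized = isTRUE(config$normalize)),
    class = "dvr_result")
}

#' @export
print.dvr_result <- function(x, ...) {
  unit <- if (x$normalized) "% baseline CBFV per mmHg" else "cm/s per mmHg"
  cat(sprintf("<dvr_result> subject %s: DVR = %.4f %s (%g-s pulse, %g-s window)\n",
              x$subject_id, x$dvr, unit, x$pulse_duration, x$window))
  invisible(x)
}

#' @rdname dvr_pipeline
#' @param x A `dvr_result`.
#' @param ... Unused.
#' @method tidy dvr_result
#' @export
tidy.dvr_result <- function(x, ...) {
  dplyr::mutate(x$response, subject_id = x$subject_id, .before = 1L)
}

#' @rdname dvr_pipeline
#' @method glance dvr_result
#' @export
glance.dvr_result <- function(x, ...) {
  tibble(subject_id = x$subject_id, dvr = x$dvr,
         pulse_amplitude = x$pulse_amplitude,
         pulse_duration = x$pulse_duration, window = x$window,
         normalized = x$normalized,
         fit_nmse = x$model$fit_nmse)
}

#' @method autoplot dvr_result
#' @export
autoplot.dvr_result <- function(object, ...) {
  ggplot2::ggplot(object$response,
                  ggplot2::aes(x = .data$time_s, y = .data$response)) +
    ggplot2::annotate("rect", xmin = 0, xmax = object$window,
                      ymin = -Inf, ymax = Inf, alpha = 0.08) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Time from pulse onset (s)",
      y = "Predicted CBFV response (cm/s)",
      title = sprintf("ETCO2 pulse response; DVR = %.3f", object$dvr)) +
    ggplot2::theme_minimal()
}

#' @method autoplot two_input_model
#' @export
autoplot.two_input_model <- function(object, ...) {
  k <- dplyr::bind_rows(
    dplyr::mutate(kernel_of(object, "abp"), branch = "ABP"),
    dplyr::mutate(kernel_of(object, "etco2"), branch = "ETCO2"))
  ggplot2::ggplot(k, ggplot2::aes(x = .data$lag_s, y = .data$kernel)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~branch, scales = "free_y") +
    ggplot2::labs(x = "Lag (s)", y = "First-order kernel",
                  title = "Estimated input kernels") +
    ggplot2::theme_minimal()
}
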