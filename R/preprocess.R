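#' Uniformly sampled, demeaned beat-to-beat series
#'
#' The container the dynamic model is fit on: ABP, ETCO2 and CBFV
#' deviations on a uniform time grid, with the removed channel means stored
#' as baselines. Constructed by [to_uniform()] or [simulate_subject()];
#' build one directly only for already-gridded data.
#'
#' @param abp,etco2,cbfv Equal-length numeric channels (raw units; means
#'   are removed here and stored).
#' @param dt Grid step, seconds.
#' @return A tibble of class `uniform_series` with columns `time_s`,
#'   `abp`, `etco2`, `cbfv` (deviations) and attributes `dt` and
#'   `baselines` (named numeric vector of the removed means).
#' @export
uniform_series <- function(abp, etco2, cbfv, dt) {
  if (dt <= 0) dvr_abort("`dt` must be > 0.", "dvr_bad_dt")
  n <- length(abp)
  if (length(etco2) != n || length(cbfv) != n) {
    dvr_abort("Channels must have equal length.", "dvr_length_mismatch")
  }
  baselines <- c(abp = mean(abp), etco2 = mean(etco2), cbfv = mean(cbfv))
  out <- tibble(time_s = (seq_len(n) - 1) * dt,
                abp = abp - baselines[["abp"]],
                etco2 = etco2 - baselines[["etco2"]],
                cbfv = cbfv - baselines[["cbfv"]])
  structure(out, dt = dt, baselines = baselines,
            class = c("uniform_series", class(out)))
}

#' @export
print.uniform_series <- function(x, ...) {
  b <- attr(x, "baselines")
  cat(sprintf(paste0("<uniform_series> dt = %g s, %d samples; baselines:",
                     " ABP %.1f mmHg, ETCO2 %.1f mmHg, CBFV %.1f cm/s\n"),
              attr(x, "dt"), nrow(x), b[["abp"]], b[["etco2"]], b[["cbfv"]]))
  NextMethod()
}

#' Detect beat onsets in an ABP waveform
#'
#' Derivative-threshold upstroke search followed by preceding-minimum
#' refinement: candidate systolic upstrokes are threshold crossings of the
#' smoothed pressure derivative; each onset is then placed at the diastolic
#' minimum in the window just before its upstroke. A refractory period
#' suppresses double detections within one beat.
#'
#' @param record A `waveform_record` (see [simulate_waveforms()] /
#'   [read_waveforms()]), or a data frame with `time_s` and `abp_mmHg` plus
#'   an `fs` attribute.
#' @param refractory_s Minimum spacing between onsets, seconds.
#' @return Numeric vector of strictly increasing onset times (s).
#' @export
detect_beats <- function(record, refractory_s = 0.3) {
  fs <- attr(record, "fs")
  x <- record$abp_mmHg
  if (is.null(fs) || is.null(x)) {
    dvr_abort("`record` must carry an `fs` attribute and an abp_mmHg column.",
              "dvr_bad_record")
  }
  if (length(x) < 10 * fs) {
    dvr_abort("ABP channel must be at least 10 s long.", "dvr_series_too_short")
  }
  if (sd(x) < 1e-9) {
    dvr_abort("no beats detected: ABP channel has no variance (flatline).",
              "dvr_no_beats")
  }
  # light smoothing (25 ms) so sample noise cannot fake upstrokes
  w <- max(1L, round(0.025 * fs))
  xs <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  xs[is.na(xs)] <- x[is.na(xs)]
  d <- c(0, diff(xs)) * fs  # mmHg/s
  thr <- 0.35 * stats::quantile(d[d > 0], 0.98, names = FALSE)
  if (!is.finite(thr) || thr <= 0) {
    dvr_abort("no beats detected: no systolic upstrokes found.",
              "dvr_no_beats")
  }
  cross <- which(d[-1L] > thr & d[-length(d)] <= thr) + 1L
  if (length(cross) == 0L) {
    dvr_abort("no beats detected: no systolic upstrokes found.",
              "dvr_no_beats")
  }
  back <- round(0.4 * fs)  # search window for the preceding diastolic minimum
  onsets_idx <- vapply(cross, function(i) {
    lo <- max(1L, i - back)
    as.integer(lo + which.min(xs[lo:i]) - 1L)
  }, integer(1))
  onsets_idx <- sort(unique(onsets_idx))
  # refractory: greedy left-to-right suppression
  keep <- logical(length(onsets_idx))
  last_t <- -Inf
  tt <- record$time_s[onsets_idx]
  for (i in seq_along(onsets_idx)) {
    if (tt[i] - last_t >= refractory_s) {
      keep[i] <- TRUE
      last_t <- tt[i]
    }
  }
  tt[keep]
}

#' Per-beat means of a waveform channel
#'
#' Value `i` is the mean of the samples in `[onset_i, onset_{i+1})`; the
#' last beat takes the remaining samples to the end of the record.
#'
#' @param channel Numeric waveform samples.
#' @param beat_times Beat onset times (s), strictly increasing, length
#'   `>= 2`.
#' @param fs Sampling rate, Hz.
#' @return Numeric vector of per-beat means, one per onset.
#' @export
beat_average <- function(channel, beat_times, fs) {
  if (length(beat_times) < 2L) {
    dvr_abort("Need at least 2 beats.", "dvr_too_few_beats")
  }
  n <- length(channel)
  idx <- floor(beat_times * fs) + 1L
  if (any(idx < 1L) || any(idx > n)) {
    dvr_abort("Beat times fall outside the recording span.",
              "dvr_beats_outside")
  }
  bounds <- c(idx, n + 1L)
  vapply(seq_along(beat_times), function(i) {
    mean(channel[bounds[i]:(bounds[i + 1L] - 1L)])
  }, numeric(1))
}

#' Per-beat end-tidal CO2 by breath-wise maxima
#'
#' End-tidal values are the breath-wise maxima of the capnogram, detected
#' as local maxima separated by at least `min_sep_s`; each beat is then
#' assigned the most recent end-tidal value at or before its onset
#' (sample-and-hold — end-tidal CO2 is a breath-wise constant, so
#' interpolation would be physiologically wrong). Beats preceding the first
#' detected breath inherit its value.
#'
#' @param co2 Capnogram samples (mmHg).
#' @param fs Sampling rate, Hz.
#' @param beat_times Beat onset times (s).
#' @param min_sep_s Minimum separation between end-tidal maxima, seconds.
#'   A warning is raised when candidate maxima are suppressed by this rule
#'   (breathing faster than the rule allows).
#' @return Numeric vector of per-beat ETCO2 values (mmHg);
#'   `attr(, "etco2_times")` holds the detected end-tidal times.
#' @export
extract_etco2 <- function(co2, fs, beat_times, min_sep_s = 1.5) {
  n <- length(co2)
  if (max(beat_times) * fs > n) {
    dvr_abort("CO2 channel does not span the beat times.", "dvr_beats_outside")
  }
  # interior local maxima; > on the left and >= on the right dates a flat
  # alveolar plateau at its first sample, so held end-tidal values switch
  # as soon as the new plateau is reached. Peaks must sit in the upper
  # half-range so ripples near baseline never count as breaths.
  if (n < 3L) dvr_abort("No breath maxima found in the CO2 channel.",
                        "dvr_no_breaths")
  left <- co2[seq_len(n - 2L)]
  mid <- co2[seq(2L, n - 1L)]
  right <- co2[seq(3L, n)]
  cand <- which(mid > left & mid >= right) + 1L
  floor_v <- min(co2) + 0.5 * (max(co2) - min(co2))
  cand <- cand[co2[cand] > floor_v]
  if (length(cand) == 0L) {
    dvr_abort("No breath maxima found in the CO2 channel.", "dvr_no_breaths")
  }
  # enforce separation: keep the larger of any pair closer than min_sep_s
  ord <- cand[order(co2[cand], decreasing = TRUE)]
  sel <- integer(0)
  for (i in ord) {
    if (all(abs(i - sel) >= min_sep_s * fs)) sel <- c(sel, i)
  }
  sel <- sort(sel)
  n_suppressed <- length(cand) - length(sel)
  if (n_suppressed > 0L) {
    warn(sprintf(
      "extract_etco2: %d candidate end-tidal maxima suppressed by the %g s separation rule.",
      n_suppressed, min_sep_s), class = "dvr_breaths_suppressed")
  }
  et_t <- (sel - 1L) / fs
  et_v <- co2[sel]
  out <- vapply(beat_times, function(bt) {
    j <- which(et_t <= bt)
    if (length(j) == 0L) et_v[1L] else et_v[max(j)]
  }, numeric(1))
  structure(out, etco2_times = et_t)
}

#' Reduce a raw waveform record to beat-to-beat values
#'
#' Convenience wrapper chaining [detect_beats()], [beat_average()] (ABP,
#' CBFV) and [extract_etco2()].
#'
#' @inheritParams detect_beats
#' @inheritParams extract_etco2
#' @return A tibble of class `beat_series` with columns `beat_time_s`,
#'   `abp`, `cbfv`, `etco2`.
#' @export
beat_reduce <- function(record, refractory_s = 0.3, min_sep_s = 1.5) {
  fs <- attr(record, "fs")
  bt <- detect_beats(record, refractory_s = refractory_s)
  out <- tibble(
    beat_time_s = bt,
    abp = beat_average(record$abp_mmHg, bt, fs),
    cbfv = beat_average(record$cbfv_cms, bt, fs),
    etco2 = as.numeric(extract_etco2(record$co2_mmHg, fs, bt,
                                     min_sep_s = min_sep_s)))
  structure(out, class = c("beat_series", class(out)))
}

#' Artifact rejection on beat-to-beat series
#'
#' Flags beats whose ABP or CBFV mean lies more than `artifact_sd` robust
#' SDs (scaled median absolute deviation, so heavy contamination cannot
#' mask itself) from the series median, or whose inter-beat interval falls
#' outside `ibi_range`, removes them, and fills the gap by linear
#' interpolation over beat index. The run is refused as unusable when more
#' than `max_reject_frac` of beats are flagged.
#'
#' @param beats A `beat_series` from [beat_reduce()] (columns
#'   `beat_time_s`, `abp`, `cbfv`, `etco2`), at least 30 beats.
#' @param artifact_sd Rejection threshold in robust SDs from the median.
#' @param ibi_range Admissible inter-beat interval range, seconds.
#' @param max_reject_frac Maximum tolerated rejected fraction.
#' @return The cleaned `beat_series`; `attr(, "rejections")` is a tibble
#'   with columns `index` and `reason` listing every flagged beat.
#' @export
clean_beats <- function(beats, artifact_sd = 4, ibi_range = c(0.3, 2.0),
                        max_reject_frac = 0.2) {
  if (nrow(beats) < 30L) {
    dvr_abort("Need at least 30 beats to clean.", "dvr_too_few_beats")
  }
  flag_channel <- function(v) {
    s <- stats::mad(v)          # 1.4826 * MAD, consistent for normal data
    if (s == 0) s <- sd(v)      # fallback for discrete-valued channels
    if (s == 0) return(logical(length(v)))
    abs(v - median(v)) > artifact_sd * s
  }
  bad_abp <- flag_channel(beats$abp)
  bad_cbfv <- flag_channel(beats$cbfv)
  ibi <- diff(beats$beat_time_s)
  bad_ibi_edge <- ibi < ibi_range[1L] | ibi > ibi_range[2L]
  # an out-of-range interval implicates the beat that ends it
  bad_ibi <- c(FALSE, bad_ibi_edge)

  rejections <- dplyr::bind_rows(
    tibble(index = which(bad_abp), reason = "abp_outlier"),
    tibble(index = which(bad_cbfv), reason = "cbfv_outlier"),
    tibble(index = which(bad_ibi), reason = "ibi_out_of_range"))
  rejections <- dplyr::arrange(dplyr::distinct(rejections), .data$index)

  bad <- bad_abp | bad_cbfv | bad_ibi
  if (mean(bad) > max_reject_frac) {
    dvr_abort(sprintf(
      "recording unusable: %.0f%% of beats rejected (limit %.0f%%).",
      100 * mean(bad), 100 * max_reject_frac), "dvr_unusable")
  }
  out <- beats
  if (any(bad)) {
    good <- which(!bad)
    for (ch in c("abp", "cbfv", "etco2")) {
      out[[ch]] <- approx(good, beats[[ch]][good], xout = seq_len(nrow(beats)),
                          rule = 2)$y
    }
  }
  structure(out, rejections = rejections,
            class = unique(c("beat_series", class(out))))
}

#' Resample beat-to-beat values onto a uniform grid
#'
#' Linear interpolation of each beat channel onto a grid with step `dt`
#' spanning the beat-time range, followed by demeaning with the means
#' stored as baselines — the form the two-input model is fit on.
#'
#' @param beats A `beat_series`.
#' @param dt Grid step, seconds. Defaults to 1 s (about one beat at rest).
#' @return A [uniform_series()].
#' @export
to_uniform <- function(beats, dt = 1) {
  if (nrow(beats) < 2L) dvr_abort("Need at least 2 beats.", "dvr_too_few_beats")
  if (dt <= 0) dvr_abort("`dt` must be > 0.", "dvr_bad_dt")
  span <- diff(range(beats$beat_time_s))
  if (dt > span / 2) {
    dvr_abort("`dt` larger than half the recording span.", "dvr_bad_dt")
  }
  grid <- seq(min(beats$beat_time_s), max(beats$beat_time_s), by = dt)
  g <- function(ch) approx(beats$beat_time_s, beats[[ch]], xout = grid)$y
  uniform_series(abp = g("abp"), etco2 = g("etco2"), cbfv = g("cbfv"),
                 dt = dt)
}
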