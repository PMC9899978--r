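#' Smoothed first derivative of a sampled trace
#'
#' Zero-phase Savitzky-Golay (local cubic least-squares) first-derivative
#' filter. Unlike kernel smoothing followed by differencing, the local
#' polynomial fit does not displace derivative extrema of smooth waveforms
#' (it is exact through cubic terms), which is what the fiducial definitions
#' below rely on; it is at the same time a zero-phase low-pass FIR, so the
#' raw 4 kHz sample-to-sample noise does not dominate the derivative.
#'
#' @param x numeric samples.
#' @param fs sampling rate, samples/s.
#' @param window_ms filter window length, ms (rounded to an odd number of
#'   samples, floor 5).
#' @param order polynomial order.
#' @return derivative in amplitude units per ms, same length as `x`.
#' @export
sg_derivative <- function(x, fs, window_ms = 9, order = 3) {
  n <- round(window_ms / 1000 * fs)
  if (n %% 2 == 0) n <- n + 1
  n <- max(n, order + 2 + (order %% 2 == 1))  # odd, > order
  if (n %% 2 == 0) n <- n + 1
  key <- sprintf("%d_%d", n, order)
  w <- .sg_coef_cache[[key]]
  if (is.null(w)) {
    # center row of the Savitzky-Golay first-derivative projection
    w <- signal::sgolay(p = order, n = n, m = 1)[(n + 1) / 2, ]
    assign(key, w, envir = .sg_coef_cache)
  }
  d <- stats::filter(x, rev(w), sides = 2)
  # constant extension at the edges (detection windows are interior)
  h <- (n - 1) / 2
  len <- length(x)
  d[seq_len(h)] <- d[h + 1]
  d[(len - h + 1):len] <- d[len - h]
  as.numeric(d) * fs / 1000
}

.sg_coef_cache <- new.env(parent = emptyenv())

# Smoothed derivative evaluated only at the contiguous index range `idx`,
# by filtering the enclosing segment (identical to the full-trace values
# because the FIR window is local; falls back to the full trace when the
# margin would cross an edge).
.sg_deriv_seg <- function(x, fs, idx, window_ms, order = 3) {
  n <- round(window_ms / 1000 * fs)
  if (n %% 2 == 0) n <- n + 1
  n <- max(n, order + 2 + (order %% 2 == 1))
  if (n %% 2 == 0) n <- n + 1
  h <- (n - 1) / 2
  lo <- idx[1] - h; hi <- idx[length(idx)] + h
  if (lo < 1 || hi > length(x)) {
    return(sg_derivative(x, fs, window_ms, order)[idx])
  }
  key <- sprintf("%d_%d", n, order)
  w <- .sg_coef_cache[[key]]
  if (is.null(w)) {
    w <- signal::sgolay(p = order, n = n, m = 1)[(n + 1) / 2, ]
    assign(key, w, envir = .sg_coef_cache)
  }
  d <- stats::filter(x[lo:hi], rev(w), sides = 2)
  as.numeric(d[idx - lo + 1]) * fs / 1000
}

# ms of sample i (1-based, trace starts at 0 ms)
.idx_ms <- function(i, fs) (i - 1) / fs * 1000
.ms_idx <- function(ms, fs) round(ms / 1000 * fs) + 1

# QRS onset rule shared by the detector and the generator's alignment pass:
# first instant, searched backward from the global rectified-derivative
# extremum, at which |dV/dt| exceeds `frac` of its beat maximum.
.onset_ms <- function(x, fs, frac = 0.1, window_ms = 9) {
  d <- abs(sg_derivative(x, fs, window_ms))
  peak <- which.max(d)
  thr <- frac * d[peak]
  below <- which(d[seq_len(peak)] < thr)
  if (length(below) == 0) return(.idx_ms(1, fs))
  .idx_ms(max(below) + 1L, fs)
}

#' Detect the QRS onset of a single beat
#'
#' Returns the first instant at which the rectified smoothed derivative
#' exceeds a fraction (default 10%) of its beat maximum, searched backward
#' from the global derivative extremum. The fractional threshold makes the
#' rule invariant to amplitude scaling.
#'
#' @param trace an [egm_trace()].
#' @param frac threshold as a fraction of the rectified-derivative maximum.
#' @param window_ms smoothing window for the derivative, ms.
#' @return onset in ms from the trace start.
#' @export
detect_qrs_onset <- function(trace, frac = 0.1, window_ms = 31) {
  stopifnot(inherits(trace, "egm_trace"))
  if (stats::sd(trace$samples) == 0) stop("flat trace: no beat to detect")
  .onset_ms(trace$samples, trace$fs, frac, window_ms)
}

#' Detect local activation time (dV/dt minimum during the QRS)
#'
#' The activation marker of a unipolar electrogram is the steepest negative
#' deflection (intrinsic deflection) within the QRS window. Ties are broken
#' toward the earliest sample.
#'
#' @param trace an [egm_trace()].
#' @param qrs_window `c(start, end)` in ms from the trace start; default
#'   onset to onset + 80 ms.
#' @param onset QRS onset in ms (detected if `NULL`); AT is returned
#'   relative to it.
#' @param window_ms derivative smoothing window, ms.
#' @return activation time, ms from QRS onset.
#' @export
detect_at <- function(trace, qrs_window = NULL, onset = NULL, window_ms = 9) {
  stopifnot(inherits(trace, "egm_trace"))
  if (is.null(onset)) onset <- detect_qrs_onset(trace)
  if (is.null(qrs_window)) qrs_window <- c(onset, onset + 80)
  idx <- .ms_idx(qrs_window[1], trace$fs):.ms_idx(qrs_window[2], trace$fs)
  idx <- idx[idx >= 1 & idx <= length(trace$samples)]
  if (length(idx) == 0) stop("empty QRS window")
  d <- .sg_deriv_seg(trace$samples, trace$fs, idx, window_ms)
  at_idx <- idx[which.min(d)]   # which.min takes the earliest on ties
  .idx_ms(at_idx, trace$fs) - onset
}

#' Detect repolarization time (Wyatt method: dV/dt maximum during the T wave)
#'
#' The end-of-repolarization marker is the steepest positive slope of the
#' T wave, for upright and inverted T waves alike. The search is two-stage:
#' a coarse argmax of a heavily smoothed derivative (window `coarse_ms`)
#' localizes the upstroke robustly under noise, then the lightly smoothed
#' derivative (window `window_ms`) is maximized within `refine_ms` of it.
#' On a noiseless beat the two stages agree, so the result equals the global
#' argmax of the lightly smoothed derivative over the whole window.
#'
#' @param trace an [egm_trace()].
#' @param t_window `c(start, end)` in ms from the trace start; default
#'   `onset + at + 100` to `onset + 0.9 * RR`.
#' @param onset QRS onset in ms (detected if `NULL`).
#' @param at activation time in ms from onset (detected if `NULL`),
#'   used only for the default window.
#' @param window_ms fine derivative smoothing window, ms.
#' @param coarse_ms coarse derivative smoothing window, ms.
#' @param refine_ms half-width of the refinement neighbourhood, ms.
#' @return repolarization time, ms from QRS onset.
#' @export
detect_rt <- function(trace, t_window = NULL, onset = NULL, at = NULL,
                      window_ms = 9, coarse_ms = 35, refine_ms = 0.75) {
  stopifnot(inherits(trace, "egm_trace"))
  if (is.null(onset)) onset <- detect_qrs_onset(trace)
  if (is.null(t_window)) {
    if (is.null(at)) at <- detect_at(trace, onset = onset, window_ms = window_ms)
    if (is.na(trace$rr)) stop("RR needed for the default T window")
    t_window <- c(onset + at + 100, onset + 0.9 * trace$rr)
  }
  n <- length(trace$samples)
  if (t_window[2] > .idx_ms(n, trace$fs) + 0.5 / trace$fs * 1000) {
    stop("T window extends past the end of the trace")
  }
  idx <- .ms_idx(t_window[1], trace$fs):.ms_idx(t_window[2], trace$fs)
  idx <- idx[idx >= 1 & idx <= n]
  if (length(idx) < 2) stop("empty T window")
  d_coarse <- .sg_deriv_seg(trace$samples, trace$fs, idx, coarse_ms)
  ci <- idx[which.max(d_coarse)]
  near <- idx[abs(idx - ci) <= refine_ms / 1000 * trace$fs]
  d_fine <- .sg_deriv_seg(trace$samples, trace$fs, near, window_ms)
  rt_idx <- near[which.max(d_fine)]
  .idx_ms(rt_idx, trace$fs) - onset
}

#' Detect T-wave apex and tangent-method T end on a surface-ECG lead
#'
#' The apex is the largest absolute deflection from the isoelectric level
#' (mean of the PR segment, 40 ms before the QRS onset) inside the T window;
#' the T end is where the steepest-tangent line after the apex crosses the
#' isoelectric level. Both rules are polarity-independent. A biphasic T
#' (opposite-sign deflections each exceeding half the dominant one) is
#' flagged with a warning and measured on the dominant deflection.
#'
#' @param trace a surface-ECG [egm_trace()].
#' @param t_window `c(start, end)` ms from trace start; default
#'   `onset + 120` to `onset + 0.9 * RR`.
#' @param onset QRS onset, ms (detected if `NULL`).
#' @param window_ms derivative smoothing window, ms.
#' @return list with `t_peak` and `t_end`, ms from QRS onset.
#' @export
detect_t_peak_end <- function(trace, t_window = NULL, onset = NULL,
                              window_ms = 35, tangent_span_ms = 100) {
  stopifnot(inherits(trace, "egm_trace"))
  if (trace$lead_kind != "surface_ecg") stop("Tpeak/Tend detection expects a surface ECG lead")
  if (is.null(onset)) onset <- detect_qrs_onset(trace)
  if (is.null(t_window)) {
    if (is.na(trace$rr)) stop("RR needed for the default T window")
    t_window <- c(onset + 120, onset + 0.9 * trace$rr)
  }
  fs <- trace$fs
  n <- length(trace$samples)
  iso_idx <- .ms_idx(max(onset - 40, 0), fs):.ms_idx(onset, fs)
  iso <- mean(trace$samples[iso_idx])
  idx <- .ms_idx(t_window[1], fs):.ms_idx(t_window[2], fs)
  idx <- idx[idx >= 1 & idx <= n]
  if (length(idx) < 3) stop("empty T window")
  dev <- trace$samples[idx] - iso
  pk <- which.max(abs(dev))
  # biphasic check: a substantial opposite deflection elsewhere in the window
  opp <- if (dev[pk] > 0) -min(dev) else max(dev)
  if (opp > 0.5 * abs(dev[pk])) {
    warning("biphasic T wave: measuring the dominant deflection")
  }
  peak_idx <- idx[pk]
  after <- idx[idx > peak_idx & .idx_ms(idx, fs) <= .idx_ms(peak_idx, fs) + tangent_span_ms]
  if (length(after) < 2) stop("no samples after the T apex for the tangent")
  d_after <- .sg_deriv_seg(trace$samples, fs, after, window_ms)
  j <- if (dev[pk] > 0) which.min(d_after) else which.max(d_after)
  tan_idx <- after[j]
  slope <- d_after[j]                      # mV per ms
  if (slope == 0) stop("flat T limb: tangent undefined")
  t_end_abs <- .idx_ms(tan_idx, fs) + (iso - trace$samples[tan_idx]) / slope
  list(t_peak = .idx_ms(peak_idx, fs) - onset, t_end = t_end_abs - onset)
}

#' Bazett rate correction
#'
#' Divides an interval by the square root of the cycle length expressed in
#' seconds, i.e. `interval / sqrt(rr / 1000)`; identical for ARI, QT and
#' QTp. At RR = 1000 ms the corrected value equals the natural one.
#'
#' @param interval interval, ms.
#' @param rr preceding RR interval, ms (> 0).
#' @return rate-corrected interval, ms.
#' @examples
#' bazett(300, 1000)  # 300
#' bazett(241, 534)   # ~329.8
#' @export
bazett <- function(interval, rr) {
  if (any(!is.finite(rr)) || any(rr <= 0)) stop("rr must be positive")
  interval / sqrt(rr / 1000)
}

#' Measure one beat: fiducials and intervals
#'
#' Composes the detectors: QRS onset, then for epicardial leads AT, RT and
#' ARI = RT - AT; for surface-ECG leads T apex and tangent T end, QT
#' (onset to T end) and QTp (onset to apex). All intervals are also Bazett
#' rate-corrected with the beat's own RR. Fields that do not apply to the
#' lead kind are `NA`.
#'
#' @param trace an [egm_trace()] containing one analyzable beat with a
#'   known RR (from `trace$rr`).
#' @param qrs_win_ms QRS window length after onset, ms.
#' @param t_win_start_ms T window start after AT (epicardial), ms.
#' @param ... passed to [detect_rt()] / [detect_t_peak_end()].
#' @return list with `fiducials` (`qrs_onset` ms from trace start; `at`,
#'   `rt`, `t_peak`, `t_end` ms from onset; `rr`) and `intervals` (`ari`,
#'   `aric`, `qt`, `qtc`, `qtp`, `qtp_c`).
#' @export
measure_beat <- function(trace, qrs_win_ms = 80, t_win_start_ms = 100, ...) {
  stopifnot(inherits(trace, "egm_trace"))
  if (is.na(trace$rr)) stop("trace has no RR interval")
  onset <- detect_qrs_onset(trace)
  fid <- list(qrs_onset = onset, at = NA_real_, rt = NA_real_,
              t_peak = NA_real_, t_end = NA_real_, rr = trace$rr)
  itv <- list(ari = NA_real_, aric = NA_real_, qt = NA_real_, qtc = NA_real_,
              qtp = NA_real_, qtp_c = NA_real_)
  if (trace$lead_kind == "epicardial_unipolar") {
    fid$at <- detect_at(trace, qrs_window = c(onset, onset + qrs_win_ms), onset = onset)
    fid$rt <- detect_rt(trace,
                        t_window = c(onset + fid$at + t_win_start_ms,
                                     onset + 0.9 * trace$rr),
                        onset = onset, at = fid$at, ...)
    itv$ari <- fid$rt - fid$at
    itv$aric <- bazett(itv$ari, trace$rr)
  } else {
    tp <- detect_t_peak_end(trace, onset = onset, ...)
    fid$t_peak <- tp$t_peak
    fid$t_end <- tp$t_end
    itv$qt <- tp$t_end
    itv$qtc <- bazett(itv$qt, trace$rr)
    itv$qtp <- tp$t_peak
    itv$qtp_c <- bazett(itv$qtp, trace$rr)
  }
  list(fiducials = fid, intervals = itv)
}

#' Measure every trace of a synthetic dataset
#'
#' Runs [measure_beat()] over all traces and returns the long-format
#' measurement table. A lead whose detection fails is recorded with `NA`
#' measurements (per-metric missingness, never imputation) and listed in
#' the `failed` attribute.
#'
#' @param dataset a `SyntheticDataset` from [generate_cohort()], or a list
#'   of [egm_trace()] objects.
#' @return data.frame with one row per (animal, time_point, lead):
#'   `animal`, `time_point`, `lead`, `lead_kind`, `rr`, `qrs_onset`, `at`,
#'   `rt`, `ari`, `aric`, `qt`, `qtc`, `qtp`, `qtp_c`, `t_peak`, `t_end`.
#' @export
measure_cohort <- function(dataset) {
  traces <- if (inherits(dataset, "egm_cohort")) dataset$signals else dataset
  stopifnot(length(traces) > 0)
  rows <- vector("list", length(traces))
  failed <- character(0)
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    m <- tryCatch(measure_beat(tr), error = function(e) e)
    if (inherits(m, "error")) {
      failed <- c(failed, sprintf("animal %s lead %s tp %s: %s",
                                  tr$animal_id, tr$lead_id, tr$time_point,
                                  conditionMessage(m)))
      m <- list(fiducials = list(qrs_onset = NA_real_, at = NA_real_, rt = NA_real_,
                                 t_peak = NA_real_, t_end = NA_real_, rr = tr$rr),
                intervals = list(ari = NA_real_, aric = NA_real_, qt = NA_real_,
                                 qtc = NA_real_, qtp = NA_real_, qtp_c = NA_real_))
    }
    rows[[i]] <- data.frame(
      animal = tr$animal_id, time_point = tr$time_point, lead = tr$lead_id,
      lead_kind = tr$lead_kind, rr = tr$rr,
      qrs_onset = m$fiducials$qrs_onset, at = m$fiducials$at, rt = m$fiducials$rt,
      ari = m$intervals$ari, aric = m$intervals$aric,
      qt = m$intervals$qt, qtc = m$intervals$qtc,
      qtp = m$intervals$qtp, qtp_c = m$intervals$qtp_c,
      t_peak = m$fiducials$t_peak, t_end = m$fiducials$t_end,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "failed") <- failed
  out
}
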