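#' Signal trace container
#'
#' A `SignalTrace` holds one lead's sampled waveform together with the
#' metadata the measurement stage needs (sampling rate, lead identity and
#' kind, the preceding RR interval). Traces produced by the synthetic
#' generator additionally carry a `truth` list with the ground-truth
#' fiducials used by the test suite.
#'
#' @param samples numeric vector of amplitudes (mV).
#' @param fs sampling rate, samples/s.
#' @param lead_id lead identifier.
#' @param lead_kind `"epicardial_unipolar"` or `"surface_ecg"`.
#' @param animal_id animal identifier (optional).
#' @param time_point minutes relative to occlusion onset (optional).
#' @param rr preceding RR interval, ms.
#' @param truth optional list of ground-truth fiducials (generator only).
#' @return an object of class `egm_trace`.
#' @export
egm_trace <- function(samples, fs, lead_id = NA, lead_kind = "epicardial_unipolar",
                      animal_id = NA, time_point = NA, rr = NA, truth = NULL) {
  stopifnot(is.numeric(samples), length(samples) > 1, all(is.finite(samples)),
            is.numeric(fs), fs > 0)
  lead_kind <- match.arg(lead_kind, c("epicardial_unipolar", "surface_ecg"))
  structure(list(samples = samples, fs = fs, lead_id = lead_id,
                 lead_kind = lead_kind, animal_id = animal_id,
                 time_point = time_point, rr = rr, truth = truth),
            class = "egm_trace")
}

#' @export
print.egm_trace <- function(x, ...) {
  cat(sprintf("<egm_trace> %s lead %s, %d samples @ %g Hz (%.0f ms), RR %.0f ms\n",
              x$lead_kind, as.character(x$lead_id), length(x$samples), x$fs,
              length(x$samples) / x$fs * 1000, x$rr))
  invisible(x)
}

# Unit-height Gaussian bump.
.gauss <- function(t, mu, s) exp(-((t - mu)^2) / (2 * s^2))

# Default morphology parameters by lead kind. Widths in ms, amplitudes in
# mV. a_dn/w_dn: the QRS downstroke step (its steepest point is the
# intrinsic deflection = AT); a_t/s_t: the T bump. The epicardial T is
# relatively tall and narrow, as in ischemic unipolar electrograms, so the
# Wyatt upstroke remains a well-conditioned derivative extremum under noise.
.beat_shape <- function(lead_kind) {
  if (lead_kind == "surface_ecg") {
    list(a_dn = 0.9, w_dn = 6, a_t = 0.30, s_t = 25)
  } else {
    list(a_dn = 1.0, w_dn = 5, a_t = 0.85, s_t = 15)
  }
}

# QRS complex built in derivative space from three separated lobes and
# integrated analytically (each lobe is a pnorm step in value space):
#   1. a steep upstroke whose 10% rectified-derivative crossing defines the
#      QRS onset (it carries the global derivative extremum, so the onset
#      rule walks back along it);
#   2. a downstroke step whose steepest point sits exactly at `at_abs`
#      (the intrinsic deflection / activation marker);
#   3. a slow recovery step returning the dome to baseline.
# The upstroke width scales with the onset-to-AT gap, i.e. delayed
# activation comes with a wider QRS, as in ischemia.
.qrs_component <- function(t, onset_nom, at_abs, shape, corr = 0, up_boost = 1) {
  gap <- at_abs - onset_nom
  w_up <- min(max((gap - 14) / 4, 2), 8)
  # nominal crossing at t_up - 2.146 w_up; `corr` shifts the upstroke so the
  # measured threshold crossing lands exactly on onset_nom (calibration pass)
  t_up <- onset_nom + 2.146 * w_up + corr
  # upstroke nominally 35% steeper than the downstroke; `up_boost` (set by a
  # calibration pass) preserves that margin after derivative smoothing, which
  # attenuates the narrower upstroke lobe more than the downstroke
  a_up <- 1.35 * shape$a_dn * w_up / shape$w_dn * up_boost
  a_up * stats::pnorm((t - t_up) / w_up) -
    shape$a_dn * stats::pnorm((t - at_abs) / shape$w_dn) -
    (a_up - shape$a_dn) * stats::pnorm((t - (at_abs + 30)) / 10)
}

# Ratio by which the upstroke amplitude must grow so that its smoothed
# rectified-derivative peak exceeds the downstroke peak by >= 35% (keeps
# the onset rule anchored to the upstroke for every QRS geometry).
.up_boost <- function(x, fs, onset_nom, at_abs, w_dn) {
  d <- sg_derivative(x, fs, 31)
  split <- .ms_idx(at_abs - 1.5 * w_dn, fs)
  i0 <- .ms_idx(max(onset_nom - 10, 0), fs)
  i1 <- .ms_idx(at_abs + 3 * w_dn, fs)
  u <- max(d[i0:split])
  dn <- -min(d[split:i1])
  max(1, 1.35 * dn / u)
}

# Noiseless beat template on the time grid t (ms). The ST plateau rises
# just after the QRS and decays at the end of the beat so that its slope
# never competes with the intrinsic deflection or the T upstroke inside
# the detection windows.
.beat_template <- function(t, onset_nom, at_abs, rt_abs, end_abs, st_shift,
                           t_polarity, shape, corr = 0, up_boost = 1) {
  mu_t <- if (t_polarity >= 0) rt_abs + shape$s_t else rt_abs - shape$s_t
  x <- .qrs_component(t, onset_nom, at_abs, shape, corr, up_boost) +
    sign(t_polarity) * shape$a_t * .gauss(t, mu_t, shape$s_t)
  if (st_shift != 0) {
    x <- x + st_shift * (stats::plogis((t - (at_abs + 25)) / 6) -
                           stats::plogis((t - (end_abs - 40)) / 12))
  }
  x
}

#' Generate one synthetic unipolar beat
#'
#' Builds a single-beat unipolar waveform from smooth parametric components
#' (analytically integrated derivative lobes for the QRS, a Gaussian T bump,
#' a logistic ST plateau) whose smoothed-derivative extrema realize the
#' requested fiducials: the steepest negative slope inside the QRS falls at
#' `true_at` after the QRS onset and the steepest positive slope of the
#' T wave (the Wyatt repolarization marker, for either T polarity) at
#' `true_at + true_ari`. The QRS onset is defined exactly as in
#' [detect_qrs_onset()] (10% rectified-derivative threshold crossing); the
#' generator evaluates that rule on the noiseless waveform and reports the
#' resulting ground truth in the trace's `truth` element, so generated
#' truth and detector share one time reference to sub-sample agreement.
#'
#' @param true_at activation time, ms from QRS onset (>= 19 so the QRS
#'   upstroke and the intrinsic deflection do not collide).
#' @param true_ari activation-recovery interval, ms; `true_rt = true_at + true_ari`.
#' @param rr cycle length, ms; the trace spans `pre_ms + rr`.
#' @param st_shift ST-segment plateau offset, mV (ischemic injury current).
#' @param fs sampling rate, samples/s.
#' @param noise_sd additive white Gaussian noise SD, mV. Drawn from the
#'   current RNG state, so `set.seed()` before the call makes the trace
#'   reproducible.
#' @param t_polarity +1 for an upright T wave, -1 for an inverted one.
#' @param lead_kind trace kind; selects the default morphology.
#' @param pre_ms baseline run-in before the nominal QRS onset, ms.
#' @param shape optional list overriding morphology parameters
#'   (`a_dn`, `w_dn`, `a_t`, `s_t`).
#' @param ... metadata passed to [egm_trace()] (`lead_id`, `animal_id`,
#'   `time_point`).
#' @return an [egm_trace()] whose `truth` element records `onset` (ms from
#'   trace start, on the sample grid) and `at`, `rt`, `ari` (ms from that
#'   onset), plus `st_shift` and `t_polarity`.
#' @examples
#' b <- make_beat_waveform(34, 241, 534, fs = 4000)
#' measure_beat(b)$fiducials$at
#' @export
make_beat_waveform <- function(true_at, true_ari, rr, st_shift = 0, fs = 4000,
                               noise_sd = 0, t_polarity = 1,
                               lead_kind = "epicardial_unipolar",
                               pre_ms = 100, shape = NULL, ...) {
  lead_kind <- match.arg(lead_kind, c("epicardial_unipolar", "surface_ecg"))
  def <- .beat_shape(lead_kind)
  if (!is.null(shape)) def[names(shape)] <- shape
  if (!(true_at >= 19 && true_ari > 0 && rr > 0)) {
    stop("fiducials must satisfy 19 <= true_at < true_at + true_ari < rr")
  }
  # the whole T wave (and the RT window end at 0.9 RR) must fit in the beat
  if (true_at + true_ari + 4 * def$s_t > 0.9 * rr) {
    stop(sprintf("beat geometry impossible: AT %.0f + ARI %.0f + T width exceeds 90%% of RR %.0f",
                 true_at, true_ari, rr))
  }
  n <- round((pre_ms + rr) / 1000 * fs)
  t <- (seq_len(n) - 1) / fs * 1000
  at_abs <- pre_ms + true_at
  # calibration passes on the noiseless template: (1) boost the upstroke so
  # its smoothed-derivative peak stays the beat's global extremum, (2) slide
  # it so the 10% threshold crossing fires at pre_ms (sub-sample residual is
  # absorbed into the reported truth)
  x0 <- .beat_template(t, pre_ms, at_abs, at_abs + true_ari, pre_ms + rr,
                       st_shift, t_polarity, def)
  boost <- .up_boost(x0, fs, pre_ms, at_abs, def$w_dn)
  x1 <- .beat_template(t, pre_ms, at_abs, at_abs + true_ari, pre_ms + rr,
                       st_shift, t_polarity, def, up_boost = boost)
  o0 <- .onset_ms(x1, fs, frac = 0.1, window_ms = 31)
  x <- .beat_template(t, pre_ms, at_abs, at_abs + true_ari, pre_ms + rr,
                      st_shift, t_polarity, def, corr = pre_ms - o0,
                      up_boost = boost)
  # ground truth referenced to the rule-defined onset of this very waveform
  onset <- .onset_ms(x, fs, frac = 0.1, window_ms = 31)
  if (noise_sd > 0) x <- x + stats::rnorm(n, 0, noise_sd)
  egm_trace(x, fs, lead_kind = lead_kind, rr = rr,
            truth = list(onset = onset, at = at_abs - onset,
                         rt = at_abs + true_ari - onset, ari = true_ari,
                         st_shift = st_shift, t_polarity = sign(t_polarity)),
            ...)
}

#' Generate one synthetic surface-ECG beat
#'
#' Same parametric model as [make_beat_waveform()], but parameterized by the
#' surface intervals: the tangent-method T-wave end falls at `true_qt` ms
#' from the QRS onset and the T apex at `true_qt - 2 * s_t` (for a Gaussian
#' T limb the steepest-tangent line through the inflection point meets the
#' isoelectric level one further sigma after the apex, for either polarity).
#' As for the epicardial beat, the reported `truth` is referenced to the
#' 10% rectified-derivative onset evaluated on the noiseless waveform.
#'
#' @param true_qt QT interval, ms from QRS onset to tangent T end.
#' @param rr cycle length, ms.
#' @param true_r QRS downstroke location, ms from onset (not analyzed on
#'   ECG leads; it anchors the QRS shape).
#' @inheritParams make_beat_waveform
#' @return an [egm_trace()] with `truth` recording `onset`, `qt`,
#'   `t_peak`, `t_end` (= `qt`) and `qtp` (all ms from onset).
#' @export
make_ecg_beat <- function(true_qt, rr, true_r = 30, st_shift = 0, fs = 1028,
                          noise_sd = 0, t_polarity = 1, pre_ms = 100,
                          shape = NULL, ...) {
  def <- .beat_shape("surface_ecg")
  if (!is.null(shape)) def[names(shape)] <- shape
  if (!(true_qt > true_r + 4 * def$s_t)) stop("QT too short for the T-wave width")
  if (true_qt + 2 * def$s_t > 0.9 * rr) {
    stop(sprintf("beat geometry impossible: QT %.0f does not fit in RR %.0f", true_qt, rr))
  }
  n <- round((pre_ms + rr) / 1000 * fs)
  t <- (seq_len(n) - 1) / fs * 1000
  t_peak <- true_qt - 2 * def$s_t          # apex, ms from onset
  mu_t <- pre_ms + t_peak
  build <- function(corr, up_boost = 1) {
    x <- .qrs_component(t, pre_ms, pre_ms + true_r, def, corr, up_boost) +
      sign(t_polarity) * def$a_t * .gauss(t, mu_t, def$s_t)
    if (st_shift != 0) {
      x <- x + st_shift * (stats::plogis((t - (pre_ms + true_r + 25)) / 6) -
                             stats::plogis((t - (pre_ms + rr - 40)) / 12))
    }
    x
  }
  x0 <- build(0)
  boost <- .up_boost(x0, fs, pre_ms, pre_ms + true_r, def$w_dn)
  o0 <- .onset_ms(build(0, boost), fs, frac = 0.1, window_ms = 31)
  x <- build(pre_ms - o0, boost)
  onset <- .onset_ms(x, fs, frac = 0.1, window_ms = 31)
  if (noise_sd > 0) x <- x + stats::rnorm(n, 0, noise_sd)
  off <- pre_ms - onset   # sub-sample onset correction
  egm_trace(x, fs, lead_kind = "surface_ecg", rr = rr,
            truth = list(onset = onset, qt = true_qt + off, t_peak = t_peak + off,
                         t_end = true_qt + off, qtp = t_peak + off, r = true_r + off,
                         t_polarity = sign(t_polarity)),
            ...)
}

#' Noise level for a target signal-to-noise ratio
#'
#' @param x noiseless samples.
#' @param snr_db target SNR in dB, relative to the RMS of the mean-removed
#'   waveform.
#' @return the white-noise SD giving the requested SNR.
#' @export
noise_for_snr <- function(x, snr_db) {
  rms <- sqrt(mean((x - mean(x))^2))
  rms / 10^(snr_db / 20)
}
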