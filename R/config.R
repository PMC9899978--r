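#' Synthetic-cohort generator configuration
#'
#' Bundles and validates every parameter of the virtual occlusion
#' experiment. Defaults emulate the porcine study design the analysis
#' pipeline is written for: 18 animals, a 6 x 8 epicardial plate sampled at
#' 4 kHz, 12 surface-ECG leads at 1028 Hz, snapshots at baseline and 1,
#' 2.5, 5 and 10 min of occlusion, a contiguous core ischemic patch with
#' activation delay, a biphasic border-zone ARI time-course (prolongation
#' at 1-2.5 min, shortening later) and a ventricular-fibrillation outcome
#' whose probability follows a logistic model on the animal's true maximal
#' rate-corrected QT at 2.5 min.
#'
#' Interval baselines are specified on the rate-corrected (Bazett) scale so
#' that the generated beats remain geometrically feasible across the RR
#' distribution; the delta profiles are natural milliseconds added to the
#' beat at each time-point.
#'
#' Setting `noise_sd = 0` selects a fully deterministic cohort: waveform
#' noise, per-time-point RR drift and per-lead interval jitter are all
#' disabled, so interval truths are constant across time-points whenever
#' the delta profiles are zero.
#'
#' @param n_animals number of animals.
#' @param n_leads epicardial leads per animal, 32-64.
#' @param grid_shape `c(rows, cols)` with `rows * cols == n_leads`.
#' @param n_ecg_leads surface-ECG leads.
#' @param fs_egm,fs_ecg sampling rates, samples/s.
#' @param time_points minutes relative to occlusion onset, ascending, 0 first.
#' @param rr_mean,rr_sd between-animal RR distribution, ms (lognormal).
#' @param rr_drift_sd within-animal across-time-point RR drift, log-scale SD.
#' @param baseline_at_mean,baseline_at_sd per-lead baseline activation time, ms.
#' @param baseline_aric_mean,baseline_aric_sd per-lead baseline rate-corrected
#'   ARI, ms.
#' @param baseline_qtc_mean,baseline_qtc_sd per-ECG-lead baseline QTc, ms.
#' @param qtc_animal_sd between-animal QTc random effect, ms.
#' @param core_at_delay_profile named (by minute) activation delay added to
#'   core leads, ms.
#' @param border_ari_delta_profile named ARI change in border leads, ms;
#'   biphasic by default (+24 at 1 and 2.5 min — the study's border-zone
#'   median — negative later).
#' @param core_ari_delta_profile named ARI change in core leads, ms.
#' @param qt_delta_profile named QT change on ECG leads, ms.
#' @param st_shift_mv ST plateau of core leads, mV (border gets half).
#' @param core_frac_range fraction of leads in the core patch (uniform draw).
#' @param susceptibility_sd log-scale SD of the per-animal factor scaling all
#'   ischemic interval deltas (couples ARI and QT prolongation within animal).
#' @param jitter_sd per-lead per-time-point interval jitter, ms.
#' @param noise_sd waveform white-noise SD, mV; 0 = deterministic cohort.
#' @param t_neg_frac fraction of leads given an inverted T wave.
#' @param vf_model list `(intercept, slope)` of the logistic VF model on the
#'   animal's true maximal QTc at 2.5 min (slope per ms). Default slope
#'   `log(1.024)`, with the intercept centred at the generator's expected
#'   maximal QTc (474 ms) so an average animal has ~50% VF risk.
#' @param vf_window minutes `c(min, max)` within which VF times are drawn
#'   (uniform); non-VF animals are censored at `censor_time`.
#' @param censor_time censoring time for VF-free animals, minutes.
#' @param seed integer RNG seed used by [generate_cohort()].
#' @return validated config object of class `egm_config`.
#' @export
cohort_config <- function(n_animals = 18,
                          n_leads = 48,
                          grid_shape = NULL,
                          n_ecg_leads = 12,
                          fs_egm = 4000,
                          fs_ecg = 1028,
                          time_points = c(0, 1, 2.5, 5, 10),
                          rr_mean = 534, rr_sd = 97, rr_drift_sd = 0.015,
                          baseline_at_mean = 24, baseline_at_sd = 5,
                          baseline_aric_mean = 330, baseline_aric_sd = 12,
                          baseline_qtc_mean = 430, baseline_qtc_sd = 12,
                          qtc_animal_sd = 35,
                          core_at_delay_profile = c("0" = 0, "1" = 6, "2.5" = 25, "5" = 30, "10" = 35),
                          border_ari_delta_profile = c("0" = 0, "1" = 24, "2.5" = 24, "5" = -10, "10" = -30),
                          core_ari_delta_profile = c("0" = 0, "1" = 10, "2.5" = -15, "5" = -40, "10" = -60),
                          qt_delta_profile = c("0" = 0, "1" = 20, "2.5" = 18, "5" = -8, "10" = -20),
                          st_shift_mv = 0.25,
                          core_frac_range = c(0.2, 0.4),
                          susceptibility_sd = 0.3,
                          jitter_sd = 2,
                          noise_sd = 0.01,
                          t_neg_frac = 0.5,
                          vf_model = list(intercept = -log(1.024) * 474, slope = log(1.024)),
                          vf_window = c(1, 8),
                          censor_time = 10,
                          seed = 1L) {
  if (is.null(grid_shape)) {
    rows <- max(which(sapply(1:floor(sqrt(n_leads)), function(r) n_leads %% r == 0)))
    grid_shape <- c(rows, n_leads / rows)
  }
  cfg <- list(n_animals = n_animals, n_leads = n_leads, grid_shape = grid_shape,
              n_ecg_leads = n_ecg_leads, fs_egm = fs_egm, fs_ecg = fs_ecg,
              time_points = time_points, rr_mean = rr_mean, rr_sd = rr_sd,
              rr_drift_sd = rr_drift_sd,
              baseline_at_mean = baseline_at_mean, baseline_at_sd = baseline_at_sd,
              baseline_aric_mean = baseline_aric_mean, baseline_aric_sd = baseline_aric_sd,
              baseline_qtc_mean = baseline_qtc_mean, baseline_qtc_sd = baseline_qtc_sd,
              qtc_animal_sd = qtc_animal_sd,
              core_at_delay_profile = core_at_delay_profile,
              border_ari_delta_profile = border_ari_delta_profile,
              core_ari_delta_profile = core_ari_delta_profile,
              qt_delta_profile = qt_delta_profile,
              st_shift_mv = st_shift_mv, core_frac_range = core_frac_range,
              susceptibility_sd = susceptibility_sd, jitter_sd = jitter_sd,
              noise_sd = noise_sd, t_neg_frac = t_neg_frac,
              vf_model = vf_model, vf_window = vf_window,
              censor_time = censor_time, seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "egm_config")
}

validate_config <- function(cfg) {
  with(cfg, {
    if (n_animals < 1) stop("n_animals must be >= 1")
    if (n_leads < 32 || n_leads > 64) stop("n_leads must be within 32-64")
    if (prod(grid_shape) != n_leads) stop("grid_shape inconsistent with n_leads")
    if (fs_egm <= 0 || fs_ecg <= 0) stop("sampling rates must be positive")
    if (is.unsorted(time_points, strictly = TRUE) || time_points[1] != 0) {
      stop("time_points must be sorted ascending with 0 first")
    }
    if (rr_mean <= 0) stop("rr_mean must be positive")
    for (p in list(core_at_delay_profile, border_ari_delta_profile,
                   core_ari_delta_profile, qt_delta_profile)) {
      if (!all(as.character(time_points) %in% names(p))) {
        stop("delta profiles must name every time point")
      }
    }
    if (!all(c("intercept", "slope") %in% names(vf_model))) {
      stop("vf_model needs intercept and slope")
    }
  })
  invisible(cfg)
}

#' Read / write a generator configuration as YAML
#'
#' @param file path to a YAML key-value file.
#' @return for `read_config`, an `egm_config`.
#' @export
read_config <- function(file) {
  vals <- yaml::read_yaml(file)
  for (p in grep("_profile$", names(vals), value = TRUE)) {
    vals[[p]] <- unlist(vals[[p]])
  }
  do.call(cohort_config, vals)
}

#' @rdname read_config
#' @param config an `egm_config`.
#' @export
write_config <- function(config, file) {
  stopifnot(inherits(config, "egm_config"))
  vals <- unclass(config)
  # named vectors must become YAML maps or the time-point keys are lost
  for (p in grep("_profile$", names(vals), value = TRUE)) {
    vals[[p]] <- as.list(vals[[p]])
  }
  yaml::write_yaml(vals, file, precision = 15)
  invisible(file)
}

#' @export
print.egm_config <- function(x, ...) {
  cat(sprintf("<egm_config> %d animals, %d epicardial leads (%dx%d) @ %g Hz, %d ECG leads @ %g Hz\n",
              x$n_animals, x$n_leads, x$grid_shape[1], x$grid_shape[2],
              x$fs_egm, x$n_ecg_leads, x$fs_ecg))
  cat(sprintf("  time points (min): %s; noise SD %g mV; seed %d\n",
              paste(x$time_points, collapse = ", "), x$noise_sd, x$seed))
  invisible(x)
}
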