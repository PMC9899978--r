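#' Generate a fully ground-truthed virtual occlusion cohort
#'
#' Simulates the complete experiment the analysis pipeline expects:
#' per-animal epicardial lead grids with a contiguous core ischemic patch
#' and its adjacency-frontier border, per-lead per-time-point ground-truth
#' activation and repolarization fiducials following the configured delay /
#' delta profiles, single-beat unipolar waveforms and surface-ECG beats, and
#' an animal-level ventricular-fibrillation outcome drawn from a logistic
#' model on the true maximal QTc at 2.5 min.
#'
#' @param config an [cohort_config()] object.
#' @param signals if `FALSE`, skip waveform synthesis and return ground
#'   truth and outcomes only (fast path for statistical simulations).
#' @return an object of class `egm_cohort` with elements
#'   \describe{
#'     \item{signals}{list of [egm_trace()] (empty when `signals = FALSE`)}
#'     \item{ground_truth}{per (animal, epicardial lead, time-point) truths:
#'       `zone`, `true_at`, `true_ari`, `true_rt = true_at + true_ari`,
#'       `true_aric`, `rr`, `st_shift`}
#'     \item{ecg_truth}{per (animal, ECG lead, time-point) truths: `true_qt`,
#'       `true_qtc`, `true_qtp`, `true_t_peak`, `true_t_end`, `rr`}
#'     \item{zones}{per (animal, lead) zone labels with grid coordinates}
#'     \item{cohort}{per animal: `occlusion_site`, `vf`, `vf_time`,
#'       `max_qtc_25` (the true covariate driving the outcome model)}
#'     \item{grid}{the [lead_grid()]}
#'     \item{config}{the config used}
#'   }
#' @export
generate_cohort <- function(config = cohort_config(), signals = TRUE) {
  stopifnot(inherits(config, "egm_config"))
  validate_config(config)
  set.seed(config$seed)
  cfg <- config
  grid <- lead_grid(cfg$grid_shape[1], cfg$grid_shape[2])
  tps <- cfg$time_points
  tkey <- as.character(tps)
  noisy <- cfg$noise_sd > 0
  ecg_leads <- c("I", "II", "III", "aVR", "aVL", "aVF",
                 paste0("V", 1:6))[seq_len(cfg$n_ecg_leads)]
  s_t_ecg <- .beat_shape("surface_ecg")$s_t

  gt <- list(); et <- list(); zn <- list(); coh <- list(); traces <- list()
  for (a in seq_len(cfg$n_animals)) {
    aid <- sprintf("A%02d", a)
    site <- if (a %% 2 == 1) "LAD" else "LCX"
    # cycle length: between-animal lognormal, small within-animal drift
    rr_a <- min(max(stats::rlnorm(1, log(cfg$rr_mean), cfg$rr_sd / cfg$rr_mean), 400), 850)
    rr_tp <- rr_a * exp(if (noisy) stats::rnorm(length(tps), 0, cfg$rr_drift_sd) else rep(0, length(tps)))
    rr_tp <- pmin(pmax(rr_tp, 400), 850)
    names(rr_tp) <- tkey
    # ischemic zone geometry
    core_n <- round(stats::runif(1, cfg$core_frac_range[1], cfg$core_frac_range[2]) * cfg$n_leads)
    core <- .grow_patch(grid, core_n)
    border <- grid_adjacent(grid, core)
    zone <- ifelse(grid$lead %in% core, "core",
                   ifelse(grid$lead %in% border, "border", "remote"))
    names(zone) <- grid$lead
    # per-lead baselines and T polarity
    # truncated below at 19.5 ms: the parametric QRS needs the upstroke and the
    # intrinsic deflection to be separable (see make_beat_waveform)
    at0 <- pmin(pmax(stats::rnorm(cfg$n_leads, cfg$baseline_at_mean, cfg$baseline_at_sd), 19.5), 42)
    aric0 <- stats::rnorm(cfg$n_leads, cfg$baseline_aric_mean, cfg$baseline_aric_sd)
    tpol <- ifelse(stats::runif(cfg$n_leads) < cfg$t_neg_frac, -1, 1)
    suscept <- exp(stats::rnorm(1, 0, cfg$susceptibility_sd))
    # ECG baselines
    qtc0 <- stats::rnorm(cfg$n_ecg_leads, cfg$baseline_qtc_mean, cfg$baseline_qtc_sd) +
      stats::rnorm(1, 0, cfg$qtc_animal_sd)
    tpol_ecg <- ifelse(stats::runif(cfg$n_ecg_leads) < cfg$t_neg_frac, -1, 1)

    for (k in seq_along(tps)) {
      tp <- tps[k]; key <- tkey[k]; rr <- unname(rr_tp[key])
      delay <- ifelse(zone == "core", cfg$core_at_delay_profile[key], 0)
      delta <- ifelse(zone == "core", cfg$core_ari_delta_profile[key] * suscept,
                      ifelse(zone == "border", cfg$border_ari_delta_profile[key] * suscept, 0))
      jit_at <- if (noisy) stats::rnorm(cfg$n_leads, 0, cfg$jitter_sd / 2) else 0
      jit_ari <- if (noisy) stats::rnorm(cfg$n_leads, 0, cfg$jitter_sd) else 0
      true_at <- pmax(at0 + delay + jit_at, 19.5)
      # keep the beat geometry feasible at short cycle lengths: AT + ARI +
      # the T-wave width must stay inside 90% of RR
      true_ari <- pmin(aric0 * sqrt(rr / 1000) + delta + jit_ari,
                       0.9 * rr - true_at - 62)
      st <- ifelse(zone == "core", cfg$st_shift_mv,
                   ifelse(zone == "border", cfg$st_shift_mv / 2, 0)) *
        (if (tp > 0) 1 else 0)
      gt_tp <- data.frame(
        animal = aid, lead = grid$lead, time_point = tp, zone = zone,
        true_at = true_at, true_ari = true_ari, true_rt = true_at + true_ari,
        true_aric = bazett(true_ari, rr), rr = rr, st_shift = st,
        stringsAsFactors = FALSE, row.names = NULL)
      jit_qt <- if (noisy) stats::rnorm(cfg$n_ecg_leads, 0, cfg$jitter_sd) else 0
      true_qt <- qtc0 * sqrt(rr / 1000) + cfg$qt_delta_profile[key] * suscept + jit_qt
      # T end (and its 2-sigma tangent margin) must stay inside 90% of RR
      true_qt <- pmin(pmax(true_qt, 135), 0.9 * rr - 2 * s_t_ecg - 2)
      et_tp <- data.frame(
        animal = aid, lead = ecg_leads, time_point = tp,
        true_qt = true_qt, true_qtc = bazett(true_qt, rr),
        true_qtp = true_qt - 2 * s_t_ecg,
        true_t_peak = true_qt - 2 * s_t_ecg, true_t_end = true_qt, rr = rr,
        stringsAsFactors = FALSE, row.names = NULL)
      if (signals) {
        for (l in seq_len(cfg$n_leads)) {
          tr <- make_beat_waveform(
            true_at[l], true_ari[l], rr, st_shift = st[l], fs = cfg$fs_egm,
            noise_sd = cfg$noise_sd, t_polarity = tpol[l],
            lead_id = grid$lead[l], animal_id = aid, time_point = tp)
          traces[[length(traces) + 1]] <- tr
          # the trace's truth is referenced to the rule-defined QRS onset
          # of its own waveform (sub-sample shift from the nominal values)
          gt_tp$true_at[l] <- tr$truth$at
          gt_tp$true_rt[l] <- tr$truth$rt
        }
        for (l in seq_len(cfg$n_ecg_leads)) {
          tr <- make_ecg_beat(
            true_qt[l], rr, fs = cfg$fs_ecg, noise_sd = cfg$noise_sd / 2,
            t_polarity = tpol_ecg[l],
            lead_id = ecg_leads[l], animal_id = aid, time_point = tp)
          traces[[length(traces) + 1]] <- tr
          et_tp$true_qt[l] <- tr$truth$qt
          et_tp$true_qtc[l] <- bazett(tr$truth$qt, rr)
          et_tp$true_qtp[l] <- tr$truth$qtp
          et_tp$true_t_peak[l] <- tr$truth$t_peak
          et_tp$true_t_end[l] <- tr$truth$t_end
        }
      }
      gt[[length(gt) + 1]] <- gt_tp
      et[[length(et) + 1]] <- et_tp
    }
    zn[[a]] <- data.frame(animal = aid, lead = grid$lead, row = grid$row,
                          col = grid$col, zone = zone,
                          stringsAsFactors = FALSE, row.names = NULL)
    # outcome model on the true maximal QTc at 2.5 min (closest time point
    # if 2.5 is not among the configured snapshots)
    et_a <- do.call(rbind, et[(length(et) - length(tps) + 1):length(et)])
    tp_out <- tps[which.min(abs(tps - 2.5))]
    max_qtc <- max(et_a$true_qtc[et_a$time_point == tp_out])
    p_vf <- stats::plogis(cfg$vf_model$intercept + cfg$vf_model$slope * max_qtc)
    vf <- stats::runif(1) < p_vf
    vf_time <- if (vf) stats::runif(1, cfg$vf_window[1], cfg$vf_window[2]) else cfg$censor_time
    coh[[a]] <- data.frame(animal = aid, occlusion_site = site, vf = vf,
                           vf_time = vf_time, max_qtc_25 = max_qtc,
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  structure(list(signals = traces,
                 ground_truth = do.call(rbind, gt),
                 ecg_truth = do.call(rbind, et),
                 zones = do.call(rbind, zn),
                 cohort = do.call(rbind, coh),
                 grid = grid, config = cfg),
            class = "egm_cohort")
}

#' @export
print.egm_cohort <- function(x, ...) {
  cat(sprintf("<egm_cohort> %d animals, %d traces, %d ground-truth rows, VF %d/%d\n",
              x$config$n_animals, length(x$signals), nrow(x$ground_truth),
              sum(x$cohort$vf), nrow(x$cohort)))
  invisible(x)
}
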