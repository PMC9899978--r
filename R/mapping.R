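#' Classify core / border / remote ischemic zones from activation delay
#'
#' Core leads are those whose activation time during ischemia exceeds their
#' own baseline by more than `delay_threshold` (strictly) at any of the
#' early ischemic time-points; border leads are the non-core leads
#' grid-adjacent to the core; the rest are remote. With `mode = "rel"` the
#' criterion is a relative delay greater than `rel_threshold` of the
#' baseline AT instead.
#'
#' @param at_table data.frame with `lead`, `time_point`, `at` (ms) for one
#'   animal, containing the baseline and at least one ischemic time-point.
#' @param grid [lead_grid()] geometry for these leads.
#' @param delay_threshold absolute delay criterion, ms (strict inequality).
#' @param mode `"abs"` (default) or `"rel"`.
#' @param rel_threshold relative criterion used when `mode = "rel"`.
#' @param baseline_tp minute labelling the baseline snapshot.
#' @param ischemia_tps minutes compared against baseline.
#' @param diagonal if `TRUE`, border uses the 8-neighbourhood.
#' @return data.frame `lead`, `row`, `col`, `zone` (factor core/border/
#'   remote). Leads with a missing baseline AT are excluded and listed in
#'   the `excluded` attribute.
#' @export
classify_zones <- function(at_table, grid, delay_threshold = 5,
                           mode = c("abs", "rel"), rel_threshold = 0.2,
                           baseline_tp = 0, ischemia_tps = c(1, 2.5, 5),
                           diagonal = FALSE) {
  mode <- match.arg(mode)
  stopifnot(all(c("lead", "time_point", "at") %in% names(at_table)))
  base <- at_table[at_table$time_point == baseline_tp, c("lead", "at")]
  if (nrow(base) == 0) stop("no baseline time-point in at_table")
  isch <- at_table[at_table$time_point %in% ischemia_tps & !is.na(at_table$at), ]
  excluded <- base$lead[is.na(base$at)]
  base <- base[!is.na(base$at), ]
  delays <- merge(isch, base, by = "lead", suffixes = c("", "_base"))
  delays$delay <- delays$at - delays$at_base
  is_core <- if (mode == "abs") {
    delays$delay > delay_threshold
  } else {
    delays$delay > rel_threshold * delays$at_base
  }
  core <- unique(delays$lead[is_core])
  core <- core[core %in% grid$lead]
  border <- if (length(core)) grid_adjacent(grid, core, diagonal) else character(0)
  out <- grid[!(grid$lead %in% excluded), , drop = FALSE]
  out$zone <- factor(ifelse(out$lead %in% core, "core",
                            ifelse(out$lead %in% border, "border", "remote")),
                     levels = c("core", "border", "remote"))
  attr(out, "excluded") <- excluded
  attr(out, "mode") <- mode
  row.names(out) <- NULL
  out
}

#' Dispersion of repolarization
#'
#' Difference between the maximal and minimal repolarization times across
#' all epicardial leads at one time-point.
#'
#' @param rts per-lead RT values, ms (`NA`s dropped).
#' @return DOR in ms.
#' @export
dispersion_of_repolarization <- function(rts) {
  rts <- rts[!is.na(rts)]
  if (length(rts) < 2) stop("DOR needs at least two valid RT values")
  max(rts) - min(rts)
}

#' Global Tpeak-Tend dispersion across ECG leads
#'
#' The interval from the earliest T apex to the latest T end throughout all
#' leads, natural and Bazett rate-corrected.
#'
#' @param t_peaks per-lead T-apex times, ms from QRS onset.
#' @param t_ends per-lead T-end times, ms from QRS onset.
#' @param rr RR interval, ms, for the rate correction.
#' @return list with `tpe` and `tpe_c`, ms.
#' @export
tpeak_tend_dispersion <- function(t_peaks, t_ends, rr) {
  t_peaks <- t_peaks[!is.na(t_peaks)]
  t_ends <- t_ends[!is.na(t_ends)]
  if (length(t_peaks) == 0 || length(t_ends) == 0) {
    stop("no valid T measurements")
  }
  tpe <- max(t_ends) - min(t_peaks)
  list(tpe = tpe, tpe_c = bazett(tpe, rr))
}

#' Rate-corrected repolarization-time map
#'
#' Elementwise `RTc = AT + ARIc` over matched leads.
#'
#' @param at named per-lead activation times, ms.
#' @param aric named per-lead rate-corrected ARIs, ms.
#' @return named per-lead RTc, ms (`NA` where either input is missing).
#' @export
rtc_map <- function(at, aric) {
  if (is.null(names(at)) || is.null(names(aric))) {
    if (length(at) != length(aric)) stop("mismatched lead sets")
    return(at + aric)
  }
  if (!setequal(names(at), names(aric))) stop("mismatched lead sets")
  at + aric[names(at)]
}

#' Cross-lead summary of one animal / time-point
#'
#' Extrema and dispersions over all leads of one measurement snapshot, with
#' per-metric missing-lead exclusion (a lead missing RT still contributes
#' its AT, and so on).
#'
#' @param measurements [measure_cohort()] rows for a single animal and
#'   time-point (both lead kinds).
#' @return one-row data.frame: `animal`, `time_point`, `rr`, `at_max`,
#'   `dor`, `aric_min`, `aric_max`, `aric_mean`, `qt_max`, `qtc_max`,
#'   `qtp_min`, `qtp_c_min`, `tpe`, `tpe_c`, and the numbers of
#'   contributing leads `n_epi`, `n_ecg`.
#' @export
summarize_timepoint <- function(measurements) {
  stopifnot(nrow(measurements) > 0)
  if (length(unique(measurements$animal)) > 1 ||
      length(unique(measurements$time_point)) > 1) {
    stop("summarize_timepoint expects a single animal / time-point")
  }
  epi <- measurements[measurements$lead_kind == "epicardial_unipolar", ]
  ecg <- measurements[measurements$lead_kind == "surface_ecg", ]
  mx <- function(x) if (any(!is.na(x))) max(x, na.rm = TRUE) else NA_real_
  mn <- function(x) if (any(!is.na(x))) min(x, na.rm = TRUE) else NA_real_
  av <- function(x) if (any(!is.na(x))) mean(x, na.rm = TRUE) else NA_real_
  rr <- stats::median(measurements$rr, na.rm = TRUE)
  dor <- if (sum(!is.na(epi$rt)) >= 2) dispersion_of_repolarization(epi$rt) else NA_real_
  tpe <- tpe_c <- NA_real_
  if (nrow(ecg) > 0 && any(!is.na(ecg$t_peak)) && any(!is.na(ecg$t_end))) {
    d <- tpeak_tend_dispersion(ecg$t_peak, ecg$t_end, rr)
    tpe <- d$tpe; tpe_c <- d$tpe_c
  }
  data.frame(animal = measurements$animal[1],
             time_point = measurements$time_point[1], rr = rr,
             at_max = mx(epi$at), dor = dor,
             aric_min = mn(epi$aric), aric_max = mx(epi$aric),
             aric_mean = av(epi$aric),
             qt_max = mx(ecg$qt), qtc_max = mx(ecg$qtc),
             qtp_min = mn(ecg$qtp), qtp_c_min = mn(ecg$qtp_c),
             tpe = tpe, tpe_c = tpe_c,
             n_epi = sum(!is.na(epi$at)), n_ecg = sum(!is.na(ecg$qt)),
             stringsAsFactors = FALSE)
}

#' Early repolarization-prolongation flag
#'
#' An animal is flagged when its maximal rate-corrected ARI exceeds the
#' baseline value by strictly more than `threshold` at 1 and/or 2.5 min of
#' occlusion.
#'
#' @param aric_max_by_time numeric vector of maximal ARIc per time-point,
#'   named by minutes (must include `"0"` and at least one of `"1"`,
#'   `"2.5"`).
#' @param threshold prolongation criterion, ms (strict inequality).
#' @param early_tps the time-points tested against baseline.
#' @return logical flag.
#' @export
flag_early_prolongation <- function(aric_max_by_time, threshold = 10,
                                    early_tps = c("1", "2.5")) {
  v <- aric_max_by_time
  if (!("0" %in% names(v)) || is.na(v["0"])) stop("missing baseline maximal ARIc")
  avail <- intersect(early_tps, names(v))
  avail <- avail[!is.na(v[avail])]
  if (length(avail) == 0) stop("no early ischemic time-point available")
  any(v[avail] - v["0"] > threshold)
}

#' Map summaries and prolongation flags for a whole cohort
#'
#' Applies [summarize_timepoint()] to every animal / time-point of a
#' measurement table and [flag_early_prolongation()] to every animal.
#'
#' @param measurements a [measure_cohort()] table.
#' @param threshold prolongation criterion, ms.
#' @return list with `summaries` (per animal x time-point data.frame) and
#'   `flags` (per animal data.frame with `prolongation_flag`).
#' @export
summarize_cohort <- function(measurements, threshold = 10) {
  keys <- unique(measurements[, c("animal", "time_point")])
  keys <- keys[order(keys$animal, keys$time_point), ]
  sm <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    summarize_timepoint(measurements[measurements$animal == keys$animal[i] &
                                       measurements$time_point == keys$time_point[i], ])
  }))
  flags <- do.call(rbind, lapply(split(sm, sm$animal), function(s) {
    v <- stats::setNames(s$aric_max, as.character(s$time_point))
    data.frame(animal = s$animal[1],
               prolongation_flag = tryCatch(flag_early_prolongation(v, threshold),
                                            error = function(e) NA),
               stringsAsFactors = FALSE)
  }))
  row.names(flags) <- NULL
  list(summaries = sm, flags = flags)
}
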