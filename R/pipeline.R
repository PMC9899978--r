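#' Write / read signal snapshots as CSV
#'
#' One file per animal and time-point, leads in columns (first column
#' `t_ms`), plus a `signals_index.csv` recording sampling rates, RR and
#' lead kinds.
#'
#' @param dataset an `egm_cohort` with signals.
#' @param dir output directory (created if needed).
#' @return invisibly, the index data.frame.
#' @export
write_signals <- function(dataset, dir) {
  stopifnot(inherits(dataset, "egm_cohort"), length(dataset$signals) > 0)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idx <- do.call(rbind, lapply(dataset$signals, function(tr) {
    data.frame(animal = tr$animal_id, time_point = tr$time_point,
               lead = tr$lead_id, lead_kind = tr$lead_kind, fs = tr$fs,
               rr = tr$rr, stringsAsFactors = FALSE)
  }))
  for (aid in unique(idx$animal)) for (tp in unique(idx$time_point[idx$animal == aid])) {
    sel <- which(idx$animal == aid & idx$time_point == tp)
    for (kind in unique(idx$lead_kind[sel])) {
      ksel <- sel[idx$lead_kind[sel] == kind]
      trs <- dataset$signals[ksel]
      n <- max(vapply(trs, function(tr) length(tr$samples), integer(1)))
      m <- data.frame(t_ms = (seq_len(n) - 1) / trs[[1]]$fs * 1000)
      for (tr in trs) m[[tr$lead_id]] <- c(tr$samples, rep(NA, n - length(tr$samples)))
      fn <- sprintf("%s_tp%s_%s.csv", aid, gsub("[.]", "p", tp),
                    if (kind == "surface_ecg") "ecg" else "egm")
      utils::write.csv(m, file.path(dir, fn), row.names = FALSE)
    }
  }
  utils::write.csv(idx, file.path(dir, "signals_index.csv"), row.names = FALSE)
  invisible(idx)
}

#' @rdname write_signals
#' @param dir directory written by `write_signals`.
#' @return for `read_signals`, a list of [egm_trace()].
#' @export
read_signals <- function(dir) {
  idx <- utils::read.csv(file.path(dir, "signals_index.csv"),
                         stringsAsFactors = FALSE)
  traces <- list()
  for (aid in unique(idx$animal)) for (tp in unique(idx$time_point[idx$animal == aid])) {
    sel <- idx[idx$animal == aid & idx$time_point == tp, ]
    for (kind in unique(sel$lead_kind)) {
      fn <- sprintf("%s_tp%s_%s.csv", aid, gsub("[.]", "p", tp),
                    if (kind == "surface_ecg") "ecg" else "egm")
      m <- utils::read.csv(file.path(dir, fn), check.names = FALSE)
      for (lead in sel$lead[sel$lead_kind == kind]) {
        row <- sel[sel$lead == lead, ][1, ]
        x <- m[[lead]]
        traces[[length(traces) + 1]] <- egm_trace(
          x[!is.na(x)], fs = row$fs, lead_id = lead, lead_kind = kind,
          animal_id = aid, time_point = tp, rr = row$rr)
      }
    }
  }
  traces
}

.write_stage_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full pipeline: simulate, measure, map, stats
#'
#' Executes the four stages over a synthetic cohort and writes every
#' intermediate table as CSV plus a JSON run manifest with the config
#' snapshot, seed, package version and MD5 digests of all outputs, so a
#' completed run can be verified to reproduce bit-identically.
#'
#' @param config an [cohort_config()] (or path to a YAML config file).
#' @param out_dir output directory.
#' @param seed optional seed overriding `config$seed`.
#' @param write_signal_files if `TRUE`, also dump raw signal CSVs.
#' @param qtc_cutoff categorical QTc cutoff (ms) used for the Kaplan-Meier /
#'   log-rank comparison.
#' @return the manifest, invisibly; stage outputs live in `out_dir`
#'   (`ground_truth.csv`, `measurements.csv`, `zones_measured.csv`,
#'   `summaries.csv`, `flags.csv`, `cohort.csv`, `stats.csv`,
#'   `manifest.json`).
#' @export
run_pipeline <- function(config = cohort_config(), out_dir, seed = NULL,
                         write_signal_files = FALSE, qtc_cutoff = 460) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "egm_config"))
  validate_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  stage <- "simulate"
  res <- tryCatch({
    ds <- generate_cohort(config)
    files <- c(files,
               .write_stage_csv(ds$ground_truth, file.path(out_dir, "ground_truth.csv")),
               .write_stage_csv(ds$cohort, file.path(out_dir, "cohort.csv")))
    if (write_signal_files) write_signals(ds, file.path(out_dir, "signals"))

    stage <- "measure"
    meas <- measure_cohort(ds)
    files <- c(files, .write_stage_csv(meas, file.path(out_dir, "measurements.csv")))

    stage <- "map"
    epi <- meas[meas$lead_kind == "epicardial_unipolar", ]
    zones <- do.call(rbind, lapply(split(epi, epi$animal), function(am) {
      z <- classify_zones(am[, c("lead", "time_point", "at")], ds$grid,
                          ischemia_tps = setdiff(config$time_points, c(0, 10)))
      z$animal <- am$animal[1]
      z
    }))
    row.names(zones) <- NULL
    sc <- summarize_cohort(meas)
    files <- c(files,
               .write_stage_csv(zones, file.path(out_dir, "zones_measured.csv")),
               .write_stage_csv(sc$summaries, file.path(out_dir, "summaries.csv")),
               .write_stage_csv(sc$flags, file.path(out_dir, "flags.csv")))

    stage <- "stats"
    assoc <- vf_association_table(sc$summaries, ds$cohort)
    qtc25 <- sc$summaries[sc$summaries$time_point == 2.5, c("animal", "qtc_max")]
    coh <- merge(ds$cohort, qtc25, by = "animal")
    xrow <- function(analysis, covariate, estimate, p) {
      data.frame(analysis = analysis, covariate = covariate,
                 mode = "per_animal", estimate = estimate,
                 ci_low = NA_real_, ci_high = NA_real_, p_value = p,
                 n = nrow(coh), flag = "", stringsAsFactors = FALSE)
    }
    # each per-animal analysis needs both outcome classes (and for the
    # Kaplan-Meier split, both cutoff groups); degenerate cohorts just omit
    # the corresponding rows
    extra <- list()
    roc <- tryCatch(roc_analysis(coh$vf, coh$qtc_max), error = function(e) NULL)
    if (!is.null(roc)) {
      extra <- c(extra, list(xrow("roc_auc", "qtc_max@2.5", roc$auc, roc$p_value),
                             xrow("roc_cutoff", "qtc_max@2.5", roc$optimal_cutoff, NA)))
    }
    km <- tryCatch(km_logrank(coh$vf_time, coh$vf, coh$qtc_max > qtc_cutoff),
                   error = function(e) NULL)
    if (!is.null(km)) {
      extra <- c(extra, list(xrow("logrank", sprintf("qtc_max@2.5>%g", qtc_cutoff),
                                  km$logrank_statistic, km$p_value)))
    }
    chi <- tryCatch(site_chisquare(coh$occlusion_site, coh$vf),
                    error = function(e) NULL)
    if (!is.null(chi)) {
      extra <- c(extra, list(xrow("site_chisq", "occlusion_site",
                                  chi$statistic, chi$p_value)))
    }
    stats_tab <- rbind(assoc, do.call(rbind, extra))
    if (is.null(stats_tab)) {
      stats_tab <- data.frame(analysis = character(0), covariate = character(0),
                              mode = character(0), estimate = numeric(0),
                              ci_low = numeric(0), ci_high = numeric(0),
                              p_value = numeric(0), n = integer(0),
                              flag = character(0))
    }
    files <- c(files, .write_stage_csv(stats_tab, file.path(out_dir, "stats.csv")))
    list(dataset = ds, measurements = meas, summaries = sc, stats = stats_tab)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  manifest <- list(
    package = "epimap",
    version = as.character(utils::packageVersion("epimap")),
    seed = config$seed,
    config = unclass(config),
    measurement_failures = attr(res$measurements, "failed"),
    files = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
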