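# Independent oracles used across the suite. Each re-derives its quantity
# from first principles through a different code path than the package.

# Savitzky-Golay first-derivative weights derived independently of
# signal::sgolay: least-squares polynomial fit on a Vandermonde basis,
# solved with base solve(); returns the center-point derivative weights.
oracle_sg_weights <- function(n, order = 3) {
  h <- (n - 1) / 2
  j <- -h:h
  A <- outer(j, 0:order, "^")
  # coefficient row for the 1st-degree term of the LS fit at the window center
  solve(t(A) %*% A, t(A))[2, ]
}

# Smoothed derivative at interior indices `idx` (units per ms), via explicit
# windowed dot products on an embed() matrix.
oracle_sg_deriv_at <- function(x, fs, idx, window_ms, order = 3) {
  n <- round(window_ms / 1000 * fs)
  if (n %% 2 == 0) n <- n + 1
  n <- max(n, order + 2 + (order %% 2 == 1))
  if (n %% 2 == 0) n <- n + 1
  h <- (n - 1) / 2
  stopifnot(all(idx - h >= 1), all(idx + h <= length(x)))
  w <- oracle_sg_weights(n, order)
  vapply(idx, function(i) sum(w * x[(i - h):(i + h)]), numeric(1)) * fs / 1000
}

# Brute-force scan: index (within the full trace) of the extremum of the
# smoothed derivative over a window given in ms from trace start.
oracle_scan_extremum <- function(x, fs, window_ms_range, deriv_window_ms,
                                 minimum = TRUE) {
  i0 <- round(window_ms_range[1] / 1000 * fs) + 1
  i1 <- round(window_ms_range[2] / 1000 * fs) + 1
  idx <- i0:i1
  d <- oracle_sg_deriv_at(x, fs, idx, deriv_window_ms)
  if (minimum) idx[which.min(d)] else idx[which.max(d)]
}

# All-pairs concordance count for the ROC AUC (ties worth 1/2).
oracle_auc <- function(outcome, covariate) {
  x1 <- covariate[as.logical(outcome)]
  x0 <- covariate[!as.logical(outcome)]
  s <- 0
  for (a in x1) for (b in x0) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(x1) * length(x0))
}

# Exhaustive Youden search over all observed cutoffs with the "> cutoff"
# positivity rule; ties resolved toward the lower cutoff.
oracle_youden <- function(outcome, covariate) {
  x1 <- covariate[as.logical(outcome)]
  x0 <- covariate[!as.logical(outcome)]
  cuts <- sort(unique(covariate))
  best <- -Inf; best_cut <- NA
  for (c in cuts) {
    j <- mean(x1 > c) + mean(x0 <= c) - 1
    if (j > best) { best <- j; best_cut <- c }
  }
  list(cutoff = best_cut, j = best)
}

# Independent set-expansion frontier: leads not in `core` having a
# 4-neighbour in `core`, found by explicit coordinate comparison.
oracle_frontier <- function(grid, core) {
  out <- character(0)
  for (i in seq_len(nrow(grid))) {
    if (grid$lead[i] %in% core) next
    for (j in which(grid$lead %in% core)) {
      if (abs(grid$row[i] - grid$row[j]) + abs(grid$col[i] - grid$col[j]) == 1) {
        out <- c(out, grid$lead[i]); break
      }
    }
  }
  sort(out)
}

# Two-group log-rank statistic from first principles: summed observed -
# expected events with hypergeometric variance terms at each distinct
# event time.
oracle_logrank <- function(time, event, group) {
  g <- as.integer(factor(group))
  ts <- sort(unique(time[event]))
  o_minus_e <- 0; v <- 0
  for (tt in ts) {
    at_risk <- time >= tt
    n <- sum(at_risk); n1 <- sum(at_risk & g == 1)
    d <- sum(time == tt & event); d1 <- sum(time == tt & event & g == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n - d) / (n - 1) * n1 * (n - n1) / n^2
  }
  o_minus_e^2 / v
}

# A standard small cohort for mapping/stats tests.
make_test_cohort <- function(n_animals = 2, n_leads = 32, seed = 42,
                             noise_sd = 0, time_points = c(0, 1, 2.5, 5, 10),
                             signals = TRUE, ...) {
  prof <- function(p) p[as.character(time_points)]
  defaults <- list(
    n_animals = n_animals, n_leads = n_leads, seed = seed, noise_sd = noise_sd,
    time_points = time_points,
    core_at_delay_profile = prof(c("0" = 0, "1" = 6, "2.5" = 25, "5" = 30, "10" = 35)),
    border_ari_delta_profile = prof(c("0" = 0, "1" = 24, "2.5" = 24, "5" = -10, "10" = -30)),
    core_ari_delta_profile = prof(c("0" = 0, "1" = 10, "2.5" = -15, "5" = -40, "10" = -60)),
    qt_delta_profile = prof(c("0" = 0, "1" = 20, "2.5" = 18, "5" = -8, "10" = -20)))
  cfg <- do.call(cohort_config, utils::modifyList(defaults, list(...)))
  generate_cohort(cfg, signals = signals)
}

# Beat parameters drawn from the study-like operating range, geometry-safe.
draw_beat_params <- function() {
  repeat {
    ta <- stats::runif(1, 19.5, 62)
    ari <- stats::runif(1, 180, 300)
    rr <- stats::runif(1, 420, 700)
    if (ta + ari + 60 < 0.9 * rr) return(list(ta = ta, ari = ari, rr = rr))
  }
}
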