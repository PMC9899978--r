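#' Repeated-measures comparison across time-points
#'
#' Friedman test over the time-points (animals as blocks, listwise-complete)
#' followed by pairwise Wilcoxon signed-rank tests of each ischemic
#' time-point against baseline with Bonferroni correction (multiplier =
#' number of pairwise tests).
#'
#' @param values data.frame with `animal`, `time_point`, `value`.
#' @param baseline_tp the reference time-point.
#' @return list with `friedman` (`statistic`, `df`, `p_value`, `n`) and
#'   `pairwise` (data.frame `time_point`, `p_raw`, `p_bonferroni`).
#' @export
compare_repeated <- function(values, baseline_tp = 0) {
  stopifnot(all(c("animal", "time_point", "value") %in% names(values)))
  wide <- stats::reshape(values[, c("animal", "time_point", "value")],
                         idvar = "animal", timevar = "time_point",
                         direction = "wide")
  wide <- wide[stats::complete.cases(wide), , drop = FALSE]
  m <- as.matrix(wide[, -1, drop = FALSE])
  if (ncol(m) < 3) stop("need at least 3 time-points")
  if (nrow(m) < 5) warning("fewer than 5 complete animals: low power")
  if (all(m == m[, 1])) {
    # every time-point identical within animal: all ranks tie
    fr <- list(statistic = c("Friedman chi-squared" = 0),
               parameter = c(df = ncol(m) - 1), p.value = 1)
  } else {
    fr <- stats::friedman.test(m)
  }
  tps <- sub("^value\\.", "", colnames(m))
  others <- tps[tps != as.character(baseline_tp)]
  k <- length(others)
  pw <- do.call(rbind, lapply(others, function(tp) {
    d <- m[, paste0("value.", tp)] - m[, paste0("value.", baseline_tp)]
    p <- if (all(d == 0)) 1 else {
      suppressWarnings(stats::wilcox.test(d, exact = FALSE)$p.value)
    }
    data.frame(time_point = as.numeric(tp), p_raw = p,
               p_bonferroni = min(1, p * k))
  }))
  list(friedman = list(statistic = unname(fr$statistic), df = unname(fr$parameter),
                       p_value = fr$p.value, n = nrow(m)),
       pairwise = pw)
}

# Wald CI on the log scale for exp(coef) scales, shared by logistic and Cox.
.wald_exp <- function(beta, se, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(exp(beta - z * se), exp(beta + z * se))
}

#' Univariate logistic regression of a binary outcome on one covariate
#'
#' Maximum-likelihood fit of `logit P(event) = b0 + b1 x`, reported as the
#' odds ratio per unit of `x` with a Wald 95% CI on the log scale. Complete
#' separation is detected (fitted probabilities collapsing to 0/1) and
#' flagged rather than silently reported.
#'
#' @param outcome logical (or 0/1) event indicator per observation.
#' @param covariate numeric covariate per observation.
#' @return data.frame of class `AssocResult`: `analysis`, `estimate` (OR),
#'   `ci_low`, `ci_high`, `p_value`, `n`, `flag`.
#' @export
univariate_logistic <- function(outcome, covariate) {
  ok <- !is.na(outcome) & !is.na(covariate)
  outcome <- as.logical(outcome[ok]); covariate <- covariate[ok]
  if (length(unique(outcome)) < 2) stop("both outcome classes must be present")
  fit <- suppressWarnings(stats::glm(outcome ~ covariate, family = stats::binomial()))
  sm <- summary(fit)$coefficients
  sep <- !fit$converged || any(abs(fit$fitted.values - 0.5) > 0.5 - 1e-8) ||
    sm["covariate", "Std. Error"] > 100
  ci <- .wald_exp(sm["covariate", "Estimate"], sm["covariate", "Std. Error"])
  structure(data.frame(analysis = "logistic",
                       estimate = exp(sm["covariate", "Estimate"]),
                       ci_low = ci[1], ci_high = ci[2],
                       p_value = sm["covariate", "Pr(>|z|)"],
                       n = length(outcome),
                       flag = if (sep) "separation" else "",
                       stringsAsFactors = FALSE),
            class = c("AssocResult", "data.frame"))
}

#' Univariate ordinary-least-squares regression
#'
#' Slope `B` of `y ~ x` with its 95% confidence interval.
#'
#' @param y,x numeric vectors.
#' @return data.frame of class `AssocResult` with the slope as `estimate`.
#' @export
univariate_linear <- function(y, x) {
  ok <- !is.na(y) & !is.na(x)
  y <- y[ok]; x <- x[ok]
  if (length(y) < 3) stop("need n >= 3")
  if (stats::sd(x) == 0) stop("zero variance in x")
  fit <- stats::lm(y ~ x)
  # an exact fit trips harmless "perfect fit" warnings in summary/confint
  ci <- suppressWarnings(stats::confint(fit)["x", ])
  sm <- suppressWarnings(summary(fit)$coefficients)
  structure(data.frame(analysis = "linear", estimate = sm["x", "Estimate"],
                       ci_low = ci[1], ci_high = ci[2],
                       p_value = sm["x", "Pr(>|t|)"], n = length(y), flag = "",
                       stringsAsFactors = FALSE),
            class = c("AssocResult", "data.frame"))
}

#' Empirical ROC analysis with Youden-optimal cutoff
#'
#' The AUC is the pairwise concordance (Mann-Whitney) probability that an
#' event observation scores higher than a non-event one, ties counted 0.5;
#' the ROC is traced over all observed thresholds with the rule
#' "positive if covariate > threshold"; the optimal cutoff maximizes the
#' Youden index J = sensitivity + specificity - 1 (ties resolved toward the
#' lower cutoff). The AUC p-value comes from the normal-approximation
#' Wilcoxon rank-sum test.
#'
#' @param outcome logical event indicator.
#' @param covariate numeric marker, higher values indicating the event.
#' @return list of class `RocResult`: `auc`, `p_value`, `thresholds`
#'   (data.frame `cutoff`, `sensitivity`, `specificity`), `optimal_cutoff`,
#'   `sens_at_cutoff`, `spec_at_cutoff`, `n`.
#' @export
roc_analysis <- function(outcome, covariate) {
  ok <- !is.na(outcome) & !is.na(covariate)
  outcome <- as.logical(outcome[ok]); covariate <- covariate[ok]
  n1 <- sum(outcome); n0 <- sum(!outcome)
  if (n1 == 0 || n0 == 0) stop("both outcome classes must be present")
  x1 <- covariate[outcome]; x0 <- covariate[!outcome]
  # Mann-Whitney AUC via midranks (ties count 0.5)
  r <- rank(c(x1, x0))
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  p <- suppressWarnings(stats::wilcox.test(x1, x0, exact = FALSE,
                                           correct = FALSE)$p.value)
  cuts <- sort(unique(covariate))
  sens <- vapply(cuts, function(c) mean(x1 > c), numeric(1))
  spec <- vapply(cuts, function(c) mean(x0 <= c), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))[1]   # cuts ascending: first max = lowest cutoff
  structure(list(auc = auc, p_value = p,
                 thresholds = data.frame(cutoff = cuts, sensitivity = sens,
                                         specificity = spec),
                 optimal_cutoff = cuts[best], sens_at_cutoff = sens[best],
                 spec_at_cutoff = spec[best], n = n1 + n0),
            class = "RocResult")
}

#' @export
print.RocResult <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f (p = %.4g), optimal cutoff > %.4g (sens %.3f, spec %.3f), n = %d\n",
              x$auc, x$p_value, x$optimal_cutoff, x$sens_at_cutoff,
              x$spec_at_cutoff, x$n))
  invisible(x)
}

#' Univariate Cox proportional-hazards regression
#'
#' Partial-likelihood hazard ratio per unit covariate (Efron tie handling)
#' with a Wald 95% CI. A constant covariate is flagged as degenerate.
#'
#' @param time event/censoring times.
#' @param event logical event indicator.
#' @param covariate numeric covariate.
#' @return data.frame of class `AssocResult` with the HR as `estimate`.
#' @export
cox_univariate <- function(time, event, covariate) {
  ok <- !is.na(time) & !is.na(event) & !is.na(covariate)
  time <- time[ok]; event <- as.logical(event[ok]); covariate <- covariate[ok]
  if (sum(event) == 0) stop("no events")
  if (stats::sd(covariate) == 0) {
    return(structure(data.frame(analysis = "cox", estimate = NA_real_,
                                ci_low = NA_real_, ci_high = NA_real_,
                                p_value = NA_real_, n = length(time),
                                flag = "constant covariate",
                                stringsAsFactors = FALSE),
                     class = c("AssocResult", "data.frame")))
  }
  fit <- survival::coxph(survival::Surv(time, event) ~ covariate, ties = "efron")
  sm <- summary(fit)$coefficients
  ci <- .wald_exp(sm[1, "coef"], sm[1, "se(coef)"])
  structure(data.frame(analysis = "cox", estimate = exp(sm[1, "coef"]),
                       ci_low = ci[1], ci_high = ci[2],
                       p_value = sm[1, "Pr(>|z|)"], n = length(time), flag = "",
                       stringsAsFactors = FALSE),
            class = c("AssocResult", "data.frame"))
}

#' Kaplan-Meier curves and log-rank test for two groups
#'
#' Product-limit survival estimates per group and the 1-df log-rank
#' chi-square from the summed observed-minus-expected events over the
#' distinct event times.
#'
#' @param time event/censoring times (minutes).
#' @param event logical event indicator.
#' @param group two-level grouping vector.
#' @return list of class `SurvivalFit`: `fit` (a [survival::survfit()]
#'   object), `curves` (data.frame `group`, `time`, `survival`),
#'   `logrank_statistic`, `p_value`.
#' @export
km_logrank <- function(time, event, group) {
  ok <- !is.na(time) & !is.na(event) & !is.na(group)
  time <- time[ok]; event <- as.logical(event[ok]); group <- group[ok]
  g <- factor(group)
  if (nlevels(g) != 2 || any(table(g) == 0)) stop("need two nonempty groups")
  fit <- survival::survfit(survival::Surv(time, event) ~ g)
  # degenerate splits (zero log-rank variance) yield NaN, reported as such
  sd <- suppressWarnings(survival::survdiff(survival::Surv(time, event) ~ g, rho = 0))
  curves <- data.frame(
    group = rep(sub("^g=", "", names(fit$strata)), fit$strata),
    time = fit$time, survival = fit$surv, stringsAsFactors = FALSE)
  structure(list(fit = fit, curves = curves,
                 logrank_statistic = sd$chisq,
                 p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)),
            class = "SurvivalFit")
}

#' @export
print.SurvivalFit <- function(x, ...) {
  cat(sprintf("Kaplan-Meier, log-rank chi-square %.3f (1 df), p = %.4g\n",
              x$logrank_statistic, x$p_value))
  invisible(x)
}

#' Chi-square test of VF incidence by occlusion site
#'
#' Pearson chi-square on the 2x2 site-by-outcome table, without continuity
#' correction.
#'
#' @param site factor-like vector (e.g. LAD/LCX) per animal.
#' @param vf logical VF indicator per animal.
#' @return list with `statistic`, `p_value`, `table`.
#' @export
site_chisquare <- function(site, vf) {
  tab <- table(site, as.logical(vf))
  if (any(dim(tab) != 2)) stop("need a 2x2 table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) stop("empty margin")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = ct$p.value, table = tab)
}

#' Univariate VF-association battery over map summaries
#'
#' Runs [univariate_logistic()] of the VF outcome on each covariate over
#' the ischemic period, either pooling one row per animal per time-point
#' (`mode = "pooled"`; repeated animal rows, flagged as unclustered) or
#' reducing to each animal's maximum over the period
#' (`mode = "per_animal_max"`).
#'
#' @param summaries per animal x time-point summary table
#'   (from [summarize_cohort()]).
#' @param outcomes per-animal data.frame with `animal`, `vf`.
#' @param covariates covariate column names to test.
#' @param period inclusive minute range of ischemic time-points used.
#' @param mode pooling mode.
#' @return tidy data.frame: `analysis`, `covariate`, `mode`, `estimate`
#'   (OR), `ci_low`, `ci_high`, `p_value`, `n`, `flag`.
#' @export
vf_association_table <- function(summaries, outcomes,
                                 covariates = c("at_max", "dor", "aric_mean",
                                                "aric_min", "aric_max", "rr",
                                                "qtp_min", "qtp_c_min",
                                                "qt_max", "qtc_max",
                                                "tpe", "tpe_c"),
                                 period = c(1, 10),
                                 mode = c("pooled", "per_animal_max")) {
  mode <- match.arg(mode)
  d <- summaries[summaries$time_point >= period[1] &
                   summaries$time_point <= period[2], ]
  d <- merge(d, outcomes[, c("animal", "vf")], by = "animal")
  covariates <- intersect(covariates, names(d))
  out <- lapply(covariates, function(cv) {
    if (mode == "per_animal_max") {
      agg <- stats::aggregate(d[[cv]], by = list(animal = d$animal),
                              FUN = function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
      y <- outcomes$vf[match(agg$animal, outcomes$animal)]
      x <- agg$x
    } else {
      y <- d$vf; x <- d[[cv]]
    }
    res <- tryCatch(univariate_logistic(y, x), error = function(e) NULL)
    if (is.null(res)) return(NULL)
    res$covariate <- cv
    res$mode <- mode
    if (mode == "pooled" && res$flag == "") res$flag <- "repeated rows per animal, unclustered"
    res
  })
  out <- do.call(rbind, out)
  out[, c("analysis", "covariate", "mode", "estimate", "ci_low", "ci_high",
          "p_value", "n", "flag")]
}
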