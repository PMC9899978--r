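grid22 <- lead_grid(2, 2)

test_that("zone classification applies the strict >5 ms delay rule", {
  at_tab <- data.frame(
    lead = rep(grid22$lead, 2),
    time_point = rep(c(0, 2.5), each = 4),
    at = c(34, 30, 28, 32,    # baseline
           41, 35, 28, 32))   # 2.5 min: E01 +7 (core), E02 exactly +5 (not)
  z <- classify_zones(at_tab, grid22)
  expect_equal(as.character(z$zone[z$lead == "E01"]), "core")
  expect_false(any(z$zone[z$lead == "E02"] == "core"))
  # E02 (row 2, col 1) and E03 (row 1, col 2) are 4-neighbours of E01
  expect_setequal(z$lead[z$zone == "border"], c("E02", "E03"))
  expect_equal(as.character(z$zone[z$lead == "E04"]), "remote")
})

test_that("zero delay everywhere yields no core and no border leads", {
  at_tab <- data.frame(lead = rep(grid22$lead, 2),
                       time_point = rep(c(0, 1), each = 4), at = rep(30, 8))
  z <- classify_zones(at_tab, grid22)
  expect_true(all(z$zone == "remote"))
})

test_that("relative zoning mode uses a fraction of the baseline AT", {
  at_tab <- data.frame(lead = rep(grid22$lead, 2),
                       time_point = rep(c(0, 1), each = 4),
                       at = c(30, 30, 30, 30, 37, 35, 30, 30))
  z <- classify_zones(at_tab, grid22, mode = "rel", rel_threshold = 0.2)
  expect_equal(z$lead[z$zone == "core"], "E01")  # +7 > 6; +5 < 6
})

test_that("leads with missing baseline AT are excluded and logged", {
  at_tab <- data.frame(lead = rep(grid22$lead, 2),
                       time_point = rep(c(0, 1), each = 4),
                       at = c(NA, 30, 30, 30, 50, 30, 30, 30))
  z <- classify_zones(at_tab, grid22)
  expect_equal(attr(z, "excluded"), "E01")
  expect_false("E01" %in% z$lead)
})

test_that("dispersion of repolarization is the cross-lead RT range", {
  expect_equal(dispersion_of_repolarization(c(257, 200, 230)), 57)
  expect_equal(dispersion_of_repolarization(c(300, 300, 300)), 0)
  set.seed(8)
  v <- runif(20, 200, 320)
  expect_equal(dispersion_of_repolarization(sample(v)),
               dispersion_of_repolarization(v))
  expect_error(dispersion_of_repolarization(c(250, NA)), "two valid")
})

test_that("Tpeak-Tend dispersion spans earliest apex to latest end", {
  d <- tpeak_tend_dispersion(c(300, 310), c(380, 370), rr = 534)
  expect_equal(d$tpe, 80)
  expect_equal(d$tpe_c, bazett(80, 534))
  single <- tpeak_tend_dispersion(305, 371, rr = 1000)
  expect_equal(single$tpe, 66)
  expect_equal(single$tpe_c, 66)   # Bazett identity at RR 1000
  expect_error(tpeak_tend_dispersion(NA, NA, 500), "no valid")
})

test_that("RTc map is the elementwise AT + ARIc sum", {
  at <- c(E01 = 34, E02 = 30)
  aric <- c(E01 = 330, E02 = NA)
  rtc <- rtc_map(at, aric)
  expect_equal(unname(rtc["E01"]), 364)
  expect_true(is.na(rtc["E02"]))
  expect_equal(rtc_map(at, c(E01 = 100, E02 = 100)), at + 100)
  expect_error(rtc_map(at, c(E01 = 330, E09 = 300)), "mismatched")
})

test_that("time-point summaries take cross-lead extrema with per-metric missingness", {
  m <- data.frame(
    animal = "A01", time_point = 1,
    lead = c("E01", "E02", "E03", "I", "II", "III"),
    lead_kind = rep(c("epicardial_unipolar", "surface_ecg"), each = 3),
    rr = 534,
    qrs_onset = 100, at = c(34, 30, 28, NA, NA, NA),
    rt = c(291, 230, NA, NA, NA, NA),
    ari = c(257, 200, NA, NA, NA, NA),
    aric = c(350, 364, 310, NA, NA, NA),
    qt = c(NA, NA, NA, 331, 320, 310),
    qtc = c(NA, NA, NA, 455, 440, 430),
    qtp = c(NA, NA, NA, 281, 270, 260),
    qtp_c = c(NA, NA, NA, 384, 369, 356),
    t_peak = c(NA, NA, NA, 281, 270, 260),
    t_end = c(NA, NA, NA, 331, 320, 310))
  s <- summarize_timepoint(m)
  expect_equal(s$aric_max, 364)
  expect_equal(s$aric_min, 310)
  expect_equal(s$qtc_max, 455)
  expect_equal(s$at_max, 34)       # E03 missing rt still contributes at
  expect_equal(s$dor, 61)          # from the two valid RTs
  expect_equal(s$tpe, 331 - 260)
  expect_equal(s$n_epi, 3)
  # lead order must not matter
  s2 <- summarize_timepoint(m[sample(nrow(m)), ])
  s2$n_epi <- s$n_epi  # row order only
  expect_equal(s[, -1], s2[, -1], ignore_attr = TRUE)
})

test_that("the early-prolongation flag uses a strict 10 ms criterion", {
  expect_true(flag_early_prolongation(c("0" = 364, "1" = 377, "2.5" = 370)))
  expect_false(flag_early_prolongation(c("0" = 364, "1" = 374, "2.5" = 374)))
  expect_false(flag_early_prolongation(c("0" = 364, "1" = 360, "2.5" = 350)))
  expect_true(flag_early_prolongation(c("0" = 364, "2.5" = 380)))
  expect_error(flag_early_prolongation(c("1" = 377)), "baseline")
})

test_that("cohort summaries recover generator zone structure end to end", {
  ds <- make_test_cohort(n_animals = 2, noise_sd = 0, time_points = c(0, 1, 2.5, 5))
  meas <- measure_cohort(ds)
  epi <- meas[meas$lead_kind == "epicardial_unipolar", ]
  for (a in unique(epi$animal)) {
    z <- classify_zones(epi[epi$animal == a, c("lead", "time_point", "at")],
                        ds$grid, ischemia_tps = c(1, 2.5, 5))
    truth <- ds$zones[ds$zones$animal == a, ]
    expect_identical(sort(z$lead[z$zone == "core"]),
                     sort(truth$lead[truth$zone == "core"]))
    expect_identical(sort(z$lead[z$zone == "border"]),
                     sort(truth$lead[truth$zone == "border"]))
  }
  sc <- summarize_cohort(meas)
  expect_equal(nrow(sc$summaries), 8)
  expect_true(all(sc$summaries$aric_min <= sc$summaries$aric_mean + 1e-9))
  expect_true(all(sc$summaries$aric_mean <= sc$summaries$aric_max + 1e-9))
  expect_true(all(sc$summaries$dor >= 0))
})
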