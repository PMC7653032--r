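test_that("CDM tables round-trip through delimited text", {
  co <- simulate_cohort(site_spec("io", n_encounters = 15, seed = 3))
  dir <- withr::local_tempdir()
  write_cdm(co$tables, dir)
  back <- read_cdm(dir)
  expect_setequal(names(back), names(co$tables))
  expect_equal(as.data.frame(back$LAB_RESULT_CM),
               as.data.frame(co$tables$LAB_RESULT_CM))
  labs <- label_cohort(back)
  expect_gt(nrow(labs), 0)
})

test_that("eligibility filters apply in order with a tally", {
  cdm <- tiny_cdm()
  fl <- filter_eligible(cdm)
  # e2: one-day stay; e3: dialysis procedure before admission
  expect_setequal(fl$kept, c("e1", "e4"))
  expect_equal(unname(fl$tally["stay_lt_2d"]), 1L)
  expect_equal(unname(fl$tally["prior_rrt"]), 1L)
  expect_equal(sum(fl$tally), 2L)
  expect_true(all(fl$cdm$LAB_RESULT_CM$encounter_id %in% fl$kept))

  # age out of range
  cdm2 <- tiny_cdm()
  cdm2$ENCOUNTER$age[1] <- 95
  expect_false("e1" %in% filter_eligible(cdm2)$kept)

  # eGFR below threshold at admission (high SCr, old age)
  cdm3 <- tiny_cdm()
  cdm3$LAB_RESULT_CM[encounter_id == "e4" & time == 0.25, value := 6.0]
  cdm3$ENCOUNTER[encounter_id == "e4", age := 85]
  fl3 <- filter_eligible(cdm3)
  expect_false("e4" %in% fl3$kept)
  expect_equal(unname(fl3$tally["egfr_lt_threshold"]), 1L)

  # burn diagnosis
  cdm4 <- tiny_cdm()
  cdm4$DIAGNOSIS <- rbind(cdm4$DIAGNOSIS, data.table::data.table(
    encounter_id = "e1", code = "T21.20XA", vocabulary = "ICD10", time = 0.1))
  expect_false("e1" %in% filter_eligible(cdm4)$kept)

  expect_error(filter_eligible(list(ENCOUNTER = data.frame(x = 1))),
               "missing columns")
})

test_that("CKD-EPI eGFR reproduces known reference values", {
  # 60-year-old male, SCr 1.0: 141 * (1/0.9)^-1.209 * 0.993^60 = 81.4
  expect_equal(egfr_ckdepi(1.0, 60, FALSE), 81.44, tolerance = 1e-3)
  expect_gt(egfr_ckdepi(1.0, 60, TRUE, black = TRUE),
            egfr_ckdepi(1.0, 60, TRUE))
  expect_lt(egfr_ckdepi(6.0, 85, FALSE), 15)
})

test_that("percentile trimming removes exactly the out-of-bound values", {
  set.seed(7)
  x <- rnorm(1000)
  q <- quantile(x, c(0.01, 0.99), names = FALSE)
  expected_removed <- sum(x < q[1] | x > q[2])
  tr <- trim_outliers(x)
  expect_equal(sum(is.na(tr)), expected_removed)
  expect_true(expected_removed >= 10 && expected_removed <= 30)  # ~2% of 1000
  expect_equal(trim_outliers(rep(5, 200)), rep(5, 200))
  expect_warning(short <- trim_outliers(1:10), "skipped")
  expect_equal(short, 1:10)
})

test_that("daily matrix encodes cumulative exposure, held labs and BP slopes", {
  enc <- data.table::data.table(encounter_id = "e1", patient_id = "e1",
                                age = 50, admission_time = 0,
                                discharge_time = 5, site = "t")
  demo <- data.table::data.table(patient_id = "e1", sex = "F", race = "01",
                                 birth_offset_years = 50)
  med <- data.table::data.table(encounter_id = "e1", code = "11124",
                                vocabulary = "RXNORM",
                                time = c(0.4, 1.4, 2.4))
  lab <- data.table::data.table(encounter_id = "e1", code = "2160-0",
                                value = c(1.0, 1.4), unit = "mg/dL",
                                time = c(0.25, 2.25))
  vit <- data.table::data.table(encounter_id = "e1",
                                time = c(8, 12) / 24,
                                systolic = c(120, 110),
                                diastolic = c(80, 70), bmi = NA_real_)
  cdm <- list(ENCOUNTER = enc, DEMOGRAPHIC = demo, PRESCRIBING = med,
              LAB_RESULT_CM = lab, VITAL = vit)
  m <- build_daily_matrix(cdm, max_day = 7)
  expect_equal(m$med_11124_cumdays, c(1, 2, 3, 3, 3))
  expect_equal(m$lab_2160_0, c(1.0, 1.0, 1.4, 1.4, 1.4))   # sample-and-hold
  expect_equal(m$lab_2160_0_chg[3], 0.4)
  # two-point least squares: (110 - 120) / (12 - 8) = -2.5 mmHg/hour
  expect_equal(m$sbp_slope[1], -2.5)
  expect_equal(m$dbp_slope[1], -2.5)
  expect_equal(m$sbp_min[1], 110)
  expect_equal(m$sbp_max[1], 120)
  expect_equal(m$sex_F, rep(1L, 5))
  dict <- attr(m, "dictionary")
  expect_true(all(c("feature", "kind", "source") %in% names(dict)))
  expect_equal(dict$kind[dict$feature == "med_11124_cumdays"],
               "cumulative_days")
})

test_that("sample-and-hold never moves information backward in time", {
  co <- simulate_cohort(site_spec("hold", n_encounters = 40, seed = 9))
  full <- build_daily_matrix(co$tables, max_day = 7)
  # drop every observation after the end of day 3 and rebuild
  trunc <- lapply(co$tables, function(tb) {
    if ("time" %in% names(tb)) {
      enc <- co$tables$ENCOUNTER[, c("encounter_id", "admission_time")]
      if ("encounter_id" %in% names(tb)) {
        adm <- enc$admission_time[match(tb$encounter_id, enc$encounter_id)]
        tb <- tb[(tb$time - adm) < 3 | is.na(adm)]
      }
      tb
    } else tb
  })
  part <- build_daily_matrix(trunc, max_day = 7)
  shared <- intersect(names(full), names(part))
  a <- full[full$day <= 3, shared, with = FALSE]
  b <- part[part$day <= 3, shared, with = FALSE]
  data.table::setkey(a, encounter_id, day); data.table::setkey(b, encounter_id, day)
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("discrete-time rows follow the at-risk window rules", {
  mk_labels <- function(onsets_dt) {
    lt <- data.table::data.table(encounter_id = character(), day = integer(),
                                 stage = integer(), censored = integer())
    data.table::setattr(lt, "onsets", onsets_dt)
    lt
  }
  mat <- data.table::CJ(encounter_id = "e1", day = 1:7)
  mat[, f1 := day * 1.0]
  on <- data.table::data.table(encounter_id = "e1", censor_day = 7L,
                               onset_stage1 = 5L, onset_stage2 = 5L,
                               onset_stage3 = NA_integer_)
  rows <- assemble_rows(mat, mk_labels(on), dt = 2, min_stage = 2)
  expect_equal(rows$day, 1:4)
  expect_equal(rows$outcome, c(0L, 0L, 1L, 1L))

  on2 <- data.table::data.table(encounter_id = "e1", censor_day = 7L,
                                onset_stage1 = NA_integer_,
                                onset_stage2 = NA_integer_,
                                onset_stage3 = NA_integer_)
  rows2 <- assemble_rows(mat, mk_labels(on2), dt = 2, min_stage = 2)
  expect_equal(rows2$day, 1:5)
  expect_true(all(rows2$outcome == 0L))

  on3 <- data.table::copy(on)[, onset_stage2 := 1L]
  expect_equal(nrow(assemble_rows(mat, mk_labels(on3), dt = 2, min_stage = 2)),
               0L)
  expect_error(assemble_rows(mat, mk_labels(on), dt = 3), "must be 1 or 2")
})

test_that("row assembly matches the window enumerator on simulated cohorts", {
  co <- simulate_cohort(site_spec("rows", n_encounters = 120, seed = 31))
  ps <- prepare_site(co, filter = FALSE, trim = FALSE)
  onsets <- attr(ps$labels, "onsets")
  for (dt_h in 1:2) {
    rows <- assemble_rows(ps$matrix, ps$labels, dt = dt_h, min_stage = 2)
    for (i in seq_len(nrow(onsets))) {
      want <- oracle_row_plan(onsets$onset_stage2[i], onsets$censor_day[i],
                              dt_h)
      got <- rows[rows$encounter_id == onsets$encounter_id[i], ]
      expect_equal(got$day, want$day)
      expect_equal(got$outcome, want$outcome)
    }
  }
})

test_that("cumulative exposure features never decrease within an encounter", {
  co <- simulate_cohort(site_spec("mono", n_encounters = 60, seed = 13))
  m <- build_daily_matrix(co$tables, max_day = 7)
  cum_cols <- grep("_cumdays$", names(m), value = TRUE)
  expect_true(length(cum_cols) >= 1)
  for (cc in cum_cols) {
    diffs <- m[, list(ok = all(diff(get(cc)) >= 0)), by = encounter_id]$ok
    expect_true(all(diffs))
  }
})
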