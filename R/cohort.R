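# Eligibility filtering and automated daily feature curation for CDM-style
# EHR tables (PCORnet-like naming: DEMOGRAPHIC, ENCOUNTER, LAB_RESULT_CM,
# PRESCRIBING, VITAL, DIAGNOSIS, PROCEDURES).

#' Read / write CDM-like delimited tables
#'
#' `read_cdm()` reads the tab-separated tables found in `dir` (one file per
#' table, named `<TABLE>.tsv`); `write_cdm()` writes them back.
#'
#' @param dir directory containing the tables.
#' @return `read_cdm()`: a named list of data.tables.
#' @export
read_cdm <- function(dir) {
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  if (!length(files)) stop("no .tsv tables found in ", dir)
  out <- lapply(files, data.table::fread)
  names(out) <- toupper(sub("\\.tsv$", "", basename(files)))
  out
}

#' @rdname read_cdm
#' @param cdm named list of tables (e.g. `simulate_cohort(spec)$tables`).
#' @export
write_cdm <- function(cdm, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(cdm)) {
    data.table::fwrite(cdm[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t")
  }
  invisible(dir)
}

#' CKD-EPI (2009) estimated glomerular filtration rate
#'
#' @param scr serum creatinine, mg/dL.
#' @param age years.
#' @param female logical.
#' @param black logical (2009 equation race coefficient; included because
#'   eligibility screening on historical records used it).
#' @return eGFR in mL/min/1.73 m^2.
#' @export
egfr_ckdepi <- function(scr, age, female, black = FALSE) {
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  141 * pmin(scr / kappa, 1)^alpha * pmax(scr / kappa, 1)^(-1.209) *
    0.993^age * ifelse(female, 1.018, 1) * ifelse(black, 1.159, 1)
}

sanitize_code <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

#' Apply eligibility and exclusion filters to a CDM cohort
#'
#' Sequentially keeps stays of at least 2 days with at least two SCr
#' records and age 18-90, then removes encounters with admission
#' eGFR < 15 mL/min/1.73 m^2, any dialysis/transplant procedure before
#' admission, RRT within 48 h of the first documented SCr, or a burn
#' diagnosis (ICD-9 940-949 / ICD-10 T20-T32 prefixes).
#'
#' @param cdm named list of CDM-like tables.
#' @param scr_loinc LOINC code set for serum creatinine.
#' @param rrt_codes dialysis/transplant procedure codes.
#' @param egfr_threshold exclusion threshold, mL/min/1.73 m^2.
#' @param burn_prefixes regular expression of burn diagnosis prefixes.
#' @return List with `cdm` (filtered tables), `kept` (encounter ids) and
#'   `tally` (named integer: encounters removed per rule, in application
#'   order).
#' @export
filter_eligible <- function(cdm, scr_loinc = "2160-0",
                            rrt_codes = c("90935", "90937", "90945", "50360"),
                            egfr_threshold = 15,
                            burn_prefixes = "^(94[0-9]|T2[0-9]|T3[0-2])") {
  enc <- data.table::as.data.table(cdm$ENCOUNTER)
  lab <- data.table::as.data.table(cdm$LAB_RESULT_CM)
  need <- c("encounter_id", "admission_time", "discharge_time", "age")
  if (!all(need %in% names(enc))) stop("ENCOUNTER table missing columns: ",
                                       paste(setdiff(need, names(enc)), collapse = ", "))
  scr <- lab[lab$code %in% scr_loinc]
  tally <- c(stay_lt_2d = 0L, scr_lt_2 = 0L, age_out_of_range = 0L,
             egfr_lt_threshold = 0L, prior_rrt = 0L, rrt_within_48h = 0L,
             burn = 0L)
  keep <- enc$encounter_id

  drop_rule <- function(keep, bad, rule) {
    bad <- intersect(bad, keep)
    tally[rule] <<- length(bad)
    setdiff(keep, bad)
  }

  los <- ceiling(enc$discharge_time - enc$admission_time)
  keep <- drop_rule(keep, enc$encounter_id[los < 2], "stay_lt_2d")
  n_scr <- scr[, .N, by = encounter_id]
  enough <- n_scr$encounter_id[n_scr$N >= 2L]
  keep <- drop_rule(keep, setdiff(enc$encounter_id, enough), "scr_lt_2")
  keep <- drop_rule(keep, enc$encounter_id[enc$age < 18 | enc$age > 90],
                    "age_out_of_range")

  # admission eGFR from the earliest SCr
  demo <- data.table::as.data.table(cdm$DEMOGRAPHIC)
  first_scr <- scr[order(time), .SD[1L], by = encounter_id]
  emap <- merge(first_scr, enc[, list(encounter_id, age)], by = "encounter_id")
  emap <- merge(emap, demo[, list(encounter_id = patient_id, sex, race)],
                by = "encounter_id", all.x = TRUE)
  emap[, egfr := egfr_ckdepi(value, age, !is.na(sex) & sex == "F",
                             !is.na(race) & race == "03")]
  keep <- drop_rule(keep, emap$encounter_id[emap$egfr < egfr_threshold],
                    "egfr_lt_threshold")

  px <- data.table::as.data.table(cdm$PROCEDURES)
  if (!is.null(px) && nrow(px)) {
    px <- merge(px, enc[, list(encounter_id, admission_time)],
                by = "encounter_id")
    prior <- px[code %in% rrt_codes & time < admission_time, unique(encounter_id)]
    keep <- drop_rule(keep, prior, "prior_rrt")
    early <- merge(px[code %in% rrt_codes],
                   first_scr[, list(encounter_id, first_scr_time = time)],
                   by = "encounter_id")
    bad <- early[time >= first_scr_time & time <= first_scr_time + 2,
                 unique(encounter_id)]
    keep <- drop_rule(keep, bad, "rrt_within_48h")
  }

  dx <- data.table::as.data.table(cdm$DIAGNOSIS)
  if (!is.null(dx) && nrow(dx)) {
    burn <- dx[grepl(burn_prefixes, code), unique(encounter_id)]
    keep <- drop_rule(keep, burn, "burn")
  }

  out <- lapply(cdm, function(tb) {
    tb <- data.table::as.data.table(tb)
    if ("encounter_id" %in% names(tb)) tb[encounter_id %in% keep] else tb
  })
  if (!is.null(out$DEMOGRAPHIC) && "patient_id" %in% names(out$DEMOGRAPHIC)) {
    pid <- enc[encounter_id %in% keep, unique(patient_id)]
    out$DEMOGRAPHIC <- out$DEMOGRAPHIC[patient_id %in% pid]
  }
  list(cdm = out, kept = keep, tally = tally)
}

#' Trim numeric outliers beyond the 1st/99th percentile
#'
#' Values strictly below the 1st or strictly above the 99th empirical
#' percentile are set to `NA`. With fewer than `min_n` observations the
#' percentiles are unstable and the vector is returned untouched with a
#' warning.
#'
#' @param x numeric vector.
#' @param probs lower/upper percentile bounds.
#' @param min_n minimum observations required to trim.
#' @return `x` with outliers replaced by `NA`.
#' @export
trim_outliers <- function(x, probs = c(0.01, 0.99), min_n = 100) {
  ok <- is.finite(x)
  if (sum(ok) < min_n) {
    warning(sprintf("only %d values (< %d): outlier trimming skipped",
                    sum(ok), min_n))
    return(x)
  }
  q <- stats::quantile(x[ok], probs = probs, names = FALSE, type = 7)
  x[ok & (x < q[1] | x > q[2])] <- NA_real_
  x
}

#' Trim outliers in every numeric observation stream of a cohort
#'
#' Applies [trim_outliers()] per lab code and per vital-sign column over the
#' whole population, dropping the trimmed records.
#'
#' @param cdm named list of CDM-like tables.
#' @param min_n minimum observations per stream to trim.
#' @return The cohort with outlying numeric records removed.
#' @export
trim_cohort_outliers <- function(cdm, min_n = 100) {
  lab <- data.table::as.data.table(cdm$LAB_RESULT_CM)
  lab[, value := suppressWarnings(trim_outliers(value, min_n = min_n)),
      by = code]
  cdm$LAB_RESULT_CM <- lab[!is.na(value)]
  if (!is.null(cdm$VITAL)) {
    vit <- data.table::as.data.table(cdm$VITAL)
    for (col in intersect(c("systolic", "diastolic", "bmi"), names(vit))) {
      vit[, (col) := suppressWarnings(trim_outliers(get(col), min_n = min_n))]
    }
    cdm$VITAL <- vit
  }
  cdm
}

ls_slope <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 2L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  vx <- stats::var(x)
  if (vx == 0) return(NA_real_)
  stats::cov(x, y) / vx
}

#' Build the daily feature matrix of a cohort
#'
#' One row per (encounter, day) with: per-lab most-recent value of the day
#' and change since the last observation; per-day min/max of systolic and
#' diastolic pressure and their within-day least-squares hourly slopes; BMI;
#' cumulative medication exposure days; binary presence of diagnosis and
#' procedure codes (sticky from first coding); demographics (age, sex, race
#' one-hot); and the day index. Gaps are filled by sample-and-hold from
#' earlier days only, so a feature at day t never uses information after
#' day t.
#'
#' @param cdm named list of CDM-like tables (after filtering/trimming).
#' @param max_day last day to materialise (defaults to 7, the usual
#'   censoring horizon).
#' @param lab_lookback days of pre-admission lab history folded into day 1.
#' @param dx_lookback days of pre-admission diagnosis/procedure history
#'   treated as present on admission.
#' @return A [data.table::data.table] keyed by (`encounter_id`, `day`) with
#'   attribute `dictionary` (feature name, kind, source).
#' @export
build_daily_matrix <- function(cdm, max_day = 7, lab_lookback = 7,
                               dx_lookback = 90) {
  enc <- data.table::as.data.table(cdm$ENCOUNTER)
  enc[, n_days := pmin(pmax(1L, as.integer(ceiling(discharge_time - admission_time))),
                       as.integer(max_day))]
  grid <- enc[, list(day = seq_len(n_days)), by = list(encounter_id, admission_time, age)]
  data.table::setkey(grid, encounter_id, day)
  dict <- list(data.frame(feature = c("day", "age"),
                          kind = c("numeric", "numeric"),
                          source = c("derived", "DEMOGRAPHIC")))

  # ---- labs: most recent per day, sample-and-hold, change feature --------
  lab <- data.table::as.data.table(cdm$LAB_RESULT_CM)
  if (nrow(lab)) {
    lab <- merge(lab, enc[, list(encounter_id, admission_time)],
                 by = "encounter_id")
    lab[, day := as.integer(floor(time - admission_time)) + 1L]
    lab <- lab[day >= 1L - lab_lookback & day <= max_day & is.finite(value)]
    lab[, day := pmax(day, 1L)]  # recent pre-admission history enters day 1
    data.table::setorder(lab, encounter_id, code, time)
    lab[, chg := value - data.table::shift(value), by = list(encounter_id, code)]
    daily <- lab[, list(value = value[.N], chg = chg[.N]),
                 by = list(encounter_id, code, day)]
    for (cd in sort(unique(daily$code))) {
      vcol <- paste0("lab_", sanitize_code(cd))
      ccol <- paste0(vcol, "_chg")
      sub <- daily[code == cd, list(encounter_id, day, value, chg)]
      data.table::setnames(sub, c("value", "chg"), c(vcol, ccol))
      grid <- merge(grid, sub, by = c("encounter_id", "day"), all.x = TRUE)
      grid[, (vcol) := data.table::nafill(get(vcol), type = "locf"),
           by = encounter_id]
      grid[, (ccol) := data.table::nafill(get(ccol), type = "locf"),
           by = encounter_id]
      dict[[length(dict) + 1L]] <- data.frame(
        feature = c(vcol, ccol), kind = "numeric", source = paste0("LOINC:", cd))
    }
  }

  # ---- vitals: BP min/max + within-day hourly slope, BMI -----------------
  vit <- data.table::as.data.table(cdm$VITAL)
  if (!is.null(vit) && nrow(vit)) {
    vit <- merge(vit, enc[, list(encounter_id, admission_time)],
                 by = "encounter_id")
    vit[, day := as.integer(floor(time - admission_time)) + 1L]
    vit[, hour := (time - admission_time - (day - 1L)) * 24]
    vit <- vit[day >= 1L & day <= max_day]
    bp <- vit[is.finite(systolic) | is.finite(diastolic),
              list(sbp_min = suppressWarnings(min(systolic, na.rm = TRUE)),
                   sbp_max = suppressWarnings(max(systolic, na.rm = TRUE)),
                   dbp_min = suppressWarnings(min(diastolic, na.rm = TRUE)),
                   dbp_max = suppressWarnings(max(diastolic, na.rm = TRUE)),
                   sbp_slope = ls_slope(hour, systolic),
                   dbp_slope = ls_slope(hour, diastolic)),
              by = list(encounter_id, day)]
    for (col in setdiff(names(bp), c("encounter_id", "day"))) {
      bp[!is.finite(get(col)), (col) := NA_real_]
    }
    grid <- merge(grid, bp, by = c("encounter_id", "day"), all.x = TRUE)
    bpcols <- setdiff(names(bp), c("encounter_id", "day"))
    grid[, (bpcols) := lapply(.SD, data.table::nafill, type = "locf"),
         .SDcols = bpcols, by = encounter_id]
    dict[[length(dict) + 1L]] <- data.frame(feature = bpcols, kind = "numeric",
                                            source = "VITAL")
    if ("bmi" %in% names(vit) && any(is.finite(vit$bmi))) {
      bm <- vit[is.finite(bmi), list(bmi = bmi[.N]), by = list(encounter_id, day)]
      grid <- merge(grid, bm, by = c("encounter_id", "day"), all.x = TRUE)
      grid[, bmi := data.table::nafill(bmi, type = "locf"), by = encounter_id]
      dict[[length(dict) + 1L]] <- data.frame(feature = "bmi",
                                              kind = "numeric", source = "VITAL")
    }
  }

  # ---- medications: cumulative exposure days -----------------------------
  med <- data.table::as.data.table(cdm$PRESCRIBING)
  if (!is.null(med) && nrow(med)) {
    med <- merge(med, enc[, list(encounter_id, admission_time)],
                 by = "encounter_id")
    med[, day := as.integer(floor(time - admission_time)) + 1L]
    med <- unique(med[day >= 1L & day <= max_day,
                      list(encounter_id, code, day)])
    for (cd in sort(unique(med$code))) {
      col <- paste0("med_", sanitize_code(cd), "_cumdays")
      sub <- med[code == cd][, exp_day := 1L]
      grid <- merge(grid, sub[, list(encounter_id, day, exp_day)],
                    by = c("encounter_id", "day"), all.x = TRUE)
      grid[is.na(exp_day), exp_day := 0L]
      grid[, (col) := cumsum(exp_day), by = encounter_id]
      grid[, exp_day := NULL]
      dict[[length(dict) + 1L]] <- data.frame(
        feature = col, kind = "cumulative_days", source = paste0("RXNORM:", cd))
    }
  }

  # ---- diagnoses / procedures: sticky binary presence --------------------
  for (tb in c("DIAGNOSIS", "PROCEDURES")) {
    dd <- data.table::as.data.table(cdm[[tb]])
    if (is.null(dd) || !nrow(dd)) next
    pref <- if (tb == "DIAGNOSIS") "dx_" else "px_"
    dd <- merge(dd, enc[, list(encounter_id, admission_time)],
                by = "encounter_id")
    dd <- dd[time - admission_time >= -dx_lookback]
    dd[, day := pmax(1L, as.integer(floor(time - admission_time)) + 1L)]
    first <- dd[, list(first_day = min(day)), by = list(encounter_id, code)]
    for (cd in sort(unique(first$code))) {
      col <- paste0(pref, sanitize_code(cd))
      sub <- first[code == cd, list(encounter_id, first_day)]
      grid <- merge(grid, sub, by = "encounter_id", all.x = TRUE)
      grid[, (col) := as.integer(!is.na(first_day) & day >= first_day)]
      grid[, first_day := NULL]
      dict[[length(dict) + 1L]] <- data.frame(feature = col, kind = "binary",
                                              source = paste0(tb, ":", cd))
    }
  }

  # ---- demographics one-hot ----------------------------------------------
  demo <- data.table::as.data.table(cdm$DEMOGRAPHIC)
  if (!is.null(demo) && nrow(demo)) {
    dd <- demo[, list(encounter_id = patient_id, sex, race)]
    dd <- merge(enc[, list(encounter_id, patient_id)],
                demo, by = "patient_id")[, list(encounter_id, sex, race)]
    dd[, sex_F := as.integer(!is.na(sex) & sex == "F")]
    onehots <- "sex_F"
    for (rc in sort(unique(dd$race[!is.na(dd$race)]))) {
      col <- paste0("race_", sanitize_code(as.character(rc)))
      dd[, (col) := as.integer(!is.na(race) & race == rc)]
      onehots <- c(onehots, col)
    }
    grid <- merge(grid, dd[, c("encounter_id", onehots), with = FALSE],
                  by = "encounter_id", all.x = TRUE)
    dict[[length(dict) + 1L]] <- data.frame(feature = onehots, kind = "binary",
                                            source = "DEMOGRAPHIC")
  }

  grid[, admission_time := NULL]
  data.table::setkey(grid, encounter_id, day)
  data.table::setattr(grid, "dictionary", do.call(rbind, dict))
  grid[]
}

#' Assemble discrete-time survival design rows
#'
#' Expands the daily feature matrix into person-period rows for the task
#' "first onset of stage >= `min_stage` within `(t, t + dt]`". Encounters
#' leave the risk set at event or censoring: with onset at day `o` the rows
#' are `t = 1..o-1` (the last `dt` of them labeled 1); without an event the
#' rows are `t = 1..censor_day - dt`, all 0 (windows extending past
#' discharge or the censoring horizon are dropped as right-censored).
#'
#' @param matrix daily feature matrix from [build_daily_matrix()].
#' @param labels label table from [label_cohort()] (carries the per-encounter
#'   onsets attribute).
#' @param dt prediction horizon in days, 1 or 2.
#' @param min_stage target stage threshold in 1:3.
#' @return A `discrete_time_dataset`: data.table with `encounter_id`, `day`
#'   (= t), the feature columns and `outcome`; attributes `dt`, `min_stage`,
#'   `feature_cols`, `dictionary`.
#' @export
assemble_rows <- function(matrix, labels, dt = 2, min_stage = 2) {
  if (!dt %in% c(1L, 2L)) stop("`dt` must be 1 or 2")
  stopifnot(min_stage %in% 1:3)
  onsets <- attr(labels, "onsets")
  if (is.null(onsets)) stop("`labels` must carry the onsets attribute from label_cohort()")
  ocol <- paste0("onset_stage", min_stage)
  plan <- data.table::as.data.table(onsets)[, list(
    encounter_id, onset = get(ocol), censor_day)]
  plan[, t_max := ifelse(is.na(onset), censor_day - dt, onset - 1L)]
  plan <- plan[t_max >= 1L]
  if (nrow(plan)) {
    rows <- plan[, list(day = seq_len(t_max)),
                 by = list(encounter_id, onset)]
    rows[, outcome := as.integer(!is.na(onset) & onset <= day + dt)]
    rows[, onset := NULL]
  } else {
    rows <- data.table::data.table(encounter_id = plan$encounter_id,
                                   day = integer(), outcome = integer())
  }
  out <- merge(rows, matrix, by = c("encounter_id", "day"))
  data.table::setkey(out, encounter_id, day)
  feature_cols <- setdiff(names(out), c("encounter_id", "outcome"))
  data.table::setattr(out, "dt", as.integer(dt))
  data.table::setattr(out, "min_stage", as.integer(min_stage))
  data.table::setattr(out, "feature_cols", feature_cols)
  data.table::setattr(out, "dictionary", attr(matrix, "dictionary"))
  class(out) <- c("discrete_time_dataset", class(out))
  out[]
}
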