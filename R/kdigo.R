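# KDIGO serum-creatinine staging and discrete-time AKI labels.
#
# Times are numeric days relative to an arbitrary origin; admission day is
# calendar day 1 of the stay, so a measurement at time t maps to day index
# floor(t - admission_time) + 1. Pre-admission measurements (t < admission)
# are allowed and participate in baseline lookback only.

#' Serum-creatinine series for one encounter
#'
#' Bundles the longitudinal serum creatinine (SCr, mg/dL) of one inpatient
#' encounter together with the stay boundaries and any renal replacement
#' therapy (RRT) initiation times. This is the input to KDIGO staging.
#'
#' @param encounter_id scalar identifier.
#' @param times numeric times of the SCr measurements, in days. May include
#'   pre-admission values (times before `admission_time`).
#' @param values SCr results in mg/dL, all positive.
#' @param admission_time,discharge_time stay boundaries (days,
#'   `admission_time <= discharge_time`).
#' @param rrt_times numeric times at which RRT (dialysis) was initiated;
#'   empty when no RRT occurred.
#' @return An object of class `scr_series`.
#' @export
scr_series <- function(encounter_id, times, values, admission_time = 0,
                       discharge_time, rrt_times = numeric()) {
  if (length(times) != length(values)) {
    stop("`times` and `values` must have equal length")
  }
  if (length(values) > 0 && any(!is.finite(values) | values <= 0)) {
    stop("SCr values must be finite and positive")
  }
  if (admission_time > discharge_time) {
    stop("admission_time must not exceed discharge_time")
  }
  o <- order(times)
  structure(
    list(
      encounter_id = encounter_id,
      times = as.numeric(times)[o],
      values = as.numeric(values)[o],
      admission_time = as.numeric(admission_time),
      discharge_time = as.numeric(discharge_time),
      rrt_times = sort(as.numeric(rrt_times))
    ),
    class = "scr_series"
  )
}

#' @export
print.scr_series <- function(x, ...) {
  cat(sprintf(
    "<scr_series> encounter %s: %d measurement(s), stay [%.2f, %.2f]%s\n",
    format(x$encounter_id), length(x$values), x$admission_time,
    x$discharge_time,
    if (length(x$rrt_times)) sprintf(", RRT at %s", paste(round(x$rrt_times, 2), collapse = ", ")) else ""
  ))
  invisible(x)
}

los_days <- function(scr) {
  max(1L, as.integer(ceiling(scr$discharge_time - scr$admission_time)))
}

day_index <- function(scr, t) {
  as.integer(floor(t - scr$admission_time)) + 1L
}

#' Assign a baseline SCr to every measurement
#'
#' The baseline for a measurement is the most recent SCr strictly earlier in
#' time and within `lookback_days` (pre-admission records included). When no
#' such record exists the admission SCr (first measurement at or after
#' admission) is used; the degenerate first measurement is its own baseline.
#'
#' @param scr an [scr_series()].
#' @param lookback_days lookback window for prior measurements, in days.
#' @return A data.frame with one row per measurement: `time`, `value`,
#'   `baseline` (mg/dL) and `source` (`"prior_measurement"` or
#'   `"admission_value"`).
#' @export
assign_baselines <- function(scr, lookback_days = 7) {
  stopifnot(inherits(scr, "scr_series"))
  n <- length(scr$values)
  if (n == 0L) stop("no SCr measurements in series")
  in_adm <- which(scr$times >= scr$admission_time)
  admission_scr <- if (length(in_adm)) scr$values[in_adm[1L]] else scr$values[1L]
  baseline <- numeric(n)
  source <- character(n)
  for (i in seq_len(n)) {
    prior <- which(scr$times < scr$times[i] &
                     scr$times >= scr$times[i] - lookback_days)
    if (length(prior)) {
      baseline[i] <- scr$values[max(prior)]
      source[i] <- "prior_measurement"
    } else {
      baseline[i] <- admission_scr
      source[i] <- "admission_value"
    }
  }
  data.frame(time = scr$times, value = scr$values,
             baseline = baseline, source = source)
}

#' KDIGO stage of a single SCr measurement
#'
#' Applies the SCr-based KDIGO criteria (urine output is not used):
#' stage 3 for RRT initiation, SCr more than 3x baseline, or SCr >= 4 mg/dL
#' reached through an acute rise of >= 0.3 mg/dL within 48 h; stage 2 for a
#' baseline ratio in \[2, 3); stage 1 ("any AKI") for a rise of >= 0.3 mg/dL
#' within 48 h or a ratio >= 1.5. The highest qualifying stage wins. All
#' arguments are vectorised.
#'
#' @param current SCr value (mg/dL).
#' @param baseline baseline SCr (mg/dL, positive).
#' @param delta48 rise in SCr over the preceding 48 h (mg/dL).
#' @param rrt_started logical, RRT initiated at or before this measurement.
#' @return Integer stage in `0:3`.
#' @export
stage_measurement <- function(current, baseline, delta48 = 0,
                              rrt_started = FALSE) {
  n <- max(length(current), length(baseline), length(delta48),
           length(rrt_started))
  current <- rep_len(current, n)
  baseline <- rep_len(baseline, n)
  delta48 <- rep_len(delta48, n)
  rrt_started <- rep_len(rrt_started, n)
  if (any(!is.finite(current) | current <= 0) ||
      any(!is.finite(baseline) | baseline <= 0)) {
    stop("`current` and `baseline` must be finite and positive")
  }
  ratio <- current / baseline
  stage <- integer(n)
  stage[delta48 >= 0.3 | ratio >= 1.5] <- 1L
  stage[ratio >= 2.0 & ratio < 3.0] <- 2L
  stage[rrt_started | ratio > 3.0 | (current >= 4.0 & delta48 >= 0.3)] <- 3L
  stage
}

# Acute 48-h rise for each measurement: current minus the reference SCr among
# strictly earlier measurements within the closed 48-h (2-day) window.
# reference = "min" (default, most conservative) or "recent".
delta48_rise <- function(scr, reference = c("min", "recent"), window_days = 2) {
  reference <- match.arg(reference)
  n <- length(scr$values)
  out <- numeric(n)
  for (i in seq_len(n)) {
    w <- which(scr$times < scr$times[i] &
                 scr$times >= scr$times[i] - window_days)
    if (length(w)) {
      ref <- if (reference == "min") min(scr$values[w]) else scr$values[max(w)]
      out[i] <- scr$values[i] - ref
    }
  }
  out
}

#' Per-day KDIGO stages with right-censoring
#'
#' Evaluates the KDIGO stage at every SCr measurement (baseline per
#' [assign_baselines()], 48-h delta against the minimum — or most recent,
#' see `delta48_ref` — prior SCr in the closed 48-h window) and carries each
#' stage forward in time until the next measurement. Days after RRT
#' initiation are stage 3. The sequence covers days
#' `1..min(length_of_stay, tau)`; `tau` imposes independent right-censoring.
#'
#' @param scr an [scr_series()].
#' @param tau maximum follow-up in days (default 7). `Inf` disables
#'   censoring beyond the stay itself.
#' @param lookback_days baseline lookback window (days).
#' @param delta48_ref `"min"` (default) or `"recent"`: reference SCr for the
#'   48-h acute-rise criterion.
#' @return An object of class `aki_labels`: list with `encounter_id`,
#'   `stages` (integer vector, day 1 onward), `censor_day`, `tau` and
#'   `onset_day_by_stage` (first day at which stage >= s is reached, for
#'   s = 1, 2, 3; `NA` when never reached).
#' @export
build_label_sequence <- function(scr, tau = 7, lookback_days = 7,
                                 delta48_ref = c("min", "recent")) {
  stopifnot(inherits(scr, "scr_series"))
  delta48_ref <- match.arg(delta48_ref)
  bl <- assign_baselines(scr, lookback_days = lookback_days)
  d48 <- delta48_rise(scr, reference = delta48_ref)
  rrt_flag <- if (length(scr$rrt_times)) scr$times >= min(scr$rrt_times) else
    rep(FALSE, length(scr$times))
  meas_stage <- stage_measurement(bl$value, bl$baseline, d48, rrt_flag)

  censor_day <- as.integer(min(los_days(scr), tau))
  stages <- integer(censor_day)
  days <- day_index(scr, scr$times)
  in_stay <- which(days >= 1L & days <= censor_day)
  # stage set at the measurement day, carried forward until next measurement
  for (i in in_stay) {
    stages[days[i]:censor_day] <- meas_stage[i]
  }
  # several measurements on one day: the day takes the stage of its last
  # measurement (already guaranteed: in_stay is in time order)
  if (length(scr$rrt_times)) {
    rrt_day <- day_index(scr, min(scr$rrt_times))
    if (rrt_day <= censor_day) stages[max(1L, rrt_day):censor_day] <- 3L
  }
  onset <- vapply(1:3, function(s) {
    hit <- which(stages >= s)
    if (length(hit)) hit[1L] else NA_integer_
  }, integer(1))
  structure(
    list(encounter_id = scr$encounter_id, stages = stages,
         censor_day = censor_day, tau = tau,
         onset_day_by_stage = stats::setNames(onset, c("1", "2", "3"))),
    class = "aki_labels"
  )
}

#' @export
print.aki_labels <- function(x, ...) {
  cat(sprintf("<aki_labels> encounter %s: stages [%s], censored day %d (tau=%s)\n",
              format(x$encounter_id), paste(x$stages, collapse = ","),
              x$censor_day, format(x$tau)))
  invisible(x)
}

#' Label a cohort of encounters from CDM-style tables
#'
#' Builds per-day KDIGO label sequences for every encounter from a lab table
#' keyed by LOINC code plus the encounter table, and returns a tidy label
#' table of encounter-days.
#'
#' @param cdm list of CDM-like tables as returned by [read_cdm()] or
#'   [simulate_cohort()]; requires `ENCOUNTER` (`encounter_id`,
#'   `admission_time`, `discharge_time`) and `LAB_RESULT_CM`
#'   (`encounter_id`, `code`, `value`, `time`). An optional `PROCEDURES`
#'   table provides RRT events via `rrt_codes`.
#' @param tau maximum follow-up in days.
#' @param scr_loinc LOINC code set identifying serum creatinine.
#' @param rrt_codes procedure codes counted as RRT initiation.
#' @param ... passed to [build_label_sequence()].
#' @return A [data.table::data.table] with columns `encounter_id`, `day`,
#'   `stage`, `censored` (1 on the censoring day), plus attribute `onsets`:
#'   one row per encounter with `censor_day` and `onset_stage1/2/3`.
#' @export
label_cohort <- function(cdm, tau = 7, scr_loinc = "2160-0",
                         rrt_codes = c("90935", "90937", "90945"), ...) {
  enc <- data.table::as.data.table(cdm$ENCOUNTER)
  lab <- data.table::as.data.table(cdm$LAB_RESULT_CM)
  scr <- lab[lab$code %in% scr_loinc & is.finite(lab$value) & lab$value > 0, ]
  rrt <- NULL
  if (!is.null(cdm$PROCEDURES)) {
    px <- data.table::as.data.table(cdm$PROCEDURES)
    # only in-stay initiations count as stage-3 events; pre-admission
    # dialysis is an eligibility matter, not a label
    px <- merge(px, enc[, list(encounter_id, admission_time)],
                by = "encounter_id")
    rrt <- px[px$code %in% rrt_codes & px$time >= px$admission_time, ]
  }
  scr_split <- split(scr, by = "encounter_id", keep.by = TRUE)
  rrt_split <- if (!is.null(rrt) && nrow(rrt)) split(rrt, by = "encounter_id") else list()

  out <- vector("list", nrow(enc))
  onsets <- vector("list", nrow(enc))
  for (i in seq_len(nrow(enc))) {
    eid <- enc$encounter_id[i]
    s <- scr_split[[as.character(eid)]]
    if (is.null(s) || nrow(s) == 0L) next
    rt <- rrt_split[[as.character(eid)]]
    series <- scr_series(eid, s$time, s$value,
                         admission_time = enc$admission_time[i],
                         discharge_time = enc$discharge_time[i],
                         rrt_times = if (is.null(rt)) numeric() else rt$time)
    lab_seq <- build_label_sequence(series, tau = tau, ...)
    nd <- length(lab_seq$stages)
    out[[i]] <- data.table::data.table(
      encounter_id = eid, day = seq_len(nd), stage = lab_seq$stages,
      censored = as.integer(seq_len(nd) == lab_seq$censor_day))
    onsets[[i]] <- data.table::data.table(
      encounter_id = eid, censor_day = lab_seq$censor_day,
      onset_stage1 = lab_seq$onset_day_by_stage[["1"]],
      onset_stage2 = lab_seq$onset_day_by_stage[["2"]],
      onset_stage3 = lab_seq$onset_day_by_stage[["3"]])
  }
  res <- data.table::rbindlist(out)
  data.table::setattr(res, "onsets", data.table::rbindlist(onsets))
  res[]
}
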