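#' @import data.table
#' @keywords internal
"_PACKAGE"

.datatable.aware <- TRUE

# data.table non-standard evaluation columns
utils::globalVariables(c(
  ".N", ".SD", "encounter_id", "day", "code", "value", "time", "stage",
  "censored", "n_days", "admission_time", "discharge_time", "chg",
  "systolic", "diastolic", "bmi", "hour", "exp_day", "first_day", "sex",
  "race", "sex_F", "egfr", "age", "patient_id", "row", "sbp_slope",
  "dbp_slope", "sbp_mid", "dbp_mid", "vanco_exposed", "vanco_cum", "hazard",
  "event_draw", "scr", "outcome", "onset", "censor_day", "t_max",
  "sbp_min", "sbp_max", "dbp_min", "dbp_max"
))
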