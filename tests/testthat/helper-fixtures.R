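# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# small single-site cohort + trained/calibrated model for model-level tests
fixture_model <- function() {
  if (!is.null(.fixtures$model)) return(.fixtures$model)
  co <- simulate_cohort(site_spec("fix", n_encounters = 900, seed = 42))
  ps <- prepare_site(co)
  sp <- make_splits(ps$rows, split_plan(2556, seed = 42),
                    co$tables$ENCOUNTER)
  m <- tune_and_train(ps$rows, encounters = sp$derivation, budget = 1,
                      seed = 42)
  m <- recalibrate(m, ps$rows[ps$rows$encounter_id %in% sp$calibration])
  .fixtures$model <- list(cohort = co, site = ps, splits = sp, model = m)
  .fixtures$model
}

# hand-built miniature CDM with known contents
tiny_cdm <- function() {
  enc <- data.table::data.table(
    encounter_id = c("e1", "e2", "e3", "e4"),
    patient_id = c("e1", "e2", "e3", "e4"),
    age = c(45, 60, 70, 50),
    admission_time = c(0, 0, 0, 0),
    discharge_time = c(6, 1, 5, 5),   # e2: one-day stay
    site = "tiny")
  lab <- data.table::data.table(
    encounter_id = c("e1", "e1", "e2", "e2", "e3", "e3", "e4", "e4"),
    code = "2160-0",
    value = c(1.0, 2.1, 0.9, 0.9, 1.1, 1.0, 0.8, 0.9),
    unit = "mg/dL",
    time = c(0.25, 3.25, 0.25, 0.5, 0.25, 2.25, 0.25, 1.25))
  demo <- data.table::data.table(
    patient_id = c("e1", "e2", "e3", "e4"),
    sex = c("F", "M", "M", "F"), race = c("01", "01", "03", "01"),
    birth_offset_years = c(45, 60, 70, 50))
  px <- data.table::data.table(
    encounter_id = "e3", code = "90935", vocabulary = "CPT", time = -5)
  dx <- data.table::data.table(
    encounter_id = c("e1", "e4"), code = c("I10", "I10"),
    vocabulary = "ICD10", time = c(0.1, 0.1))
  med <- data.table::data.table(
    encounter_id = character(), code = character(), vocabulary = character(),
    time = numeric())
  vit <- data.table::data.table(
    encounter_id = character(), time = numeric(), systolic = numeric(),
    diastolic = numeric(), bmi = numeric())
  list(DEMOGRAPHIC = demo, ENCOUNTER = enc, LAB_RESULT_CM = lab,
       PRESCRIBING = med, VITAL = vit, DIAGNOSIS = dx, PROCEDURES = px)
}
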