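# Multi-site synthetic inpatient EHR generator.
#
# Emulates the statistical structure the modelling pipeline assumes: per
# encounter demographics, daily labs/vitals around patient-level latent
# means, Bernoulli medication exposure, and a per-day logistic hazard for
# AKI onset driven by a stated set of covariates. On event, the serum
# creatinine trajectory jumps to the mid-interval of the intended KDIGO
# stage so that the staging rules recover the intent. Controllable per-site
# mean shifts, variance scaling and encounter-level feature missingness
# emulate cross-site heterogeneity (including the fully-absent-code case).

# deterministic substream seed from a base seed and a stream name, < 2^31
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  (as.integer(seed) %% 1009L) * 1000003L %% 2147483647L + h %% 65011L
}

default_lab_defs <- function() {
  data.frame(
    code = c("1963-8", "718-7", "6690-2", "1751-7"),
    name = c("bicarbonate", "hemoglobin", "wbc", "albumin"),
    mean = c(24, 12.5, 9, 3.8),
    sd = c(3, 1.5, 3, 0.5),
    noise_sd = c(1, 0.5, 1, 0.2),
    stringsAsFactors = FALSE
  )
}

# per-day log-odds contributions; covariates standardised to their source
# scale inside simulate_cohort
default_hazard_coefs <- function() {
  c(intercept = stats::qlogis(0.025),
    age = 0.15,          # per 10 years above 60
    bmi = 0.15,          # per source SD above 29
    sepsis = 0.50,       # ICD-10 A41.9 present
    vanco_cumdays = 0.50, # per cumulative exposure day
    sbp_slope = -0.50,   # per mmHg/hour within-day trend
    `1963-8` = -0.80,    # bicarbonate, per source SD
    `718-7` = -0.60,     # hemoglobin
    `6690-2` = 0.30,     # white cell count
    `1751-7` = -0.25)    # albumin
}

#' Specification of one synthetic site
#'
#' Describes a site's encounter count, covariate distributions relative to the
#' reference population, per-feature missingness, and the discrete-time AKI
#' hazard coefficients. Shifts are expressed per feature: `delta` in source-SD
#' units added to the latent mean, `scale` multiplying the latent SD, and
#' `missingness` as the fraction of encounters at which the feature is not
#' captured at all (1 reproduces a code absent from the site's vocabulary).
#'
#' @param site_id scalar site label.
#' @param n_encounters number of inpatient encounters to simulate.
#' @param seed integer seed; all randomness flows from it through named
#'   substreams, so individual tables are independently reproducible.
#' @param delta,scale,missingness named numeric vectors keyed by feature
#'   (lab LOINC code, `"bmi"`, `"sbp"`, or medication code such as
#'   `"med_11124"`); unnamed features take 0 / 1 / 0.
#' @param hazard_coefs named per-day log-odds coefficients; see
#'   `default_hazard_coefs()` in the package source for the reference set.
#' @param stage_probs probabilities of intended KDIGO stages 1:3 given onset.
#' @param tau maximum follow-up used downstream (days).
#' @param los_range integer range of lengths of stay to draw uniformly.
#' @return An object of class `site_spec`.
#' @export
site_spec <- function(site_id, n_encounters = 1000, seed = 1,
                      delta = numeric(), scale = numeric(),
                      missingness = numeric(),
                      hazard_coefs = default_hazard_coefs(),
                      stage_probs = c(0.50, 0.35, 0.15),
                      tau = 7, los_range = 3:10) {
  stopifnot(n_encounters >= 1, all(missingness >= 0 & missingness <= 1))
  structure(
    list(site_id = site_id, n_encounters = as.integer(n_encounters),
         seed = as.integer(seed), delta = delta, scale = scale,
         missingness = missingness, hazard_coefs = hazard_coefs,
         stage_probs = stage_probs / sum(stage_probs),
         tau = tau, los_range = los_range),
    class = "site_spec"
  )
}

#' Derive a shifted target-site specification
#'
#' @param source_spec a [site_spec()].
#' @param delta,scale,missingness named shift parameters replacing those of
#'   the source (see [site_spec()]); setting `missingness = 1` for a feature
#'   reproduces the scenario where a code is absent from the target site's
#'   vocabulary altogether.
#' @param site_id,seed,n_encounters overrides for the target site.
#' @return A new `site_spec` for the target site.
#' @export
shift_site <- function(source_spec, delta = numeric(), scale = numeric(),
                       missingness = numeric(),
                       site_id = paste0(source_spec$site_id, "_shifted"),
                       seed = source_spec$seed + 1L,
                       n_encounters = source_spec$n_encounters) {
  spec <- source_spec
  spec$site_id <- site_id
  spec$seed <- as.integer(seed)
  spec$n_encounters <- as.integer(n_encounters)
  spec$delta <- delta
  spec$scale <- scale
  spec$missingness <- missingness
  class(spec) <- "site_spec"
  spec
}

shift_of <- function(vec, key, default) {
  if (!is.null(names(vec)) && key %in% names(vec)) vec[[key]] else default
}

#' Simulate a synthetic inpatient cohort for one site
#'
#' Generates CDM-like delimited-style tables (`DEMOGRAPHIC`, `ENCOUNTER`,
#' `LAB_RESULT_CM`, `VITAL`, `PRESCRIBING`, `DIAGNOSIS`, `PROCEDURES`)
#' together with the ground truth of the data-generating process: per-day
#' true event hazards, true onset days and intended KDIGO stages. Admission
#' dates are spread uniformly over a 9-year window (days 0..3287 from the
#' epoch, with day 2556 playing the role of the temporal-validation cutoff
#' downstream).
#'
#' @param spec a [site_spec()].
#' @return An object of class `synthetic_cohort`: list with `tables` (named
#'   list of data.tables), `truth` (list: `encounters`, `hazards`, `spec`).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "site_spec"))
  n <- spec$n_encounters
  labs <- default_lab_defs()
  cf <- spec$hazard_coefs

  set.seed(substream_seed(spec$seed, "patients"))
  eid <- sprintf("%s_e%05d", spec$site_id, seq_len(n))
  age <- pmin(90, pmax(18, round(stats::rnorm(n, 60, 14))))
  sex <- sample(c("F", "M"), n, replace = TRUE)
  race <- sample(c("01", "02", "03", "05"), n, replace = TRUE,
                 prob = c(0.7, 0.12, 0.08, 0.1))
  los <- sample(spec$los_range, n, replace = TRUE)
  admit_day <- floor(stats::runif(n, 0, 3288))
  bmi <- stats::rnorm(n,
                      29 + shift_of(spec$delta, "bmi", 0) * 6,
                      6 * shift_of(spec$scale, "bmi", 1))
  bmi <- pmin(60, pmax(14, bmi))
  sepsis <- stats::rbinom(n, 1, 0.2)
  sbp_mu <- stats::rnorm(n, 125 + shift_of(spec$delta, "sbp", 0) * 15,
                         15 * shift_of(spec$scale, "sbp", 1))
  dbp_mu <- stats::rnorm(n, 75, 10)
  scr_base <- pmax(0.5, stats::rnorm(n, 0.85, 0.12))

  # patient latent means per lab
  set.seed(substream_seed(spec$seed, "lab_latents"))
  lab_mu <- sapply(seq_len(nrow(labs)), function(k) {
    stats::rnorm(n,
                 labs$mean[k] + shift_of(spec$delta, labs$code[k], 0) * labs$sd[k],
                 labs$sd[k] * shift_of(spec$scale, labs$code[k], 1))
  })
  colnames(lab_mu) <- labs$code

  # vancomycin exposure: user flag, start day, then continuous exposure
  set.seed(substream_seed(spec$seed, "meds"))
  vanco_user <- stats::rbinom(n, 1, 0.25)
  vanco_start <- sample(1:3, n, replace = TRUE)
  other_med <- stats::rbinom(n, 1, 0.3)

  # daily grid (day 1..los per encounter)
  grid <- data.table::data.table(
    row = rep(seq_len(n), los),
    day = unlist(lapply(los, seq_len), use.names = FALSE)
  )
  grid[, `:=`(encounter_id = eid[row])]

  set.seed(substream_seed(spec$seed, "daily"))
  m <- nrow(grid)
  for (k in seq_len(nrow(labs))) {
    grid[, (labs$code[k]) := lab_mu[row, k] + stats::rnorm(m, 0, labs$noise_sd[k])]
  }
  grid[, sbp_slope := stats::rnorm(m, 0, 1.2)]
  grid[, dbp_slope := 0.6 * sbp_slope + stats::rnorm(m, 0, 0.6)]
  grid[, sbp_mid := sbp_mu[row] + stats::rnorm(m, 0, 6)]
  grid[, dbp_mid := dbp_mu[row] + stats::rnorm(m, 0, 4)]
  grid[, vanco_exposed := as.integer(vanco_user[row] == 1L & day >= vanco_start[row])]
  grid[, vanco_cum := cumsum(vanco_exposed), by = row]

  # per-day hazard from the TRUE covariate values (standardised to the
  # reference population scale); no event possible on admission day
  z <- matrix(0, m, nrow(labs))
  for (k in seq_len(nrow(labs))) {
    z[, k] <- (grid[[labs$code[k]]] - labs$mean[k]) / labs$sd[k]
  }
  eta <- cf[["intercept"]] +
    cf[["age"]] * (age[grid$row] - 60) / 10 +
    cf[["bmi"]] * (bmi[grid$row] - 29) / 6 +
    cf[["sepsis"]] * sepsis[grid$row] +
    cf[["vanco_cumdays"]] * grid$vanco_cum +
    cf[["sbp_slope"]] * grid$sbp_slope +
    as.vector(z %*% cf[labs$code])
  grid[, hazard := stats::plogis(eta)]
  grid[day == 1L, hazard := 0]

  set.seed(substream_seed(spec$seed, "events"))
  grid[, event_draw := stats::runif(m) < hazard]
  onset <- grid[, {
    hit <- which(event_draw)
    list(onset_day = if (length(hit)) day[hit[1L]] else NA_integer_)
  }, by = row]
  intended_stage <- rep(NA_integer_, n)
  has_event <- !is.na(onset$onset_day)
  intended_stage[onset$row[has_event]] <-
    sample(1:3, sum(has_event), replace = TRUE, prob = spec$stage_probs)
  onset_day <- rep(NA_integer_, n)
  onset_day[onset$row] <- onset$onset_day

  # SCr trajectory: flat around the patient baseline, jumping at onset to
  # mid-interval of the intended stage and staying elevated
  set.seed(substream_seed(spec$seed, "scr"))
  stage_ratio <- c(1.7, 2.4, 3.4)
  grid[, scr := scr_base[row] + stats::rnorm(m, 0, 0.04)]
  post <- !is.na(onset_day[grid$row]) & grid$day >= onset_day[grid$row]
  if (any(post)) {
    r <- stage_ratio[intended_stage[grid$row[post]]]
    grid[post, scr := r * scr_base[row] + stats::rnorm(sum(post), 0, 0.04)]
  }

  # ---- emit CDM-like tables ----------------------------------------------
  abs_time <- admit_day[grid$row] + grid$day - 1
  demographic <- data.table::data.table(
    patient_id = eid, sex = sex, race = race, birth_offset_years = age)
  encounter <- data.table::data.table(
    encounter_id = eid, patient_id = eid, age = age,
    admission_time = admit_day, discharge_time = admit_day + los,
    site = spec$site_id)

  lab_rows <- list()
  lab_rows$scr <- data.table::data.table(
    encounter_id = grid$encounter_id, code = "2160-0",
    value = round(grid$scr, 2), unit = "mg/dL", time = abs_time + 0.25)
  set.seed(substream_seed(spec$seed, "missingness"))
  for (k in seq_len(nrow(labs))) {
    miss_frac <- shift_of(spec$missingness, labs$code[k], 0)
    capt <- stats::runif(n) >= miss_frac  # encounter-level capture
    keep <- capt[grid$row]
    if (!any(keep)) next
    lab_rows[[labs$code[k]]] <- data.table::data.table(
      encounter_id = grid$encounter_id[keep], code = labs$code[k],
      value = round(grid[[labs$code[k]]][keep], 2), unit = "",
      time = abs_time[keep] + 0.25)
  }
  lab_result <- data.table::rbindlist(lab_rows)

  # vitals: 4 BP readings/day at 08/12/16/20h encoding the within-day slope
  hours <- c(8, 12, 16, 20)
  bp_miss <- stats::runif(n) < shift_of(spec$missingness, "bp", 0)
  vit <- grid[rep(seq_len(m), each = length(hours))][!bp_miss[row]]
  vit[, hour := rep_len(hours, .N)]
  vital <- data.table::data.table(
    encounter_id = vit$encounter_id,
    time = admit_day[vit$row] + vit$day - 1 + vit$hour / 24,
    systolic = round(vit$sbp_mid + vit$sbp_slope * (vit$hour - 14), 1),
    diastolic = round(vit$dbp_mid + vit$dbp_slope * (vit$hour - 14), 1),
    bmi = NA_real_)
  bmi_miss <- stats::runif(n) < shift_of(spec$missingness, "bmi", 0)
  bmi_rows <- data.table::data.table(
    encounter_id = eid[!bmi_miss], time = admit_day[!bmi_miss] + 8 / 24,
    systolic = NA_real_, diastolic = NA_real_,
    bmi = round(bmi[!bmi_miss], 1))
  vital <- data.table::rbindlist(list(vital, bmi_rows), use.names = TRUE)

  med_rows <- list()
  vanco_miss <- stats::runif(n) < shift_of(spec$missingness, "med_11124", 0)
  vsel <- grid$vanco_exposed == 1L & !vanco_miss[grid$row]
  if (any(vsel)) {
    med_rows$vanco <- data.table::data.table(
      encounter_id = grid$encounter_id[vsel], code = "11124",
      vocabulary = "RXNORM", time = abs_time[vsel] + 0.4)
  }
  osel <- other_med[grid$row] == 1L & grid$day <= 2L
  if (any(osel)) {
    med_rows$other <- data.table::data.table(
      encounter_id = grid$encounter_id[osel], code = "29046",
      vocabulary = "RXNORM", time = abs_time[osel] + 0.4)
  }
  prescribing <- data.table::rbindlist(med_rows)

  set.seed(substream_seed(spec$seed, "diagnoses"))
  dx_rows <- list()
  if (any(sepsis == 1L)) {
    dx_rows$sepsis <- data.table::data.table(
      encounter_id = eid[sepsis == 1L], code = "A41.9", vocabulary = "ICD10",
      time = admit_day[sepsis == 1L] + 0.1)
  }
  htn <- stats::rbinom(n, 1, 0.4) == 1L
  dm <- stats::rbinom(n, 1, 0.25) == 1L
  dx_rows$htn <- data.table::data.table(
    encounter_id = eid[htn], code = "I10", vocabulary = "ICD10",
    time = admit_day[htn] + 0.1)
  dx_rows$dm <- data.table::data.table(
    encounter_id = eid[dm], code = "E11.9", vocabulary = "ICD10",
    time = admit_day[dm] + 0.1)
  diagnosis <- data.table::rbindlist(dx_rows)

  procedures <- data.table::data.table(
    encounter_id = character(), code = character(),
    vocabulary = character(), time = numeric())

  tables <- list(DEMOGRAPHIC = demographic, ENCOUNTER = encounter,
                 LAB_RESULT_CM = lab_result, VITAL = vital,
                 PRESCRIBING = prescribing, DIAGNOSIS = diagnosis,
                 PROCEDURES = procedures)
  truth_enc <- data.table::data.table(
    encounter_id = eid, age = age, bmi = bmi, sepsis = sepsis,
    scr_base = scr_base, los = los, admit_day = admit_day,
    onset_day = onset_day, intended_stage = intended_stage)
  hazards <- grid[, list(encounter_id, day, hazard)]
  structure(list(tables = tables,
                 truth = list(encounters = truth_enc, hazards = hazards,
                              spec = spec)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  te <- x$truth$encounters
  cat(sprintf("<synthetic_cohort> site %s: %d encounters, %.1f%% with AKI onset\n",
              x$truth$spec$site_id, nrow(te),
              100 * mean(!is.na(te$onset_day))))
  invisible(x)
}

#' True per-row event probability under the generator
#'
#' For an at-risk row (encounter, day t) the probability that the first onset
#' of an event of at least `min_stage` falls in `(t, t + dt]`, computed from
#' the stored true hazards: `1 - prod(1 - p_d * P(stage >= min_stage))` over
#' `d` in `t+1 .. t+dt`. Used to compute the generator's Bayes-optimal AUROC.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param rows data.frame with `encounter_id` and `day` (the row time t).
#' @param dt prediction horizon in days.
#' @param min_stage target stage threshold.
#' @return Numeric vector of true probabilities, aligned with `rows`.
#' @export
true_row_probability <- function(cohort, rows, dt = 2, min_stage = 2) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  p_stage <- sum(cohort$truth$spec$stage_probs[min_stage:3])
  hz <- cohort$truth$hazards
  haz_map <- hz[, list(encounter_id, day, p = hazard * p_stage)]
  out <- numeric(nrow(rows))
  for (k in seq_len(dt)) {
    look <- data.table::data.table(encounter_id = rows$encounter_id,
                                   day = rows$day + k)
    mm <- haz_map[look, on = c("encounter_id", "day")]
    pk <- mm$p
    pk[is.na(pk)] <- 0  # window extends past discharge: no event possible
    out <- 1 - (1 - out) * (1 - pk)
  }
  out
}

#' Build a graded multi-site transportability benchmark
#'
#' Simulates one source site plus `n_sites` target sites whose covariate
#' shift grows along a monotone ladder: increasing encounter-level
#' missingness of informative features (vancomycin exposure, bicarbonate,
#' hemoglobin — the strongest model inputs), a growing mean shift of the
#' white-cell count and systolic pressure, and variance shrinkage of
#' albumin. A model trained at the source site degrades increasingly along
#' the ladder, which is what the adjMMD-vs-deltaAUC correlation analysis
#' consumes.
#'
#' @param n_sites number of target sites (>= 3).
#' @param n_encounters encounters per site.
#' @param shift_grades numeric vector in `[0, 1]`, one per site (default an
#'   equally spaced monotone ladder).
#' @param seed integer master seed.
#' @return List with `source` (a `synthetic_cohort`), `targets` (list of
#'   `synthetic_cohort`s), `shift_grades` and `specs`.
#' @export
make_transportability_benchmark <- function(n_sites = 6, n_encounters = 2000,
                                            shift_grades = NULL, seed = 1) {
  stopifnot(n_sites >= 3)
  if (is.null(shift_grades)) {
    shift_grades <- seq(0, 1, length.out = n_sites)
  }
  stopifnot(length(shift_grades) == n_sites)
  src_spec <- site_spec("src", n_encounters = n_encounters, seed = seed)
  source <- simulate_cohort(src_spec)
  targets <- vector("list", n_sites)
  specs <- vector("list", n_sites)
  for (i in seq_len(n_sites)) {
    # convex intensity ramp: discrimination loss is steepest at low
    # missingness, so a convex ladder spreads the sites across the
    # responsive range instead of saturating after the first steps
    g <- shift_grades[i]^2
    specs[[i]] <- shift_site(
      src_spec,
      delta = c("6690-2" = 1.2 * g, sbp = -0.6 * g),
      scale = c("1751-7" = 1 - 0.5 * g),
      # vocabulary presence is all-or-nothing: the medication code is either
      # mapped at a site or absent from its dictionary altogether
      missingness = c("1963-8" = 0.9 * g, "718-7" = 0.9 * g,
                      med_11124 = as.numeric(shift_grades[i] >= 0.75),
                      bp = 0.5 * g),
      site_id = sprintf("tgt%d", i),
      # one shared substream across targets: a paired (common-random-numbers)
      # design, so sites differ only in the shift applied, not in cohort
      # sampling noise, and the missingness masks are nested along the ladder
      seed = seed + 101L, n_encounters = n_encounters)
    targets[[i]] <- simulate_cohort(specs[[i]])
  }
  list(source = source, targets = targets, shift_grades = shift_grades,
       specs = specs)
}
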