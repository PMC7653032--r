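# synthetic discrete-time rows with a known logistic hazard, used by the
# training tests: one strong feature plus noise features
logistic_rows <- function(n_enc, seed, beta = c(f1 = 2.5), noise_feats = 3,
                          base = -2.5) {
  set.seed(seed)
  rows_per <- sample(2:5, n_enc, replace = TRUE)
  eid <- rep(sprintf("e%04d", seq_len(n_enc)), rows_per)
  n <- length(eid)
  X <- data.table::data.table(encounter_id = eid,
                              day = unlist(lapply(rows_per, seq_len)))
  for (f in names(beta)) X[, (f) := stats::rnorm(n)]
  for (k in seq_len(noise_feats)) X[, (paste0("noise", k)) := stats::rnorm(n)]
  eta <- base + as.matrix(X[, names(beta), with = FALSE]) %*% beta
  X[, true_p := stats::plogis(eta)]
  X[, outcome := stats::rbinom(n, 1, true_p)]
  feature_cols <- setdiff(names(X), c("encounter_id", "outcome", "true_p"))
  data.table::setattr(X, "feature_cols", feature_cols)
  data.table::setattr(X, "dt", 1L)
  data.table::setattr(X, "min_stage", 2L)
  X
}

test_that("splits are by encounter with floor counts and temporal cutoff", {
  rows <- data.table::data.table(
    encounter_id = rep(sprintf("e%03d", 1:100), each = 3))
  adm <- data.table::data.table(encounter_id = sprintf("e%03d", 1:100),
                                admission_time = c(rep(100, 80), rep(900, 20)))
  sp <- make_splits(rows, split_plan(500, seed = 3), adm)
  expect_length(sp$temporal, 20)
  expect_length(sp$derivation, 56)
  expect_length(sp$calibration, 12)
  expect_length(sp$internal, 12)
  all_ids <- unlist(sp)
  expect_equal(sort(unique(all_ids)), sort(unique(rows$encounter_id)))
  expect_equal(anyDuplicated(all_ids), 0L)  # no encounter in two partitions

  sp2 <- make_splits(rows, split_plan(500, seed = 3), adm)
  expect_identical(sp, sp2)  # fixed seed, identical membership

  expect_warning(sp3 <- make_splits(rows, split_plan(0, seed = 1), adm),
                 "empty partition")
  expect_length(sp3$temporal, 100)
})

test_that("training recovers a dominant feature and approaches Bayes AUROC", {
  train <- logistic_rows(1500, seed = 21)
  test_rows <- logistic_rows(1500, seed = 22)
  m <- tune_and_train(train, budget = 3, folds = 3, seed = 21,
                      nrounds_max = 300)
  expect_lte(m$n_trees, 300)
  # the single informative feature should dominate the normalized gain
  w <- gain_weights(m, top_k = length(m$gains))
  expect_gte(unname(w["f1"]), 0.9)
  # held-out AUROC within 0.03 of the generator's Bayes AUROC
  bayes <- auroc(test_rows$true_p, test_rows$outcome)
  got <- auroc(predict_risk(m, test_rows, calibrated = FALSE),
               test_rows$outcome)
  expect_gte(got, bayes - 0.03)
  expect_lte(got, bayes + 0.03)  # Bayes bounds up to Monte-Carlo error

  # same seed reproduces identical gains
  m2 <- tune_and_train(train, budget = 3, folds = 3, seed = 21,
                       nrounds_max = 300)
  expect_identical(m$gains, m2$gains)
  expect_identical(m$params, m2$params)
})

test_that("degenerate budgets and single-class data are handled", {
  train <- logistic_rows(200, seed = 5)
  m <- tune_and_train(train, budget = 1, seed = 5, nrounds_max = 50)
  expect_equal(m$params$max_depth, 6L)  # mid-range default
  expect_equal(m$params$eta, 0.055)
  one_class <- data.table::copy(train)[, outcome := 0L]
  data.table::setattr(one_class, "feature_cols", attr(train, "feature_cols"))
  expect_error(tune_and_train(one_class, budget = 1), "single outcome class")
})

test_that("logistic recalibration is near-identity for calibrated scores", {
  set.seed(8)
  p <- runif(5000, 0.01, 0.6)
  y <- rbinom(5000, 1, p)
  cal <- akitransport:::fit_recalibration(p, y, "logistic")
  expect_equal(cal$method, "logistic")
  expect_gte(cal$slope, 0.9); expect_lte(cal$slope, 1.1)

  # over-confident scores: calibration strictly improves the HL score
  over <- plogis(2 * qlogis(p))
  cal2 <- akitransport:::fit_recalibration(over, y, "logistic")
  fixed <- akitransport:::apply_calibration(cal2, over)
  expect_lt(hosmer_lemeshow(fixed, y)$hls, hosmer_lemeshow(over, y)$hls)

  # constant scores map to the prevalence
  cal3 <- akitransport:::fit_recalibration(rep(0.3, 500), rbinom(500, 1, 0.1),
                                           "logistic")
  expect_equal(cal3$method, "constant")
  expect_equal(akitransport:::apply_calibration(cal3, 0.3), cal3$value)
})

test_that("risk prediction aligns features and is deterministic", {
  fx <- fixture_model()
  m <- fx$model
  rows <- fx$site$rows[1:50]
  p1 <- predict_risk(m, rows)
  p2 <- predict_risk(m, rows)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))

  # all-missing row: prior-leaning probability, no crash
  empty <- data.table::data.table(encounter_id = "x", day = 1L)
  p3 <- predict_risk(m, empty)
  expect_true(is.finite(p3) && p3 >= 0 && p3 <= 1)

  # unknown feature names are ignored with a message
  odd <- data.table::copy(rows)[, mystery_feature := 1]
  expect_message(p4 <- predict_risk(m, odd), "unknown")
  expect_equal(p4, p1)

  # round-trip: training-set AUROC not far below the internal estimate
  internal <- fx$site$rows[fx$site$rows$encounter_id %in% fx$splits$internal]
  train_rows <- fx$site$rows[fx$site$rows$encounter_id %in% fx$splits$derivation]
  auc_int <- auroc(predict_risk(m, internal), internal$outcome)
  auc_train <- auroc(predict_risk(m, train_rows), train_rows$outcome)
  expect_gte(auc_train, auc_int - 0.05)
})

test_that("model bundles round-trip through disk", {
  fx <- fixture_model()
  path <- withr::local_tempfile(fileext = ".rds")
  save_ds_gbt(fx$model, path)
  back <- load_ds_gbt(path)
  rows <- fx$site$rows[1:40]
  expect_identical(predict_risk(back, rows), predict_risk(fx$model, rows))
  expect_identical(back$gains, fx$model$gains)
  expect_identical(back$task, fx$model$task)
})

test_that("gain weights normalize, truncate and break ties by name", {
  g <- c(a = 3, b = 1)
  expect_equal(gain_weights(g, 2), c(a = 0.75, b = 0.25))
  expect_equal(gain_weights(g, 1), c(a = 1))
  expect_warning(w <- gain_weights(g, 5), "truncating")
  expect_length(w, 2)
  tied <- c(zed = 1, abc = 1, mid = 1)
  expect_equal(names(gain_weights(tied, 3)), c("abc", "mid", "zed"))
})
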