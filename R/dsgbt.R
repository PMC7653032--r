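# Discrete-time survival gradient-boosted trees (DS-GBT): encounter-level
# splits, sequential hyperparameter search with early stopping, logistic
# recalibration, prediction and gain-based feature weights. Built on xgboost,
# whose default-direction splits provide the learned handling of missing
# numeric values.

#' Split plan for derivation / calibration / internal / temporal sets
#'
#' @param temporal_cutoff admission time (same units as
#'   `ENCOUNTER$admission_time`) after which encounters form the temporal
#'   validation set.
#' @param fractions derivation / calibration / internal fractions of the
#'   pre-cutoff encounters; must sum to 1.
#' @param seed integer seed for the randomised assignment.
#' @return An object of class `split_plan`.
#' @export
split_plan <- function(temporal_cutoff, fractions = c(0.70, 0.15, 0.15),
                       seed = 1) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  structure(list(temporal_cutoff = temporal_cutoff,
                 fractions = fractions, seed = as.integer(seed)),
            class = "split_plan")
}

#' Partition encounters into derivation/calibration/internal/temporal sets
#'
#' Encounters admitted after the cutoff form the temporal validation set;
#' the remainder are randomised by encounter (never by row) into
#' derivation/calibration/internal using floor counts, any remainder going
#' to derivation.
#'
#' @param dataset a `discrete_time_dataset` (or any table with
#'   `encounter_id`).
#' @param plan a [split_plan()].
#' @param admissions data.frame mapping `encounter_id` to `admission_time`
#'   (e.g. the ENCOUNTER table).
#' @return Named list of encounter-id vectors: `derivation`, `calibration`,
#'   `internal`, `temporal`.
#' @export
make_splits <- function(dataset, plan, admissions) {
  adm <- data.table::as.data.table(admissions)
  ids <- unique(dataset$encounter_id)
  adm <- adm[encounter_id %in% ids]
  temporal <- adm$encounter_id[adm$admission_time > plan$temporal_cutoff]
  pool <- sort(setdiff(ids, temporal))
  n <- length(pool)
  n_der <- floor(plan$fractions[1] * n)
  n_cal <- floor(plan$fractions[2] * n)
  n_int <- floor(plan$fractions[3] * n)
  n_der <- n_der + (n - n_der - n_cal - n_int)  # remainder to derivation
  set.seed(plan$seed)
  pool <- sample(pool)
  out <- list(derivation = pool[seq_len(n_der)],
              calibration = pool[n_der + seq_len(n_cal)],
              internal = pool[n_der + n_cal + seq_len(n_int)],
              temporal = temporal)
  empty <- names(out)[vapply(out, length, 1L) == 0L]
  if (length(empty)) warning("empty partition(s): ", paste(empty, collapse = ", "))
  out
}

dtd_design <- function(dataset, feature_cols) {
  X <- as.matrix(dataset[, feature_cols, with = FALSE])
  storage.mode(X) <- "double"
  X
}

default_search_space <- function() {
  list(max_depth = c(2L, 10L), eta = c(0.01, 0.1), min_child_weight = c(1, 10),
       subsample = c(0.6, 1), colsample_bytree = c(0.6, 1))
}

draw_params <- function(space) {
  list(max_depth = sample(space$max_depth[1]:space$max_depth[2], 1),
       eta = stats::runif(1, space$eta[1], space$eta[2]),
       min_child_weight = stats::runif(1, space$min_child_weight[1],
                                       space$min_child_weight[2]),
       subsample = stats::runif(1, space$subsample[1], space$subsample[2]),
       colsample_bytree = stats::runif(1, space$colsample_bytree[1],
                                       space$colsample_bytree[2]))
}

mid_params <- function(space) {
  list(max_depth = as.integer(round(mean(space$max_depth))),
       eta = mean(space$eta),
       min_child_weight = mean(space$min_child_weight),
       subsample = mean(space$subsample),
       colsample_bytree = mean(space$colsample_bytree))
}

encounter_folds <- function(encounter_id, k, seed) {
  ids <- unique(encounter_id)
  set.seed(seed)
  fold_of <- sample(rep(seq_len(k), length.out = length(ids)))
  names(fold_of) <- ids
  lapply(seq_len(k), function(f) {
    which(fold_of[as.character(encounter_id)] == f)
  })
}

#' Tune and train the DS-GBT risk model
#'
#' Randomised sequential search over tree depth (2-10), learning rate
#' (0.01-0.1), minimum child weight (1-10) and row/column subsampling, scored
#' by encounter-grouped cross-validated AUROC; the number of trees is set by
#' early stopping (no held-out AUROC improvement for `early_stopping` rounds).
#' The final model is refit on all derivation rows with a 10% encounter-level
#' holdout driving early stopping. Missing numeric values are handled by the
#' learned default-direction splits.
#'
#' @param dataset a `discrete_time_dataset` from [assemble_rows()].
#' @param encounters optional encounter ids restricting the derivation rows.
#' @param search_space parameter ranges (see source for the defaults).
#' @param folds cross-validation folds (default 5).
#' @param budget number of search iterations; `budget = 1` skips the search
#'   and uses mid-range hyperparameters.
#' @param seed integer seed.
#' @param nrounds_max maximum boosting rounds.
#' @param early_stopping early-stopping patience in rounds.
#' @return An object of class `ds_gbt`: the booster plus hyperparameters,
#'   feature dictionary, per-feature gains, task metadata and (after
#'   [recalibrate()]) a monotone calibration map.
#' @export
tune_and_train <- function(dataset, encounters = NULL,
                           search_space = default_search_space(),
                           folds = 5, budget = 10, seed = 1,
                           nrounds_max = 400, early_stopping = 100) {
  dat <- if (is.null(encounters)) dataset else
    dataset[dataset$encounter_id %in% encounters]
  if (length(unique(dat$outcome)) < 2L) {
    stop("derivation rows contain a single outcome class")
  }
  feature_cols <- attr(dataset, "feature_cols")
  X <- dtd_design(dat, feature_cols)
  y <- dat$outcome
  base <- list(objective = "binary:logistic", eval_metric = "auc",
               nthread = 1)

  set.seed(seed)
  if (budget <= 1) {
    best <- mid_params(search_space)
  } else {
    fold_idx <- encounter_folds(dat$encounter_id, folds, seed)
    dtrain <- xgboost::xgb.DMatrix(X, label = y)
    best <- NULL; best_auc <- -Inf
    for (b in seq_len(budget)) {
      cand <- draw_params(search_space)
      auc <- tryCatch({
        cv <- xgboost::xgb.cv(params = c(base, cand), data = dtrain,
                              nrounds = nrounds_max, folds = fold_idx,
                              early_stopping_rounds = early_stopping,
                              maximize = TRUE, verbose = 0)
        max(cv$evaluation_log$test_auc_mean, na.rm = TRUE)
      }, error = function(e) NA_real_)
      if (is.finite(auc) && auc > best_auc) { best_auc <- auc; best <- cand }
    }
    if (is.null(best)) best <- mid_params(search_space)
  }

  # final refit on all derivation rows; 10% encounter holdout for stopping
  ids <- unique(dat$encounter_id)
  set.seed(seed + 1L)
  hold <- sample(ids, max(1L, floor(0.1 * length(ids))))
  hi <- dat$encounter_id %in% hold
  # both sides of the holdout must contain both classes for AUROC stopping
  ev_ids <- unique(dat$encounter_id[dat$outcome == 1L])
  if (!any(y[hi] == 1L) && length(ev_ids)) {
    hold <- c(hold, sample(ev_ids, max(1L, ceiling(0.1 * length(ev_ids)))))
    hi <- dat$encounter_id %in% hold
  }
  if (!any(y[!hi] == 1L)) {
    hi <- rep(FALSE, length(y))  # degenerate: stop on training rows
  }
  dtr <- xgboost::xgb.DMatrix(X[!hi, , drop = FALSE], label = y[!hi])
  dva <- xgboost::xgb.DMatrix(X[hi, , drop = FALSE], label = y[hi])
  set.seed(seed + 2L)
  booster <- xgboost::xgb.train(params = c(base, best), data = dtr,
                                nrounds = nrounds_max,
                                evals = list(holdout = dva),
                                early_stopping_rounds = early_stopping,
                                maximize = TRUE, verbose = 0)
  n_trees <- xgboost::xgb.attributes(booster)$best_iteration
  if (is.null(n_trees)) n_trees <- nrounds_max
  imp <- xgboost::xgb.importance(model = booster)
  gains <- stats::setNames(imp$Gain, imp$Feature)

  structure(list(booster = booster, params = best, n_trees = as.integer(n_trees),
                 feature_cols = feature_cols,
                 dictionary = attr(dataset, "dictionary"),
                 gains = gains, calibration = NULL,
                 task = list(dt = attr(dataset, "dt"),
                             min_stage = attr(dataset, "min_stage")),
                 seed = seed),
            class = "ds_gbt")
}

#' @export
print.ds_gbt <- function(x, ...) {
  cat(sprintf(
    "<ds_gbt> stage>=%d within %d day(s): %d trees (depth %d, eta %.3f), %d features%s\n",
    x$task$min_stage, x$task$dt, x$n_trees, x$params$max_depth, x$params$eta,
    length(x$feature_cols),
    if (is.null(x$calibration)) ", uncalibrated" else ", recalibrated"))
  invisible(x)
}

raw_score <- function(model, rows) {
  X <- matrix(NA_real_, nrow(rows), length(model$feature_cols),
              dimnames = list(NULL, model$feature_cols))
  have <- intersect(model$feature_cols, names(rows))
  X[, have] <- as.matrix(rows[, have, with = FALSE])
  # binary one-hot columns unseen at the scoring site map to all-zero
  if (!is.null(model$dictionary)) {
    bin <- intersect(setdiff(model$feature_cols, have),
                     model$dictionary$feature[model$dictionary$kind == "binary"])
    if (length(bin)) X[, bin] <- 0
  }
  stats::predict(model$booster, xgboost::xgb.DMatrix(X))
}

#' Recalibrate a trained model on held-out calibration rows
#'
#' Fits a monotone map from raw scores to probabilities. The default is
#' logistic recalibration (intercept and slope on the logit of the raw
#' score); `method = "isotonic"` uses an isotonic regression step function.
#'
#' @param model a `ds_gbt`.
#' @param rows calibration rows (disjoint from derivation).
#' @param method `"logistic"` or `"isotonic"`.
#' @return The model with its calibration map set.
#' @export
recalibrate <- function(model, rows, method = c("logistic", "isotonic")) {
  method <- match.arg(method)
  if (nrow(rows) < 100) warning("fewer than 100 calibration rows")
  model$calibration <- fit_recalibration(raw_score(model, rows),
                                         rows$outcome, method)
  model
}

fit_recalibration <- function(p, y, method = c("logistic", "isotonic")) {
  method <- match.arg(method)
  eps <- 1e-6
  lg <- stats::qlogis(pmin(pmax(p, eps), 1 - eps))
  if (method == "logistic") {
    if (length(unique(y)) < 2L || stats::var(lg) == 0) {
      # degenerate scores: map everything to the observed prevalence
      list(method = "constant", value = mean(y))
    } else {
      fit <- stats::glm(y ~ lg, family = stats::binomial())
      cal <- unname(stats::coef(fit))
      if (cal[2] < 0) cal[2] <- 0  # enforce monotone nondecreasing
      list(method = "logistic", intercept = cal[1], slope = cal[2])
    }
  } else {
    o <- order(p)
    iso <- stats::isoreg(p[o], y[o])
    list(method = "isotonic", x = iso$x, yf = iso$yf)
  }
}

apply_calibration <- function(cal, p) {
  if (is.null(cal)) return(p)
  eps <- 1e-6
  switch(cal$method,
         constant = rep(cal$value, length(p)),
         logistic = stats::plogis(cal$intercept +
                                    cal$slope * stats::qlogis(pmin(pmax(p, eps), 1 - eps))),
         isotonic = {
           f <- stats::approxfun(cal$x, cal$yf, rule = 2, ties = mean)
           pmin(pmax(f(p), 0), 1)
         })
}

#' Predict calibrated event risk for design rows
#'
#' Columns are aligned to the training dictionary: numeric features missing
#' from `rows` are scored as missing (the booster's learned default
#' directions apply), unseen binary one-hot columns score as zero, and
#' feature names unknown to the model are ignored.
#'
#' @param model a `ds_gbt`.
#' @param rows design rows.
#' @param calibrated apply the stored calibration map (if any).
#' @return Probabilities in `[0, 1]`.
#' @export
predict_risk <- function(model, rows, calibrated = TRUE) {
  rows <- data.table::as.data.table(rows)
  unknown <- setdiff(setdiff(names(rows), c("encounter_id", "day", "outcome")),
                     model$feature_cols)
  if (length(unknown)) {
    message("ignoring ", length(unknown), " feature(s) unknown to the model")
  }
  p <- raw_score(model, rows)
  if (calibrated) p <- apply_calibration(model$calibration, p)
  p
}

#' Normalized gain weights of the top-K features
#'
#' @param model a `ds_gbt`.
#' @param top_k number of features to keep (truncated with a warning when it
#'   exceeds the number of features with positive gain). Ties in gain break
#'   by feature-name lexicographic order.
#' @return Named numeric vector of weights summing to 1, descending.
#' @export
gain_weights <- function(model, top_k = 50) {
  g <- if (inherits(model, "ds_gbt")) model$gains else model
  g <- g[order(-g, names(g))]
  if (top_k > length(g)) {
    warning("top_k exceeds number of features with gain; truncating to ",
            length(g))
    top_k <- length(g)
  }
  g <- g[seq_len(top_k)]
  g / sum(g)
}

#' Persist / restore a trained model bundle
#'
#' Saves the booster (raw serialised form), feature dictionary, calibration
#' coefficients and task metadata as one versioned RDS bundle.
#'
#' @param model a `ds_gbt`.
#' @param path file path for the bundle.
#' @return `save_ds_gbt()`: the path, invisibly; `load_ds_gbt()`: the
#'   restored `ds_gbt`.
#' @export
save_ds_gbt <- function(model, path) {
  stopifnot(inherits(model, "ds_gbt"))
  bundle <- model
  bundle$booster <- xgboost::xgb.save.raw(model$booster)
  bundle$bundle_version <- 1L
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname save_ds_gbt
#' @export
load_ds_gbt <- function(path) {
  bundle <- readRDS(path)
  bundle$booster <- xgboost::xgb.load.raw(bundle$booster)
  class(bundle) <- "ds_gbt"
  bundle
}
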