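# SHAP marginal effects with bootstrap intervals, log-odds fold-change
# conversion, soft ranking, and cross-site feature-commonality analysis.

#' Per-row SHAP attributions on the log-odds scale
#'
#' Tree-path (TreeSHAP) attributions of the raw (uncalibrated) model logit;
#' the rows of the returned matrix satisfy the local-accuracy identity
#' `sum(phi) + base = logit(raw prediction)`.
#'
#' @param model a `ds_gbt`.
#' @param rows design rows.
#' @return Matrix (rows x features) of SHAP values with attribute `base`
#'   (the expected-value term, one per row).
#' @export
shap_values <- function(model, rows) {
  rows <- data.table::as.data.table(rows)
  X <- matrix(NA_real_, nrow(rows), length(model$feature_cols),
              dimnames = list(NULL, model$feature_cols))
  have <- intersect(model$feature_cols, names(rows))
  X[, have] <- as.matrix(rows[, have, with = FALSE])
  contrib <- stats::predict(model$booster, xgboost::xgb.DMatrix(X),
                            predcontrib = TRUE)
  base <- contrib[, ncol(contrib)]
  phi <- contrib[, -ncol(contrib), drop = FALSE]
  colnames(phi) <- model$feature_cols
  attr(phi, "base") <- base
  phi
}

#' Bootstrap summary of SHAP marginal effects
#'
#' Bins each feature's observed values into `bins` equal-count bins
#' (binary/discrete features keep their distinct values) and reports the
#' mean SHAP per (feature, bin) with a percentile interval over `B`
#' bootstrap resamples of the rows.
#'
#' @param model a `ds_gbt`.
#' @param rows design rows to attribute.
#' @param features features to summarise (default: the model's features with
#'   positive gain, at most 20).
#' @param B bootstrap replicates (default 100). `B < 2` yields point
#'   estimates only, flagged by `degenerate = TRUE`.
#' @param bins number of equal-count value bins for continuous features.
#' @param seed integer seed.
#' @return List with `summary` (data.table: `feature`, `bin`, `value`
#'   (bin midpoint), `n`, `mean_shap`, `lo`, `hi`), `B` and `degenerate`.
#' @export
bootstrap_shap <- function(model, rows, features = NULL, B = 100, bins = 50,
                           seed = 1) {
  phi <- shap_values(model, rows)
  if (is.null(features)) {
    features <- names(gain_weights(model, min(20, length(model$gains))))
  }
  rows <- data.table::as.data.table(rows)
  degenerate <- B < 2
  set.seed(seed)
  n <- nrow(phi)
  boot_idx <- if (degenerate) NULL else
    replicate(B, sample.int(n, replace = TRUE), simplify = FALSE)

  out <- list()
  for (f in features) {
    x <- if (f %in% names(rows)) rows[[f]] else rep(NA_real_, n)
    ux <- unique(x[is.finite(x)])
    if (length(ux) <= bins) {
      bin <- match(x, sort(ux))
      mids <- sort(ux)
    } else {
      br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                                   na.rm = TRUE, names = FALSE))
      bin <- as.integer(cut(x, breaks = br, include.lowest = TRUE))
      mids <- (br[-1] + br[-length(br)]) / 2
    }
    bin[!is.finite(x)] <- NA_integer_
    ph <- phi[, f]
    for (bi in sort(unique(bin[!is.na(bin)]))) {
      sel <- which(bin == bi)
      mean_shap <- mean(ph[sel])
      if (degenerate) {
        lo <- hi <- NA_real_
      } else {
        reps <- vapply(boot_idx, function(ix) {
          s <- ix[ix %in% sel]
          if (length(s)) mean(ph[s]) else NA_real_
        }, numeric(1))
        qs <- stats::quantile(reps, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
        lo <- qs[1]; hi <- qs[2]
      }
      out[[length(out) + 1L]] <- data.table::data.table(
        feature = f, bin = bi, value = mids[bi], n = length(sel),
        mean_shap = mean_shap, lo = lo, hi = hi)
    }
  }
  list(summary = data.table::rbindlist(out), B = B, degenerate = degenerate)
}

#' Convert a log-odds SHAP value to a fold-change in odds
#'
#' `exp(phi)`, reported to one decimal below 10 and to the nearest integer
#' above.
#'
#' @param phi finite log-odds value(s).
#' @return Fold-change(s), rounded for reporting.
#' @export
shap_to_odds <- function(phi) {
  fc <- exp(phi)
  ifelse(fc < 10, round(fc, 1), round(fc))
}

#' Exponentially decaying soft rank
#'
#' `f(r) = exp(-r / s)`: a soft membership score emphasising features ranked
#' within the top `s` without discarding weaker ones.
#'
#' @param r importance rank(s), `>= 1`.
#' @param s decay scale (default 100).
#' @return Membership in `(0, 1]`.
#' @export
soft_rank <- function(r, s = 100) {
  stopifnot(all(r >= 1))
  exp(-r / s)
}

#' Cross-site feature-commonality analysis
#'
#' Takes per-site gain rankings (named numeric vectors, larger = more
#' important, or character vectors already in rank order) and, over the
#' union of features ranked top-`top` anywhere, reports the fraction of
#' sites ranking each feature top-`top` (commonality) together with the
#' median and IQR of its soft ranks across sites. A feature absent from a
#' site's ranking contributes soft rank 0 there.
#'
#' @param site_rankings list (length >= 2) of per-site rankings.
#' @param top rank cutoff defining "important" (default 100).
#' @param s soft-rank decay scale.
#' @return data.table: `feature`, `commonality`, `median_soft_rank`,
#'   `iqr_soft_rank`, `n_sites`.
#' @export
commonality_analysis <- function(site_rankings, top = 100, s = 100) {
  if (length(site_rankings) < 2L) stop("need rankings from at least 2 sites")
  as_ranked <- function(r) {
    if (is.character(r)) r else names(sort(r, decreasing = TRUE))
  }
  ranked <- lapply(site_rankings, as_ranked)
  S <- length(ranked)
  union_top <- unique(unlist(lapply(ranked, utils::head, top)))
  out <- lapply(union_top, function(f) {
    rks <- vapply(ranked, function(rr) {
      i <- match(f, rr)
      if (is.na(i)) NA_integer_ else i
    }, integer(1))
    softs <- numeric(S)
    softs[!is.na(rks)] <- soft_rank(rks[!is.na(rks)], s)
    data.table::data.table(
      feature = f,
      commonality = sum(!is.na(rks) & rks <= top) / S,
      median_soft_rank = stats::median(softs),
      iqr_soft_rank = stats::IQR(softs),
      n_sites = S)
  })
  res <- data.table::rbindlist(out)
  data.table::setorder(res, -commonality, -median_soft_rank)
  res[]
}
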