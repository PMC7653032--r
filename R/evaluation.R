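# Discrimination (AUROC / AUPRC with encounter-level bootstrap CIs),
# Hosmer-Lemeshow calibration, HL-score comparison by F ratio, stratified
# evaluation and the cross-site AUROC difference.

#' Rank-based AUROC
#'
#' Equivalent to the concordant-pair fraction with ties counting one half.
#'
#' @param scores numeric predictions.
#' @param outcomes 0/1 outcomes, both classes present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, outcomes) {
  outcomes <- as.integer(outcomes)
  n1 <- sum(outcomes == 1L); n0 <- sum(outcomes == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUROC undefined: single outcome class")
  r <- rank(scores, ties.method = "average")
  (sum(r[outcomes == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Step-interpolated area under the precision-recall curve
#'
#' @inheritParams auroc
#' @return AUPRC in `[0, 1]`.
#' @export
auprc <- function(scores, outcomes) {
  outcomes <- as.integer(outcomes)
  if (length(unique(outcomes)) < 2L) stop("AUPRC undefined: single outcome class")
  o <- order(scores, decreasing = TRUE)
  y <- outcomes[o]; s <- scores[o]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  # evaluate at distinct thresholds only (last index of each tied block)
  last <- which(s != c(s[-1], NA))
  last[length(last) + 1L] <- length(s)
  last <- unique(last)
  prec <- tp[last] / (tp[last] + fp[last])
  rec <- tp[last] / sum(y)
  sum(diff(c(0, rec)) * prec)
}

#' Discrimination metrics with encounter-level bootstrap intervals
#'
#' Point AUROC/AUPRC plus percentile 95% confidence intervals from a
#' bootstrap that resamples encounters (the dependence unit: rows within an
#' encounter are correlated), not rows.
#'
#' @param scores,outcomes per-row predictions and 0/1 outcomes.
#' @param encounter_id optional encounter labels; when omitted, rows are
#'   treated as independent.
#' @param B bootstrap replicates.
#' @param seed integer seed.
#' @return List with `auroc`, `auprc`, `auroc_ci`, `auprc_ci`, `n`,
#'   `n_events`.
#' @export
discrimination <- function(scores, outcomes, encounter_id = NULL,
                           B = 200, seed = 1) {
  point <- list(auroc = auroc(scores, outcomes),
                auprc = auprc(scores, outcomes))
  if (is.null(encounter_id)) encounter_id <- seq_along(scores)
  ids <- unique(encounter_id)
  idx_of <- split(seq_along(scores), match(encounter_id, ids))
  set.seed(seed)
  boot <- matrix(NA_real_, B, 2)
  for (b in seq_len(B)) {
    take <- sample(length(ids), replace = TRUE)
    idx <- unlist(idx_of[take], use.names = FALSE)
    if (length(unique(outcomes[idx])) < 2L) next
    boot[b, ] <- c(auroc(scores[idx], outcomes[idx]),
                   auprc(scores[idx], outcomes[idx]))
  }
  ci <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  list(auroc = point$auroc, auprc = point$auprc,
       auroc_ci = unname(ci[, 1]), auprc_ci = unname(ci[, 2]),
       n = length(scores), n_events = sum(outcomes == 1))
}

#' Hosmer-Lemeshow calibration score
#'
#' Groups rows into `g` bins by quantiles of predicted risk and computes
#' `HLS = sum_g (O_g - E_g)^2 / (E_g (1 - pbar_g))` with `E_g = n_g pbar_g`
#' (set `variant = "pearson"` for the plain `(O-E)^2/E` version). Empty or
#' degenerate bins are merged with their neighbour. Reference distribution
#' chi-squared with `df = g - 2`.
#'
#' @param scores predicted probabilities.
#' @param outcomes 0/1 outcomes.
#' @param g number of risk groups (default deciles).
#' @param variant `"hl"` (default) or `"pearson"`.
#' @return List with `hls`, `df`, `p_value`, `g_effective`.
#' @export
hosmer_lemeshow <- function(scores, outcomes, g = 10,
                            variant = c("hl", "pearson")) {
  variant <- match.arg(variant)
  br <- unique(stats::quantile(scores, probs = seq(0, 1, length.out = g + 1),
                               names = FALSE))
  if (length(br) < 3) {
    # all scores (nearly) identical: a single effective bin, perfect fit of
    # the prevalence, HLS 0 by convention
    return(list(hls = 0, df = max(1L, g - 2L), p_value = 1, g_effective = 1L))
  }
  bin <- cut(scores, breaks = br, include.lowest = TRUE)
  n_g <- tabulate(bin, nbins = nlevels(bin))
  keep <- n_g > 0L
  obs <- tapply(outcomes, bin, sum)[keep]
  pbar <- tapply(scores, bin, mean)[keep]
  n_g <- n_g[keep]
  expd <- n_g * pbar
  denom <- if (variant == "hl") expd * (1 - pbar) else expd
  ok <- denom > 0
  hls <- sum((obs[ok] - expd[ok])^2 / denom[ok])
  df <- max(1L, length(n_g) - 2L)
  list(hls = hls, df = df,
       p_value = stats::pchisq(hls, df, lower.tail = FALSE),
       g_effective = length(n_g))
}

#' Compare two Hosmer-Lemeshow scores by an F ratio
#'
#' `F = (hls_a / df_a) / (hls_b / df_b)` referred to `F(df_a, df_b)`;
#' two-sided p-value.
#'
#' @param hls_a,hls_b HL scores (nonnegative).
#' @param df_a,df_b their degrees of freedom.
#' @return List with `F`, `df`, `p_value`.
#' @export
compare_hls <- function(hls_a, hls_b, df_a, df_b) {
  if (hls_b <= 0) stop("F undefined: zero denominator HL score")
  f <- (hls_a / df_a) / (hls_b / df_b)
  p <- 2 * min(stats::pf(f, df_a, df_b), stats::pf(f, df_a, df_b,
                                                   lower.tail = FALSE))
  list(F = f, df = c(df_a, df_b), p_value = min(1, p))
}

#' Stratified discrimination report
#'
#' @param scores,outcomes,encounter_id as in [discrimination()].
#' @param strata factor-like vector assigning each row to a stratum.
#' @param B,seed bootstrap controls.
#' @return Data frame with one row per stratum: `stratum`, `n`, `n_events`,
#'   `auroc`, `auprc` and `evaluable` (FALSE when a stratum holds a single
#'   class).
#' @export
stratified_eval <- function(scores, outcomes, strata, encounter_id = NULL,
                            B = 200, seed = 1) {
  levs <- unique(as.character(strata))
  out <- lapply(levs, function(lv) {
    i <- which(as.character(strata) == lv)
    if (length(i) == 0L || length(unique(outcomes[i])) < 2L) {
      return(data.frame(stratum = lv, n = length(i),
                        n_events = sum(outcomes[i] == 1),
                        auroc = NA_real_, auprc = NA_real_, evaluable = FALSE))
    }
    data.frame(stratum = lv, n = length(i), n_events = sum(outcomes[i] == 1),
               auroc = auroc(scores[i], outcomes[i]),
               auprc = auprc(scores[i], outcomes[i]), evaluable = TRUE)
  })
  do.call(rbind, out)
}

#' Cross-site AUROC deterioration
#'
#' `delta = source_auc - target_auc`; positive values mean the model
#' discriminates worse at the target site.
#'
#' @param source_auc AUROC on the source temporal validation set.
#' @param target_auc AUROC at the external target site.
#' @param source,target optional labels.
#' @return List with `delta`, `source_auc`, `target_auc`, labels.
#' @export
delta_auc <- function(source_auc, target_auc, source = "source",
                      target = "target") {
  list(delta = source_auc - target_auc, source_auc = source_auc,
       target_auc = target_auc, source = source, target = target)
}

#' Serialize a metric report as structured JSON
#'
#' @param report any list-like metric report (e.g. [discrimination()] output,
#'   possibly nested by stratum or site).
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_metric_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
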