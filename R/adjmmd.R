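# Adjusted maximum mean discrepancy (adjMMD): per-feature unbiased kernel
# MMD between source and target samples, adversarial imputation that
# penalises missingness harder than distribution discrepancy, gain-weighted
# aggregation over the top-K model features, minimal-feature-set search,
# the adjMMD -> deltaAUC transportability regression, its random-slope
# mixed-effect generalisation, and sample-/model-agnostic validation tests.

#' Unbiased kernel MMD between two samples
#'
#' The U-statistic estimator: the mean Gaussian kernel over ordered pairs
#' within each sample minus twice the mean over cross pairs,
#' `kappa(a, b) = exp(-(a - b)^2 / (2 h^2))`. Being unbiased it may come out
#' slightly negative when the distributions match.
#'
#' @param x,y numeric samples from source and target (length >= 2 each).
#' @param h Gaussian kernel bandwidth (> 0).
#' @return The MMD estimate (scalar).
#' @export
mmd_unbiased <- function(x, y, h) {
  n <- length(x); m <- length(y)
  if (n < 2 || m < 2) stop("need at least 2 points in each sample")
  if (!is.finite(h) || h <= 0) stop("bandwidth must be positive")
  kxx <- exp(-outer(x, x, "-")^2 / (2 * h^2))
  kyy <- exp(-outer(y, y, "-")^2 / (2 * h^2))
  kxy <- exp(-outer(x, y, "-")^2 / (2 * h^2))
  (sum(kxx) - n) / (n * (n - 1)) + (sum(kyy) - m) / (m * (m - 1)) -
    2 * mean(kxy)
}

# median-heuristic bandwidth: median absolute pairwise difference of the
# pooled sample (positive differences only; 1 as a floor for degenerate data)
median_bandwidth <- function(pooled, cap = 2000) {
  pooled <- pooled[is.finite(pooled)]
  if (length(pooled) > cap) pooled <- pooled[seq(1, length(pooled), length.out = cap)]
  d <- abs(outer(pooled, pooled, "-"))
  d <- d[upper.tri(d)]
  d <- d[d > 0]
  if (!length(d)) return(1)
  stats::median(d)
}

#' Adversarial draws for missing target values
#'
#' Imputes missing target observations with values that are very unlikely
#' under the source distribution, so that missingness is penalised harder
#' than ordinary distribution discrepancy. `"kde_tails"` (default) samples
#' from the bottom and top 1% of a kernel density estimate of the source;
#' `"se_band"` samples outside `mean(x) +/- z_0.99 * sd(x) / sqrt(n)` (a
#' standard-error band that narrows with n and therefore penalises weakly
#' for large samples; kept for completeness).
#'
#' @param source_values observed source sample for the feature.
#' @param m_missing number of values to draw.
#' @param method `"kde_tails"` or `"se_band"`.
#' @param tail_prob tail mass used by `"kde_tails"`.
#' @return Numeric vector of `m_missing` adversarial draws.
#' @export
adversarial_impute <- function(source_values, m_missing,
                               method = c("kde_tails", "se_band"),
                               tail_prob = 0.01) {
  method <- match.arg(method)
  if (m_missing <= 0) return(numeric())
  x <- source_values[is.finite(source_values)]
  s <- stats::sd(x)
  if (length(x) < 2 || !is.finite(s) || s == 0) {
    message("degenerate source sample: offset-constant adversarial fallback")
    off <- max(1, abs(mean(x)))
    return(rep(mean(x) + 6 * off, m_missing))
  }
  if (method == "kde_tails") {
    de <- stats::density(x, n = 2048, cut = 4)
    cdf <- cumsum(de$y); cdf <- cdf / cdf[length(cdf)]
    u <- ifelse(stats::runif(m_missing) < 0.5,
                stats::runif(m_missing, 0, tail_prob),
                stats::runif(m_missing, 1 - tail_prob, 1))
    ok <- !duplicated(cdf)
    stats::approx(cdf[ok], de$x[ok], xout = u, rule = 2)$y
  } else {
    half <- stats::qnorm(0.99) * s / sqrt(length(x))
    side <- sample(c(-1, 1), m_missing, replace = TRUE)
    mean(x) + side * (half + abs(stats::rnorm(m_missing, 0, s)))
  }
}

#' Gain-weighted missingness-penalised MMD profile
#'
#' For each of the top-`K_max` model features (ordered by the supplied gain
#' weights): standardise source and target values by the source mean/SD,
#' pick the Gaussian bandwidth by the median heuristic on the pooled
#' observed sample, replace missing target values (a feature absent from the
#' target schema counts as 100% missing) by [adversarial_impute()] draws,
#' and evaluate the unbiased MMD. Binary features use their raw 0/1 samples
#' with the same kernel; their missing values are imputed from the
#' complement of the source Bernoulli distribution. The aggregate
#' `adjMMD(K)` is the weight-renormalised mean of the first K per-feature
#' MMDs, reported for every `K <= K_max`.
#'
#' @param source_data,target_data data frames of feature columns (e.g. the
#'   design-matrix columns of the derivation set and of the target site).
#' @param weights named gain weights from [gain_weights()], descending.
#' @param K_max number of top features profiled.
#' @param method imputation method, see [adversarial_impute()].
#' @param cap per-feature subsample cap for the O(n^2) kernel sums.
#' @param clip_negative set negative per-feature MMDs to zero.
#' @param seed integer seed (subsampling and imputation draws).
#' @return An object of class `adjmmd_profile`: list with `features`
#'   (data.table: `feature`, `weight`, `mmd`, `missing_fraction`,
#'   `bandwidth`), `adjmmd` (vector over K = 1..K_max), `method`.
#' @export
compute_adjmmd <- function(source_data, target_data, weights,
                           K_max = length(weights),
                           method = c("kde_tails", "se_band"),
                           cap = 2000, clip_negative = FALSE, seed = 1) {
  method <- match.arg(method)
  source_data <- data.table::as.data.table(source_data)
  target_data <- data.table::as.data.table(target_data)
  feats <- names(weights)[seq_len(min(K_max, length(weights)))]
  feats <- feats[feats %in% names(source_data)]
  if (!length(feats)) stop("no profiled features present in the source data")
  set.seed(seed)
  rows <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[i]
    xs <- source_data[[f]]
    xs <- xs[is.finite(xs)]
    xt_all <- if (f %in% names(target_data)) target_data[[f]] else
      rep(NA_real_, nrow(target_data))
    miss_frac <- mean(!is.finite(xt_all))
    xt_obs <- xt_all[is.finite(xt_all)]

    if (length(xs) > cap) xs <- sample(xs, cap)
    m_total <- min(cap, length(xt_all))
    m_obs <- min(length(xt_obs), round((1 - miss_frac) * m_total))
    m_miss <- m_total - m_obs
    if (length(xt_obs) > m_obs) xt_obs <- sample(xt_obs, m_obs)

    is_binary <- all(xs %in% c(0, 1)) &&
      (length(xt_obs) == 0 || all(xt_obs %in% c(0, 1)))
    if (is_binary) {
      # penalty for absent codes: draws from the complement distribution
      p_src <- mean(xs)
      imp <- if (m_miss > 0) stats::rbinom(m_miss, 1, 1 - p_src) else numeric()
      xt <- c(xt_obs, imp)
      h <- max(median_bandwidth(c(xs, xt_obs), cap = min(cap, 500)), 0.5)
      mmd <- mmd_unbiased(xs, xt, h)
    } else {
      mu <- mean(xs); sdv <- stats::sd(xs)
      if (!is.finite(sdv) || sdv == 0) sdv <- 1
      zs <- (xs - mu) / sdv
      zt_obs <- (xt_obs - mu) / sdv
      imp <- if (m_miss > 0) adversarial_impute(zs, m_miss, method = method)
        else numeric()
      zt <- c(zt_obs, imp)
      h <- median_bandwidth(c(zs, zt_obs), cap = min(cap, 500))
      mmd <- if (length(zt) >= 2) mmd_unbiased(zs, zt, h) else NA_real_
    }
    if (clip_negative && is.finite(mmd)) mmd <- max(0, mmd)
    rows[[i]] <- data.table::data.table(
      feature = f, weight = unname(weights[f]), mmd = mmd,
      missing_fraction = miss_frac, bandwidth = h)
  }
  tab <- data.table::rbindlist(rows)
  w <- tab$weight
  adj <- cumsum(w * tab$mmd) / cumsum(w)
  structure(list(features = tab, adjmmd = adj, method = method),
            class = "adjmmd_profile")
}

#' @export
print.adjmmd_profile <- function(x, ...) {
  K <- length(x$adjmmd)
  cat(sprintf("<adjmmd_profile> %d feature(s), adjMMD(1)=%.3f adjMMD(%d)=%.3f [%s]\n",
              K, x$adjmmd[1], K, x$adjmmd[K], x$method))
  invisible(x)
}

#' Minimal feature set for transportability inference
#'
#' Correlates, for every K, the per-site `adjMMD(K)` with the per-site
#' AUROC drop, and returns the Pearson curve together with `K*`, the
#' smallest K attaining its maximum.
#'
#' @param profiles list of `adjmmd_profile`s, one per target site, computed
#'   with the same feature ordering.
#' @param deltas per-site AUROC drops, aligned with `profiles`.
#' @return List with `K_star`, `rho` (vector over K) and `rho_max`.
#' @export
minimal_feature_set <- function(profiles, deltas) {
  if (length(profiles) < 3) stop("need at least 3 (site, deltaAUC) pairs")
  if (length(profiles) != length(deltas)) stop("profiles/deltas length mismatch")
  if (stats::sd(deltas) == 0) stop("deltaAUC constant across sites: correlation undefined")
  K <- min(vapply(profiles, function(p) length(p$adjmmd), 1L))
  mm <- vapply(profiles, function(p) p$adjmmd[seq_len(K)], numeric(K))
  if (K == 1) mm <- matrix(mm, nrow = 1)
  rho <- apply(mm, 1, function(v) {
    if (stats::sd(v) == 0) NA_real_ else stats::cor(v, deltas)
  })
  k_star <- which(rho >= max(rho, na.rm = TRUE) - 1e-12)[1]
  list(K_star = k_star, rho = rho, rho_max = rho[k_star])
}

#' Linear transportability regression of AUROC drop on adjMMD
#'
#' Ordinary least squares `deltaAUC = beta0 + beta1 * adjMMD`.
#'
#' @param adjmmd_values per-site adjMMD at the chosen K.
#' @param deltas per-site AUROC drops.
#' @param conf_level CI level for the slope/intercept.
#' @return List with `beta0`, `beta1`, `ci` (matrix), `fit` (the `lm`).
#' @export
fit_transport_regression <- function(adjmmd_values, deltas,
                                     conf_level = 0.95) {
  if (length(adjmmd_values) < 2) stop("need at least 2 pairs")
  if (stats::sd(adjmmd_values) == 0) stop("adjMMD values are constant: rank-deficient fit")
  fit <- stats::lm(deltas ~ adjmmd_values)
  ci <- if (length(adjmmd_values) > 2) {
    suppressWarnings(stats::confint(fit, level = conf_level))
  } else matrix(NA_real_, 2, 2)
  co <- unname(stats::coef(fit))
  list(beta0 = co[1], beta1 = co[2], ci = ci, fit = fit)
}

#' Expected AUROC of a model transported to a new site
#'
#' `"slope_only"` subtracts `beta1 * adjMMD` from the source AUROC (the
#' intercept-free back-of-envelope arithmetic); `"full"` subtracts the whole
#' fitted drop `beta0 + beta1 * adjMMD`. The reported value rounds the
#' expectation DOWN to 2 decimals — a deliberately conservative report that
#' never overstates transported performance.
#'
#' @param source_auc AUROC on the source temporal validation set.
#' @param adjmmd_value observed adjMMD at the target site.
#' @param fit a [fit_transport_regression()] result, or a list with `beta0`
#'   and `beta1`.
#' @param mode `"slope_only"` (default) or `"full"`.
#' @return List with `expected` (raw) and `reported` (floored to 2
#'   decimals).
#' @export
predict_target_auc <- function(source_auc, adjmmd_value, fit,
                               mode = c("slope_only", "full")) {
  mode <- match.arg(mode)
  drop <- switch(mode,
                 slope_only = fit$beta1 * adjmmd_value,
                 full = fit$beta0 + fit$beta1 * adjmmd_value)
  expected <- source_auc - drop
  list(expected = expected, reported = floor(expected * 100) / 100,
       mode = mode)
}

#' Random-slope mixed-effect transportability model
#'
#' Generalises the linear adjMMD -> deltaAUC relation over several models
#' (i) and derivation sites (j): fixed intercept and slope, a random
#' intercept by site, and random slopes by model and by site, fitted by
#' REML:
#' `y ~ x + (1 | site) + (0 + x | site) + (0 + x | model)`.
#'
#' @param pairs data.frame with columns `y` (deltaAUC), `x` (adjMMD),
#'   `model` and `site` labels (>= 2 levels each).
#' @param conf_level Wald CI level for the fixed effects.
#' @return List with `beta0`, `beta1`, `ci`, `varcomp` (data frame of
#'   variance components), `converged`, `fit` (the `lmerMod`).
#' @export
fit_mixed_effect <- function(pairs, conf_level = 0.95) {
  pairs <- as.data.frame(pairs)
  stopifnot(all(c("y", "x", "model", "site") %in% names(pairs)))
  if (length(unique(pairs$site)) < 2) stop("need >= 2 site levels")
  if (length(unique(pairs$model)) < 2) stop("need >= 2 model levels")
  fit <- lme4::lmer(
    y ~ x + (1 | site) + (0 + x | site) + (0 + x | model),
    data = pairs, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = FALSE))
  msgs <- fit@optinfo$conv$lme4$messages
  fe <- lme4::fixef(fit)
  ci <- suppressWarnings(stats::confint(fit, parm = "beta_",
                                        method = "Wald", level = conf_level))
  list(beta0 = unname(fe[1]), beta1 = unname(fe[2]), ci = ci,
       varcomp = as.data.frame(lme4::VarCorr(fit)),
       converged = is.null(msgs), messages = msgs, fit = fit)
}

#' Sample- and model-agnostic robustness tests
#'
#' Fits the transportability line on the pairs of a single group (one
#' derivation site for the sample-agnostic scheme, one model for the
#' model-agnostic scheme), computes each group's mean squared prediction
#' error (RSS) under that line, and repeats over all derivation groups. The
#' collections of same-group and different-group RSS values are compared by
#' a two-sided location test (Welch by default): a small p-value means the
#' fitted relation does not generalise across groups.
#'
#' @param pairs data.frame with `y`, `x` and the grouping columns `site`
#'   and/or `model`.
#' @param held_out_scheme `"sample"` (group = derivation site) or
#'   `"model"`.
#' @param test `"welch"` or `"wilcoxon"`.
#' @return List with `rss` (data.table: `fit_group`, `eval_group`, `rss`,
#'   `same`), `statistic`, `p_value`, `test`.
#' @export
agnostic_tests <- function(pairs, held_out_scheme = c("sample", "model"),
                           test = c("welch", "wilcoxon")) {
  held_out_scheme <- match.arg(held_out_scheme)
  test <- match.arg(test)
  pairs <- as.data.frame(pairs)
  gcol <- if (held_out_scheme == "sample") "site" else "model"
  if (!gcol %in% names(pairs)) stop("pairs lack a `", gcol, "` column")
  groups <- unique(pairs[[gcol]])
  sizes <- table(pairs[[gcol]])
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    message("excluding group(s) with < 2 observations: ",
            paste(small, collapse = ", "))
    groups <- setdiff(groups, small)
  }
  if (length(groups) < 2) stop("need at least 2 groups with >= 2 observations")
  out <- list()
  for (g in groups) {
    sub <- pairs[pairs[[gcol]] == g, ]
    fit <- stats::lm(y ~ x, data = sub)
    for (h in groups) {
      ev <- pairs[pairs[[gcol]] == h, ]
      pred <- stats::predict(fit, newdata = ev)
      out[[length(out) + 1L]] <- data.table::data.table(
        fit_group = as.character(g), eval_group = as.character(h),
        rss = mean((ev$y - pred)^2), same = identical(g, h))
    }
  }
  rss <- data.table::rbindlist(out)
  same <- rss$rss[rss$same]; diff <- rss$rss[!rss$same]
  ht <- if (test == "welch") stats::t.test(same, diff) else
    stats::wilcox.test(same, diff, exact = FALSE)
  list(rss = rss, statistic = unname(ht$statistic),
       p_value = ht$p.value, test = test)
}
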