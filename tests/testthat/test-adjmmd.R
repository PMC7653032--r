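test_that("unbiased MMD matches closed forms and the double-loop oracle", {
  # identical constant samples: 1 + 1 - 2
  expect_equal(mmd_unbiased(c(2, 2), c(2, 2), h = 1), 0)
  # two distinct constants: closed form 2 * (1 - exp(-(a-b)^2 / (2 h^2)))
  a <- 1; b <- 2.5; h <- 0.8
  expect_equal(mmd_unbiased(c(a, a), c(b, b), h),
               2 * (1 - exp(-(a - b)^2 / (2 * h^2))))
  set.seed(1)
  for (i in 1:20) {
    x <- rnorm(20); y <- rnorm(20, 0.5)
    expect_equal(mmd_unbiased(x, y, 1), oracle_mmd(x, y, 1),
                 tolerance = 1e-12)
  }
  expect_error(mmd_unbiased(1, c(1, 2), 1), "at least 2")
  expect_error(mmd_unbiased(c(1, 2), c(1, 2), 0), "bandwidth")
})

test_that("MMD estimator is centred at zero for matched distributions", {
  set.seed(2)
  vals <- replicate(200, mmd_unbiased(rnorm(40), rnorm(40), 1))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 3 * se)
})

test_that("adversarial draws land in the source tails", {
  set.seed(3)
  x <- rnorm(800)
  imp <- adversarial_impute(x, 300, method = "kde_tails")
  q <- quantile(x, c(0.02, 0.98))
  expect_true(all(imp <= q[1] | imp >= q[2]))

  band <- adversarial_impute(x, 300, method = "se_band")
  half <- qnorm(0.99) * sd(x) / sqrt(length(x))
  expect_true(all(abs(band - mean(x)) >= half - 1e-12))

  expect_message(flat <- adversarial_impute(rep(2, 50), 10), "degenerate")
  expect_true(all(flat > 2))
  expect_length(adversarial_impute(x, 0), 0)
})

test_that("adjMMD is zero for identical data and decays as matched features dilute", {
  src <- data.frame(a = rep(0.5, 60), b = rep(1, 60))
  w <- c(a = 0.6, b = 0.4)
  # identical constant source/target
  pr0 <- compute_adjmmd(src, src, w)
  expect_equal(unname(pr0$adjmmd), c(0, 0), tolerance = 1e-12)

  set.seed(4)
  n <- 400
  srcd <- data.frame(top = rnorm(n), m1 = rnorm(n), m2 = rnorm(n),
                     m3 = rnorm(n))
  tgtd <- data.frame(m1 = rnorm(n), m2 = rnorm(n), m3 = rnorm(n))
  w4 <- c(top = 0.4, m1 = 0.2, m2 = 0.2, m3 = 0.2)
  pr <- compute_adjmmd(srcd, tgtd, w4, seed = 9)
  expect_equal(pr$features$missing_fraction[1], 1)
  # the top-weight feature (w = 0.4) is fully missing, the rest matched:
  # the weighted mean decays toward ~0.4x the initial jump as the matched
  # features dilute it
  expect_gt(pr$adjmmd[1], 0.5)
  expect_lt(pr$adjmmd[4], 0.6 * pr$adjmmd[1])
  expect_true(all(diff(pr$adjmmd) < 0))
})

test_that("adjMMD is invariant to affine rescaling and feature permutation", {
  set.seed(5)
  n <- 300
  src <- data.frame(a = rnorm(n, 5, 2), b = rnorm(n))
  tgt <- data.frame(a = rnorm(n, 6, 2), b = rnorm(n))
  w <- c(a = 0.5, b = 0.5)
  base <- compute_adjmmd(src, tgt, w, seed = 11)
  resc <- compute_adjmmd(
    transform(src, a = 10 * a + 3), transform(tgt, a = 10 * a + 3), w,
    seed = 11)
  expect_equal(base$adjmmd, resc$adjmmd, tolerance = 1e-8)
  # permuting two equally weighted matched features keeps the aggregate
  perm <- compute_adjmmd(src[, c("b", "a")], tgt, c(b = 0.5, a = 0.5),
                         seed = 11)
  expect_equal(perm$adjmmd[2], base$adjmmd[2], tolerance = 1e-10)
})

test_that("penalised MMD rises monotonically with target missingness", {
  set.seed(6)
  n <- 300
  src <- data.frame(f = rnorm(n))
  fracs <- seq(0, 1, length.out = 8)
  base_target <- rnorm(n)
  mmds <- sapply(fracs, function(fr) {
    tgt <- data.frame(f = base_target)
    if (fr > 0) tgt$f[seq_len(round(fr * n))] <- NA
    compute_adjmmd(src, tgt, c(f = 1), seed = 21)$adjmmd[1]
  })
  expect_true(all(diff(mmds) > 0))
})

test_that("binary features are penalised through the complement distribution", {
  set.seed(7)
  src <- data.frame(flag = rbinom(500, 1, 0.15))
  tgt_absent <- data.frame(other = rnorm(500))
  pr <- compute_adjmmd(src, tgt_absent, c(flag = 1), seed = 3)
  expect_equal(pr$features$missing_fraction, 1)
  # complement imputation flips p = 0.15 to 0.85; with unit bandwidth the
  # expected MMD is 2(1 - exp(-1/2))(p - q)^2 * 2 ~ 0.39
  expect_gt(pr$adjmmd[1], 0.25)
  tgt_same <- data.frame(flag = rbinom(500, 1, 0.15))
  pr2 <- compute_adjmmd(src, tgt_same, c(flag = 1), seed = 3)
  expect_lt(abs(pr2$adjmmd[1]), 0.05)
})

test_that("minimal feature set finds where correlation peaks", {
  mk_profile <- function(adj) structure(list(
    features = NULL, adjmmd = adj, method = "kde_tails"),
    class = "adjmmd_profile")
  # only the first feature shifts, deltas proportional to its MMD
  shift <- c(0.05, 0.1, 0.2, 0.4)
  profiles <- lapply(shift, function(s) mk_profile(c(s, s / 2, s / 3)))
  res <- minimal_feature_set(profiles, deltas = 0.3 * shift)
  expect_equal(res$K_star, 1L)
  expect_equal(res$rho_max, 1, tolerance = 1e-12)

  # constant deltas: undefined
  expect_error(minimal_feature_set(profiles, rep(0.1, 4)), "constant")
  expect_error(minimal_feature_set(profiles[1:2], c(0.1, 0.2)), "at least 3")

  # shift spread over the first five features: correlation saturates by K=5
  set.seed(8)
  shifts5 <- seq(0.1, 0.6, length.out = 6)
  profs <- lapply(shifts5, function(s) {
    per_feat <- c(rep(s, 5), rep(0.02, 5)) + rnorm(10, 0, 0.005)
    mk_profile(cumsum(per_feat) / seq_len(10))
  })
  res5 <- minimal_feature_set(profs, 0.3 * shifts5 + rnorm(6, 0, 0.002))
  expect_gte(res5$rho[5], 0.99)
})

test_that("transport regression recovers exact and noisy lines", {
  x <- c(0.05, 0.1, 0.2, 0.3)
  fit <- fit_transport_regression(x, 0.3 * x)
  expect_equal(fit$beta0, 0, tolerance = 1e-12)
  expect_equal(fit$beta1, 0.3, tolerance = 1e-12)

  two <- fit_transport_regression(c(0.1, 0.2), c(0.02, 0.05))
  expect_equal(unname(stats::resid(two$fit)), c(0, 0), tolerance = 1e-12)

  set.seed(9)
  cover <- mean(replicate(100, {
    xs <- runif(8, 0, 0.3)
    ys <- -0.018 + 0.344 * xs + rnorm(8, 0, 0.01)
    ci <- fit_transport_regression(xs, ys)$ci
    ci[2, 1] <= 0.344 && 0.344 <= ci[2, 2]
  }))
  expect_gte(cover, 0.9)
  expect_error(fit_transport_regression(rep(0.1, 3), 1:3 / 10), "constant")
})

test_that("expected target AUROC follows the slope-only and full arithmetic", {
  fit <- list(beta0 = -0.018, beta1 = 0.344)
  slope <- predict_target_auc(0.81, 0.1, fit, mode = "slope_only")
  expect_equal(slope$reported, 0.77)
  expect_equal(slope$expected, 0.81 - 0.0344, tolerance = 1e-12)
  full <- predict_target_auc(0.81, 0.1, fit, mode = "full")
  expect_equal(full$reported, 0.79)
  none <- predict_target_auc(0.81, 0, fit, mode = "slope_only")
  expect_equal(none$expected, 0.81)
})

test_that("mixed-effect fit degenerates to OLS without group variance", {
  set.seed(10)
  x <- runif(60, 0, 0.3)
  y <- -0.01 + 0.3 * x + rnorm(60, 0, 0.002)
  pairs <- data.frame(y = y, x = x,
                      model = rep(c("m1", "m2"), 30),
                      site = rep(c("s1", "s2", "s3"), each = 20))
  fit <- fit_mixed_effect(pairs)
  ols <- coef(lm(y ~ x))
  expect_equal(fit$beta1, unname(ols[2]), tolerance = 0.05)
  expect_true(all(fit$varcomp$vcov >= 0))
  expect_error(fit_mixed_effect(transform(pairs, site = "s1")), "site levels")
})

test_that("agnostic tests detect group-specific relations and not null ones", {
  set.seed(12)
  mk_pairs <- function(slopes_by_site) {
    do.call(rbind, lapply(names(slopes_by_site), function(s) {
      x <- runif(12, 0, 0.3)
      data.frame(y = 0.01 + slopes_by_site[[s]] * x + rnorm(12, 0, 0.005),
                 x = x, site = s, model = rep(c("m1", "m2"), 6))
    }))
  }
  null_pairs <- mk_pairs(list(s1 = 0.3, s2 = 0.3, s3 = 0.3, s4 = 0.3))
  res <- agnostic_tests(null_pairs, "sample")
  expect_gt(res$p_value, 0.01)
  expect_true(all(c("fit_group", "eval_group", "rss", "same") %in%
                    names(res$rss)))

  strong <- mk_pairs(list(s1 = -0.5, s2 = 0.9, s3 = 0.1, s4 = 1.8))
  res2 <- agnostic_tests(strong, "sample")
  expect_lt(res2$p_value, 0.05)
  expect_gt(mean(res2$rss$rss[!res2$rss$same]),
            mean(res2$rss$rss[res2$rss$same]))

  expect_error(agnostic_tests(null_pairs[null_pairs$site == "s1", ], "sample"),
               "at least 2 groups")
})
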