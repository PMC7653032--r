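# Independent brute-force oracles. These deliberately re-derive every rule
# from scratch (plain loops over a dense day grid / exhaustive pairs), so
# they share no code path with the package implementation they check.

# random SCr trajectory with optional pre-admission records and RRT
random_scr_trajectory <- function(seed) {
  set.seed(seed)
  los <- sample(1:12, 1)
  n <- sample(1:10, 1)
  times <- sort(round(runif(n, -3, los - 1e-6), 3))
  if (runif(1) < 0.3) times <- c(times, times[sample(n, 1)])  # duplicates
  values <- round(runif(length(times), 0.4, 5), 2)
  rrt <- if (runif(1) < 0.15) runif(1, 0, los) else numeric()
  scr_series(paste0("t", seed), times, values,
             admission_time = 0, discharge_time = los, rrt_times = rrt)
}

# dense-grid re-evaluation of the staging rules at every day
oracle_label_sequence <- function(scr, tau = 7, lookback = 7) {
  los <- max(1, ceiling(scr$discharge_time - scr$admission_time))
  censor <- min(los, tau)
  adm_idx <- which(scr$times >= scr$admission_time)
  adm_val <- if (length(adm_idx)) scr$values[adm_idx[1]] else scr$values[1]
  stage_at <- function(i) {
    t_i <- scr$times[i]; v_i <- scr$values[i]
    prior <- which(scr$times < t_i & scr$times >= t_i - lookback)
    base <- if (length(prior)) scr$values[prior[length(prior)]] else adm_val
    w48 <- which(scr$times < t_i & scr$times >= t_i - 2)
    d48 <- if (length(w48)) v_i - min(scr$values[w48]) else 0
    rrt <- length(scr$rrt_times) > 0 && any(scr$rrt_times <= t_i)
    ratio <- v_i / base
    st <- 0L
    if (d48 >= 0.3 || ratio >= 1.5) st <- 1L
    if (ratio >= 2 && ratio < 3) st <- 2L
    if (rrt || ratio > 3 || (v_i >= 4 && d48 >= 0.3)) st <- 3L
    st
  }
  day_of <- floor(scr$times - scr$admission_time) + 1
  stages <- integer(censor)
  for (d in seq_len(censor)) {
    cand <- which(day_of >= 1 & day_of <= d)
    stages[d] <- if (length(cand)) stage_at(cand[length(cand)]) else 0L
  }
  if (length(scr$rrt_times)) {
    rd <- floor(min(scr$rrt_times) - scr$admission_time) + 1
    if (rd <= censor) stages[max(1, rd):censor] <- 3L
  }
  stages
}

# person-period window enumerator: walk days while at risk, emit a row when
# the window either contains the onset or closes before censoring
oracle_row_plan <- function(onset, censor_day, dt) {
  t <- integer(); y <- integer()
  for (tt in seq_len(censor_day)) {
    if (!is.na(onset) && onset <= tt) break
    window <- (tt + 1):(tt + dt)
    if (!is.na(onset) && onset %in% window) {
      t <- c(t, tt); y <- c(y, 1L)
    } else if (max(window) <= censor_day) {
      t <- c(t, tt); y <- c(y, 0L)
    }
  }
  data.frame(day = t, outcome = y)
}

# exhaustive concordant-pair AUROC with ties counting one half
oracle_auroc <- function(scores, outcomes) {
  pos <- scores[outcomes == 1]; neg <- scores[outcomes == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# double-loop evaluation of the unbiased MMD estimator, term by term
oracle_mmd <- function(x, y, h) {
  k <- function(a, b) exp(-(a - b)^2 / (2 * h^2))
  n <- length(x); m <- length(y)
  s1 <- 0
  for (j in 1:n) for (i in 1:n) if (i != j) s1 <- s1 + k(x[i], x[j])
  s2 <- 0
  for (j in 1:m) for (i in 1:m) if (i != j) s2 <- s2 + k(y[i], y[j])
  s3 <- 0
  for (j in 1:m) for (i in 1:n) s3 <- s3 + k(x[i], y[j])
  s1 / (n * (n - 1)) + s2 / (m * (m - 1)) - 2 * s3 / (n * m)
}
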