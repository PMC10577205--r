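# Independent oracles used by the test suite. These deliberately avoid the
# code paths they check: midranks are computed from first principles, peak
# search by an explicit element-by-element scan, and OLS through the normal
# equations.

# Midranks without rank(): average position of each tied value in the
# sorted sequence.
oracle_midranks <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    less <- sum(x < x[i])
    tied <- sum(x == x[i])
    r[i] <- less + (tied + 1) / 2
  }
  r
}

# Kruskal-Wallis H with tie correction, straight from the rank formula.
oracle_kruskal_h <- function(a, b) {
  x <- c(a, b)
  g <- rep(1:2, c(length(a), length(b)))
  n <- length(x)
  r <- oracle_midranks(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, sum)^2 / tabulate(g)) - 3 * (n + 1)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h / corr
}

# Extremum by explicit scan with the earliest-sample tie rule.
oracle_scan <- function(values, idx, decreasing = FALSE) {
  best <- idx[1]
  for (i in idx[-1]) {
    better <- if (decreasing) values[i] < values[best] else values[i] > values[best]
    if (better) best <- i
  }
  best
}

# OLS through the normal equations plus R^2 = 1 - SSE/SST.
oracle_ols <- function(X, y) {
  X1 <- cbind(1, X)
  beta <- solve(t(X1) %*% X1, t(X1) %*% y)
  fitted <- X1 %*% beta
  sse <- sum((y - fitted)^2)
  sst <- sum((y - mean(y))^2)
  n <- length(y); p <- ncol(X)
  r2 <- 1 - sse / sst
  list(beta = drop(beta), r2 = r2,
       adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p - 1))
}

# A generation config with noise and blinks off, for exact-recovery tests.
quiet_config <- function(group = "burnout") {
  cfg <- erp_gen_config(group)
  cfg$noise_sd_uv <- 0
  cfg$blink_rate <- 0
  cfg
}

# A small block of Go/NoGo test trials.
test_trials <- function(seed = 1, n_test = 1) {
  s <- generate_session(seed, n_practice = 0, n_test = n_test)
  s
}

# Epochs from n copies of one condition's trials under a config.
condition_epochs <- function(cfg, condition = "Go", n = 50, seed = 1) {
  set.seed(seed)
  tr <- test_trials(seed)
  tr <- tr[tr$condition == condition, , drop = FALSE]
  tr <- tr[rep(seq_len(nrow(tr)), length.out = n), , drop = FALSE]
  simulate_epochs(tr, cfg)
}

# Trial-level outcome table with a known commission-error generating model:
# logit(p) = qlogis(p_base) + log(or_group)*[burnout] + u_subject,
# u ~ N(0, sd_subj^2). Groups split evenly; stimulator and valence balanced.
simulate_error_trials <- function(n_subj, n_trials, p_base, or_group,
                                  sd_subj) {
  rows <- lapply(seq_len(n_subj), function(s) {
    grp <- if (s <= n_subj / 2) "burnout" else "non_burnout"
    u <- rnorm(1, 0, sd_subj)
    lp <- qlogis(p_base) + log(or_group) * (grp == "burnout") + u
    d <- data.frame(
      subject = sprintf("s%03d", s),
      group = grp,
      condition = "NoGo",
      stimulator = rep(c("ON", "OFF"), length.out = n_trials),
      distractor = rep(c("emotional", "emotional", "neutral", "neutral"),
                       length.out = n_trials),
      is_practice = FALSE,
      stringsAsFactors = FALSE)
    err <- runif(n_trials) < plogis(lp)
    d$outcome <- ifelse(err, "commission", "correct")
    d$class_total <- ifelse(err, "error", "correct")
    d$class_incorrect <- "other"
    d$class_miss <- "other"
    d$class_commission <- ifelse(err, "commission_error", "correct")
    d
  })
  do.call(rbind, rows)
}
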