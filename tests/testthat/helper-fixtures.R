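# Shared fixture builders for the test suite.

# minimal valid trial table, deterministic, no RT violations
make_session_fixture <- function(subject_id = "s1", group = "placebo",
                                 n_trials = 144, n_blocks = 4,
                                 rt_ms = 600) {
  per_block <- n_trials / n_blocks
  set.seed(123)
  conf <- round(runif(n_trials), 6)
  stim <- rep(c("left", "right"), length.out = n_trials)
  resp <- ifelse(runif(n_trials) < 0.71, stim,
                 ifelse(stim == "left", "right", "left"))
  data.frame(subject_id = subject_id, group = group,
             block = rep(seq_len(n_blocks), each = per_block),
             trial = seq_len(n_trials),
             variance_condition = rep(c(20, 30), length.out = n_trials),
             mean_orientation_deg = 10,
             stimulus_direction = stim, response = resp,
             correct = resp == stim, rt_ms = rt_ms, confidence = conf,
             slider_start = 0.5, stringsAsFactors = FALSE)
}

# exhaustive tie-corrected pairwise rank statistic: the AUROC2 oracle
pairwise_auroc2 <- function(conf_correct, conf_incorrect) {
  tot <- 0
  for (a in conf_correct) for (b in conf_incorrect)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(conf_correct) * length(conf_incorrect))
}

# independent fine-grid Simpson quadrature for the JZS two-sample BF10,
# integrating over u = g/(1+g) in (0,1)
simpson_bf10 <- function(t, n1, n2, r_scale, n_grid = 4001) {
  nu <- n1 + n2 - 2
  n_eff <- n1 * n2 / (n1 + n2)
  f <- function(u) {
    g <- u / (1 - u)
    (1 + n_eff * g)^(-0.5) *
      (1 + t^2 / ((1 + n_eff * g) * nu))^(-(nu + 1) / 2) *
      r_scale / sqrt(2 * pi) * g^(-1.5) * exp(-r_scale^2 / (2 * g)) /
      (1 - u)^2
  }
  u <- seq(1e-9, 1 - 1e-9, length.out = n_grid)
  y <- f(u)
  h <- u[2] - u[1]
  w <- rep(c(2, 4), length.out = n_grid); w[1] <- 1; w[n_grid] <- 1
  alt <- sum(w * y) * h / 3
  alt / (1 + t^2 / nu)^(-(nu + 1) / 2)
}

# two samples with an exact pooled two-sample t statistic
samples_with_t <- function(t, n1, n2) {
  # unit variance in both groups, means 0 and -delta
  delta <- t * sqrt(1 / n1 + 1 / n2)
  a <- scale(seq_len(n1))[, 1]              # mean 0, sd 1
  b <- scale(seq_len(n2))[, 1] - delta
  list(a = a, b = b)
}
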