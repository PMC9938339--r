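# Independent oracles, deliberately written as direct transcriptions of the
# defining formulas (loops / all-pairs enumeration), never reusing package
# internals.

# Brute-force Harrell's C over every pair.
bf_cindex <- function(t, d, p) {
  pairs <- t(utils::combn(length(t), 2))
  i <- pairs[, 1]; j <- pairs[, 2]
  swap <- t[j] < t[i] | (t[j] == t[i] & d[j] == 1 & d[i] != 1)
  a <- ifelse(swap, j, i); b <- ifelse(swap, i, j)
  comparable <- d[a] == 1 & !(t[a] == t[b] & d[b] == 1)
  conc <- comparable & p[a] > p[b]
  tie <- comparable & p[a] == p[b]
  list(c = (sum(conc) + 0.5 * sum(tie)) / sum(comparable),
       n_pairs = sum(comparable))
}

# Product-limit risk at a horizon, one factor per distinct event time.
oracle_km_risk <- function(t, d, horizon) {
  s <- 1
  for (u in sort(unique(t[d == 1]))) {
    if (u > horizon) break
    n_at_risk <- sum(t >= u)
    s <- s * (1 - sum(t == u & d == 1) / n_at_risk)
  }
  1 - s
}

# Aalen-Johansen cause-k cumulative incidence at a horizon.
oracle_cif <- function(t, code, horizon, cause = 1) {
  times <- sort(unique(t[code != 0]))
  s_left <- 1
  cif <- 0
  for (u in times) {
    n_at_risk <- sum(t >= u)
    d_cause <- sum(t == u & code == cause)
    d_all <- sum(t == u & code != 0)
    if (u <= horizon) cif <- cif + s_left * d_cause / n_at_risk
    s_left <- s_left * (1 - d_all / n_at_risk)
  }
  cif
}

# Breslow-ties Cox log partial likelihood, direct per-event loop.
oracle_cox_logpl <- function(beta, t, d, x) {
  s <- 0
  for (i in which(d == 1)) {
    s <- s + beta * x[i] - log(sum(exp(beta * x[t >= t[i]])))
  }
  s
}

# Random censored-survival instance with tied predictions and times.
rand_surv_instance <- function(n, competing = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- round(rexp(n, 0.15) + 0.05, 1) # one-decimal grid forces tied times
  p <- round(runif(n), 1)             # heavily tied predictions
  code <- sample(0:1, n, replace = TRUE, prob = c(0.3, 0.7))
  if (competing) {
    is_comp <- code == 1 & runif(n) < 0.4
    code[is_comp] <- 2L
  }
  tibble::tibble(time = t, event = code, pred = p)
}

toy_model_3pred <- function() {
  risk_model(
    name = "toy3",
    predictors = list(
      list(name = "age", transform = "identity", coefficient = 0.05, mean = 68),
      list(name = "sbp", transform = "log", coefficient = 0.8, mean = 5),
      list(name = "smoker", transform = "indicator", coefficient = 0.4, mean = 0.2)),
    baseline_survival = 0.9)
}

extdata_model <- function(file) {
  system.file("extdata", "models", file, package = "survalid")
}
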