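# Independent oracles: small brute-force implementations used only to check
# the package's results, never sharing code with them.

# Longest common subsequence by full dynamic programming over a matrix.
oracle_lcs <- function(a, b) {
  n <- length(a); m <- length(b)
  d <- matrix(0L, n + 1, m + 1)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    d[i + 1, j + 1] <- if (a[i] == b[j]) d[i, j] + 1L
                       else max(d[i, j + 1], d[i + 1, j])
  }
  d[n + 1, m + 1]
}

# Linear-interpolation quantile between order statistics.
oracle_quantile <- function(x, p) {
  x <- sort(x); n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Product-limit estimator written as the literal product over event times.
oracle_km <- function(days, event) {
  times <- sort(unique(days[event]))
  surv <- numeric(length(times))
  s <- 1
  for (k in seq_along(times)) {
    t <- times[k]
    at_risk <- sum(days >= t)
    d <- sum(days == t & event)
    s <- s * (1 - d / at_risk)
    surv[k] <- s
  }
  list(time = times, surv = surv)
}

# Empirical survivor function: share of observations strictly beyond t.
oracle_empirical_surv <- function(days, t) {
  mean(days > t)
}

random_assessment <- function() {
  conclusion_assessment(sample(c("positive", "neutral", "negative"), 1),
                        sample(c("reported", "not_reported"), 1))
}

random_result_list <- function(n = 3) {
  labels <- sample(c("mortality", "recovery", "viral load", "icu stay"), n)
  lapply(seq_len(n), function(i) {
    reported_result(labels[i], "odds_ratio",
                    estimate = round(runif(1, 0.2, 4), 3),
                    p_value = round(runif(1), 3))
  })
}
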