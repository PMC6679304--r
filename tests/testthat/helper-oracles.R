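# Independent literal-loop re-implementations of every window statistic,
# written directly from the defining formulas.  These stay deliberately
# naive (explicit loops, no shared code with the package) so they can serve
# as oracles.

oracle_mav <- function(s) {
  acc <- 0
  for (k in seq_along(s)) acc <- acc + abs(s[k])
  acc / length(s)
}

oracle_rms <- function(s) {
  acc <- 0
  for (k in seq_along(s)) acc <- acc + s[k]^2
  sqrt(acc / length(s))
}

oracle_ssc <- function(s) {
  acc <- 0
  for (k in 2:(length(s) - 1)) {
    acc <- acc + abs((s[k] - s[k - 1]) * (s[k] - s[k + 1]))
  }
  acc
}

oracle_wl <- function(s) {
  acc <- 0
  for (k in 2:length(s)) acc <- acc + abs(s[k] - s[k - 1])
  acc
}

oracle_var <- function(s) {
  acc <- 0
  for (k in seq_along(s)) acc <- acc + s[k]^2
  acc / (length(s) - 1)
}

oracle_hjorth <- function(s) {
  d1 <- s[-1] - s[-length(s)]
  d2 <- d1[-1] - d1[-length(d1)]
  v0 <- oracle_var(s)
  v1 <- oracle_var(d1)
  v2 <- oracle_var(d2)
  mob <- sqrt(v1 / v0)
  mob_d <- sqrt(v2 / v1)
  list(activity = v0, mobility = mob, complexity = mob_d / mob)
}

# Brute-force vote-rule oracle: simulate the counters step by step and stop
# at the first eligible class whose count satisfies the threshold rule.
oracle_vote <- function(labels, tau, n_classes, rest_decides = FALSE,
                        strict = FALSE) {
  counts <- integer(n_classes)
  for (i in seq_along(labels)) {
    lab <- labels[i]
    counts[lab + 1] <- counts[lab + 1] + 1
    eligible <- rest_decides || lab >= 1
    hit <- if (strict) counts[lab + 1] > tau else counts[lab + 1] >= tau
    if (eligible && hit) {
      return(list(label = lab, decision_index = i - 1L))
    }
  }
  list(label = 0L, decision_index = NA_integer_)
}

# Central-difference gradient of a scalar function of a parameter vector.
numeric_gradient <- function(f, theta, eps = 1e-5) {
  g <- numeric(length(theta))
  for (i in seq_along(theta)) {
    up <- theta
    dn <- theta
    up[i] <- up[i] + eps
    dn[i] <- dn[i] - eps
    g[i] <- (f(up) - f(dn)) / (2 * eps)
  }
  g
}
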