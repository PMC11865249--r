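# Independent oracles, written as plain arithmetic so they share no code
# path with the package internals.

oracle_ror <- function(a, b, c, d) {
  if (min(a, b, c, d) == 0) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  est <- (a / b) / (c / d)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  c(ror = est, lo = est * exp(-1.96 * se), hi = est * exp(1.96 * se))
}

oracle_rrr <- function(a, b, c, d) {
  n <- a + b + c + d
  expected <- (a + b) / n * (a + c)
  if (a == 0) return(0)
  if (expected == 0) return(Inf)
  a / expected
}

oracle_signal <- function(a, b, c, d) {
  n <- a + b + c + d
  expected <- (a + b) / n * (a + c)
  log((a + 0.5) / (expected + 0.5)) / log(2)
}

# Monte-Carlo credible bounds for the gamma-shrinkage IC
oracle_ic_mc <- function(a, b, c, d, ndraw = 1e6, seed = 1) {
  n <- a + b + c + d
  expected <- (a + b) / n * (a + c)
  set.seed(seed)
  draws <- log2(stats::rgamma(ndraw, shape = a + 0.5, rate = 1) / (expected + 0.5))
  stats::quantile(draws, c(0.025, 0.975), names = FALSE)
}

# Exact inclusion probabilities under successive (without-replacement)
# sampling proportional to weights, by enumeration of ordered draws.
oracle_inclusion_prob <- function(w, k) {
  m <- length(w)
  prob <- numeric(m)
  recurse <- function(remaining, depth, path_p, chosen) {
    if (depth == 0) {
      prob[chosen] <<- prob[chosen] + path_p
      return(invisible())
    }
    tot <- sum(w[remaining])
    for (j in remaining) {
      recurse(setdiff(remaining, j), depth - 1, path_p * w[j] / tot,
              c(chosen, j))
    }
  }
  recurse(seq_len(m), k, 1, integer())
  prob
}

# closed-form expected 2x2 for a single planted drug-event pair:
# P(event | drug) follows the logistic odds-multiplier model
oracle_expected_table <- function(n, pi_drug, p0, theta) {
  p1 <- stats::plogis(stats::qlogis(p0) + log(theta))
  c(a = n * pi_drug * p1,
    b = n * pi_drug * (1 - p1),
    c = n * (1 - pi_drug) * p0,
    d = n * (1 - pi_drug) * (1 - p0))
}

rand_table <- function() {
  cells <- stats::rpois(4, lambda = sample(c(2, 10, 50, 300), 4, replace = TRUE))
  contingency_table(cells[1], cells[2], cells[3], cells[4])
}
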