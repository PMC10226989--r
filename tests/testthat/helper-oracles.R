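# Fixture builders and independent brute-force oracles used across tests.
# The oracles deliberately share no code with the package implementation:
# explicit loops and textbook formulas only.

make_expr <- function(g = 10, n = 8, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(g * n), nrow = g,
              dimnames = list(sprintf("g%02d", seq_len(g)),
                              sprintf("s%02d", seq_len(n))))
  x
}

make_surv <- function(n = 8, seed = 1, event_rate = 0.7) {
  set.seed(seed)
  data.frame(sample_id = sprintf("s%02d", seq_len(n)),
             time = rexp(n, rate = 0.2),
             event = rbinom(n, 1, event_rate),
             stringsAsFactors = FALSE)
}

# Log-rank by explicit per-event-time risk-table accumulation.
logrank_oracle <- function(labels, time, event) {
  utimes <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in utimes) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    n_a <- sum(at_risk & labels == "A")
    d_t <- sum(time == t & event == 1)
    d_a <- sum(time == t & event == 1 & labels == "A")
    o_minus_e <- o_minus_e + (d_a - d_t * n_a / n_t)
    if (n_t > 1) {
      v <- v + d_t * (n_a / n_t) * (1 - n_a / n_t) * (n_t - d_t) / (n_t - 1)
    }
  }
  chi <- o_minus_e^2 / v
  list(chi_square = chi, p_value = pchisq(chi, 1, lower.tail = FALSE))
}

# SAM d-statistic per gene by direct evaluation of the formula, one gene at
# a time.
sam_oracle <- function(expr, labels) {
  in_a <- labels == "A"
  n_a <- sum(in_a)
  n_b <- sum(!in_a)
  s <- numeric(nrow(expr))
  num <- numeric(nrow(expr))
  for (i in seq_len(nrow(expr))) {
    xa <- expr[i, in_a]
    xb <- expr[i, !in_a]
    num[i] <- mean(xa) - mean(xb)
    s[i] <- sqrt((1 / n_a + 1 / n_b) *
                   (sum((xa - mean(xa))^2) + sum((xb - mean(xb))^2)) /
                   (n_a + n_b - 2))
  }
  s0 <- median(s)
  list(d = num / (s + s0), s = s, s0 = s0)
}

# PC1 sample scores via eigen-decomposition of the sample-space covariance of
# the row-standardized submatrix.
pc1_oracle <- function(expr, genes) {
  x <- expr[genes, , drop = FALSE]
  x <- t(scale(t(x)))          # standardize each gene across samples
  cov_s <- crossprod(x) / (nrow(x) - 1)  # samples x samples
  eigen(cov_s, symmetric = TRUE)$vectors[, 1]
}

# Partition equality up to the A/B label swap.
same_partition <- function(l1, l2) {
  identical(l1, l2) || identical(l1, ifelse(l2 == "A", "B", "A"))
}

binom_interval <- function(n, p = 0.05) {
  c(qbinom(0.025, n, p), qbinom(0.975, n, p)) / n
}
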