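# Independent oracles, kept free of any package internals.

# Brute-force Benjamini-Hochberg step-up: sort, scale by m/i, enforce
# monotonicity by cumulative minimum from the largest p down, unsort.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- ps * m / seq_len(m)
  for (i in seq(m - 1, 1, length.out = max(m - 1, 0))) {
    q[i] <- min(q[i], q[i + 1])
  }
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Textbook pooled-variance two-sample t statistic and p value.
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# One-sample t of x against 0.
one_sample_t_oracle <- function(x) {
  t <- mean(x) / (sd(x) / sqrt(length(x)))
  df <- length(x) - 1
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

table1_conc <- function() concentration_vector(zm4_concentrations())
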