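# Independent brute-force evaluation of the published formulas for one
# 2x2 table at a time. Deliberately scalar and spelled out step by step
# so it shares no code path with the package's vectorized
# implementations.

oracle_one <- function(a, b, c, d,
                       a1 = 1, b1 = 1, g11 = 1, al = 2, be = 2) {
  N <- a + b + c + d

  # ROR = (a/c) / (b/d), Woolf interval
  ror <- (a / c) / (b / d)
  se_ror <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  ror_lo <- exp(log(ror) - 1.96 * se_ror)
  ror_hi <- exp(log(ror) + 1.96 * se_ror)

  # PRR = rate in exposed over rate in unexposed
  rate_exp <- a / (a + b)
  rate_une <- c / (c + d)
  prr <- rate_exp / rate_une
  se_prr <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  prr_lo <- exp(log(prr) - 1.96 * se_prr)
  prr_hi <- exp(log(prr) + 1.96 * se_prr)

  # Pearson chi-square via expected counts (no closed form)
  obs <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  expc <- outer(rowSums(obs), colSums(obs)) / N
  chi2_plain <- sum((obs - expc)^2 / expc)
  chi2_yates <- sum((pmax(abs(obs - expc) - 0.5, 0))^2 / expc)

  # BCPNN posterior expectation and variance of IC
  gamma <- g11 * (N + al) * (N + be) / ((a + b + a1) * (a + c + b1))
  e_ic <- log2((a + g11) * (N + al) * (N + be) /
                 ((N + gamma) * (a + b + a1) * (a + c + b1)))
  v_ic <- (1 / log(2)^2) *
    ((N - a + gamma - g11) / ((a + g11) * (1 + N + gamma)) +
       (N - (a + b) + al - a1) / ((a + b + a1) * (1 + N + al)) +
       (N - (a + c) + be - b1) / ((a + c + b1) * (1 + N + be)))
  ic025 <- e_ic - 2 * sqrt(v_ic)

  # EBGM: observed count over the count expected under independence
  expected_a <- (a + b) * (a + c) / N
  ebgm <- a / expected_a
  ebgm05 <- exp(log(ebgm) - 1.96 * sqrt(1 / a + 1 / b + 1 / c + 1 / d))

  list(ror = ror, ror_lo = ror_lo, ror_hi = ror_hi,
       prr = prr, prr_lo = prr_lo, prr_hi = prr_hi,
       chi2_plain = chi2_plain, chi2_yates = chi2_yates,
       ic = e_ic, ic_var = v_ic, ic025 = ic025,
       ebgm = ebgm, ebgm05 = ebgm05)
}

# Random strictly positive tables, cells in 1..10^4.
random_tables <- function(n, seed) {
  withr::with_seed(seed, {
    tibble::tibble(
      a = sample(1:10000, n, replace = TRUE),
      b = sample(1:10000, n, replace = TRUE),
      c = sample(1:10000, n, replace = TRUE),
      d = sample(1:10000, n, replace = TRUE)
    )
  })
}

max_rel_err <- function(x, y) max(abs(x - y) / pmax(abs(y), 1e-300))
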