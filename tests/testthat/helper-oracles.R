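# Independent numerical oracles for the statistical routines.

# Two-sided t-tail by quadrature of the t density written from the gamma
# form (independent of stats::pt).
t_tail_quadrature <- function(stat, df) {
  lc <- lgamma((df + 1) / 2) - lgamma(df / 2) - 0.5 * log(df * pi)
  dens <- function(x) exp(lc - ((df + 1) / 2) * log1p(x^2 / df))
  2 * stats::integrate(dens, abs(stat), Inf, rel.tol = 1e-12)$value
}

# Upper chi-square tail by quadrature of the density written from the gamma
# form (independent of stats::pchisq).
chisq_tail_quadrature <- function(stat, df) {
  if (stat <= 0) return(1)
  lc <- -(df / 2) * log(2) - lgamma(df / 2)
  dens <- function(x) exp(lc + (df / 2 - 1) * log(x) - x / 2)
  stats::integrate(dens, stat, Inf, rel.tol = 1e-12)$value
}

# Permutation null of the Pearson statistic with fixed margins: returns the
# non-strict and strict tail probabilities P(X2 >= obs), P(X2 > obs). The
# continuous chi-square approximation should land inside this discreteness
# bracket.
perm_chisq_tails <- function(tab, B = 1e5) {
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  E <- outer(rs, cs) / n
  stat <- function(o) sum((o - E)^2 / E)
  obs <- stat(tab)
  sims <- vapply(r2dtable(B, rs, cs), stat, numeric(1))
  c(ge = mean(sims >= obs - 1e-9), gt = mean(sims > obs + 1e-9))
}

# Brute-force proximity oracle: tokenises the sentence and scans all token
# pairs (first stem exact word, second stem prefix) at token gap <= w.
brute_force_vh <- function(sentence, w) {
  toks <- stringr::str_extract_all(tolower(sentence), "[a-z0-9]+")[[1]]
  i1 <- which(toks == "visual")
  i2 <- which(startsWith(toks, "hallucinat"))
  for (i in i1) for (j in i2)
    if (i != j && abs(i - j) - 1L <= w) return(TRUE)
  FALSE
}
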