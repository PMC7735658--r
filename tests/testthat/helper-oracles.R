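# Independent oracles: literal transcriptions of the defining formulas,
# deliberately written without reference to the package implementations.

# Dunning log-likelihood, two-term sum, zero counts contribute 0
oracle_ll <- function(a, b, c, d) {
  e1 <- c * (a + b) / (c + d)
  e2 <- d * (a + b) / (c + d)
  t1 <- if (a > 0) a * log(a / e1) else 0
  t2 <- if (b > 0) b * log(b / e2) else 0
  2 * (t1 + t2)
}

# Pearson chi-square on a 2x2 table: sum (O - E)^2 / E
oracle_pearson <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# empirical survivor function #(T > t) / n
oracle_surv <- function(times, t) sum(times > t) / length(times)

# two-sample log-rank chi-square from the observed-minus-expected /
# hypergeometric-variance definition, all observations events
oracle_logrank <- function(ta, tb) {
  t_all <- sort(unique(c(ta, tb)))
  O <- E <- V <- 0
  for (t in t_all) {
    n1 <- sum(ta >= t); n2 <- sum(tb >= t); n <- n1 + n2
    d1 <- sum(ta == t); d2 <- sum(tb == t); d <- d1 + d2
    if (n < 2 || d == 0) next
    O <- O + d1
    E <- E + d * n1 / n
    V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V == 0) return(0)
  (O - E)^2 / V
}

# brute-force tagger: scan every keyword / window alignment
oracle_tag <- function(tokens, taxonomy) {
  hits <- character(0)
  for (g in names(taxonomy)) {
    for (kw in taxonomy[[g]]) {
      kt <- tokenize(kw)
      nk <- length(kt)
      if (nk > length(tokens)) next
      for (i in seq_len(length(tokens) - nk + 1L)) {
        if (all(tokens[i:(i + nk - 1L)] == kt)) { hits <- c(hits, g); break }
      }
    }
  }
  sort(unique(hits))
}
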