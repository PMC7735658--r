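# N-gram term-frequency comparison between two subject-header corpora using
# the Dunning log-likelihood (G-type) statistic. For a term with count a in
# the comparison corpus (size c n-gram tokens) and b in the base corpus
# (size d):
#   e1 = c (a + b) / (c + d),   e2 = d (a + b) / (c + d)
#   LL = 2 [ a log(a / e1) + b log(b / e2) ]
# with zero counts contributing 0 (the x log x -> 0 limit). LL is referred to
# a chi-square distribution with 1 df; LL >= 3.84 corresponds to p <= .05 and
# LL >= 10.83 to p <= .001.

#' Extract n-grams from one token sequence
#'
#' All contiguous length-`n` windows within a single subject; windows never
#' span subjects (callers extract per subject and pool).
#'
#' @param tokens character vector of tokens
#' @param n gram length, 1, 2 or 3
#' @return character vector of n-grams, tokens joined by single spaces;
#'   empty when the subject is shorter than `n`
#' @export
extract_ngrams <- function(tokens, n) {
  stopifnot(n %in% 1:3)
  m <- length(tokens) - n + 1L
  if (m <= 0L) return(character(0))
  if (n == 1L) return(tokens)
  vapply(seq_len(m),
         function(i) paste(tokens[i:(i + n - 1L)], collapse = " "), "")
}

# internal: pooled n-gram counts for a corpus of subjects
corpus_ngram_counts <- function(subjects, n) {
  toks <- tokenize_all(subjects)
  grams <- unlist(lapply(toks, extract_ngrams, n = n), use.names = FALSE)
  if (length(grams) == 0L)
    return(list(counts = integer(0), total = 0L))
  tab <- table(grams)
  list(counts = stats::setNames(as.integer(tab), names(tab)),
       total = length(grams))
}

#' Dunning log-likelihood statistic
#'
#' Compares a term's relative frequency between two corpora. `a` and `b` are
#' the term's counts in corpus 1 and corpus 2; `c` and `d` are the total
#' n-gram token counts of those corpora. Vectorized over `a` and `b`.
#'
#' @param a,b term counts (a + b >= 1)
#' @param c,d corpus sizes in n-gram tokens (c >= a, d >= b, both >= 1)
#' @return nonnegative statistic; 0 iff `a/c == b/d`
#' @export
log_likelihood <- function(a, b, c, d) {
  if (any(a < 0) || any(b < 0) || any(a + b < 1))
    abort("log_likelihood: need a, b >= 0 and a + b >= 1")
  if (any(c < a) || any(d < b) || any(c < 1) || any(d < 1))
    abort("log_likelihood: need corpus sizes c >= a, d >= b, c, d >= 1")
  e1 <- c * (a + b) / (c + d)
  e2 <- d * (a + b) / (c + d)
  t1 <- ifelse(a > 0, a * log(a / e1), 0)
  t2 <- ifelse(b > 0, b * log(b / e2), 0)
  ll <- 2 * (t1 + t2)
  pmax(ll, 0) # clamp tiny negative float residue at equality
}

#' Compare two corpora by n-gram log-likelihood
#'
#' Builds `n`-gram counts for the base and comparison corpora and scores
#' every term whose pooled count is at least `min_count`, ranked by the
#' statistic (descending, ties broken lexicographically by term). The
#' conventional use compares a minimally-invasive treatment group's subjects
#' (comparison) against the abdominal group's (base); a symptom-conditioned
#' comparison is obtained by pre-filtering both inputs to posts tagged with
#' the symptom of interest.
#'
#' @param base_posts character vector of subjects, or a data.frame with a
#'   `subject` column (the reference corpus)
#' @param comparison_posts same, for the corpus being compared
#' @param n gram length in 1..3
#' @param min_count minimum pooled occurrence count (default 5)
#' @return `data.table` with columns `term`, `a` (comparison count), `b`
#'   (base count), `e1`, `e2`, `ll`, `p` (chi-square 1 df upper tail) and
#'   `direction` (`over_in_comparison`, `over_in_base`, `equal`)
#' @export
compare_corpora <- function(base_posts, comparison_posts, n = 1L, min_count = 5L) {
  get_subjects <- function(x, nm) {
    s <- if (is.data.frame(x)) x$subject else x
    s <- s[!is.na(s) & nzchar(s)]
    if (length(s) == 0L) abort("empty corpus: %s", nm)
    s
  }
  base <- corpus_ngram_counts(get_subjects(base_posts, "base"), n)
  comp <- corpus_ngram_counts(get_subjects(comparison_posts, "comparison"), n)
  if (base$total == 0L) abort("empty corpus: base (no n-grams of length %d)", n)
  if (comp$total == 0L) abort("empty corpus: comparison (no n-grams of length %d)", n)

  terms <- union(names(comp$counts), names(base$counts))
  a <- ifelse(terms %in% names(comp$counts), comp$counts[terms], 0L)
  b <- ifelse(terms %in% names(base$counts), base$counts[terms], 0L)
  keep <- (a + b) >= min_count
  terms <- terms[keep]; a <- as.integer(a[keep]); b <- as.integer(b[keep])
  cc <- comp$total; dd <- base$total
  if (length(terms) == 0L) {
    return(data.table::data.table(term = character(0), a = integer(0),
                                  b = integer(0), e1 = numeric(0), e2 = numeric(0),
                                  ll = numeric(0), p = numeric(0),
                                  direction = character(0)))
  }
  e1 <- cc * (a + b) / (cc + dd)
  e2 <- dd * (a + b) / (cc + dd)
  ll <- log_likelihood(a, b, cc, dd)
  p <- stats::pchisq(ll, df = 1, lower.tail = FALSE)
  rel <- a / cc - b / dd
  direction <- ifelse(rel > 0, "over_in_comparison",
                      ifelse(rel < 0, "over_in_base", "equal"))
  out <- data.table::data.table(term = terms, a = a, b = b, e1 = e1, e2 = e2,
                                ll = ll, p = p, direction = direction)
  data.table::setorderv(out, c("ll", "term"), order = c(-1L, 1L))
  out[]
}
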