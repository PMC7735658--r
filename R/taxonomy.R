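# Symptom keyword taxonomy: 12 fixed groups, each a set of keywords, where a
# keyword is a sequence of one or more lowercase tokens. Tagging is whole-token
# contiguous-subsequence matching against tokenized subject headers; there is
# deliberately no stemming (morphological variants are enumerated as keywords).

#' The 12 symptom group names
#'
#' Fixed vocabulary of symptom groups recognised by the tagger, in canonical
#' reporting order.
#'
#' @return character vector of length 12
#' @export
symptom_groups <- function() {
  c("pain", "sleep_and_fatigue", "hormones_and_emotions", "digestion",
    "swelling", "bleeding", "urination", "intimacy", "odd_sensations",
    "drugs", "fever_and_infection", "family")
}

#' Tokenize subject-header text
#'
#' Lowercases and splits on any run of non-alphanumeric characters; empty
#' tokens are dropped, digits are retained as tokens. This is the single
#' tokenizer used everywhere (tagging, n-grams, keyword-in-context), so all
#' analyses see the same token stream.
#'
#' @param text a single character string
#' @return character vector of tokens (length 0 for empty text)
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text)) return(character(0))
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

#' Tokenize many subjects at once
#'
#' Vectorized form of [tokenize()].
#'
#' @param texts character vector
#' @return list of token vectors, one per input element
#' @export
tokenize_all <- function(texts) {
  texts[is.na(texts)] <- ""
  lapply(strsplit(tolower(texts), "[^a-z0-9]+"), function(t) t[nzchar(t)])
}

new_taxonomy <- function(groups) {
  structure(groups, class = "symptom_taxonomy")
}

validate_taxonomy <- function(groups) {
  expected <- symptom_groups()
  if (!setequal(names(groups), expected)) {
    bad <- c(setdiff(names(groups), expected), setdiff(expected, names(groups)))
    abort("taxonomy must have exactly the 12 known groups; offending: %s",
          paste(bad, collapse = ", "))
  }
  groups <- groups[expected]
  for (g in expected) {
    kw <- groups[[g]]
    if (!is.character(kw) || length(kw) == 0L || any(!nzchar(kw)) || anyNA(kw))
      abort("group '%s' must be a nonempty character vector of keywords", g)
    if (any(kw != tolower(kw)))
      abort("group '%s' has non-lowercase keywords", g)
    # keyword tokens must themselves survive tokenization unchanged
    for (k in kw) {
      toks <- tokenize(k)
      if (length(toks) == 0L) abort("keyword '%s' in '%s' has no tokens", k, g)
    }
  }
  # keywords are disjoint across groups so mention counts are well-defined
  all_kw <- unlist(groups, use.names = FALSE)
  owner <- rep(names(groups), lengths(groups))
  dup <- duplicated(all_kw)
  if (any(dup)) {
    k <- all_kw[dup][1]
    abort("keyword '%s' appears in groups: %s",
          k, paste(unique(owner[all_kw == k]), collapse = ", "))
  }
  new_taxonomy(groups)
}

#' Default symptom taxonomy
#'
#' The curated default shipped with the package: 12 disjoint keyword groups
#' covering pain, sleep and fatigue, hormones and emotions, digestion,
#' swelling, bleeding, urination, intimacy, odd sensations, drugs, fever and
#' infection, and family. It mixes clinical terms, plain English, community
#' slang (e.g. "swellybelly") and common misspellings (e.g. "achey",
#' "vomitting"). It is a configuration artifact, not ground truth: real
#' analyses should supply their own curated file via [load_taxonomy()].
#'
#' @return a `symptom_taxonomy` object
#' @export
default_taxonomy <- function() {
  path <- system.file("extdata", "default_taxonomy.json",
                      package = "forumlisten", mustWork = TRUE)
  load_taxonomy(path)
}

#' Load a symptom taxonomy from JSON
#'
#' The file is a JSON object mapping each of the 12 group names to an array
#' of lowercase keywords; keywords may contain spaces (multi-token phrases).
#' Unknown group names and keywords assigned to more than one group are fatal.
#'
#' @param path path to the JSON file
#' @return a `symptom_taxonomy` object
#' @export
load_taxonomy <- function(path) {
  if (!file.exists(path)) abort("taxonomy file not found: %s", path)
  groups <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  validate_taxonomy(lapply(groups, as.character))
}

#' @export
print.symptom_taxonomy <- function(x, ...) {
  cat("<symptom_taxonomy> 12 groups,", sum(lengths(x)), "keywords\n")
  for (g in names(x)) cat(sprintf("  %-22s %d keywords\n", g, length(x[[g]])))
  invisible(x)
}

# internal: taxonomy as a long data.table of tokenized keywords
taxonomy_table <- function(taxonomy) {
  kw <- unlist(taxonomy, use.names = FALSE)
  grp <- rep(names(taxonomy), lengths(taxonomy))
  toks <- tokenize_all(kw)
  data.table::data.table(
    group = grp,
    keyword = vapply(toks, paste, "", collapse = " "),
    ntok = lengths(toks)
  )
}

#' Tag one tokenized subject with symptom groups
#'
#' A group is tagged iff at least one of its keywords occurs as a contiguous
#' whole-token subsequence of `tokens`; matching is never substring-level
#' ("painting" does not tag pain), and each group appears at most once.
#'
#' @param tokens character vector from [tokenize()]
#' @param taxonomy a `symptom_taxonomy`
#' @return character vector of matched group names (possibly empty), in
#'   canonical group order
#' @export
tag_subject <- function(tokens, taxonomy) {
  stopifnot(inherits(taxonomy, "symptom_taxonomy"))
  if (length(tokens) == 0L) return(character(0))
  hits <- character(0)
  for (g in names(taxonomy)) {
    for (k in taxonomy[[g]]) {
      ktoks <- tokenize(k)
      nk <- length(ktoks)
      if (nk > length(tokens)) next
      if (nk == 1L) {
        found <- ktoks %in% tokens
      } else {
        found <- FALSE
        for (i in seq_len(length(tokens) - nk + 1L)) {
          if (all(tokens[i:(i + nk - 1L)] == ktoks)) { found <- TRUE; break }
        }
      }
      if (found) { hits <- c(hits, g); break }
    }
  }
  hits
}

#' Tag a whole cohort of posts
#'
#' Adds a `mentioned` list-column (character vector of symptom groups per
#' post) to a cohort table. Implemented with keyword-table joins so it scales
#' to 10^5-10^6 posts; equivalent to calling [tag_subject()] per post.
#'
#' @param cohort a cohort `data.table` with a `subject` column (from
#'   [build_cohort()] or compatible)
#' @param taxonomy a `symptom_taxonomy` (default [default_taxonomy()])
#' @return the cohort with columns `mentioned` (list) and `n_symptoms`
#'   (integer count of distinct groups mentioned)
#' @export
tag_cohort <- function(cohort, taxonomy = default_taxonomy()) {
  stopifnot(is.data.frame(cohort), "subject" %in% names(cohort))
  out <- data.table::as.data.table(cohort)
  toks <- tokenize_all(out$subject)
  tags <- tag_tokens_bulk(toks, taxonomy)
  out[, `:=`(mentioned = tags, n_symptoms = lengths(tags))]
  out[]
}

# internal bulk tagger: joins exploded n-gram strings against the keyword
# table for n = 1..max keyword length
tag_tokens_bulk <- function(toks, taxonomy) {
  tt <- taxonomy_table(taxonomy)
  npost <- length(toks)
  found <- vector("list", npost)
  lens <- lengths(toks)
  for (n in sort(unique(tt$ntok))) {
    kws <- tt[tt$ntok == n, ]
    idx <- which(lens >= n)
    if (length(idx) == 0L) next
    if (n == 1L) {
      grams <- toks[idx]
    } else {
      grams <- lapply(toks[idx], function(t) {
        m <- length(t) - n + 1L
        vapply(seq_len(m), function(i) paste(t[i:(i + n - 1L)], collapse = " "), "")
      })
    }
    long <- data.table::data.table(
      post = rep(idx, lengths(grams)),
      gram = unlist(grams, use.names = FALSE)
    )
    hit <- long[kws, on = c(gram = "keyword"), nomatch = NULL]
    if (nrow(hit)) {
      hit <- unique(hit[, c("post", "group")])
      sp <- split(hit$group, hit$post)
      for (nm in names(sp)) {
        i <- as.integer(nm)
        found[[i]] <- c(found[[i]], sp[[nm]])
      }
    }
  }
  order_ref <- symptom_groups()
  lapply(found, function(g) {
    if (is.null(g)) character(0) else order_ref[order_ref %in% g]
  })
}

#' Keyword-in-context search
#'
#' Pulls the subjects whose token sequence contains `keyword` (tokenized,
#' contiguous whole-token match), supporting manual curation of the taxonomy.
#'
#' @param keyword a keyword string (1+ tokens)
#' @param cohort_posts a data.frame with a `subject` column, or a character
#'   vector of subjects
#' @return character vector of matching subjects
#' @export
keyword_in_context <- function(keyword, cohort_posts) {
  subjects <- if (is.data.frame(cohort_posts)) cohort_posts$subject else cohort_posts
  ktoks <- tokenize(keyword)
  if (length(ktoks) == 0L) abort("keyword must contain at least one token")
  toks <- tokenize_all(subjects)
  hit <- vapply(toks, function(t) contains_subseq(t, ktoks), logical(1))
  subjects[hit]
}

# internal: contiguous subsequence test
contains_subseq <- function(tokens, ktoks) {
  nk <- length(ktoks)
  nt <- length(tokens)
  if (nk > nt) return(FALSE)
  if (nk == 1L) return(ktoks %in% tokens)
  for (i in seq_len(nt - nk + 1L)) {
    if (all(tokens[i:(i + nk - 1L)] == ktoks)) return(TRUE)
  }
  FALSE
}
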