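# Per-user symptom mention analysis: users are the unit, a user "mentions" a
# symptom if any of their subject headers in the 0-84 day window was tagged
# with it, and each minimally invasive group's mention proportion is compared
# with the abdominal group's by a chi-square test for homogeneity.

#' Aggregate tagged posts to per-user symptom profiles
#'
#' One record per user; `mentioned` is the union of the post-level tag sets.
#'
#' @param tagged_posts table from [tag_cohort()] (needs `user_id`,
#'   `treatment_group`, `mentioned`)
#' @return `data.table` with `user_id`, `treatment_group`, `mentioned`
#'   (list-column), `n_mentioned`
#' @export
aggregate_user_mentions <- function(tagged_posts) {
  dt <- data.table::as.data.table(tagged_posts)
  stopifnot(all(c("user_id", "treatment_group", "mentioned") %in% names(dt)))
  order_ref <- symptom_groups()
  out <- dt[, .(mentioned = list({
    g <- unique(unlist(mentioned, use.names = FALSE))
    order_ref[order_ref %in% g]
  })), by = .(user_id, treatment_group)]
  out[, n_mentioned := lengths(mentioned)]
  out[]
}

#' 2x2 mention contingency table
#'
#' Rows are (comparison group, reference group), columns (mentioned,
#' not mentioned), counted over users.
#'
#' @param profiles output of [aggregate_user_mentions()]
#' @param symptom a symptom group name
#' @param group comparison treatment group
#' @param reference_group reference treatment group (default `"abdominal"`)
#' @return 2x2 integer matrix with dimnames
#' @export
mention_contingency <- function(profiles, symptom, group,
                                reference_group = "abdominal") {
  dt <- data.table::as.data.table(profiles)
  m_g <- dt$treatment_group == group
  m_r <- dt$treatment_group == reference_group
  if (!any(m_g)) abort("empty group: %s", group)
  if (!any(m_r)) abort("empty group: %s", reference_group)
  has <- vapply(dt$mentioned, function(s) symptom %in% s, logical(1))
  tab <- matrix(c(sum(m_g & has), sum(m_g & !has),
                  sum(m_r & has), sum(m_r & !has)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c(group, reference_group),
                                c("mentioned", "not_mentioned")))
  storage.mode(tab) <- "integer"
  tab
}

#' Chi-square test for homogeneity on a 2x2 table
#'
#' Pearson chi-square with 1 df and no continuity correction. A table with a
#' zero margin is degenerate: the test is undefined and `NA`s are returned
#' with `degenerate = TRUE` (not an error).
#'
#' @param table 2x2 numeric matrix
#' @return list with `statistic`, `p`, `degenerate`
#' @export
chi_square_homogeneity <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == c(2L, 2L)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    return(list(statistic = NA_real_, p = NA_real_, degenerate = TRUE))
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ht$statistic), p = unname(ht$p.value),
       degenerate = FALSE)
}

#' Mention-frequency comparison report
#'
#' For every symptom group and each comparison treatment group, computes the
#' proportion of users mentioning the symptom, the absolute percentage-point
#' difference versus the reference group (positive = the comparison group
#' mentions more), and a chi-square homogeneity test with tiered significance
#' annotation at .05/.01/.001.
#'
#' By default proportions are among users who mention at least one taxonomy
#' symptom (`denominator = "mentioners"`), matching the convention that the
#' analysed user universe is symptom-mentioning users; set
#' `denominator = "all"` to use every cohort user.
#'
#' @param profiles output of [aggregate_user_mentions()]
#' @param reference_group reference group, default `"abdominal"`
#' @param groups comparison groups, default vaginal and laparoscopic
#' @param denominator `"mentioners"` or `"all"`
#' @param adjust `"none"` (default, raw tiered p-values) or `"holm"`
#' @return `data.table` with one row per (symptom, group): `n_group`,
#'   `k_group`, `n_ref`, `k_ref`, `p_group`, `p_ref`, `pct_diff` (full
#'   precision), `pct_diff_display` (2 dp, half-up), `chi2`, `p`, `sig_tier`,
#'   `degenerate`
#' @export
mention_frequency_report <- function(profiles,
                                     reference_group = "abdominal",
                                     groups = c("vaginal", "laparoscopic"),
                                     denominator = c("mentioners", "all"),
                                     adjust = c("none", "holm")) {
  denominator <- match.arg(denominator)
  adjust <- match.arg(adjust)
  dt <- data.table::as.data.table(profiles)
  present <- unique(dt$treatment_group)
  need <- c(reference_group, groups)
  if (!all(need %in% present))
    abort("missing treatment group(s): %s",
          paste(setdiff(need, present), collapse = ", "))
  if (denominator == "mentioners") dt <- dt[n_mentioned > 0]
  rows <- list()
  for (g in groups) {
    for (s in symptom_groups()) {
      tab <- mention_contingency(dt, s, g, reference_group)
      ht <- chi_square_homogeneity(tab)
      n_g <- sum(tab[1, ]); k_g <- tab[1, 1]
      n_r <- sum(tab[2, ]); k_r <- tab[2, 1]
      p_g <- k_g / n_g; p_r <- k_r / n_r
      rows[[length(rows) + 1L]] <- data.table::data.table(
        symptom = s, group = g,
        n_group = n_g, k_group = k_g, n_ref = n_r, k_ref = k_r,
        p_group = p_g, p_ref = p_r,
        pct_diff = 100 * (p_g - p_r),
        chi2 = ht$statistic, p = ht$p, degenerate = ht$degenerate)
    }
  }
  out <- data.table::rbindlist(rows)
  if (adjust == "holm") out[, p := stats::p.adjust(p, method = "holm")]
  out[, pct_diff_display := round_half_up(pct_diff, 2)]
  out[, sig_tier := sig_tier(p)]
  out[]
}
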