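# Conversation-volume and symptom-distribution summaries over the 12-week
# window, plus the cohort's descriptive statistics. Day bins are 0-84; week
# bins are 1-12 after merging the 1-day week-13 bin (day 84) into week 12,
# which is flagged via the merge_week13 argument.

#' Post volume histogram
#'
#' Counts posts per day (bins 0-84) or per week (bins 1-12), stratified by
#' the number of distinct symptom groups each post subject mentions
#' (0, 1, 2, 3+).
#'
#' @param tagged_posts table from [tag_cohort()]
#' @param axis `"day"` or `"week"`
#' @param merge_week13 merge the single-day week-13 bin (day 84) into week 12
#'   (default `TRUE`); only relevant for the week axis
#' @return `data.table` with `bin`, `count`, and strata columns `s0`, `s1`,
#'   `s2`, `s3plus` summing to `count`
#' @export
post_volume_histogram <- function(tagged_posts, axis = c("day", "week"),
                                  merge_week13 = TRUE) {
  axis <- match.arg(axis)
  dt <- data.table::as.data.table(tagged_posts)
  bins <- if (axis == "day") 0:84 else 1:12
  out <- data.table::data.table(bin = bins, count = 0L, s0 = 0L, s1 = 0L,
                                s2 = 0L, s3plus = 0L)
  if (nrow(dt) == 0L) return(out[])
  b <- if (axis == "day") dt$days_postop else {
    w <- dt$week_postop
    if (merge_week13) w[w == 13L] <- 12L
    w
  }
  stratum <- pmin(dt$n_symptoms, 3L)
  for (i in seq_along(bins)) {
    sel <- b == bins[i]
    out[i, `:=`(count = sum(sel),
                s0 = sum(sel & stratum == 0L),
                s1 = sum(sel & stratum == 1L),
                s2 = sum(sel & stratum == 2L),
                s3plus = sum(sel & stratum == 3L))]
  }
  out[]
}

#' Weekly distribution of symptom mentions
#'
#' For each week (1-12, with the day-84 bin merged into week 12), each
#' symptom's share of that week's total mentions; rows sum to 1 where the
#' week has any mentions and are `NA` (not zero) for weeks with none.
#'
#' @param tagged_posts table from [tag_cohort()]
#' @param merge_week13 merge day 84 into week 12 (default `TRUE`)
#' @return `data.table` with `week`, `total_mentions`, and one share column
#'   per symptom group
#' @export
symptom_week_distribution <- function(tagged_posts, merge_week13 = TRUE) {
  dt <- data.table::as.data.table(tagged_posts)
  k <- lengths(dt$mentioned)
  long <- data.table::data.table(
    week = rep(dt$week_postop, k),
    symptom = unlist(dt$mentioned, use.names = FALSE))
  if (merge_week13 && nrow(long)) long[week == 13L, week := 12L]
  groups <- symptom_groups()
  out <- data.table::data.table(week = 1:12)
  out[, total_mentions := vapply(week, function(w) sum(long$week == w), integer(1))]
  for (s in groups) {
    out[[s]] <- vapply(out$week, function(w) {
      tot <- sum(long$week == w)
      if (tot == 0L) return(NA_real_)
      sum(long$week == w & long$symptom == s) / tot
    }, numeric(1))
  }
  out[]
}

#' Cohort descriptive summary
#'
#' The descriptive statistics of the analysis cohort: user and post counts,
#' share of subjects mentioning at least one symptom, treatment-group and
#' ovary-status breakdowns (among symptom-mentioning users, the analysed
#' user universe), post-day and posts-per-contributor statistics, total
#' symptom mentions (one per distinct (post, group) pair) and per-symptom
#' counts and shares. All percentages are computed from the stored integer
#' counts with [pct()] (half-up, 2 decimals).
#'
#' @param tagged_posts table from [tag_cohort()]
#' @return nested list (class `cohort_summary`), serialisable to JSON
#' @export
cohort_summary <- function(tagged_posts) {
  dt <- data.table::as.data.table(tagged_posts)
  if (nrow(dt) == 0L) abort("cohort_summary: empty cohort")
  n_posts <- nrow(dt)
  n_with <- sum(dt$n_symptoms > 0L)
  first3 <- sum(dt$days_postop <= 20L) # days 0-20 inclusive = first 3 weeks

  users_all <- unique(dt[, .(user_id, treatment_group, ovary_status)])
  prof <- aggregate_user_mentions(dt)
  mentioners <- prof[n_mentioned > 0L, user_id]
  users <- users_all[user_id %in% mentioners]
  n_users <- nrow(users)

  group_counts <- vapply(c("abdominal", "vaginal", "laparoscopic"),
                         function(g) sum(users$treatment_group == g), integer(1))
  ovary_counts <- vapply(c("kept_at_least_one", "both_removed", "unknown"),
                         function(o) sum(users$ovary_status == o), integer(1))

  per_user_posts <- dt[, .N, by = user_id]$N

  k <- lengths(dt$mentioned)
  mention_long <- unlist(dt$mentioned, use.names = FALSE)
  total_mentions <- length(mention_long)
  per_symptom <- vapply(symptom_groups(),
                        function(s) sum(mention_long == s), integer(1))

  structure(list(
    n_users = n_users,
    n_users_all = nrow(users_all),
    n_posts = n_posts,
    posts_with_symptom = list(k = n_with, n = n_posts, pct = pct(n_with, n_posts)),
    posts_without_symptom = list(k = n_posts - n_with, n = n_posts,
                                 pct = pct(n_posts - n_with, n_posts)),
    posts_first_3_weeks = list(k = first3, n = n_posts, pct = pct(first3, n_posts)),
    group_counts = as.list(group_counts),
    group_pct = as.list(pct(group_counts, n_users)),
    ovary_counts = as.list(ovary_counts),
    ovary_pct = as.list(pct(ovary_counts, n_users)),
    post_day = list(median = stats::median(dt$days_postop),
                    mean = round_half_up(mean(dt$days_postop), 2),
                    sd = round_half_up(stats::sd(dt$days_postop), 2)),
    posts_per_contributor = list(median = stats::median(per_user_posts),
                                 mean = round_half_up(mean(per_user_posts), 2),
                                 sd = round_half_up(stats::sd(per_user_posts), 2)),
    total_symptom_mentions = total_mentions,
    per_symptom_mentions = as.list(per_symptom),
    per_symptom_share_pct = if (total_mentions > 0)
      as.list(pct(per_symptom, total_mentions)) else as.list(per_symptom * NA_real_)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d users (%d mentioning a symptom), %d posts\n",
              x$n_users_all, x$n_users, x$n_posts))
  cat(sprintf("  posts mentioning >=1 symptom: %d/%d (%.2f%%)\n",
              x$posts_with_symptom$k, x$posts_with_symptom$n,
              x$posts_with_symptom$pct))
  cat(sprintf("  posts in first 3 weeks:       %d/%d (%.2f%%)\n",
              x$posts_first_3_weeks$k, x$posts_first_3_weeks$n,
              x$posts_first_3_weeks$pct))
  cat(sprintf("  post day: median %s, mean %.2f, sd %.2f\n",
              format(x$post_day$median), x$post_day$mean, x$post_day$sd))
  cat(sprintf("  posts/contributor: median %s, mean %.2f, sd %.2f\n",
              format(x$posts_per_contributor$median),
              x$posts_per_contributor$mean, x$posts_per_contributor$sd))
  invisible(x)
}
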