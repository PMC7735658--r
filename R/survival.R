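# Time-to-last-mention analysis. Each user's "event time" for a symptom is
# the day of their final tagged mention of it within the 84-day window; every
# such time is treated as an observed event (no censoring — the central
# interpretive assumption: subject-only data cannot distinguish "stopped
# mentioning" from "kept posting about something else"). Curves are
# product-limit estimates, group comparisons use the log-rank test, and the
# headline effect size is the mean of the 25/50/75% quartile-time differences.

#' Per-user last-mention records
#'
#' For each (user, symptom) pair with at least one tagged post, the latest
#' `days_postop` among those posts. Users who never mention a symptom
#' contribute no record for it.
#'
#' @param tagged_posts table from [tag_cohort()] (needs `user_id`,
#'   `treatment_group`, `days_postop`, `mentioned`)
#' @return `data.table` with `user_id`, `treatment_group`, `symptom`,
#'   `last_day`
#' @export
last_mentions <- function(tagged_posts) {
  dt <- data.table::as.data.table(tagged_posts)
  stopifnot(all(c("user_id", "treatment_group", "days_postop", "mentioned")
                %in% names(dt)))
  k <- lengths(dt$mentioned)
  long <- data.table::data.table(
    user_id = rep(dt$user_id, k),
    treatment_group = rep(dt$treatment_group, k),
    symptom = unlist(dt$mentioned, use.names = FALSE),
    day = rep(dt$days_postop, k))
  if (nrow(long) == 0L)
    return(data.table::data.table(user_id = character(0),
                                  treatment_group = character(0),
                                  symptom = character(0),
                                  last_day = integer(0)))
  out <- long[, .(last_day = max(day)), by = .(user_id, treatment_group, symptom)]
  out[]
}

#' Kaplan-Meier survival curve for uncensored event days
#'
#' Product-limit estimate; with every observation an event this equals the
#' empirical survivor function S(t) = #(T > t) / n, reaching 0 at the largest
#' event time.
#'
#' @param times nonempty numeric vector of event days
#' @return a `survival_curve`: list with `event_times` (ascending unique),
#'   `survival` (S(t) just after each event time), `n_at_risk` (at each event
#'   time), `n`
#' @export
km_estimate <- function(times) {
  if (length(times) == 0L || anyNA(times)) abort("km_estimate: empty or NA input")
  fit <- survival::survfit(survival::Surv(times, rep(1L, length(times))) ~ 1)
  keep <- fit$n.event > 0
  structure(list(event_times = fit$time[keep],
                 survival = fit$surv[keep],
                 n_at_risk = fit$n.risk[keep],
                 n = length(times)),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("<survival_curve> n = %d, %d event times (day %s to %s)\n",
              x$n, length(x$event_times),
              format(min(x$event_times)), format(max(x$event_times))))
  invisible(x)
}

#' Two-sample log-rank test
#'
#' Standard log-rank chi-square (1 df) comparing two uncensored event-day
#' samples, with the hypergeometric-variance handling of tied event days.
#'
#' @param times_a,times_b nonempty numeric vectors of event days
#' @return list with `statistic`, `p`
#' @export
log_rank <- function(times_a, times_b) {
  if (length(times_a) == 0L || length(times_b) == 0L)
    abort("log_rank: both groups must be nonempty")
  time <- c(times_a, times_b)
  grp <- rep(c("a", "b"), c(length(times_a), length(times_b)))
  if (length(unique(time)) == 1L || identical(sort(times_a), sort(times_b))) {
    # survdiff is undefined/exact-zero here; identical samples give 0 by design
    if (isTRUE(all.equal(as.numeric(sort(times_a)), as.numeric(sort(times_b)))))
      return(list(statistic = 0, p = 1))
  }
  sd <- survival::survdiff(survival::Surv(time, rep(1L, length(time))) ~ grp)
  stat <- unname(sd$chisq)
  if (!is.finite(stat)) stat <- 0 # zero-variance degenerate case (all ties)
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Quartile time of a survival curve
#'
#' The q-th quantile of the event-time distribution: the smallest event time
#' t with S(t) <= 1 - q (the standard Kaplan-Meier quantile convention,
#' deterministic under ties). Because the curves here are uncensored and
#' reach 0, every quartile exists.
#'
#' @param curve a `survival_curve`
#' @param q quantile level, one of 0.25, 0.5, 0.75 (any value in (0,1) works)
#' @return the quartile day
#' @export
quartile_time <- function(curve, q) {
  stopifnot(inherits(curve, "survival_curve"), q > 0, q < 1)
  idx <- which(curve$survival <= 1 - q + 1e-12)
  curve$event_times[idx[1]]
}

#' Mean interquartile difference between two survival curves
#'
#' Mean over q in {0.25, 0.5, 0.75} of the comparison curve's quartile time
#' minus the reference curve's. Negative values mean the comparison group
#' ceases mentioning earlier.
#'
#' @param curve_group comparison `survival_curve`
#' @param curve_reference reference `survival_curve`
#' @return difference in days
#' @export
mean_interquartile_difference <- function(curve_group, curve_reference) {
  qs <- c(0.25, 0.5, 0.75)
  dg <- vapply(qs, function(q) quartile_time(curve_group, q), numeric(1))
  dr <- vapply(qs, function(q) quartile_time(curve_reference, q), numeric(1))
  mean(dg - dr)
}

#' Survival comparison report (time to last mention)
#'
#' Per (symptom, comparison group): the mean interquartile difference versus
#' the reference group (rounded half-up to 1 decimal for display, full
#' precision retained), the log-rank p-value with tiered significance
#' annotation, and a cessation-direction label. Symptom/group cells with
#' fewer than 2 records in either arm are emitted with an insufficient-data
#' marker rather than dropped.
#'
#' @param records output of [last_mentions()]
#' @param reference_group default `"abdominal"`
#' @param groups comparison groups, default vaginal and laparoscopic
#' @return `data.table` with `symptom`, `group`, `n_group`, `n_ref`,
#'   `mean_iq_diff`, `mean_iq_diff_display`, `logrank_chi2`, `p`, `sig_tier`,
#'   `direction` (`earlier_cessation` / `later_cessation` / `no_difference` /
#'   `insufficient_data`)
#' @export
survival_report <- function(records, reference_group = "abdominal",
                            groups = c("vaginal", "laparoscopic")) {
  dt <- data.table::as.data.table(records)
  if (!reference_group %in% dt$treatment_group)
    abort("missing reference group: %s", reference_group)
  groups <- intersect(groups, unique(dt$treatment_group))
  if (length(groups) == 0L) abort("no comparison group present")
  rows <- list()
  for (g in groups) {
    for (s in symptom_groups()) {
      t_g <- dt[treatment_group == g & symptom == s, last_day]
      t_r <- dt[treatment_group == reference_group & symptom == s, last_day]
      if (length(t_g) < 2L || length(t_r) < 2L) {
        rows[[length(rows) + 1L]] <- data.table::data.table(
          symptom = s, group = g, n_group = length(t_g), n_ref = length(t_r),
          mean_iq_diff = NA_real_, logrank_chi2 = NA_real_, p = NA_real_,
          direction = "insufficient_data")
        next
      }
      diff <- mean_interquartile_difference(km_estimate(t_g), km_estimate(t_r))
      lr <- log_rank(t_g, t_r)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        symptom = s, group = g, n_group = length(t_g), n_ref = length(t_r),
        mean_iq_diff = diff, logrank_chi2 = lr$statistic, p = lr$p,
        direction = if (diff < 0) "earlier_cessation"
                    else if (diff > 0) "later_cessation" else "no_difference")
    }
  }
  out <- data.table::rbindlist(rows)
  out[, mean_iq_diff_display := round_half_up(mean_iq_diff, 1)]
  out[, sig_tier := sig_tier(p)]
  out[]
}

#' Export survival curves as a tidy table
#'
#' One row per (symptom, group, event day), suitable for CSV export and
#' plotting.
#'
#' @param records output of [last_mentions()]
#' @return `data.table` with `symptom`, `group`, `day`, `survival`,
#'   `n_at_risk`
#' @export
survival_curves_table <- function(records) {
  dt <- data.table::as.data.table(records)
  rows <- list()
  for (s in unique(dt$symptom)) {
    for (g in unique(dt$treatment_group)) {
      t <- dt[symptom == s & treatment_group == g, last_day]
      if (length(t) == 0L) next
      cv <- km_estimate(t)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        symptom = s, group = g, day = cv$event_times,
        survival = cv$survival, n_at_risk = cv$n_at_risk)
    }
  }
  data.table::rbindlist(rows)
}
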