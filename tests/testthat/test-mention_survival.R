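test_that("last_mentions takes the max day per (user, symptom)", {
  tagged <- make_tagged(
    user_id = c("u1", "u1", "u1", "u2"),
    treatment_group = "abdominal",
    days_postop = c(3, 17, 9, 5),
    mentioned = list("pain", "pain", "bleeding", c("pain", "bleeding")))
  rec <- last_mentions(tagged)
  expect_equal(rec[rec$user_id == "u1" & rec$symptom == "pain", ]$last_day, 17L)
  expect_equal(rec[rec$user_id == "u1" & rec$symptom == "bleeding", ]$last_day, 9L)
  expect_equal(nrow(rec[rec$user_id == "u2", ]), 2L) # one record per symptom
  # never-mentioned symptom contributes no record
  expect_equal(nrow(rec[rec$symptom == "drugs", ]), 0L)
  empty <- last_mentions(make_tagged("u1", "abdominal", 3, list(character(0))))
  expect_equal(nrow(empty), 0L)
})

test_that("km_estimate equals the empirical survivor function", {
  cv <- km_estimate(c(2, 2, 5))
  expect_equal(cv$event_times, c(2, 5))
  expect_equal(cv$survival, c(1 / 3, 0))
  cv1 <- km_estimate(7)
  expect_equal(cv1$event_times, 7)
  expect_equal(cv1$survival, 0)
  expect_error(km_estimate(numeric(0)), "empty")
  set.seed(41)
  for (i in 1:100) {
    times <- sample(0:84, sample(3:60, 1), replace = TRUE)
    cv <- km_estimate(times)
    for (t in 0:84) {
      s_hat <- if (any(cv$event_times <= t)) {
        cv$survival[max(which(cv$event_times <= t))]
      } else 1
      expect_equal(s_hat, oracle_surv(times, t))
    }
    expect_equal(cv$survival[length(cv$survival)], 0) # no censoring: reaches 0
    expect_true(all(diff(cv$survival) <= 0))
  }
})

test_that("log_rank matches the O-E/V oracle and handles ties", {
  expect_equal(log_rank(c(1, 5, 9), c(1, 5, 9)), list(statistic = 0, p = 1))
  r <- log_rank(c(1, 4, 6, 9), c(2, 3, 7, 8))
  expect_equal(r$statistic, oracle_logrank(c(1, 4, 6, 9), c(2, 3, 7, 8)),
               tolerance = 1e-9)
  set.seed(42)
  for (i in 1:50) {
    ta <- sample(0:30, sample(4:20, 1), replace = TRUE)
    tb <- sample(0:30, sample(4:20, 1), replace = TRUE)
    r <- log_rank(ta, tb)
    expect_equal(r$statistic, oracle_logrank(ta, tb), tolerance = 1e-9)
    expect_equal(r$p, stats::pchisq(r$statistic, 1, lower.tail = FALSE))
    # invariance under adding a constant to all times
    r2 <- log_rank(ta + 7, tb + 7)
    expect_equal(r2$statistic, r$statistic, tolerance = 1e-9)
  }
  expect_error(log_rank(numeric(0), 1:3), "nonempty")
})

test_that("quartile_time follows the smallest-time-at-or-below convention", {
  cv <- km_estimate(c(1, 2, 3, 4))
  expect_equal(quartile_time(cv, 0.25), 1)
  expect_equal(quartile_time(cv, 0.5), 2)
  expect_equal(quartile_time(cv, 0.75), 3)
  pm <- km_estimate(rep(10, 8))
  for (q in c(0.25, 0.5, 0.75)) expect_equal(quartile_time(pm, q), 10)
})

test_that("mean_interquartile_difference: identity, shift, antisymmetry", {
  a <- km_estimate(c(3, 8, 15, 22, 40))
  expect_equal(mean_interquartile_difference(a, a), 0)
  b <- km_estimate(c(3, 8, 15, 22, 40) + 3)
  expect_equal(mean_interquartile_difference(a, b), -3) # reference 3 days later
  expect_equal(mean_interquartile_difference(b, a), 3)
  set.seed(43)
  for (i in 1:20) {
    x <- sort(sample(0:84, 15)) # distinct times: quartiles uniquely attained
    y <- sort(sample(0:84, 11))
    cx <- km_estimate(x); cy <- km_estimate(y)
    expect_equal(mean_interquartile_difference(cx, cy),
                 -mean_interquartile_difference(cy, cx))
  }
})

test_that("survival_report shapes output and flags thin cells", {
  set.seed(44)
  mk <- function(group, n, shift) {
    data.table::data.table(
      user_id = paste0(group, seq_len(n)), treatment_group = group,
      symptom = "pain",
      last_day = pmin(pmax(sample(5:40, n, TRUE) + shift, 0), 84))
  }
  rec <- rbind(mk("abdominal", 80, 0), mk("vaginal", 80, -6),
               mk("laparoscopic", 1, 0))
  rep <- survival_report(rec)
  vag <- rep[rep$symptom == "pain" & rep$group == "vaginal", ]
  expect_lt(vag$mean_iq_diff, 0)
  expect_equal(vag$direction, "earlier_cessation")
  lap <- rep[rep$symptom == "pain" & rep$group == "laparoscopic", ]
  expect_equal(lap$direction, "insufficient_data")
  expect_true(is.na(lap$mean_iq_diff))
  # symptoms with no records at all are emitted with the marker too
  expect_equal(nrow(rep), 24L)
  expect_error(survival_report(rec[rec$treatment_group != "abdominal", ]),
               "reference")
  expect_equal(rep$mean_iq_diff_display, round_half_up(rep$mean_iq_diff, 1))
})

test_that("survival_curves_table matches km_estimate per stratum", {
  rec <- data.table::data.table(
    user_id = sprintf("u%d", 1:6), treatment_group = rep(c("abdominal", "vaginal"), 3),
    symptom = "pain", last_day = c(3, 5, 3, 9, 12, 5))
  tab <- survival_curves_table(rec)
  ab <- tab[tab$group == "abdominal", ]
  cv <- km_estimate(c(3, 3, 12))
  expect_equal(ab$day, cv$event_times)
  expect_equal(ab$survival, cv$survival)
  expect_equal(ab$n_at_risk, cv$n_at_risk)
})
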