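test_that("read_posts passes valid rows through and rejects malformed ones", {
  p <- write_posts_csv(list(
    user_id = c("u1", "u2", "u3"),
    subject = c("first post", "", "third"),
    posted_at = c("2015-01-10T08:00:00", "2015-01-11T09:30:00", "2015-02-01T12:00:00")))
  posts <- read_posts(p)
  expect_equal(nrow(posts), 3L)
  expect_equal(attr(posts, "n_rejected"), 0L)
  expect_s3_class(posts$posted_at, "POSIXct")

  p2 <- write_posts_csv(list(
    user_id = c("u1", "u2", "u3"),
    subject = c("a", "b", "c"),
    posted_at = c("2015-01-10T08:00:00", "", "2015-02-01T12:00:00")))
  expect_message(posts2 <- read_posts(p2), "rejected 1")
  expect_equal(nrow(posts2), 2L)
  expect_equal(attr(posts2, "n_rejected"), 1L)

  # header-only file: empty result, no error
  p3 <- tempfile(fileext = ".csv")
  writeLines("user_id,thread_id,is_thread_initial,subject,posted_at", p3)
  expect_equal(nrow(read_posts(p3)), 0L)

  # missing required column is fatal and names the column
  p4 <- tempfile(fileext = ".csv")
  writeLines(c("user_id,thread_id,subject", "u1,t1,hello"), p4)
  expect_error(read_posts(p4), "posted_at")
  expect_error(read_posts(tempfile()), "not found")
})

test_that("read_posts reads JSON-lines", {
  p <- tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"user_id":"u1","thread_id":"t1","is_thread_initial":true,"subject":"pain update","posted_at":"2015-01-05T10:00:00"}',
    '{"user_id":"u2","thread_id":"t2","is_thread_initial":false,"subject":"re","posted_at":"2015-01-06T10:00:00"}'), p)
  posts <- read_posts(p)
  expect_equal(nrow(posts), 2L)
  expect_equal(posts$is_thread_initial, c(TRUE, FALSE))
})

test_that("map_treatment_group follows the type-code vocabulary", {
  expect_equal(map_treatment_group("LAVH"), "vaginal")
  expect_equal(map_treatment_group("DVH"), "laparoscopic")
  expect_true(is.na(map_treatment_group("SILS")))
  expect_true(is.na(map_treatment_group("LESS")))
  expect_equal(map_treatment_group(c("TAH", "SAH", "TAH/SAH", "TAH-SAH")),
               rep("abdominal", 4))
  expect_equal(map_treatment_group(c("TVH", "tlh", "LSH")),
               c("vaginal", "laparoscopic", "laparoscopic"))
  expect_warning(res <- map_treatment_group("XYZ"), "unrecognised")
  expect_true(is.na(res))
})

test_that("days_postop uses the floor-of-whole-days convention", {
  d0 <- as.Date("2015-03-01")
  expect_equal(days_postop("2015-03-01T09:00:00", d0), 0L)
  expect_equal(days_postop("2015-05-24T23:00:00", d0), 84L)
  expect_equal(days_postop("2015-02-28T10:00:00", d0), -1L)
})

test_that("build_cohort applies the four filters in order with attrition log", {
  profiles <- read_profiles(write_profiles_csv(list(
    user_id = c("u1", "u2", "u3", "u4"),
    hysterectomy_type = c("TLH", "SILS", "TAH", ""),
    surgery_date = c("2015-01-01", "2015-01-01", "", "2015-01-01"))))
  posts <- read_posts(write_posts_csv(list(
    user_id = c("u1", "u1", "u1", "u2", "u3", "u4", "u9"),
    is_thread_initial = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE),
    subject = letters[1:7],
    posted_at = c("2015-01-11T08:00:00",  # u1 day 10: kept
                  "2015-04-01T08:00:00",  # u1 day 90: window
                  "2015-01-12T08:00:00",  # reply
                  "2015-01-11T08:00:00",  # SILS -> excluded group
                  "2015-01-11T08:00:00",  # no date declared
                  "2015-01-11T08:00:00",  # no type declared
                  "2015-01-11T08:00:00")  # no profile at all
  )))
  cohort <- build_cohort(posts, profiles)
  expect_equal(nrow(cohort), 1L)
  expect_equal(cohort$treatment_group, "laparoscopic")
  expect_equal(cohort$days_postop, 10L)
  expect_equal(cohort$week_postop, 2L)
  att <- attr(cohort, "attrition")
  expect_equal(unname(att["not_thread_initial"]), 1L)
  expect_equal(unname(att["undeclared_type_or_date"]), 3L)
  expect_equal(unname(att["excluded_treatment_group"]), 1L)
  expect_equal(unname(att["outside_window"]), 1L)
  expect_equal(sum(att), nrow(posts) - nrow(cohort))
})

test_that("window boundaries are closed [0, 84] and day 84 is week 13", {
  profiles <- read_profiles(write_profiles_csv(list(
    user_id = "u1", hysterectomy_type = "TVH", surgery_date = "2015-01-01")))
  posts <- read_posts(write_posts_csv(list(
    user_id = rep("u1", 4), subject = c("day0", "day84", "day85", "daym1"),
    posted_at = c("2015-01-01T10:00:00", "2015-03-26T10:00:00",
                  "2015-03-27T10:00:00", "2014-12-31T10:00:00"))))
  cohort <- build_cohort(posts, profiles)
  expect_equal(sort(cohort$days_postop), c(0L, 84L))
  expect_equal(cohort[cohort$days_postop == 84L, ]$week_postop, 13L)
  expect_true(all(cohort$days_postop >= 0 & cohort$days_postop <= 84))
})

test_that("duplicate profiles keep the first record with a warning", {
  p <- write_profiles_csv(list(
    user_id = c("u1", "u1"),
    hysterectomy_type = c("TAH", "TLH"),
    surgery_date = c("2015-01-01", "2015-06-01")))
  expect_warning(profiles <- read_profiles(p), "duplicate")
  expect_equal(nrow(profiles), 1L)
  expect_equal(profiles$hysterectomy_type, "TAH")
})

test_that("empty cohort is legal and warns", {
  profiles <- read_profiles(write_profiles_csv(list(
    user_id = "u1", hysterectomy_type = "TAH", surgery_date = "2015-01-01")))
  posts <- read_posts(write_posts_csv(list(
    user_id = "u1", subject = "late", posted_at = "2016-01-01T10:00:00")))
  expect_warning(cohort <- build_cohort(posts, profiles), "empty")
  expect_equal(nrow(cohort), 0L)
})
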