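test_that("tokenize lowercases, splits on non-alphanumerics, keeps digits", {
  expect_equal(tokenize("Spotting at 10 weeks!"), c("spotting", "at", "10", "weeks"))
  expect_equal(tokenize(""), character(0))
  expect_equal(tokenize("swelly-belly?"), c("swelly", "belly"))
  expect_equal(tokenize("PAIN...pain, Pain"), c("pain", "pain", "pain"))
  expect_equal(tokenize_all(c("a b", "", "C!d")),
               list(c("a", "b"), character(0), c("c", "d")))
})

test_that("tag_subject matches whole tokens only, deduplicated", {
  tax <- default_taxonomy()
  expect_setequal(tag_subject(tokenize("terrible pain and spotting"), tax),
                  c("pain", "bleeding"))
  expect_equal(tag_subject(tokenize("painting my room"), tax), character(0))
  expect_equal(tag_subject(tokenize("pain pain pain"), tax), "pain")
  expect_equal(tag_subject(character(0), tax), character(0))
  # multi-token keyword requires contiguity ("swelly belly" but not
  # "belly ... swelly"); tiny taxonomy isolates the phrase from unigrams
  tiny <- tiny_taxonomy()
  expect_equal(tag_subject(tokenize("my swelly belly woes"), tiny), "swelling")
  expect_equal(tag_subject(tokenize("belly of swelly"), tiny), character(0))
})

test_that("default taxonomy covers all groups and the documented keywords", {
  tax <- default_taxonomy()
  expect_s3_class(tax, "symptom_taxonomy")
  expect_setequal(names(tax), symptom_groups())
  expect_true(all(lengths(tax) >= 5))
  where <- function(kw) names(tax)[vapply(tax, function(x) kw %in% x, logical(1))]
  expect_equal(where("gastritis"), "digestion")
  expect_equal(where("vomitting"), "digestion")
  expect_equal(where("itches"), "odd_sensations")
  expect_equal(where("burns"), "odd_sensations")
  expect_equal(where("weepies"), "hormones_and_emotions")
  expect_equal(where("swellybelly"), "swelling")
  expect_equal(where("achey"), "pain")
  expect_equal(where("spotting"), "bleeding")
  # deliberately excluded: appears in forum text unassociated with a symptom
  expect_length(where("catheter"), 0)
})

test_that("load_taxonomy validates structure", {
  tax <- tiny_taxonomy()
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(unclass(tax), f)
  expect_equal(unclass(load_taxonomy(f)), lapply(unclass(tax), as.character))
  expect_equal(tag_subject(tokenize("so achey today"), load_taxonomy(f)), "pain")

  bad <- unclass(tax); names(bad)[1] <- "not_a_group"
  f2 <- tempfile(fileext = ".json"); jsonlite::write_json(bad, f2)
  expect_error(load_taxonomy(f2), "not_a_group")

  dup <- unclass(tax); dup$bleeding <- c(dup$bleeding, "pain")
  f3 <- tempfile(fileext = ".json"); jsonlite::write_json(dup, f3)
  expect_error(load_taxonomy(f3), "pain.*bleeding|bleeding.*pain")
})

test_that("keyword_in_context returns exactly the containing subjects", {
  subjects <- c("new spotting at 3 weeks", "all good here", "spot of bother")
  expect_equal(keyword_in_context("spotting", subjects), subjects[1])
  expect_equal(keyword_in_context("dizzy", subjects), character(0))
  multi <- c("having hot flashes daily", "hot day no flashes")
  expect_equal(keyword_in_context("hot flashes", multi), multi[1])
  expect_error(keyword_in_context("!!!", subjects), "token")
})

test_that("tagging equals the brute-force alignment oracle on random fixtures", {
  tax <- default_taxonomy()
  pool <- c("the", "at", "week", "update", "hello", "pain", "spotting",
            "swelly", "belly", "hot", "flashes", "painting", "10",
            "gastritis", "tired", "fever", "hubby", "meds")
  set.seed(42)
  for (i in 1:200) {
    toks <- tokenize(random_subject(pool, sample(0:8, 1)))
    expect_equal(sort(tag_subject(toks, tax)), oracle_tag(toks, tax))
  }
})

test_that("tagging is invariant to case and repetition, monotone in keywords", {
  tax <- tiny_taxonomy()
  s <- "Achey and SPOTTING again"
  expect_equal(tag_subject(tokenize(s), tax), tag_subject(tokenize(tolower(s)), tax))
  expect_equal(tag_subject(tokenize("achey achey spotting spotting"), tax),
               tag_subject(tokenize("achey spotting"), tax))
  # adding a keyword never removes existing tags
  grown <- unclass(tax)
  grown$digestion <- c(grown$digestion, "queasy")
  grown <- forumlisten:::validate_taxonomy(grown)
  subjects <- c("achey and queasy", "spotting", "queasy only", "nothing here")
  for (s in subjects) {
    before <- tag_subject(tokenize(s), tax)
    after <- tag_subject(tokenize(s), grown)
    expect_true(all(before %in% after))
  }
})

test_that("tag_cohort agrees with per-post tag_subject", {
  tax <- default_taxonomy()
  subjects <- c("pain at 3 weeks", "hello all", "swelly belly and hot flashes",
                "spotting and cramping", "", "painting class tonight")
  cohort <- data.table::data.table(user_id = "u", subject = subjects,
                                   days_postop = 1L)
  tagged <- tag_cohort(cohort, tax)
  for (i in seq_along(subjects)) {
    expect_setequal(tagged$mentioned[[i]], tag_subject(tokenize(subjects[i]), tax))
  }
  expect_equal(tagged$n_symptoms, lengths(tagged$mentioned))
})
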