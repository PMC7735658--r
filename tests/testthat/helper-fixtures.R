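# Fixture builders: everything is generated in code at test time.

write_posts_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  df <- data.frame(user_id = rows$user_id,
                   thread_id = rows$thread_id %||% sprintf("t%03d", seq_along(rows$user_id)),
                   is_thread_initial = rows$is_thread_initial %||% TRUE,
                   subject = rows$subject,
                   posted_at = rows$posted_at,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

write_profiles_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  df <- data.frame(user_id = rows$user_id,
                   hysterectomy_type = rows$hysterectomy_type,
                   surgery_date = rows$surgery_date,
                   ovary_status = rows$ovary_status %||% "unknown",
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a small tagged-cohort table built directly (bypasses file IO)
make_tagged <- function(user_id, treatment_group, days_postop, mentioned,
                        ovary_status = "unknown", subject = "") {
  data.table::data.table(
    user_id = user_id, treatment_group = treatment_group,
    ovary_status = ovary_status, subject = subject,
    days_postop = as.integer(days_postop),
    week_postop = as.integer(days_postop) %/% 7L + 1L,
    mentioned = mentioned, n_symptoms = lengths(mentioned))
}

# a tiny two-group taxonomy for targeted tests (not the shipped default)
tiny_taxonomy <- function() {
  forumlisten:::validate_taxonomy(list(
    pain = c("pain", "achey"),
    sleep_and_fatigue = c("tired"),
    hormones_and_emotions = c("weepies"),
    digestion = c("nausea"),
    swelling = c("swellybelly", "swelly belly"),
    bleeding = c("spotting"),
    urination = c("bladder"),
    intimacy = c("intimacy"),
    odd_sensations = c("tingling"),
    drugs = c("meds"),
    fever_and_infection = c("fever"),
    family = c("hubby")))
}

# random subject built from a pool of filler and keyword tokens
random_subject <- function(pool, n_tokens) {
  paste(sample(pool, n_tokens, replace = TRUE), collapse = " ")
}
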