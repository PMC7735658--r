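# Cohort ingestion: raw post + profile records -> filtered analysis cohort.
# Filters, in fixed order: thread-initial posts only; user must declare both a
# hysterectomy type and a surgery date; the type must map to one of the three
# treatment groups (SILS/LESS and unknown codes are excluded); the post must
# fall in the closed window [0, 84] days after surgery (surgery day = day 0).

POST_COLUMNS <- c("user_id", "thread_id", "is_thread_initial", "subject", "posted_at")
PROFILE_COLUMNS <- c("user_id", "hysterectomy_type", "surgery_date", "ovary_status")

#' Map a hysterectomy type code to a treatment group
#'
#' Total function over the site's type-code vocabulary: TAH, SAH and TAH/SAH
#' map to `"abdominal"`; TVH and LAVH to `"vaginal"`; TLH, LSH and DVH
#' (da Vinci robotic) to `"laparoscopic"`. Single-incision codes (SILS, LESS)
#' are excluded from analysis and map to `NA`, as does any unrecognised code
#' (with a warning). Matching is case-insensitive and tolerates `-` for `/`.
#'
#' @param type_code character vector of type codes
#' @return character vector: `"abdominal"`, `"vaginal"`, `"laparoscopic"`, or
#'   `NA` for excluded codes
#' @export
map_treatment_group <- function(type_code) {
  code <- toupper(trimws(as.character(type_code)))
  code <- gsub("-", "/", code, fixed = TRUE)
  lut <- c(TAH = "abdominal", SAH = "abdominal", "TAH/SAH" = "abdominal",
           TVH = "vaginal", LAVH = "vaginal",
           TLH = "laparoscopic", LSH = "laparoscopic", DVH = "laparoscopic",
           SILS = NA, LESS = NA, "SILS/LESS" = NA)
  out <- unname(lut[code])
  unknown <- !(code %in% names(lut)) & !is.na(code) & nzchar(code)
  if (any(unknown)) {
    warning(sprintf("unrecognised hysterectomy type code(s): %s (excluded)",
                    paste(unique(code[unknown]), collapse = ", ")),
            call. = FALSE)
  }
  out
}

#' Whole days between surgery and a post
#'
#' Floor of the whole-day difference between the post timestamp's calendar
#' date (UTC) and the surgery date; negative when the post precedes surgery.
#'
#' @param posted_at POSIXct vector (or parseable character)
#' @param surgery_date Date vector (or parseable character)
#' @return integer days
#' @export
days_postop <- function(posted_at, surgery_date) {
  if (is.character(posted_at)) posted_at <- parse_timestamp(posted_at)
  if (!inherits(surgery_date, "Date")) surgery_date <- as.Date(surgery_date)
  as.integer(as.Date(posted_at, tz = "UTC") - surgery_date)
}

# lenient ISO-8601 parser: malformed strings yield NA instead of an error
parse_timestamp <- function(x) {
  x <- as.character(x)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S", "%Y-%m-%d")) {
    need <- is.na(out)
    if (!any(need)) break
    out[need] <- as.POSIXct(strptime(x[need], fmt, tz = "UTC"))
  }
  out
}

#' Read raw post records
#'
#' Reads a CSV or JSON-lines file of post records with columns
#' `user_id`, `thread_id`, `is_thread_initial`, `subject`, `posted_at`
#' (ISO-8601). Rows with an unparseable or missing timestamp or missing
#' user/thread id are rejected, counted and reported via a message — never
#' silently dropped. An empty subject is legal.
#'
#' @param path file path
#' @param format `"csv"` or `"jsonl"` (default guessed from extension)
#' @return `data.table` of posts; the number of rejected rows is attached as
#'   `attr(, "n_rejected")`
#' @export
read_posts <- function(path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort("post file not found: %s", path)
  if (format == "auto")
    format <- if (grepl("\\.jsonl$", path)) "jsonl" else "csv"
  dt <- if (format == "csv") {
    data.table::fread(path, colClasses = "character")
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    data.table::rbindlist(lapply(lines, function(l) jsonlite::fromJSON(l)),
                          fill = TRUE)
  }
  missing_cols <- setdiff(POST_COLUMNS, names(dt))
  if (length(missing_cols))
    abort("post file missing required column(s): %s",
          paste(missing_cols, collapse = ", "))
  dt <- dt[, POST_COLUMNS, with = FALSE]
  dt[, subject := as.character(subject)]
  dt[is.na(subject), subject := ""]
  dt[, is_thread_initial := as.logical(is_thread_initial)]
  ts <- suppressWarnings(parse_timestamp(as.character(dt$posted_at)))
  bad <- is.na(ts) | is.na(dt$user_id) | !nzchar(dt$user_id) |
    is.na(dt$thread_id) | is.na(dt$is_thread_initial)
  n_bad <- sum(bad)
  if (n_bad > 0)
    message(sprintf("read_posts: rejected %d malformed row(s) of %d", n_bad, nrow(dt)))
  dt <- dt[!bad]
  dt[, posted_at := ts[!bad]]
  data.table::setattr(dt, "n_rejected", n_bad)
  dt[]
}

#' Read user profile records
#'
#' CSV with columns `user_id`, `hysterectomy_type`, `surgery_date`
#' (ISO-8601 date), `ovary_status` (one of `kept_at_least_one`,
#' `both_removed`, `unknown`). Duplicate `user_id`s keep the first record
#' with a warning. Empty strings are treated as missing declarations.
#'
#' @param path file path
#' @return `data.table` of profiles, one row per user
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) abort("profile file not found: %s", path)
  dt <- data.table::fread(path, colClasses = "character")
  missing_cols <- setdiff(PROFILE_COLUMNS, names(dt))
  if (length(missing_cols))
    abort("profile file missing required column(s): %s",
          paste(missing_cols, collapse = ", "))
  dt <- dt[, PROFILE_COLUMNS, with = FALSE]
  if (anyDuplicated(dt$user_id)) {
    warning(sprintf("profile file has %d duplicate user_id(s); keeping first",
                    sum(duplicated(dt$user_id))), call. = FALSE)
    dt <- dt[!duplicated(dt$user_id)]
  }
  dt[hysterectomy_type == "", hysterectomy_type := NA_character_]
  dt[surgery_date == "", surgery_date := NA_character_]
  dt[is.na(ovary_status) | ovary_status == "", ovary_status := "unknown"]
  bad_ovary <- !dt$ovary_status %in% c("kept_at_least_one", "both_removed", "unknown")
  if (any(bad_ovary)) {
    warning("unrecognised ovary_status value(s) set to 'unknown'", call. = FALSE)
    dt[bad_ovary, ovary_status := "unknown"]
  }
  dt[, surgery_date := as.Date(surgery_date)]
  dt[]
}

#' Build the analysis cohort
#'
#' Joins posts to profiles and applies the inclusion filters in fixed order:
#' 1. keep thread-initiating posts only;
#' 2. drop posts whose user did not declare both a hysterectomy type and a
#'    surgery date (or has no profile at all);
#' 3. drop users whose type code maps to no treatment group (SILS/LESS,
#'    unknown codes);
#' 4. keep posts with `days_postop` in the closed window `[window[1],
#'    window[2]]` (default 0-84: surgery day through 12 x 7 days).
#'
#' Ovary status is carried through but never used as a filter.
#'
#' @param posts posts table from [read_posts()]
#' @param profiles profiles table from [read_profiles()]
#' @param window integer length-2 inclusive day window, default `c(0, 84)`
#' @return `data.table` with columns `user_id`, `thread_id` (carried through
#'   as a stable post identifier), `treatment_group`,
#'   `ovary_status`, `subject`, `days_postop`, `week_postop`
#'   (`floor(days/7) + 1`, so day 84 alone forms week 13); the per-rule
#'   attrition counts are attached as `attr(, "attrition")`
#' @export
build_cohort <- function(posts, profiles, window = c(0L, 84L)) {
  stopifnot(length(window) == 2L, window[1] <= window[2], window[1] >= 0L)
  posts <- data.table::as.data.table(posts)
  profiles <- data.table::as.data.table(profiles)
  if (anyDuplicated(profiles$user_id)) {
    warning("duplicate profiles; keeping first per user_id", call. = FALSE)
    profiles <- profiles[!duplicated(user_id)]
  }
  n0 <- nrow(posts)
  attrition <- c(not_thread_initial = 0L, undeclared_type_or_date = 0L,
                 excluded_treatment_group = 0L, outside_window = 0L)

  keep <- posts$is_thread_initial %in% TRUE
  attrition["not_thread_initial"] <- sum(!keep)
  posts <- posts[keep]

  dt <- merge(posts, profiles, by = "user_id", all.x = TRUE, sort = FALSE)
  declared <- !is.na(dt$hysterectomy_type) & !is.na(dt$surgery_date)
  attrition["undeclared_type_or_date"] <- sum(!declared)
  dt <- dt[declared]

  dt[, treatment_group := suppressWarnings(map_treatment_group(hysterectomy_type))]
  grouped <- !is.na(dt$treatment_group)
  attrition["excluded_treatment_group"] <- sum(!grouped)
  dt <- dt[grouped]

  dt[, days_postop := days_postop(posted_at, surgery_date)]
  inwin <- dt$days_postop >= window[1] & dt$days_postop <= window[2]
  attrition["outside_window"] <- sum(!inwin)
  dt <- dt[inwin]

  dt[, week_postop := days_postop %/% 7L + 1L]
  out <- dt[, .(user_id, thread_id, treatment_group, ovary_status, subject,
                days_postop, week_postop)]
  stopifnot(sum(attrition) == n0 - nrow(out))
  if (nrow(out) == 0L)
    warning("cohort is empty after filtering", call. = FALSE)
  data.table::setattr(out, "attrition", attrition)
  out[]
}
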