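# Synthetic forum generator. Emits profile and post files in the ingest
# schema with the statistical structure the analysis assumes: a three-way
# treatment-group split, right-skewed posting times over the 84-day window,
# zero-truncated negative-binomial posts per user, per-(group, symptom)
# mention probabilities, and per-user symptom cessation times after which a
# symptom is never mentioned again. Subjects are bags of tokens: filler words
# (disjoint from the taxonomy) plus one embedded keyword per mentioned
# symptom group.

FILLER_VOCABULARY <- c(
  "question", "about", "week", "weeks", "day", "days", "post", "op",
  "surgery", "update", "help", "advice", "anyone", "else", "when", "how",
  "normal", "after", "first", "today", "feeling", "recovery", "time",
  "back", "home", "work", "doctor", "doc", "appointment", "checkup",
  "wondering", "tips", "experience", "please", "need", "know", "long",
  "soon", "okay", "good", "still", "just", "really", "getting", "going",
  "started", "finally", "thanks", "everyone", "ladies", "hello", "quick",
  "new", "here", "what", "should", "expect", "post", "at", "the", "and",
  "for", "my", "me", "is", "it", "of", "to", "a", "in", "on", "with")

# --- distribution fitting -------------------------------------------------

# zero-truncated negative binomial moments for NB(size, mu)
ztnb_moments <- function(size, mu, kmax = 500L) {
  k <- 1:kmax
  pk <- stats::dnbinom(k, size = size, mu = mu)
  p0 <- stats::dnbinom(0, size = size, mu = mu)
  pk <- pk / (1 - p0)
  m1 <- sum(k * pk)
  m2 <- sum(k^2 * pk)
  c(mean = m1, sd = sqrt(max(m2 - m1^2, 0)))
}

# fit NB(size, mu) so the zero-truncated distribution has the target moments.
# The mean is matched exactly (along the one-parameter family solved per
# size); the sd is matched as closely as the family allows — some published
# (mean, sd) pairs exceed the ZTNB's maximal dispersion at that mean (the
# log-series limit), in which case the closest attainable sd is used and
# recorded in the returned fit.
fit_ztnb <- function(target_mean, target_sd) {
  stopifnot(target_mean > 1)
  mu_for_size <- function(size) {
    f <- function(mu) {
      p0 <- stats::dnbinom(0, size = size, mu = mu)
      mu / (1 - p0) - target_mean
    }
    stats::uniroot(f, c(1e-9, target_mean), tol = 1e-12)$root
  }
  obj <- function(lsize) {
    size <- exp(lsize)
    mu <- mu_for_size(size)
    (ztnb_moments(size, mu)["sd"] - target_sd)^2
  }
  fit <- stats::optimize(obj, c(log(1e-4), log(100)), tol = 1e-10)
  size <- exp(fit$minimum); mu <- mu_for_size(size)
  ach <- ztnb_moments(size, mu)
  if (abs(ach["mean"] - target_mean) > 0.01)
    abort("posts-per-user mean target %.2f not attainable by a ZTNB", target_mean)
  list(size = size, mu = mu,
       achieved_mean = unname(ach["mean"]), achieved_sd = unname(ach["sd"]),
       target_mean = target_mean, target_sd = target_sd,
       sd_shortfall = unname(target_sd - ach["sd"]))
}

# day pmf over 0..84 implied by a gamma(shape, scale) truncated to [0, 85)
# and floored to whole days
post_day_pmf <- function(shape, scale) {
  edges <- stats::pgamma(0:85, shape = shape, scale = scale)
  p <- diff(edges) / edges[86]
  p / sum(p)
}

# fit the gamma so the truncated-floored day distribution hits a target
# median and mean
fit_post_time_gamma <- function(target_median = 19, target_mean = 23.8) {
  obj <- function(par) {
    shape <- exp(par[1]); scale <- exp(par[2])
    p <- post_day_pmf(shape, scale)
    m <- sum((0:84) * p)
    # continuous median of the truncated law keeps the objective smooth
    med <- stats::qgamma(0.5 * stats::pgamma(85, shape, scale = scale),
                         shape, scale = scale)
    (m - target_mean)^2 + (med - (target_median + 0.5))^2
  }
  fit <- stats::optim(c(log(1.6), log(15)), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  shape <- exp(fit$par[1]); scale <- exp(fit$par[2])
  p <- post_day_pmf(shape, scale)
  list(shape = shape, scale = scale,
       achieved_mean = sum((0:84) * p),
       achieved_median = (0:84)[which(cumsum(p) >= 0.5)[1]],
       target_median = target_median, target_mean = target_mean,
       fit_tol = sqrt(fit$value))
}

# --- cessation model ------------------------------------------------------

# one cessation-time specification: exp(mean) or gamma(shape, scale) with an
# optional additive shift (clamped at 0)
draw_cessation <- function(n, spec) {
  x <- switch(spec$dist,
              exp = stats::rexp(n, rate = 1 / spec$mean),
              gamma = stats::rgamma(n, shape = spec$shape, scale = spec$scale),
              abort("unknown cessation dist: %s", spec$dist))
  pmax(x + (spec$shift %||% 0), 0)
}

#' Last-mention days implied by a cessation model
#'
#' Draws cessation times for `n` users of `group` under `config`'s cessation
#' model and returns the last-mention day in the idealised dense-posting
#' limit (a user posting every day with mention probability 1 last mentions a
#' symptom on day `floor(min(cessation, 84))`). Used for event-time-level
#' validation of the survival machinery against planted shifts.
#'
#' @param config a `sim_config`
#' @param group treatment group name
#' @param n number of users
#' @return integer vector of last-mention days in `[0, 84]`
#' @export
draw_last_mention_days <- function(config, group, n) {
  spec <- config$cessation[[group]]
  as.integer(floor(pmin(draw_cessation(n, spec), 84)))
}

# --- configuration --------------------------------------------------------

default_mention_shares <- function() {
  c(pain = 0.311, bleeding = 0.187, hormones_and_emotions = 0.100,
    sleep_and_fatigue = 0.075, digestion = 0.065, swelling = 0.055,
    drugs = 0.050, urination = 0.045, odd_sensations = 0.040,
    fever_and_infection = 0.032, intimacy = 0.025, family = 0.015)
}

# default additive per-post probability offsets for the comparison groups,
# in probability units (a few percentage points, signed so that e.g. the
# vaginal group mentions urinary and intimacy keywords more and both
# minimally invasive groups mention swelling and sleep keywords less)
default_group_deltas <- function() {
  g <- symptom_groups()
  lap <- c(pain = 0.0021, sleep_and_fatigue = -0.0222,
           hormones_and_emotions = -0.0049, digestion = 0.0155,
           swelling = -0.0294, bleeding = 0.0303, urination = -0.0050,
           intimacy = -0.0025, odd_sensations = -0.0043, drugs = -0.0081,
           fever_and_infection = -0.0042, family = -0.0005)
  vag <- c(pain = 0.0098, sleep_and_fatigue = -0.0169,
           hormones_and_emotions = 0.0028, digestion = 0.0041,
           swelling = -0.0304, bleeding = -0.0146, urination = 0.0229,
           intimacy = 0.0238, odd_sensations = -0.0096, drugs = -0.0060,
           fever_and_infection = 0.0039, family = 0.0038)
  list(abdominal = stats::setNames(rep(0, 12), g),
       vaginal = vag[g], laparoscopic = lap[g])
}

# calibrate abdominal per-post mention probabilities so the expected share of
# posts mentioning >= 1 symptom (after cessation gating) hits the target
calibrate_mention_probs <- function(shares, target_with_symptom, gate) {
  shares <- shares / sum(shares)
  f <- function(lam) sum(log(1 - pmin(lam * shares * gate, 0.99))) -
    log(1 - target_with_symptom)
  lam <- stats::uniroot(f, c(1e-6, 1 / max(shares * gate) * 0.99))$root
  pmin(lam * shares, 0.95)
}

#' Build a synthetic-forum configuration
#'
#' Assembles and validates the full generative parameterisation. Defaults
#' encode the cohort the analysis pipeline expects: a 40/32/28
#' abdominal/vaginal/laparoscopic split, 56/37/7 ovary-status split,
#' zero-truncated negative-binomial posts per user (mean 2.42, sd 3.10),
#' gamma posting times truncated to 0-84 days (median day 19, mean 23.8),
#' per-symptom mention probabilities calibrated so ~42.4% of subjects mention
#' at least one symptom, group-specific probability offsets of a few
#' percentage points, and group-specific exponential symptom-cessation times
#' (abdominal mean 40 days, vaginal 37, laparoscopic 35, so the minimally
#' invasive groups cease mentions earlier).
#'
#' @param seed integer RNG seed (determinism contract: same config, same
#'   files)
#' @param n_users number of users (ignored when `group_sizes` is given)
#' @param group_probs named 3-vector of group probabilities summing to 1
#' @param group_sizes optional named integer 3-vector of exact group counts
#' @param ovary_probs named 3-vector for kept_at_least_one / both_removed /
#'   unknown
#' @param posts_per_user `list(type = "ztnb", mean =, sd =)` or
#'   `list(type = "fixed", k =)`
#' @param mention_shares named 12-vector of per-symptom mention shares
#' @param target_posts_with_symptom calibration target for the share of
#'   posts mentioning >= 1 symptom
#' @param group_deltas list of named 12-vectors of additive per-post
#'   probability offsets per group
#' @param mention_probs optional explicit group x symptom probability
#'   matrix overriding calibration (rows abdominal/vaginal/laparoscopic)
#' @param cessation per-group cessation specs, each
#'   `list(dist = "exp", mean =)` or
#'   `list(dist = "gamma", shape =, scale =, shift =)`
#' @param taxonomy taxonomy whose keywords get embedded (default
#'   [default_taxonomy()])
#' @param template_mode `"sample"` (random keyword per mention) or
#'   `"single_keyword"` (always the group's first keyword; enables exact
#'   round-trip checks)
#' @param violations `list(n_reply =, n_missing_date_users =, n_sils_users =,
#'   n_outside =)` extra records violating one ingest filter each (defaults
#'   all 0)
#' @param surgery_date_range Date range users' surgery dates are drawn from
#' @return a validated `sim_config` object
#' @export
sim_config <- function(seed = 1L,
                       n_users = 1000L,
                       group_probs = c(abdominal = 0.40, vaginal = 0.32,
                                       laparoscopic = 0.28),
                       group_sizes = NULL,
                       ovary_probs = c(kept_at_least_one = 0.56,
                                       both_removed = 0.37, unknown = 0.07),
                       posts_per_user = list(type = "ztnb", mean = 2.42, sd = 3.10),
                       mention_shares = default_mention_shares(),
                       target_posts_with_symptom = 0.4243,
                       group_deltas = default_group_deltas(),
                       mention_probs = NULL,
                       cessation = list(
                         abdominal = list(dist = "exp", mean = 40),
                         vaginal = list(dist = "exp", mean = 37),
                         laparoscopic = list(dist = "exp", mean = 35)),
                       taxonomy = default_taxonomy(),
                       template_mode = c("sample", "single_keyword"),
                       violations = list(),
                       surgery_date_range = as.Date(c("2013-01-01", "2016-12-31"))) {
  template_mode <- match.arg(template_mode)
  groups3 <- c("abdominal", "vaginal", "laparoscopic")
  stopifnot(abs(sum(group_probs) - 1) < 1e-8, all(group_probs >= 0),
            setequal(names(group_probs), groups3))
  stopifnot(abs(sum(ovary_probs) - 1) < 1e-8, all(ovary_probs >= 0))
  if (!is.null(group_sizes)) {
    stopifnot(setequal(names(group_sizes), groups3), all(group_sizes >= 0))
    n_users <- sum(group_sizes)
  }
  stopifnot(n_users >= 1L)

  # filler vocabulary must not collide with any taxonomy keyword token
  tax_tokens <- unique(unlist(tokenize_all(unlist(taxonomy, use.names = FALSE))))
  filler <- setdiff(unique(FILLER_VOCABULARY), tax_tokens)
  if (length(filler) < 20L)
    abort("filler vocabulary too small after removing taxonomy tokens")

  ppu <- posts_per_user
  if (ppu$type == "ztnb") {
    ppu <- c(ppu, fit_ztnb(ppu$mean, ppu$sd))
  } else if (ppu$type != "fixed") {
    abort("posts_per_user$type must be 'ztnb' or 'fixed'")
  }

  pt <- fit_post_time_gamma()
  day_pmf <- post_day_pmf(pt$shape, pt$scale)

  if (is.null(mention_probs)) {
    shares <- mention_shares[symptom_groups()]
    if (anyNA(shares)) abort("mention_shares must cover all 12 symptom groups")
    # cessation gate: average P(cessation >= post day) under the abdominal model
    gate <- sum(day_pmf * surv_at_days(cessation$abdominal, 0:84))
    base <- calibrate_mention_probs(shares, target_posts_with_symptom, gate)
    mention_probs <- rbind(
      abdominal = base,
      vaginal = pmin(pmax(base + group_deltas$vaginal[symptom_groups()], 0.0005), 0.95),
      laparoscopic = pmin(pmax(base + group_deltas$laparoscopic[symptom_groups()], 0.0005), 0.95))
    colnames(mention_probs) <- symptom_groups()
  } else {
    stopifnot(is.matrix(mention_probs),
              setequal(rownames(mention_probs), groups3),
              setequal(colnames(mention_probs), symptom_groups()),
              all(mention_probs >= 0), all(mention_probs <= 1))
    mention_probs <- mention_probs[groups3, symptom_groups()]
  }

  stopifnot(setequal(names(cessation), groups3))

  viol <- utils::modifyList(list(n_reply = 0L, n_missing_date_users = 0L,
                                 n_sils_users = 0L, n_outside = 0L), violations)

  structure(list(seed = as.integer(seed), n_users = as.integer(n_users),
                 group_probs = group_probs[groups3], group_sizes = group_sizes,
                 ovary_probs = ovary_probs,
                 posts_per_user = ppu, post_time = pt, day_pmf = day_pmf,
                 mention_probs = mention_probs, cessation = cessation,
                 taxonomy = taxonomy, filler = filler,
                 template_mode = template_mode, violations = viol,
                 surgery_date_range = surgery_date_range),
            class = "sim_config")
}

# P(cessation >= d) for integer days d under one cessation spec
surv_at_days <- function(spec, d) {
  shift <- spec$shift %||% 0
  dd <- pmax(d - shift, 0)
  switch(spec$dist,
         exp = exp(-dd / spec$mean),
         gamma = stats::pgamma(dd, shape = spec$shape, scale = spec$scale,
                               lower.tail = FALSE),
         abort("unknown cessation dist: %s", spec$dist))
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> seed %d, %d users, template_mode=%s\n",
              x$seed, x$n_users, x$template_mode))
  cat(sprintf("  posting: gamma(shape %.3f, scale %.3f), day median %d, mean %.2f\n",
              x$post_time$shape, x$post_time$scale,
              x$post_time$achieved_median, x$post_time$achieved_mean))
  if (x$posts_per_user$type == "ztnb")
    cat(sprintf("  posts/user: ZTNB mean %.3f sd %.3f\n",
                x$posts_per_user$achieved_mean, x$posts_per_user$achieved_sd))
  invisible(x)
}

# --- generation -----------------------------------------------------------

#' Simulate a synthetic forum cohort
#'
#' Deterministically (given `config$seed`) generates a profile file and a
#' post file in the ingest schema, plus the planted ground truth. Each user
#' gets a treatment group, ovary status, surgery date, a number of posts and
#' their days; each post's subject is filler text plus one embedded keyword
#' per symptom group mentioned, where a group is mentioned with the
#' configured per-post probability provided the day does not exceed the
#' user's drawn cessation time for the symptom. Configured violations are
#' appended as extra records, each tripping exactly one ingest filter.
#'
#' @param config a `sim_config`
#' @param dir output directory (created if needed)
#' @return list with `posts_path`, `profiles_path`, and `truth` (a
#'   `data.table` of the clean posts: `user_id`, `thread_id`, `day`, and the
#'   planted `mentioned` list-column)
#' @export
simulate_cohort <- function(config, dir = tempfile("simforum")) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  groups3 <- c("abdominal", "vaginal", "laparoscopic")
  n <- config$n_users

  group <- if (!is.null(config$group_sizes)) {
    rep(groups3, config$group_sizes[groups3])
  } else {
    sample(groups3, n, replace = TRUE, prob = config$group_probs)
  }
  ovary <- sample(names(config$ovary_probs), n, replace = TRUE,
                  prob = config$ovary_probs)
  user_id <- sprintf("u%06d", seq_len(n))
  span <- as.integer(diff(config$surgery_date_range))
  surgery <- config$surgery_date_range[1] + sample.int(span + 1L, n, replace = TRUE) - 1L

  k <- if (config$posts_per_user$type == "fixed") {
    rep(as.integer(config$posts_per_user$k), n)
  } else {
    p0 <- stats::dnbinom(0, size = config$posts_per_user$size,
                         mu = config$posts_per_user$mu)
    stats::qnbinom(stats::runif(n, p0, 1), size = config$posts_per_user$size,
                   mu = config$posts_per_user$mu)
  }
  npost <- sum(k)
  post_user <- rep(seq_len(n), k)
  day <- sample(0:84, npost, replace = TRUE, prob = config$day_pmf)

  # per-user, per-symptom cessation times
  symptoms <- symptom_groups()
  cess <- matrix(0, nrow = n, ncol = 12, dimnames = list(NULL, symptoms))
  for (g in groups3) {
    idx <- which(group == g)
    if (length(idx) == 0L) next
    for (s in symptoms)
      cess[idx, s] <- draw_cessation(length(idx), config$cessation[[g]])
  }

  # mention matrix: post x symptom
  probs <- config$mention_probs[group[post_user], , drop = FALSE]
  mention <- matrix(FALSE, nrow = npost, ncol = 12,
                    dimnames = list(NULL, symptoms))
  for (j in seq_along(symptoms)) {
    s <- symptoms[j]
    mention[, j] <- (stats::runif(npost) < probs[, s]) &
      (day <= cess[post_user, s])
  }

  subjects <- render_subjects(mention, config)
  planted <- apply(mention, 1L, function(m) symptoms[m], simplify = FALSE)

  thread_id <- sprintf("t%07d", seq_len(npost))
  posted_at <- paste0(format(surgery[post_user] + day), "T12:00:00")

  posts <- data.table::data.table(
    user_id = user_id[post_user], thread_id = thread_id,
    is_thread_initial = TRUE, subject = subjects, posted_at = posted_at)
  profiles <- data.table::data.table(
    user_id = user_id,
    hysterectomy_type = type_code_for_group(group),
    surgery_date = format(surgery),
    ovary_status = ovary)
  truth <- data.table::data.table(
    user_id = user_id[post_user], thread_id = thread_id, day = day,
    mentioned = planted)

  out <- inject_violations(posts, profiles, config)

  posts_path <- file.path(dir, "posts.csv")
  profiles_path <- file.path(dir, "profiles.csv")
  data.table::fwrite(out$posts, posts_path)
  data.table::fwrite(out$profiles, profiles_path)
  list(posts_path = posts_path, profiles_path = profiles_path, truth = truth)
}

# representative declared type code per treatment group (round-robin over the
# codes of each group, deterministic)
type_code_for_group <- function(group) {
  codes <- list(abdominal = c("TAH", "SAH", "TAH/SAH"),
                vaginal = c("TVH", "LAVH"),
                laparoscopic = c("TLH", "LSH", "DVH"))
  out <- character(length(group))
  for (g in names(codes)) {
    idx <- which(group == g)
    out[idx] <- codes[[g]][(seq_along(idx) - 1L) %% length(codes[[g]]) + 1L]
  }
  out
}

# subject = 3-6 filler words plus one keyword per mentioned group
render_subjects <- function(mention, config) {
  npost <- nrow(mention)
  symptoms <- colnames(mention)
  nf <- sample(3:6, npost, replace = TRUE)
  fill <- sample(config$filler, sum(nf), replace = TRUE)
  stops <- cumsum(nf)
  starts <- stops - nf + 1L
  parts <- vector("list", npost)
  for (i in seq_len(npost)) parts[[i]] <- fill[starts[i]:stops[i]]
  for (j in seq_along(symptoms)) {
    idx <- which(mention[, j])
    if (length(idx) == 0L) next
    kws <- config$taxonomy[[symptoms[j]]]
    chosen <- if (config$template_mode == "single_keyword") {
      rep(kws[1], length(idx))
    } else {
      kws[sample.int(length(kws), length(idx), replace = TRUE)]
    }
    for (ii in seq_along(idx)) {
      parts[[idx[ii]]] <- c(parts[[idx[ii]]], chosen[ii])
    }
  }
  vapply(parts, paste, "", collapse = " ")
}

# append records that each violate exactly one ingest filter, so attrition
# counts are known exactly by construction
inject_violations <- function(posts, profiles, config) {
  v <- config$violations
  set.seed(config$seed + 1L)
  next_thread <- nrow(posts)
  mk_thread <- function(m) {
    ids <- sprintf("t%07d", next_thread + seq_len(m))
    next_thread <<- next_thread + m
    ids
  }
  pick_user_rows <- function(m) sample.int(nrow(profiles), m, replace = TRUE)

  if (v$n_reply > 0) {
    idx <- pick_user_rows(v$n_reply)
    extra <- data.table::data.table(
      user_id = profiles$user_id[idx], thread_id = mk_thread(v$n_reply),
      is_thread_initial = FALSE, subject = "re following up",
      posted_at = paste0(format(as.Date(profiles$surgery_date[idx]) + 10L), "T12:00:00"))
    posts <- rbind(posts, extra)
  }
  if (v$n_outside > 0) {
    idx <- pick_user_rows(v$n_outside)
    offs <- sample(c(-5L, 95L), v$n_outside, replace = TRUE)
    extra <- data.table::data.table(
      user_id = profiles$user_id[idx], thread_id = mk_thread(v$n_outside),
      is_thread_initial = TRUE, subject = "checking in again",
      posted_at = paste0(format(as.Date(profiles$surgery_date[idx]) + offs), "T12:00:00"))
    posts <- rbind(posts, extra)
  }
  if (v$n_missing_date_users > 0) {
    uid <- sprintf("v_nodate%05d", seq_len(v$n_missing_date_users))
    profiles <- rbind(profiles, data.table::data.table(
      user_id = uid, hysterectomy_type = "TAH", surgery_date = "",
      ovary_status = "unknown"))
    posts <- rbind(posts, data.table::data.table(
      user_id = uid, thread_id = mk_thread(v$n_missing_date_users),
      is_thread_initial = TRUE, subject = "hello from a new member",
      posted_at = "2015-06-01T12:00:00"))
  }
  if (v$n_sils_users > 0) {
    uid <- sprintf("v_sils%05d", seq_len(v$n_sils_users))
    profiles <- rbind(profiles, data.table::data.table(
      user_id = uid, hysterectomy_type = "SILS", surgery_date = "2015-05-01",
      ovary_status = "unknown"))
    posts <- rbind(posts, data.table::data.table(
      user_id = uid, thread_id = mk_thread(v$n_sils_users),
      is_thread_initial = TRUE, subject = "first week done",
      posted_at = "2015-05-08T12:00:00"))
  }
  list(posts = posts, profiles = profiles)
}

# --- recovery validation --------------------------------------------------

#' Validate parameter recovery of the analysis pipeline
#'
#' Runs the generator and the analysis end-to-end and compares estimates
#' against the generating parameters.
#'
#' `what = "mention"`: simulates one cohort under `config`, runs
#' ingest -> tag -> user aggregation -> mention-frequency report, and returns
#' each (group, symptom) estimated percentage-point difference next to the
#' planted per-post probability difference.
#'
#' `what = "cessation"`: over `n_seeds` replicate seeds, draws last-mention
#' days from the generator's cessation component (dense-posting limit, see
#' [draw_last_mention_days()]) for `n_per_group` users per group and returns
#' the mean interquartile difference and log-rank p per replicate.
#'
#' @param config a `sim_config`
#' @param what `"mention"` or `"cessation"`
#' @param group comparison group for `"cessation"` (default laparoscopic)
#' @param n_per_group users per group for `"cessation"` draws
#' @param n_seeds replicate count for `"cessation"`
#' @param taxonomy taxonomy used for tagging (defaults to the config's)
#' @return a `data.table` of recovery results
#' @export
validate_recovery <- function(config, what = c("mention", "cessation"),
                              group = "laparoscopic", n_per_group = 2000L,
                              n_seeds = 20L, taxonomy = NULL) {
  what <- match.arg(what)
  taxonomy <- taxonomy %||% config$taxonomy
  if (what == "mention") {
    sim <- simulate_cohort(config)
    posts <- read_posts(sim$posts_path)
    profiles <- read_profiles(sim$profiles_path)
    cohort <- build_cohort(posts, profiles)
    tagged <- tag_cohort(cohort, taxonomy)
    prof <- aggregate_user_mentions(tagged)
    mrep <- mention_frequency_report(prof, denominator = "all")
    planted <- vapply(seq_len(nrow(mrep)), function(i) {
      100 * (config$mention_probs[mrep$group[i], mrep$symptom[i]] -
               config$mention_probs["abdominal", mrep$symptom[i]])
    }, numeric(1))
    mrep[, planted_pct_diff := planted]
    mrep[, bias := pct_diff - planted_pct_diff]
    return(mrep[])
  }
  rows <- lapply(seq_len(n_seeds), function(i) {
    set.seed(config$seed + i)
    t_ref <- draw_last_mention_days(config, "abdominal", n_per_group)
    t_cmp <- draw_last_mention_days(config, group, n_per_group)
    diff <- mean_interquartile_difference(km_estimate(t_cmp), km_estimate(t_ref))
    lr <- log_rank(t_cmp, t_ref)
    data.table::data.table(seed = config$seed + i, mean_iq_diff = diff,
                           logrank_p = lr$p)
  })
  data.table::rbindlist(rows)
}
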