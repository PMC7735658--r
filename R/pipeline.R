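# End-to-end orchestration: ingest -> tag -> mention stats, survival, term
# frequency, temporal summaries. One entry point for programmatic use
# (run_pipeline) and a small subcommand CLI (listen_main) wired to an
# installed Rscript wrapper in inst/cli/.

#' Build a run configuration
#'
#' @param posts path to the post file
#' @param profiles path to the profile file
#' @param taxonomy path to a taxonomy JSON, or `NULL` for the shipped default
#' @param out_dir output directory for the report bundle
#' @param window inclusive day window, default `c(0, 84)`
#' @param min_count pooled-count floor for term-frequency rankings
#' @param alpha_tiers strictly decreasing significance tiers
#' @param seed seed for any resampling options
#' @return validated `run_config` list
#' @export
run_config <- function(posts, profiles, taxonomy = NULL, out_dir = "listen_out",
                       window = c(0L, 84L), min_count = 5L,
                       alpha_tiers = c(0.05, 0.01, 0.001), seed = 1L) {
  if (!file.exists(posts)) abort("config error: post file not found: %s", posts)
  if (!file.exists(profiles)) abort("config error: profile file not found: %s", profiles)
  if (!is.null(taxonomy) && !file.exists(taxonomy))
    abort("config error: taxonomy file not found: %s", taxonomy)
  stopifnot(length(window) == 2L, window[1] >= 0L, window[1] <= window[2])
  stopifnot(all(diff(alpha_tiers) < 0))
  structure(list(posts = posts, profiles = profiles, taxonomy = taxonomy,
                 out_dir = out_dir, window = as.integer(window),
                 min_count = as.integer(min_count),
                 alpha_tiers = alpha_tiers, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full listening pipeline
#'
#' Ingests, tags, and writes the report bundle: `summary.json` (cohort
#' descriptives), `mention_frequency.csv` (per-symptom group comparisons),
#' `survival.csv` and `survival_curves.csv` (time-to-last-mention),
#' `termfreq_n{1,2,3}.csv` (log-likelihood rankings, each comparison group
#' vs the abdominal base corpus), `volume_day.csv` / `volume_week.csv`,
#' `attrition.json`, and a `manifest.json` with input digests, package
#' version and the config. Rerunning with the same inputs and config yields
#' identical CSV contents.
#'
#' @param config a `run_config`
#' @return invisibly, a named list of all output paths
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    message(sprintf("[listen] stage: %s", name))
    tryCatch(expr, error = function(e)
      abort("pipeline failed at stage '%s': %s", name, conditionMessage(e)))
  }
  taxonomy <- stage("taxonomy",
    if (is.null(config$taxonomy)) default_taxonomy() else load_taxonomy(config$taxonomy))
  posts <- stage("read_posts", read_posts(config$posts))
  profiles <- stage("read_profiles", read_profiles(config$profiles))
  cohort <- stage("build_cohort", build_cohort(posts, profiles, config$window))
  tagged <- stage("tag", tag_cohort(cohort, taxonomy))

  paths <- list()
  w <- function(name, obj) {
    p <- file.path(config$out_dir, name)
    if (grepl("\\.json$", name)) {
      jsonlite::write_json(obj, p, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    } else {
      data.table::fwrite(obj, p)
    }
    paths[[name]] <<- p
  }

  stage("summary", w("summary.json", unclass(cohort_summary(tagged))))
  w("attrition.json", as.list(attr(cohort, "attrition")))

  prof <- stage("mentions", aggregate_user_mentions(tagged))
  have_groups <- unique(prof$treatment_group)
  if (all(c("abdominal", "vaginal", "laparoscopic") %in% have_groups)) {
    w("mention_frequency.csv", mention_frequency_report(prof))
    rec <- stage("survival", last_mentions(tagged))
    w("survival.csv", survival_report(rec))
    w("survival_curves.csv", survival_curves_table(rec))
    base <- tagged[treatment_group == "abdominal"]
    for (n in 1:3) {
      tf <- data.table::rbindlist(lapply(c("vaginal", "laparoscopic"), function(g) {
        cmp <- compare_corpora(base, tagged[treatment_group == g], n = n,
                               min_count = config$min_count)
        cmp[, group := g]
        cmp
      }))
      w(sprintf("termfreq_n%d.csv", n), tf)
    }
  } else {
    message("[listen] skipping group comparisons: not all three groups present")
  }
  w("volume_day.csv", post_volume_histogram(tagged, "day"))
  w("volume_week.csv", post_volume_histogram(tagged, "week"))

  manifest <- list(
    package = "forumlisten",
    version = as.character(utils::packageVersion("forumlisten")),
    timestamp = format(Sys.time(), tz = "UTC"),
    inputs = list(posts = unname(tools::md5sum(config$posts)),
                  profiles = unname(tools::md5sum(config$profiles))),
    config = config[c("window", "min_count", "alpha_tiers", "seed")],
    outputs = names(paths))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  paths[["manifest.json"]] <- file.path(config$out_dir, "manifest.json")
  invisible(paths)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `ingest`, `run`. Invoked by the installed
#' wrapper script (`system.file("cli", "listen", package = "forumlisten")`),
#' or directly with a character vector of arguments.
#'
#' @param args character vector of command-line arguments
#' @return exit status (0 on success), invisibly
#' @export
listen_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: listen <command> [options]",
    "  simulate --out-dir DIR [--seed N] [--n-users N]",
    "  ingest   --posts FILE --profiles FILE --out FILE",
    "  run      --posts FILE --profiles FILE --out-dir DIR [--taxonomy FILE]",
    sep = "\n")
  if (length(args) == 0L) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opt <- parse_kv_args(args[-1])
  status <- tryCatch({
    switch(cmd,
      simulate = {
        cfg <- sim_config(seed = as.integer(opt[["seed"]] %||% 1),
                          n_users = as.integer(opt[["n-users"]] %||% 1000))
        res <- simulate_cohort(cfg, dir = opt[["out-dir"]] %||% "simforum")
        message("wrote ", res$posts_path, " and ", res$profiles_path)
        0L
      },
      ingest = {
        cohort <- build_cohort(read_posts(opt[["posts"]]),
                               read_profiles(opt[["profiles"]]))
        data.table::fwrite(cohort, opt[["out"]])
        message("wrote ", opt[["out"]], " (", nrow(cohort), " posts); attrition: ",
                paste(names(attr(cohort, "attrition")),
                      attr(cohort, "attrition"), sep = "=", collapse = ", "))
        0L
      },
      run = {
        cfg <- run_config(posts = opt[["posts"]], profiles = opt[["profiles"]],
                          taxonomy = opt[["taxonomy"]],
                          out_dir = opt[["out-dir"]] %||% "listen_out")
        run_pipeline(cfg)
        0L
      },
      { message("unknown command: ", cmd, "\n", usage); 1L })
  }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}

parse_kv_args <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- substring(a, 3)
      if (i + 1L <= length(args) && !startsWith(args[i + 1L], "--")) {
        out[[key]] <- args[i + 1L]; i <- i + 2L
      } else {
        out[[key]] <- TRUE; i <- i + 1L
      }
    } else i <- i + 1L
  }
  out
}
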