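Package: forumlisten
Title: Symptom-Mention Mining of Patient Forum Post Subjects
Version: 0.1.0
Authors@R:
    person("Forum", "Listen Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for "listening" to patient-experience forums through the
    subject headers of thread-initiating posts. Ingests post and profile
    records for a surgical-recovery cohort, maps self-declared hysterectomy
    type codes to abdominal/vaginal/laparoscopic treatment groups, tags
    subjects against a 12-group symptom keyword taxonomy, compares corpora
    with the Dunning log-likelihood statistic over n-grams, tests per-user
    symptom mention proportions between treatment groups with chi-square
    homogeneity tests, and analyses time-to-last-mention with Kaplan-Meier
    curves, log-rank tests, and mean interquartile differences. Includes a
    seeded synthetic-forum generator so the whole pipeline is testable
    without access to any real forum data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    survival,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
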