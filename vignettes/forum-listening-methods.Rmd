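---
title: "Methods: mining symptom mentions from forum subject headers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining symptom mentions from forum subject headers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forumlisten)
```

## The problem and the data model

`forumlisten` analyses a hysterectomy-recovery forum through the narrowest
possible lens: the subject header of each thread-initiating post, plus each
user's self-declared structured profile (hysterectomy type code, surgery
date, ovary status). Post bodies and replies are deliberately out of scope —
the unit of observation is "a user chose to start a conversation with this
title on this day". This keeps the text pipeline simple and the privacy
surface minimal, at the cost that a "mention" is evidence of engagement with
a topic, not a verified patient complaint.

The analysis cohort keeps a post when (in this order) it is thread-initial;
its user declared both a type and a date; the type code maps to one of three
treatment groups (abdominal: TAH/SAH/TAH-SAH; vaginal: TVH/LAVH;
laparoscopic: TLH/LSH/DVH — single-incision codes are excluded as too rare
to analyse); and it was posted 0–84 days after surgery. Attrition is logged
per rule. Two conventions are worth stating because the underlying
literature leaves them open:

* **Day window.** Surgery day is day 0 and the window is the closed interval
  [0, 84]: "12 weeks" is read as 12 × 7 days, inclusive at both ends.
  "First 3 weeks" likewise means days 0–20.
* **Week index.** `week_postop = floor(days/7) + 1`, so figures start at
  week 1 and day 84 alone forms a one-day week-13 bin; week-axis reports
  merge it into week 12 (the `merge_week13` flag documents this at the call
  site).

Ovary status is carried through but never filters anything. Duplicate
profiles keep the first record with a warning.

## Tagging: taxonomy, tokenizer, and what a tag means

The taxonomy maps 12 symptom groups — pain, sleep and fatigue, hormones and
emotions, digestion, swelling, bleeding, urination, intimacy, odd
sensations, drugs, fever and infection, family — to sets of keywords, each
keyword one or more lowercase tokens. The tokenizer lowercases and splits on
any non-alphanumeric run, keeping digits; this is the simplest rule that
still matches slang ("swellybelly") and misspellings ("achey",
"vomitting"). There is deliberately **no stemming**: morphology is handled
by enumerating variants as keywords, prioritising specificity per keyword
and recovering sensitivity through keyword count.

A post is tagged with a group iff one of its keywords occurs as a
*contiguous whole-token* subsequence of the subject's tokens — "painting"
never tags pain. Keywords are constrained to belong to exactly one group so
that mention counts are well-defined. The shipped `default_taxonomy()`
(~15–25 keywords per group) is a configuration artifact, not ground truth:
it was curated from clinically standard vocabulary plus community slang, and
every real analysis should review it with `keyword_in_context()` and supply
its own file. "catheter" is deliberately absent: it appears in forum text in
ways frequently unassociated with a urinary symptom, so including it would
trade too much specificity for sensitivity.

## Term-frequency comparison

Corpus contrasts use the Dunning log-likelihood statistic on n-grams
(n = 1, 2, 3; windows never span subjects). For counts `a`, `b` in the
comparison and base corpora of sizes `c`, `d` (total n-gram tokens for that
n — not post counts, matching the statistic's standard definition):

LL = 2[a·ln(a/E1) + b·ln(b/E2)], E1 = c(a+b)/(c+d), E2 = d(a+b)/(c+d),

with zero counts contributing 0 (the x·ln x → 0 limit; no pseudo-counts).
LL is referred to χ²(1), so 3.84 and 10.83 are the .05 and .001 critical
values. Terms below a pooled count of `min_count` (default 5) are dropped as
noise; rankings are per n, ties broken lexicographically so output is
deterministic. No multiple-testing correction is applied across terms — the
rankings are a prioritisation device for manual review, not a family of
confirmatory tests.

## Mention-frequency comparison

Users are aggregated to indicator sets (symptom mentioned at least once in
the window). For each symptom and each minimally invasive group, a 2×2 user
table against the abdominal group is tested with Pearson's χ² for
homogeneity, 1 df, **no continuity correction** (at forum scale the
correction is negligible; at test scale we want exact agreement with the
Σ(O−E)²/E formula the tests oracle). The effect size is the
percentage-point difference, **positive = comparison group mentions more**;
this sign convention is stated explicitly because annotation schemes pairing
signed values with "which group mentions more" footnotes are easy to make
internally inconsistent. The default denominator is users who mention at
least one taxonomy symptom (the analysed user universe); `denominator =
"all"` switches to all cohort users. Raw tiered p-values (.05/.01/.001) are
reported; a Holm option exists but is off by default to match the tiered
reporting convention. Degenerate tables (a zero margin) yield markers, not
errors.

## Time-to-last-mention survival analysis

For each (user, symptom) with at least one tagged post, the event time is
the **latest** `days_postop` among those posts. The central interpretive
assumption, stated prominently: **there is no censoring**. Every last
mention inside the fixed 84-day window is treated as an observed event.
Treating window-end as censoring would require knowing that the user kept
posting about the symptom afterwards, which subject-only data cannot show;
consequently a curve here describes cessation of *mentions*, not cessation
of symptoms, and is compressed toward the window.

With no censoring the product-limit estimate equals the empirical survivor
function S(t) = #(T > t)/n and reaches 0, so every quantile exists. The
q-quantile is the smallest event time with S(t) ≤ 1 − q (the standard
Kaplan–Meier convention, deterministic under ties). Group contrasts use the
two-sample log-rank test with the hypergeometric tied-event variance, and
the headline effect is the **mean interquartile difference**: the mean of
the three quartile-time differences (25/50/75%), in days, negative when the
comparison group ceases earlier. This operationalisation is the most literal
reading of "mean interquartile difference" and is validated by simulation
(planted shifts are recovered), not against any external table; output
metadata flags it as a package convention. Cells with fewer than 2 records
in either arm get an insufficient-data marker.

## The synthetic forum: what it emulates and what it does not

`sim_config()` assembles the generative stand-in used by every end-to-end
test. Its defaults are the stated world, chosen once:

* **Group split** 40/32/28% abdominal/vaginal/laparoscopic; ovary status
  56/37/7% kept/both-removed/unknown.
* **Posts per user**: zero-truncated negative binomial targeting mean 2.42.
  The companion dispersion target (sd 3.10) is *jointly unattainable* with
  that mean inside the ZTNB family (the dispersion ceiling at mean 2.42 is
  sd ≈ 2.39, the log-series limit); the fit matches the mean exactly, takes
  the closest attainable sd, and records the shortfall in
  `config$posts_per_user$sd_shortfall` rather than silently switching
  families.
* **Posting times**: a gamma law truncated to [0, 85) and floored to whole
  days, with shape/scale fitted at config-build time to hit a median of day
  19 and mean of day 23.8 (achieved values and fit tolerance are stored in
  the config).
* **Mentions**: each post mentions symptom s with a per-post probability;
  abdominal baselines are calibrated so ~42.4% of posts mention ≥ 1 group,
  with per-symptom shares declining from pain (~31% of mentions) and
  bleeding (~19%) through family (~1.5%) — the share profile beyond the two
  largest groups is a realism choice, not a measured quantity. Comparison
  groups get additive per-post offsets of a few percentage points, the
  magnitude and sign pattern of user-level contrasts this kind of cohort
  exhibits (e.g. vaginal urination +2.3 points, both groups' swelling
  ≈ −3 points). Applying
  user-level contrast magnitudes as per-post offsets is an approximation;
  recovery tests that need an exact planted user-level difference therefore
  fix one post per user, which makes the two scales coincide.
* **Cessation**: per (user, symptom) a group-specific exponential cessation
  time (means 40/37/35 days for abdominal/vaginal/laparoscopic), after which
  that symptom is never mentioned by that user. This is the simplest hazard
  model that induces the earlier-cessation pattern in the minimally invasive
  groups that the survival module must detect. `draw_last_mention_days()`
  exposes the implied event times in the dense-posting limit (daily posts,
  mention probability 1), which is how quartile-shift recovery is validated
  at 20 replicate seeds without rendering millions of subject strings.
* **Subjects** are bags of tokens: 3–6 filler words from a vocabulary
  verified disjoint from all taxonomy tokens, plus one keyword per mentioned
  group (`template_mode = "single_keyword"` pins each group to its first,
  single-token keyword, enabling exact round-trip checks).

The generator deliberately does **not** emulate grammatical text, thread
replies, topic drift, seasonal effects, correlated symptoms within a user
beyond the shared posting process, or user-level heterogeneity in mention
propensity. A green end-to-end test therefore establishes that the pipeline
recovers parameters from data with the assumed independence structure — not
that the taxonomy is complete, nor that a real forum satisfies these
assumptions.

Violations (`violations =`) append extra records that each trip exactly one
ingest filter (replies, missing dates, SILS users, out-of-window posts), so
attrition counts can be asserted exactly.

## Numerical and display conventions

* Displayed percentages: half-up rounding to 2 decimals, computed by one
  function (`pct()`) from stored integer counts, so every printed
  percentage is reproducible from the counts next to it. Day differences
  display at 1 decimal.
* χ² implementation is `stats::chisq.test(correct = FALSE)`; Kaplan–Meier
  and log-rank use the `survival` package. The test suite checks all three
  against independent literal-formula oracles (Σ(O−E)²/E, #(T > t)/n, the
  observed-minus-expected/variance log-rank sum) so a regression in either
  the wiring or the dependency is caught.
* The log-likelihood clamps the tiny negative floating-point residue that
  the two-term formula can produce at exact frequency equality.
* Determinism: a config's seed fixes the generator byte-for-byte; pipeline
  reruns on identical inputs produce identical CSVs; term rankings break
  ties lexicographically.

## Known limitations

Mentions are not complaints; absence of a mention is not absence of a
symptom; the no-censoring assumption compresses survival curves toward day
84; the default taxonomy is a starting point, not an instrument; per-post
mention offsets only approximate user-level contrasts when users post more
than once; and roughly half of real forum subjects fall outside any symptom
taxonomy (progress updates, chatter), which the filler vocabulary mimics
only crudely.
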