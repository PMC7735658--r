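# data.table is used via :: so we must declare awareness for [] dispatch
.datatable.aware <- TRUE

utils::globalVariables(c(
  ".", "..density..", "user_id", "thread_id", "is_thread_initial", "subject",
  "posted_at", "hysterectomy_type", "surgery_date", "ovary_status",
  "treatment_group", "week_postop", "mentioned", "n_symptoms", "n_mentioned",
  "symptom", "last_day", "day", "week", "total_mentions", "p", "pct_diff",
  "pct_diff_display", "mean_iq_diff", "mean_iq_diff_display", "group",
  "planted_pct_diff", "bias", "N"))
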