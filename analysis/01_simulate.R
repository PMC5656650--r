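#!/usr/bin/env Rscript
# Simulate the study cohort.
#
# Generates the "recovery-A" synthetic haemodialysis cohort: ~2000 patients
# followed over 36 monthly visits with treatment-confounder feedback
# (urate-lowering treatment lowers uric acid; persistently low uric acid and
# albumin predict both future prescription and death). Writes the
# long-format person-visit panel and a small table of cohort marginals.

library(dialmsm)

dir.create("results", showWarnings = FALSE)
cfg <- dgp_fixture("recovery-A", seed = 20260922)
panel <- generate_cohort(cfg)
print(panel)

b <- panel$baseline
v <- panel$visits
q <- assign_ua_quintiles(panel)
marginals <- data.frame(
  quantity = c("patients", "person_visits", "baseline_treatment_pct",
               "followup_mortality_pct", "dropout_pct",
               "treatment_prevalence_month36_pct",
               paste0("baseline_treatment_pct_q", 1:5)),
  value = round(c(
    nrow(b), nrow(v), 100 * mean(b$baseline_treatment),
    100 * sum(v$event_death) / nrow(b), 100 * sum(v$censored) / nrow(b),
    100 * mean(v$treatment[v$visit == cfg$n_visits]),
    100 * tapply(b$baseline_treatment, q[as.character(b$patient_id)], mean)
  ), 2)
)
print(marginals, row.names = FALSE)

write_panel(panel, "results/cohort.csv")
write.csv(marginals, "results/cohort_marginals.csv", row.names = FALSE)
message("cohort written to results/cohort.csv")
message("note the prescription gradient: treatment is most common in the ",
        "lowest uric-acid quintile, echoing real prescribing behaviour.")
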