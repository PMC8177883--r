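#!/usr/bin/env Rscript
# Behavioural measures and exclusions.
#
# Applies the engagement exclusions (1-30 s mean check response times,
# both catch questions correct), computes per-block ITI click rates,
# preference ratios and points, the punishment-phase suppression ratios
# and shield-use percentages, collapses the two pre-punishment blocks,
# and tests the cohort's ratios against the 0.5 indifference point.

suppressPackageStartupMessages(library(pirateplanets))

cohort <- "results/cohort"
dir.create("results", showWarnings = FALSE)

events <- read_event_log(file.path(cohort, "events.csv"))
sr <- read.csv(file.path(cohort, "self_reports.csv"))
quest <- read.csv(file.path(cohort, "questionnaires.csv"))

excl <- apply_exclusions(sr, quest)
cat(length(excl$retained), "retained,", nrow(excl$excluded), "excluded\n")
events <- events[events$participant_id %in% excl$retained, ]

summary_raw <- participant_summary(events)
summary <- collapse_pre(summary_raw)
write.csv(summary, "results/participant_summary.csv", row.names = FALSE)

pav <- unique(summary_raw[summary_raw$phase == "punish",
                          c("participant_id", "suppression_csplus",
                            "suppression_csminus", "shield_use_csplus",
                            "shield_use_csminus")])
write.csv(pav, "results/pavlovian_summary.csv", row.names = FALSE)

cat("\nOne-sample t-tests of preference ratios against 0.5:\n")
for (b in sort(unique(summary$block))) {
  r <- one_sample_ratio_test(summary$preference_ratio[summary$block == b])
  cat(sprintf("  block %s: mean %.3f, t(%d) = %.2f, p = %.3g\n",
              if (b == 0) "Pre" else b, r$mean, r$df, r$t, r$p))
}
cat("\nSuppression ratios against 0.5 (no suppression):\n")
for (m in c("suppression_csplus", "suppression_csminus")) {
  r <- one_sample_ratio_test(pav[[m]])
  cat(sprintf("  %s: mean %.3f, t(%d) = %.2f, p = %.3g\n",
              m, r$mean, r$df, r$t, r$p))
}
cat(sprintf("\nShield use: CS+ %.1f%%, CS- %.1f%% (means)\n",
            mean(pav$shield_use_csplus, na.rm = TRUE),
            mean(pav$shield_use_csminus, na.rm = TRUE)))
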