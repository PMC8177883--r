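#!/usr/bin/env Rscript
# Cohort-level statistics linking behaviour to inferences.
#
# Stepwise linear regression of punishment-phase preference ratios on the
# self-report bias ratios (Response->Attack and Response->Reward), a
# stepwise logistic regression predicting cluster membership from the same
# ratios (with Nagelkerke r2 and classification accuracy), and a
# varimax-rotated PCA of the instrumental items under the 50% communality
# retention rule.

suppressPackageStartupMessages(library(pirateplanets))

summary <- read.csv("results/participant_summary.csv")
sr <- read.csv("results/cohort/self_reports.csv")
clusters <- read.csv("results/clusters.csv")
sr <- sr[sr$participant_id %in% clusters$participant_id, ]

ratios <- self_report_ratios(sr)
pun <- summary[summary$phase == "punish", ]
pref <- aggregate(preference_ratio ~ participant_id, pun, mean)
dat <- merge(merge(pref, ratios, by = "participant_id"),
             clusters[, c("participant_id", "cluster_label")],
             by = "participant_id")
dat <- dat[complete.cases(dat[, c("preference_ratio", "attack_ratio",
                                  "reward_ratio")]), ]

cat("Stepwise linear: preference ratio ~ inference bias ratios\n")
sw <- stepwise_linear(dat$preference_ratio,
                      dat[, c("attack_ratio", "reward_ratio")])
print(as.data.frame(sw$steps), digits = 3)
write.csv(sw$steps, "results/stepwise_linear.csv", row.names = FALSE)

cat("\nStepwise logistic: cluster membership ~ inference bias ratios\n")
swl <- stepwise_logistic(dat$cluster_label == "sensitive",
                         dat[, c("attack_ratio", "reward_ratio")])
print(as.data.frame(swl$steps), digits = 3)
cat(sprintf("accuracy %.1f%%, Nagelkerke r2 = %.3f\n",
            100 * swl$accuracy, swl$nagelkerke_r2))
write.csv(swl$steps, "results/stepwise_logistic.csv", row.names = FALSE)

cat("\nVarimax PCA of instrumental items (50% communality rule)\n")
items <- merge(aggregate(cbind(overall_iti_rate, preference_ratio) ~
                           participant_id, pun, mean),
               ratios, by = "participant_id")
pca <- pca_varimax(items[, c("overall_iti_rate", "preference_ratio",
                             "attack_ratio", "reward_ratio")])
cat("components retained:", pca$n_components, "\n")
print(round(pca$loadings, 2))
load_df <- as.data.frame(pca$loadings)
load_df$item <- rownames(pca$loadings)
load_df$communality <- pca$communalities
write.csv(load_df, "results/pca_loadings.csv", row.names = FALSE)
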