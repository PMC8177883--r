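#!/usr/bin/env Rscript
# Punishment-sensitivity phenotypes.
#
# k-means clustering of final-block preference ratios with silhouette
# model selection over k = 2..4, then a check of how well the recovered
# clusters match the generative archetypes recorded in the manifest.

suppressPackageStartupMessages(library(pirateplanets))

summary <- read.csv("results/participant_summary.csv")
fin <- summary[summary$block == max(summary$block) &
                 !is.na(summary$preference_ratio), ]

cl <- cluster_sensitivity(fin$preference_ratio, seed = 1,
                          ids = fin$participant_id)
print(cl)
cat("Mean silhouette by k:",
    paste(names(cl$mean_silhouette),
          sprintf("%.3f", cl$mean_silhouette), collapse = ", "), "\n")
write.csv(cl$assignment, "results/clusters.csv", row.names = FALSE)

man <- jsonlite::read_json("results/cohort/manifest.json")
truth <- vapply(man$agents, function(a) a$archetype, character(1))
names(truth) <- vapply(man$agents, function(a) a$participant_id,
                       character(1))
common <- intersect(names(truth), names(cl$labels))
agree <- mean(cl$labels[common] == truth[common])
cat(sprintf("Archetype recovery: %.1f%% of %d participants\n",
            100 * agree, length(common)))

# development of the cluster difference across punishment blocks
pun <- summary[summary$phase == "punish", ]
wide <- reshape(pun[, c("participant_id", "block", "preference_ratio")],
                idvar = "participant_id", timevar = "block",
                direction = "wide")
cells <- as.matrix(wide[, -1])
groups <- unname(cl$labels[wide$participant_id])
nb <- ncol(cells)
a <- contrast_anova(cells,
                    contrast_spec(block_linear = seq_len(nb) -
                                    mean(seq_len(nb))),
                    groups = groups)
cat("\nBlock-linear contrast on punishment-phase preference ratios:\n")
print(as.data.frame(a))
write.csv(a, "results/cluster_block_anova.csv", row.names = FALSE)
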