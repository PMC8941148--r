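#!/usr/bin/env Rscript
# Stage 5: community composition vs environment.  Rare-ASV filtering,
# variance-stabilizing transform, Bray-Curtis dissimilarity, DistLM
# marginal/sequential tests and the dbRDA ordination.
suppressPackageStartupMessages(library(aapflux))

seed <- 1
study <- read_study("results/study")
filtered <- rare_filter(study$count_table)
cat(sprintf("Rare-ASV filter: %d of %d ASVs retained\n",
            ncol(filtered), ncol(study$count_table)))
trans <- vst_transform(filtered)
d <- suppressWarnings(bray_curtis(trans))
res <- distlm(d, study$community_covariates, n_perms = 999, seed = seed)
print(res)
write_table_csv(res$marginal, "results/tables/distlm_marginal.csv",
                c(stage = "community", seed = seed))
write_table_csv(res$selection, "results/tables/distlm_selection.csv",
                c(stage = "community", seed = seed))
ord <- dbrda(d, study$community_covariates[, res$selected, drop = FALSE])
print(ord)
scores <- data.frame(sample = rownames(ord$scores), ord$scores[, 1:2])
write_table_csv(scores, "results/tables/dbrda_scores.csv",
                c(stage = "community", seed = seed))
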