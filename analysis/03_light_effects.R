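#!/usr/bin/env Rscript
# Stage 3: random-intercept mixed models (ML) for the infrared-light
# effect on every analyte, with likelihood-ratio ANOVA significance and
# percent differences relative to the dark reference, plus
# light-by-covariate interaction fits.
suppressPackageStartupMessages(library(aapflux))

rates <- read_table_csv("results/tables/rates.csv")
eff <- light_effect_summaries(rates)
write_table_csv(eff$summary, "results/tables/light_effects.csv",
                c(stage = "light_effects"))
cat("Percent differences (vs dark reference):\n")
print(eff$summary, digits = 3)

# interaction of the light treatment with bacteriochlorophyll-a
study <- read_study("results/study")
resp <- rates[rates$analyte == "respiration" &
                rates$treatment %in% c("dark", "IR"), ]
resp$treatment <- factor(resp$treatment, levels = c("dark", "IR"))
i <- match(as.character(resp$date), as.character(study$covariate_table$date))
resp$bchla <- study$covariate_table$bchla_ug_l[i]
print(interaction_fit(resp, "bchla"))
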