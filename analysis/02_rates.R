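#!/usr/bin/env Rscript
# Stage 2: titration chemistry to rates.  Winkler records -> per-bottle O2
# -> respiration/NPP rates; Gran titrations -> alkalinity -> DIC;
# scintillation records -> tracer assimilation rates.
suppressPackageStartupMessages(library(aapflux))

study <- read_study("results/study")
o2 <- winkler_o2_table(study$titration_table, study$standardization_table)
rates_o2 <- bottle_rates(o2, hours = 24)
dics <- dic_table(study$gran_table, study$station_table)
rates_trc <- tracer_rates(study$scintillation_table, dics)
rates <- rbind(rates_o2[, c("analyte", "date", "treatment", "replicate",
                            "value", "incubation_hours")],
               rates_trc[, c("analyte", "date", "treatment", "replicate",
                             "value", "incubation_hours")])
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
prov <- c(stage = "rates", input = "results/study")
write_table_csv(o2, "results/tables/o2_concentrations.csv", prov)
write_table_csv(dics, "results/tables/dic.csv", prov)
write_table_csv(rates, "results/tables/rates.csv", prov)

cat(sprintf("Mean dark respiration: %.3f umol O2/L/h across %d dates\n",
            mean(rates$value[rates$analyte == "respiration" &
                             rates$treatment == "dark"]),
            length(unique(rates$date))))
cat(sprintf("Gran alkalinity fits: min R^2 = %.5f; DIC range %.2f-%.2f mmol/L\n",
            min(dics$gran_r_squared), 1e3 * min(dics$dic_mol_l),
            1e3 * max(dics$dic_mol_l)))
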