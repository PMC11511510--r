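#!/usr/bin/env Rscript
# Stage 4: Pearson correlations between traits on accession means, split
# by year, with Fisher-z 95% confidence intervals.

library(metsel)

trial <- read_trial("results/data/trial_long.csv")
years <- levels(trial$year)

for (y in years) {
  pc <- pearson_ci(trial, year = y)
  pc[, c("r", "lower", "upper")] <- round(pc[, c("r", "lower", "upper")], 3)
  write.csv(pc, sprintf("results/04_correlations_%s.csv", y),
            row.names = FALSE)
  pick <- function(a, b) pc$r[(pc$trait1 == a & pc$trait2 == b) |
                                (pc$trait1 == b & pc$trait2 == a)]
  message(sprintf("%s: r(dtf, dtm) = %.2f, r(dtf, plant_height) = %.2f, ",
                  y, pick("dtf", "dtm"), pick("dtf", "plant_height")),
          sprintf("r(seed_yield, mildew) = %.2f, r(seed_yield, tkw) = %.2f",
                  pick("seed_yield", "mildew"), pick("seed_yield", "tkw")))
}
message("tables written: results/04_correlations_<year>.csv")
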