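#!/usr/bin/env Rscript
# Stage 5: heritability-weighted selection index over the six key traits
# (TKW, seed yield, DTF, plant height, mildew susceptibility, saponin),
# per-year ranking, and year-stability tests of the index refitted as an
# additional trait.

library(metsel)

trial <- read_trial("results/data/trial_long.csv")
h2_tab <- read.csv("results/03_heritability.csv")
tr <- quinoa_index_traits()
specs <- quinoa_trait_specs()
w <- setNames(h2_tab$h2, h2_tab$trait)[tr]

fits <- list(); dms <- list()
means <- do.call(rbind, lapply(tr, function(tn) {
  dm <- build_design(trial, tn, "fixed_gxe", "hetero_corr")
  ft <- reml_fit(dm)
  dms[[tn]] <<- dm; fits[[tn]] <<- ft
  adjusted_cell_means(ft, dm)
}))

std <- standardize_orient(means, specs)
idx <- selection_index(std, w, tr)
idx_out <- reshape(data.frame(accession = as.character(idx$accession),
                              year = as.character(idx$year),
                              index = round(idx$index, 2), rank = idx$rank),
                   idvar = "accession", timevar = "year", direction = "wide")
write.csv(idx_out, "results/05_selection_index.csv", row.names = FALSE)

pli <- plot_level_index(trial, means, specs, w, tr)
dm_i <- build_design(pli, "selection_index", "fixed_gxe", "hetero_corr")
ft_i <- reml_fit(dm_i)
yc <- year_contrasts(ft_i, dm_i, mc_draws = 1e5, seed = 2024)
stab <- index_stability(idx, yc)
stab_out <- data.frame(accession = stab$accession,
                       index_diff = round(abs(stab$index_diff), 2),
                       p_adj = round(stab$p_adj, 3), stable = stab$stable)
write.csv(stab_out, "results/05_stability.csv", row.names = FALSE)

best <- idx[idx$rank == 1, ]
message("index weights (h2): ",
        paste(sprintf("%s=%.2f", names(w), w), collapse = ", "))
for (i in seq_len(nrow(best))) {
  message(sprintf("top-ranked accession in %s: %s (I = %.2f)",
                  best$year[i], best$accession[i], best$index[i]))
}
message(sprintf("%d of %d accessions have a stable index across years",
                sum(stab$stable), nrow(stab)))
message("tables written: results/05_selection_index.csv, results/05_stability.csv")
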