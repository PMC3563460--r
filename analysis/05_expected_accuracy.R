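#!/usr/bin/env Rscript
# Step 5 — expected accuracy of ridge SNP-BLUP from population parameters
# versus the realized cross-validation accuracy.  Ne comes from the decay
# of r2 with map distance (Sved relation, sample-size corrected); the two
# approximations of the number of independent chromosome segments bracket
# the prediction.

library(gsbench)
stopifnot(file.exists("results/evaluation_by_replicate.csv"))

pop <- simulate_population(demo_config())
geno <- qc_filter(pop$genotypes)
vc <- read_table_csv("results/variance_components.csv")
rep_tab <- read_table_csv("results/evaluation_by_replicate.csv")

ne <- estimate_ne_from_ld(geno, seed = 1)
cat(sprintf("Ne from LD decay: %.0f (%s)\n", ne$Ne,
            if (ne$informative) "informative" else "UNINFORMATIVE"))
L <- demo_config()$genome_length_morgans

rows <- list()
for (tr in unique(rep_tab$trait)) {
  # pseudo-heritability: phenotypes were cage-adjusted before training
  h2_tr <- with(vc[vc$trait == tr, ], sigma2_u / (sigma2_u + sigma2_e))
  for (strat in unique(rep_tab$strategy)) {
    sub <- rep_tab[rep_tab$trait == tr & rep_tab$strategy == strat &
                     rep_tab$method == "rr_gblup", ]
    realized <- mean(sub$accuracy, na.rm = TRUE)
    N <- round(0.55 * sum(!is.na(pop$phenotypes[[tr]])))
    e1 <- expected_accuracy(N, h2_tr, ne$Ne, L, "Me1")$accuracy
    e2 <- expected_accuracy(N, h2_tr, ne$Ne, L, "Me2")$accuracy
    rows[[paste(tr, strat)]] <- data.frame(
      trait = tr, strategy = strat, N = N, h2 = h2_tr, Ne = ne$Ne, L = L,
      expected_me1 = e1, expected_me2 = e2, realized = realized,
      within_bracket = !is.na(realized) &
        realized >= min(e1, e2) - 0.15 & realized <= max(e1, e2) + 0.15)
    cat(sprintf("%-8s %-14s expected [%.2f, %.2f]  realized %.2f\n",
                tr, strat, min(e1, e2), max(e1, e2), realized))
  }
}
write_table_csv(do.call(rbind, rows), "results/expected_accuracy.csv")
cat("wrote results/expected_accuracy.csv\n")
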