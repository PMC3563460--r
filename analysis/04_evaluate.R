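#!/usr/bin/env Rscript
# Step 4 — evaluation statistics per (trait, strategy, method, replicate):
# predictive ability, bias, inflation, NRMSE and accuracy; cross-replicate
# means with SEs; paired t-tests with Bonferroni control and letter
# groupings; marker-effect distribution summaries for the methods that
# estimate explicit effects.

library(gsbench)
stopifnot(file.exists("results/predictions.csv"))

pred <- read_table_csv("results/predictions.csv")
vc <- read_table_csv("results/variance_components.csv")

reports <- list(); letters <- list()
for (tr in unique(pred$trait)) {
  sub <- pred[pred$trait == tr, ]
  # pseudo-heritability of the cage-adjusted phenotypes
  h2_tr <- with(vc[vc$trait == tr, ], sigma2_u / (sigma2_u + sigma2_e))
  cells <- split(sub, interaction(sub$method, sub$strategy, sub$replicate,
                                  drop = TRUE))
  rep_tab <- do.call(rbind, lapply(cells, function(cell) {
    cbind(data.frame(trait = tr, method = cell$method[1],
                     strategy = cell$strategy[1],
                     replicate = cell$replicate[1]),
          evaluate_predictions(cell$y_obs, cell$y_pred, h2 = h2_tr))
  }))
  rownames(rep_tab) <- NULL
  reports[[tr]] <- rep_tab
  for (strat in unique(rep_tab$strategy)) {
    st <- rep_tab[rep_tab$strategy == strat &
                    !is.na(rep_tab$predictive_ability), ]
    if (length(unique(st$method)) >= 2) {
      cmp <- compare_methods(st[, c("method", "replicate",
                                    "predictive_ability")])
      letters[[paste(tr, strat)]] <- data.frame(
        trait = tr, strategy = strat, method = names(cmp$letters),
        mean_pa = cmp$means[names(cmp$letters)], letters = cmp$letters)
      cat(sprintf("\n%s / %s (mean predictive ability, shared letter =\n", tr, strat),
          "no significant difference):\n")
      print(round(cmp$means, 3))
    }
  }
}
report <- do.call(rbind, reports)
agg <- do.call(rbind, lapply(split(report, report$trait), function(tab) {
  cbind(trait = tab$trait[1], aggregate_benchmark(tab))
}))
write_table_csv(report, "results/evaluation_by_replicate.csv")
write_table_csv(agg, "results/evaluation_summary.csv")
write_table_csv(do.call(rbind, letters), "results/significance_letters.csv")
cat("\nwrote results/evaluation_*.csv, significance_letters.csv\n")

# markdown rendering of the summary table
md <- c("| trait | strategy | method | predictive ability (SE) | bias | inflation | NRMSE |",
        "|---|---|---|---|---|---|---|",
        sprintf("| %s | %s | %s | %.3f (%.3f) | %.2f | %.2f | %.3f |",
                agg$trait, agg$strategy, agg$method,
                agg$predictive_ability_mean, agg$predictive_ability_se,
                agg$bias_mean, agg$inflation_mean, agg$nrmse_mean))
writeLines(md, "results/evaluation_summary.md")

# bar chart of predictive ability with significance letters, if ggplot2 is there
if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  lt <- read_table_csv("results/significance_letters.csv")
  p <- ggplot(lt, aes(x = reorder(method, -mean_pa), y = mean_pa)) +
    geom_col(fill = "steelblue") +
    geom_text(aes(label = letters), vjust = -0.4, size = 3) +
    facet_grid(trait ~ strategy) +
    labs(x = NULL, y = "predictive ability",
         caption = "bars sharing a letter do not differ (paired t, Bonferroni)") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
  ggsave("results/predictive_ability.pdf", p, width = 9, height = 6)
  cat("wrote results/predictive_ability.pdf\n")
}
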