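#!/usr/bin/env Rscript
# Exhaustive 1-3 biomarker panel search for the age and frailty
# contrasts: every combination is fitted with the linear discriminant
# classifier on its complete-case patients and ranked by resubstitution
# accuracy, then residual-probability loss. Top-10 tables (one decimal,
# like the published panel tables) go to results/panels/.

library(senopanel)

d <- read_cohort("results/cohort")
dir.create("results/panels", showWarnings = FALSE, recursive = TRUE)

for (contrast in c("age", "frailty")) {
  sr <- run_search(d$cohort, d$matrix, contrast, k_list = 1:3, top_n = 10)
  write_panel_table(sr$top, sprintf("results/panels/top10_%s.csv",
                                    contrast))
  write.csv(sr$results, sprintf("results/panels/all_%s.csv", contrast),
            row.names = FALSE)
  cat(sprintf("\n%s contrast: %d evaluable panels (%d excluded)\n",
              contrast, nrow(sr$results), sr$n_excluded))
  print(format_panel_table(
    sr$top[, c("rank", "panel", "n", "accuracy", "loss")]),
    row.names = FALSE)
}

cat("\nNote: accuracies are resubstitution estimates (no cross-validation)",
    "\nand are optimistic by construction; see the methods vignette.\n")
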