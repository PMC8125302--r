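#!/usr/bin/env Rscript
# Rank every biomarker individually for the age and frailty contrasts
# (oriented ROC-AUC, Wilcoxon rank-sum p, standardized log fold-change;
# composite = 2*rank_AUC + rank_p + rank_FC) and, one-vs-rest per
# category, for CD3 infiltration in the whole tumor. Expects the cohort
# from 01_simulate_cohort.R.

library(senopanel)

d <- read_cohort("results/cohort")
z <- suppressWarnings(zscore(d$matrix))
dir.create("results/ranking", showWarnings = FALSE, recursive = TRUE)

for (contrast in c("age", "frailty")) {
  lab <- contrast_labels(d$cohort, contrast)
  rb <- rank_biomarkers(z, lab)
  write.csv(rb, sprintf("results/ranking/biomarkers_%s.csv", contrast),
            row.names = FALSE)
  cat(sprintf("\n%s contrast — top 10 of %d biomarkers:\n", contrast,
              nrow(rb)))
  print(head(rb[, c("name", "auc", "p_value", "log_fc", "composite")], 10),
        digits = 3)
}

# three-class infiltrate: one-vs-rest per category
lab3 <- contrast_labels(d$cohort, "cd3_whole")
for (cat3 in levels(lab3)) {
  rb <- rank_biomarkers(z, one_vs_rest(lab3, cat3), positive = cat3)
  write.csv(rb, sprintf("results/ranking/biomarkers_cd3_whole_%s.csv",
                        cat3), row.names = FALSE)
  cat(sprintf("\nCD3 whole-tumor '%s' vs rest — top 5: %s\n", cat3,
              paste(head(rb$name, 5), collapse = ", ")))
}
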