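#!/usr/bin/env Rscript
# Categorize the tumor immune infiltrate (sTIL fixed cutpoints; CD3/CD8
# cohort quartiles), then search three-biomarker panels for each
# three-class infiltrate contrast, with and without clinical covariates
# (age; breast-cancer parameters: tumor size, grade, nodal stage)
# appended to the classifier features.

library(senopanel)

d <- read_cohort("results/cohort")
dir.create("results/infiltrate", showWarnings = FALSE, recursive = TRUE)

il <- infiltrate_labels(d$cohort)
write.csv(il, "results/infiltrate/labels.csv", row.names = FALSE)
jsonlite::write_json(attr(il, "cutoffs"), "results/infiltrate/cutoffs.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("Infiltrate category counts:\n")
print(sapply(il[, -1], table))

cov_sets <- list(age = "age",
                 bc = c("tumor_size", "tumor_grade", "node_stage"))
for (contrast in c("stil", "cd3_whole", "cd8_whole")) {
  sr <- run_search(d$cohort, d$matrix, contrast, k_list = 3,
                   covariate_sets = cov_sets, top_n = 10)
  write_panel_table(sr$top,
                    sprintf("results/infiltrate/top10_%s.csv", contrast))
  cat(sprintf("\n%s: best panel %s (n=%d, acc %.1f%%, loss %.1f%%; ",
              contrast, sr$top$panel[1], sr$top$n[1], sr$top$accuracy[1],
              sr$top$loss[1]))
  cat(sprintf("with age %.1f%%/%.1f%%; with BC %.1f%%/%.1f%%)\n",
              sr$top$accuracy_age[1], sr$top$loss_age[1],
              sr$top$accuracy_bc[1], sr$top$loss_bc[1]))
}
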