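#!/usr/bin/env Rscript
# Export plot-ready discriminant coordinates for the top-ranked panels:
# LD1 (density-plot input) for the binary age and frailty contrasts,
# LD1/LD2 score coordinates with 66% / 95% confidence ellipsoids for the
# three-class CD3 whole-tumor contrast.

library(senopanel)

d <- read_cohort("results/cohort")
z <- suppressWarnings(zscore(d$matrix))
z <- z[, sort(colnames(z))]
dir.create("results/projections", showWarnings = FALSE, recursive = TRUE)

project_top_panel <- function(contrast) {
  top <- read.csv(sprintf("results/panels/top10_%s.csv", contrast),
                  colClasses = "character")
  panel <- strsplit(top$panel[1], " + ", fixed = TRUE)[[1]]
  lab <- contrast_labels(d$cohort, contrast)
  keep <- !is.na(lab) & rowSums(is.na(z[, panel, drop = FALSE])) == 0
  fit <- fit_lda(z[keep, panel, drop = FALSE], lab[keep])
  list(panel = panel,
       proj = export_projection(fit, z[keep, panel, drop = FALSE],
                                lab[keep]))
}

for (contrast in c("age", "frailty")) {
  pp <- project_top_panel(contrast)
  write.csv(pp$proj$coords,
            sprintf("results/projections/ld1_%s.csv", contrast),
            row.names = FALSE)
  cat(sprintf("%s: LD1 coordinates for panel [%s], %d patients\n",
              contrast, paste(pp$panel, collapse = " + "),
              nrow(pp$proj$coords)))
}

# three-class contrast with ellipsoids
top3 <- read.csv("results/infiltrate/top10_cd3_whole.csv",
                 colClasses = "character")
panel <- strsplit(top3$panel[1], " + ", fixed = TRUE)[[1]]
lab <- contrast_labels(d$cohort, "cd3_whole")
keep <- !is.na(lab) & rowSums(is.na(z[, panel, drop = FALSE])) == 0
fit <- fit_lda(z[keep, panel, drop = FALSE], lab[keep])
pr <- export_projection(fit, z[keep, panel, drop = FALSE], lab[keep])
write.csv(pr$coords, "results/projections/ld12_cd3_whole.csv",
          row.names = FALSE)
jsonlite::write_json(pr$ellipsoids,
                     "results/projections/ellipsoids_cd3_whole.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat(sprintf("cd3_whole: LD1/LD2 + ellipsoids for panel [%s], %d patients\n",
            paste(panel, collapse = " + "), nrow(pr$coords)))
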