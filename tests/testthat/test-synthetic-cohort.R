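test_that("generated cohort reproduces the study's grouping structure", {
  g <- generate_cohort(synthetic_config(seed = 1))
  coh <- g$cohort

  expect_equal(nrow(coh), 65)
  expect_equal(sum(coh$age_group == "younger"), 34)
  expect_equal(sum(coh$age_group == "older"), 31)
  expect_equal(sum(!is.na(coh$g8)), 29)
  expect_equal(sum(coh$frailty_group == "fit"), 19)
  expect_equal(sum(coh$frailty_group == "frailer"), 10)

  # grouping invariants
  expect_true(all((coh$age >= 70) == (coh$age_group == "older")))
  scored <- !is.na(coh$g8)
  expect_true(all((coh$g8[scored] > 14) ==
                    (coh$frailty_group[scored] == "fit")))
  expect_true(all(coh$frailty_group[scored][coh$g8[scored] <= 14] ==
                    "frailer"))
  expect_true(all(is.na(coh$g8[coh$age_group == "younger"])))
  expect_true(all(coh$g8[scored] >= 0 & coh$g8[scored] <= 17))

  # biomarker matrix shape and family scales
  expect_equal(dim(g$matrix), c(65, 100))
  pbmc <- g$matrix[, grep("^pbmc", colnames(g$matrix))]
  expect_true(all(pbmc >= 0 & pbmc <= 100, na.rm = TRUE))
  plasma <- g$matrix[, grep("^plasma", colnames(g$matrix))]
  expect_true(all(plasma > 0, na.rm = TRUE))
})

test_that("identical seed and config give bit-identical output", {
  cfg <- synthetic_config(seed = 42,
                          planted = data.frame(index = 3, contrast = "age",
                                               d = 1))
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(g1$matrix, g2$matrix)
  expect_identical(g1$cohort, g2$cohort)
  g3 <- generate_cohort(synthetic_config(seed = 43))
  expect_false(identical(g1$matrix, g3$matrix))
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(n_fit = 25, n_frail = 10, n_old = 31),
               "n_fit \\+ n_frail")
  expect_error(synthetic_config(n_young = -1), "counts")
  expect_error(synthetic_config(planted = data.frame(index = 999,
                                                     contrast = "age",
                                                     d = 1)),
               "out of range")
  expect_error(synthetic_config(block_missing = list(list(block = 1,
                                                          prob = 1.5))),
               "probability")
  expect_error(synthetic_config(planted = data.frame(index = 1,
                                                     contrast = "age",
                                                     d = Inf)),
               "finite")
})

test_that("planted effect sizes map to the closed-form AUC", {
  # d = 0: every biomarker's AUC near 0.5; d = 1: AUC near pnorm(1/sqrt(2));
  # d = 5: near-perfect separation. Empirical means over replicate cohorts
  # stay within 3 Monte-Carlo SEs of the closed form.
  n_rep <- 200
  auc_null <- auc_d1 <- auc_d5 <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- small_config(seed = 5000 + r, n_biomarkers = 6,
                        planted = data.frame(index = c(2, 3),
                                             contrast = "age",
                                             d = c(1, 5)))
    g <- generate_cohort(cfg)
    lab <- contrast_labels(g$cohort, "age")
    auc_null[r] <- roc_auc(g$matrix[, 1], lab, oriented = FALSE)
    auc_d1[r] <- roc_auc(g$matrix[, 2], lab, oriented = FALSE)
    auc_d5[r] <- roc_auc(g$matrix[, 3], lab, oriented = FALSE)
  }
  se <- function(x) stats::sd(x) / sqrt(length(x))
  expect_lt(abs(mean(auc_null) - 0.5), 3 * se(auc_null))
  expect_lt(abs(mean(auc_d1) - pnorm(1 / sqrt(2))), 3 * se(auc_d1))
  expect_lt(abs(mean(auc_d5) - pnorm(5 / sqrt(2))), 3 * se(auc_d5))
  expect_gt(mean(auc_d5), 0.99)
})

test_that("block-wise missingness hits the configured rate, block-wise", {
  cfg <- synthetic_config(
    n_biomarkers = 20,
    block_missing = list(list(block = 1:5, prob = 0.3)), seed = 9)
  # pool over replicates for a tight Monte-Carlo band
  miss <- unlist(lapply(1:40, function(r) {
    cfg$seed <- 100 + r
    m <- generate_cohort(cfg)$matrix
    # block-wise: a patient misses all 5 or none
    patt <- rowSums(is.na(m[, 1:5]))
    expect_true(all(patt %in% c(0, 5)))
    expect_true(all(!is.na(m[, 6:20])))
    patt > 0
  }))
  p_hat <- mean(miss)
  se <- sqrt(0.3 * 0.7 / length(miss))
  expect_lt(abs(p_hat - 0.3), 3 * se)
})

test_that("cohort CSV round trip is exact, including the missingness mask", {
  g <- generate_cohort(synthetic_config(seed = 4, n_biomarkers = 12))
  dir <- withr::local_tempdir()
  write_cohort(g$cohort, g$matrix, dir)
  back <- read_cohort(dir)
  expect_equal(back$cohort, g$cohort)
  expect_equal(back$matrix, g$matrix)
  expect_identical(is.na(back$matrix), is.na(g$matrix))
})

test_that("malformed inputs produce named parse errors", {
  g <- generate_cohort(synthetic_config(seed = 4, n_biomarkers = 4))
  dir <- withr::local_tempdir()
  write_cohort(g$cohort, g$matrix, dir)

  # text in a biomarker cell
  lines <- readLines(file.path(dir, "biomarkers.csv"))
  lines[3] <- sub("^(P[0-9]+,)[^,]*", "\\1oops", lines[3])
  writeLines(lines, file.path(dir, "biomarkers.csv"))
  expect_error(read_cohort(dir), "non-numeric value 'oops' at row 2")

  # malformed matrix header
  lines[1] <- sub("^patient_id", "id", lines[1])
  writeLines(lines, file.path(dir, "biomarkers.csv"))
  expect_error(read_cohort(dir), "malformed matrix header")

  # malformed cohort header
  coh <- readLines(file.path(dir, "cohort.csv"))
  coh[1] <- sub("age_group", "agegrp", coh[1])
  writeLines(coh, file.path(dir, "cohort.csv"))
  expect_error(read_cohort(dir), "malformed cohort header")
})

test_that("config files in YAML and JSON load equivalently", {
  dir <- withr::local_tempdir()
  ya <- file.path(dir, "c.yaml")
  writeLines(c("n_young: 10", "n_old: 10", "n_fit: 5", "n_frail: 4",
               "n_biomarkers: 8", "seed: 3",
               "planted:", "  - index: 2", "    contrast: age",
               "    d: 1.5"), ya)
  js <- file.path(dir, "c.json")
  jsonlite::write_json(list(n_young = 10, n_old = 10, n_fit = 5,
                            n_frail = 4, n_biomarkers = 8, seed = 3,
                            planted = data.frame(index = 2,
                                                 contrast = "age",
                                                 d = 1.5)),
                       js, auto_unbox = TRUE)
  c1 <- read_config(ya)
  c2 <- read_config(js)
  expect_equal(generate_cohort(c1)$matrix, generate_cohort(c2)$matrix)
})
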