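test_that("panel enumeration is exhaustive, ordered and duplicate-free", {
  p2 <- enumerate_panels(c("d", "b", "a", "c"), 2)
  expect_equal(ncol(p2), choose(4, 2))
  expect_equal(p2[, 1], c("a", "b"))          # lexicographic
  expect_equal(ncol(enumerate_panels(letters[1:6], 3)), choose(6, 3))
  p1 <- enumerate_panels(c("b", "a"), 1)
  expect_equal(sort(as.vector(p1)), c("a", "b"))
  expect_error(enumerate_panels(c("a", "b"), 3), "exceeds")
  expect_error(enumerate_panels(c("a", "a"), 1), "distinct")
  # no duplicates
  expect_equal(anyDuplicated(apply(p2, 2, paste, collapse = "+")), 0)
})

test_that("evaluate_panel restricts to complete cases and records n", {
  set.seed(30)
  z <- matrix(rnorm(65 * 5), 65, 5,
              dimnames = list(sprintf("P%03d", 1:65), paste0("b", 1:5)))
  lab <- factor(rep(c("younger", "older"), c(34, 31)))
  z[1:8, 3] <- NA                              # assay block absent for 8
  r_full <- evaluate_panel(c("b1", "b2"), z, lab)
  expect_equal(r_full$n, 65)
  r_miss <- evaluate_panel(c("b1", "b3"), z, lab)
  expect_equal(r_miss$n, 57)
  expect_true(r_miss$evaluable)
  expect_error(evaluate_panel("nope", z, lab), "unknown biomarker")
})

test_that("panels with a class below min_per_class are unevaluable", {
  set.seed(31)
  z <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  lab <- factor(rep(c("x", "y"), c(9, 1)))
  r <- evaluate_panel("a", z, lab)
  expect_false(r$evaluable)
  expect_true(is.na(r$accuracy))
})

test_that("a perfectly separating biomarker makes every panel perfect", {
  set.seed(32)
  z <- matrix(rnorm(40 * 4), 40, 4,
              dimnames = list(NULL, paste0("b", 1:4)))
  lab <- factor(rep(c("x", "y"), each = 20))
  z[, 2] <- ifelse(lab == "y", 10, -10) + rnorm(40, sd = 0.1)
  for (panel in list("b2", c("b1", "b2"), c("b2", "b3", "b4"))) {
    expect_equal(evaluate_panel(panel, z, lab)$accuracy, 100)
  }
})

test_that("ranking orders by accuracy, then loss, then panel name", {
  res <- data.frame(
    panel = c("A + B", "C + D", "E + F", "G"),
    n = 65, accuracy = c(92.3, 92.3, 95, 92.3),
    loss = c(17.4, 13.7, 20, 13.7),
    evaluable = c(TRUE, TRUE, TRUE, TRUE), stringsAsFactors = FALSE)
  rk <- rank_panels(res)
  expect_equal(rk$panel, c("E + F", "C + D", "G", "A + B"))
  expect_equal(rk$rank, 1:4)
  # permutation invariance
  rk2 <- rank_panels(res[c(3, 1, 4, 2), ])
  expect_equal(rk2, rk)
  expect_error(rank_panels(res[res$accuracy > 99, ]), "no evaluable")
})

test_that("the compiled kernel matches the reference implementation", {
  set.seed(33)
  g <- generate_cohort(synthetic_config(
    seed = 33, n_biomarkers = 12,
    planted = data.frame(index = 2, contrast = "age", d = 1.2)))
  z <- suppressWarnings(zscore(g$matrix))
  z <- z[, sort(colnames(z))]
  for (contrast in c("age", "frailty", "cd8_whole")) {
    lab <- contrast_labels(g$cohort, contrast)
    sr <- run_search(g$cohort, g$matrix, contrast, k_list = 1:3, top_n = 5)
    # exhaustiveness over evaluable + excluded panels
    expect_equal(nrow(sr$results) + sr$n_excluded,
                 sum(choose(12, 1:3)))
    expect_equal(anyDuplicated(sr$results$panel), 0)
    # spot-check 25 random ranked rows against the pure-R path
    rows <- sample(nrow(sr$results), 25)
    for (i in rows) {
      panel <- strsplit(sr$results$panel[i], " + ", fixed = TRUE)[[1]]
      ref <- evaluate_panel(panel, z, lab)
      expect_equal(sr$results$n[i], ref$n)
      expect_equal(sr$results$accuracy[i], ref$accuracy, tolerance = 1e-10)
      expect_equal(sr$results$loss[i], ref$loss, tolerance = 1e-10)
    }
  }
})

test_that("frailty searches use only patients with a G8 score", {
  g <- generate_cohort(synthetic_config(seed = 34, n_biomarkers = 8,
                                        block_missing = list()))
  sr <- run_search(g$cohort, g$matrix, "frailty", k_list = 1)
  expect_true(all(sr$results$n == 29))
})

test_that("three-class panels produce two discriminant axes", {
  g <- generate_cohort(synthetic_config(seed = 35, n_biomarkers = 6,
                                        block_missing = list()))
  lab <- contrast_labels(g$cohort, "cd3_whole")
  keep <- !is.na(lab)
  z <- suppressWarnings(zscore(g$matrix))
  fit <- fit_lda(z[keep, 1:3], lab[keep])
  expect_equal(ncol(fit$scalings), 2)
})

test_that("covariate augmentation behaves at its logical extremes", {
  set.seed(36)
  g <- generate_cohort(synthetic_config(seed = 36, n_biomarkers = 6,
                                        block_missing = list()))
  z <- suppressWarnings(zscore(g$matrix))
  z <- z[, sort(colnames(z))]
  lab <- contrast_labels(g$cohort, "age")
  panel <- colnames(z)[1:2]
  base <- evaluate_panel(panel, z, lab)

  # appending a constant covariate (ridge picks it up) leaves accuracy alone
  coh_const <- g$cohort
  coh_const$tumor_size <- 5
  aug_const <- suppressWarnings(
    augment_panel(panel, "tumor_size", z, coh_const, lab))
  expect_equal(aug_const$accuracy, base$accuracy)

  # appending the label itself is perfect leakage; its zero within-class
  # variance also trips the documented ridge fallback
  coh_leak <- g$cohort
  coh_leak$tumor_size <- as.numeric(lab)
  expect_warning(
    aug_leak <- augment_panel(panel, "tumor_size", z, coh_leak, lab),
    "singular")
  expect_equal(aug_leak$accuracy, 100)

  # real covariates are appended without changing the patient set; the
  # metrics move but are not guaranteed to improve (LDA maximizes
  # likelihood, not the margin, even with a separating feature)
  aug_age <- augment_panel(panel, "age", z, g$cohort, lab)
  expect_equal(aug_age$n, base$n)
  expect_true(aug_age$accuracy >= 0 && aug_age$accuracy <= 100)
  expect_false(identical(aug_age$loss, base$loss))

  # entirely missing covariate errors
  coh_na <- g$cohort
  coh_na$tumor_size <- NA_real_
  expect_error(augment_panel(panel, "tumor_size", z, coh_na, lab),
               "entirely missing")
})

test_that("node stage and grade are encoded ordinally before z-scoring", {
  g <- generate_cohort(synthetic_config(seed = 37, n_biomarkers = 6))
  cv <- covariate_features(g$cohort, c("node_stage", "tumor_grade", "age"))
  expect_equal(colnames(cv), c("node_stage", "tumor_grade", "age"))
  expect_lt(max(abs(colMeans(cv))), 1e-9)
  raw <- as.numeric(sub("pN", "", g$cohort$node_stage))
  expect_equal(order(cv[, "node_stage"]), order(raw))
})

test_that("run_search output is deterministic and properly ranked", {
  g <- generate_cohort(synthetic_config(seed = 38, n_biomarkers = 10))
  s1 <- run_search(g$cohort, g$matrix, "age", k_list = 2,
                   covariate_sets = list(age = "age"))
  s2 <- run_search(g$cohort, g$matrix, "age", k_list = 2,
                   covariate_sets = list(age = "age"))
  expect_identical(s1$results, s2$results)
  expect_identical(s1$top, s2$top)
  expect_equal(s1$results$rank, seq_len(nrow(s1$results)))
  # ordering invariant: accuracy non-increasing; loss ascending within ties
  acc <- s1$results$accuracy
  expect_true(all(diff(acc) <= 1e-12))
  expect_true(all(c("accuracy_age", "loss_age") %in% names(s1$top)))
})
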