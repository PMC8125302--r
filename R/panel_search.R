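# Exhaustive biomarker-panel search: enumerate all 1-3 biomarker
# combinations, evaluate each with the linear discriminant classifier on
# its complete-case patients, rank by resubstitution accuracy then
# residual-probability loss, and optionally augment top panels with
# clinical covariates.

#' Enumerate biomarker panels
#'
#' All `choose(n, k)` k-combinations of the biomarker names, in
#' lexicographic order, without duplicates.
#'
#' @param biomarker_names character vector of distinct names.
#' @param k panel size (1, 2 or 3).
#' @return character matrix with `k` rows, one column per panel.
#' @export
enumerate_panels <- function(biomarker_names, k) {
  stopifnot(k %in% 1:3)
  nm <- sort(unique(as.character(biomarker_names)))
  if (length(nm) != length(biomarker_names))
    stop("biomarker names must be distinct")
  if (k > length(nm)) stop("k exceeds the number of biomarkers")
  utils::combn(nm, k)
}

#' Evaluate one biomarker panel
#'
#' Restricts to patients with a defined label and all panel biomarkers
#' observed (complete cases), fits the discriminant classifier and scores
#' it by resubstitution accuracy and residual-probability loss. This is the
#' reference implementation; [run_search()] uses a compiled kernel that is
#' cross-checked against it.
#'
#' @param panel character vector of 1--3 biomarker names.
#' @param z z-scored patients x biomarkers matrix.
#' @param labels class labels aligned with rows (`NA` = no label).
#' @param min_per_class minimum complete-case samples per class; below it
#'   the panel is marked unevaluable.
#' @param ridge regularization passed to [fit_lda()].
#' @return one-row data.frame: `panel` (names joined by `" + "`), `n`,
#'   `accuracy`, `loss`, `evaluable`.
#' @export
evaluate_panel <- function(panel, z, labels, min_per_class = 2, ridge = 0) {
  if (!all(panel %in% colnames(z)))
    stop("unknown biomarker(s): ",
         paste(setdiff(panel, colnames(z)), collapse = ", "))
  labels <- as.factor(labels)
  sub <- z[, panel, drop = FALSE]
  keep <- !is.na(labels) & rowSums(is.na(sub)) == 0
  ys <- factor(labels[keep], levels = levels(labels))
  out <- data.frame(panel = paste(panel, collapse = " + "),
                    n = sum(keep), accuracy = NA_real_, loss = NA_real_,
                    evaluable = FALSE, stringsAsFactors = FALSE)
  if (any(table(ys) < min_per_class) || sum(keep) <= nlevels(labels))
    return(out)
  fit <- fit_lda(sub[keep, , drop = FALSE], ys, ridge = ridge)
  pr <- predict(fit, sub[keep, , drop = FALSE])
  out$accuracy <- accuracy(pr, ys)
  out$loss <- residual_loss(pr, as.character(ys))
  out$evaluable <- TRUE
  out
}

#' Rank evaluated panels
#'
#' Orders evaluable panels by accuracy (descending), then loss (ascending),
#' then panel name (lexicographic, for a reproducible total order), and
#' assigns `rank = position`.
#'
#' @param results data.frame with at least `panel`, `accuracy`, `loss`,
#'   `evaluable` columns (rows with `evaluable = FALSE` are dropped).
#' @return the ranked data.frame with a leading `rank` column.
#' @export
rank_panels <- function(results) {
  res <- results[results$evaluable, , drop = FALSE]
  if (nrow(res) == 0) stop("no evaluable panel to rank")
  ord <- order(-res$accuracy, res$loss, res$panel)
  res <- res[ord, , drop = FALSE]
  res <- cbind(rank = seq_len(nrow(res)), res)
  rownames(res) <- NULL
  res
}

#' Clinical covariate feature matrix
#'
#' Encodes covariates as z-scored numeric features: `age` and `tumor_size`
#' in their natural units, `tumor_grade` ordinal 1--3, `node_stage` ordinal
#' 0--3 (pN0..pN3), `frailty` binary (fit = 0, frailer = 1, others
#' missing). Standardization uses all cohort patients with the value
#' observed, the same convention as the biomarkers.
#'
#' @param cohort cohort data.frame.
#' @param covariates subset of
#'   `c("age", "tumor_size", "tumor_grade", "node_stage", "frailty")`.
#' @return numeric matrix, one z-scored column per covariate.
#' @export
covariate_features <- function(cohort, covariates) {
  covariates <- match.arg(covariates,
                          c("age", "tumor_size", "tumor_grade",
                            "node_stage", "frailty"), several.ok = TRUE)
  enc <- function(v) {
    switch(v,
           age = as.numeric(cohort$age),
           tumor_size = as.numeric(cohort$tumor_size),
           tumor_grade = as.numeric(cohort$tumor_grade),
           node_stage = as.numeric(sub("^pN", "", cohort$node_stage)),
           frailty = ifelse(cohort$frailty_group == "fit", 0,
                            ifelse(cohort$frailty_group == "frailer", 1,
                                   NA_real_)))
  }
  mat <- vapply(covariates, enc, numeric(nrow(cohort)))
  dimnames(mat) <- list(cohort$patient_id, covariates)
  empty <- colSums(!is.na(mat)) == 0
  if (any(empty))
    stop("covariate entirely missing: ",
         paste(covariates[empty], collapse = ", "))
  suppressWarnings(zscore(mat))
}

#' Augment a panel with clinical covariates
#'
#' Re-evaluates a panel with covariates appended as extra classifier
#' features on the panel's complete-case patient set (patients lacking a
#' covariate value are additionally dropped, with a message).
#'
#' @inheritParams evaluate_panel
#' @param covariates covariate names (see [covariate_features()]).
#' @param cohort cohort data.frame aligned with the rows of `z`.
#' @return one-row data.frame as in [evaluate_panel()], with a `covariates`
#'   column.
#' @export
augment_panel <- function(panel, covariates, z, cohort, labels,
                          min_per_class = 2, ridge = 0) {
  cv <- covariate_features(cohort, covariates)
  sub <- z[, panel, drop = FALSE]
  keep <- !is.na(as.factor(labels)) & rowSums(is.na(sub)) == 0
  miss_cv <- keep & rowSums(is.na(cv)) > 0
  if (any(miss_cv)) {
    message(sum(miss_cv), " patient(s) dropped for missing covariates")
    keep <- keep & !miss_cv
  }
  aug <- cbind(sub, cv)
  keep_mask <- ifelse(keep, 1, NA_real_)
  out <- evaluate_panel(c(panel, colnames(cv)), aug * keep_mask, labels,
                        min_per_class = min_per_class, ridge = ridge)
  out$panel <- paste(panel, collapse = " + ")
  out$covariates <- paste(covariates, collapse = "+")
  out
}

#' Exhaustive panel search over a cohort
#'
#' Builds labels for the requested contrast, z-scores the biomarker matrix,
#' evaluates every 1-, 2- and/or 3-biomarker panel on its complete-case
#' patients with the discriminant classifier (compiled kernel), ranks all
#' evaluable panels by accuracy then loss, and recomputes the top panels
#' with each covariate set appended.
#'
#' @param cohort cohort data.frame.
#' @param matrix raw patients x biomarkers matrix aligned with the cohort
#'   (rows in the same order).
#' @param contrast see [contrast_labels()].
#' @param k_list panel sizes to enumerate (subset of 1:3).
#' @param covariate_sets named list of covariate-name vectors; each set
#'   adds `accuracy_<set>` / `loss_<set>` columns to the top table.
#' @param top_n rows of the reported top table (default 10, as in the
#'   published panel tables).
#' @param min_per_class,ridge see [evaluate_panel()].
#' @param standardize z-score `matrix` first (set `FALSE` if `matrix` is
#'   already standardized).
#' @return object of class `senopanel_search`: list with `contrast`,
#'   `results` (all evaluable panels, ranked), `top` (top `top_n` with
#'   augmented columns), `n_excluded` (unevaluable panel count), `k_list`.
#' @export
run_search <- function(cohort, matrix, contrast, k_list = 1:3,
                       covariate_sets = list(), top_n = 10,
                       min_per_class = 2, ridge = 0, standardize = TRUE) {
  stopifnot(all(k_list %in% 1:3))
  labels <- contrast_labels(cohort, contrast)
  z <- if (standardize) suppressWarnings(zscore(matrix)) else matrix
  z <- z[, sort(colnames(z)), drop = FALSE]   # lexicographic panel order

  y_codes <- as.integer(labels) - 1L
  y_codes[is.na(y_codes)] <- -1L
  k_classes <- nlevels(labels)

  res_list <- lapply(sort(unique(k_list)), function(k) {
    combos <- utils::combn(ncol(z), k)
    eng <- panel_search_engine(z, y_codes, combos, k_classes, ridge,
                               as.integer(min_per_class))
    panel_names <- apply(combos, 2, function(ix)
      paste(colnames(z)[ix], collapse = " + "))
    data.frame(panel = panel_names, k = k, n = eng$n,
               accuracy = eng$accuracy, loss = eng$loss,
               evaluable = eng$evaluable, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res_list)
  n_excluded <- sum(!res$evaluable)
  if (n_excluded > 0)
    message(n_excluded, " panel(s) unevaluable (class below min_per_class)")
  ranked <- rank_panels(res)

  top <- utils::head(ranked, top_n)
  for (set_name in names(covariate_sets)) {
    acc <- loss <- rep(NA_real_, nrow(top))
    for (i in seq_len(nrow(top))) {
      panel <- strsplit(top$panel[i], " + ", fixed = TRUE)[[1]]
      a <- augment_panel(panel, covariate_sets[[set_name]], z, cohort,
                         labels, min_per_class = min_per_class,
                         ridge = ridge)
      acc[i] <- a$accuracy; loss[i] <- a$loss
    }
    top[[paste0("accuracy_", set_name)]] <- acc
    top[[paste0("loss_", set_name)]] <- loss
  }

  structure(list(contrast = contrast, results = ranked, top = top,
                 n_excluded = n_excluded, k_list = sort(unique(k_list))),
            class = "senopanel_search")
}

#' @export
print.senopanel_search <- function(x, ...) {
  cat("Panel search —", x$contrast, "contrast; panel sizes",
      paste(x$k_list, collapse = ","), "\n")
  cat(nrow(x$results), "evaluable panels (", x$n_excluded,
      "excluded )\nTop panels:\n")
  print(format_panel_table(x$top), row.names = FALSE)
  invisible(x)
}
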