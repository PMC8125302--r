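# Single-biomarker scoring: z-standardization, ROC-AUC, Wilcoxon rank-sum
# p-value, standardized log fold-change, and the composite rank in which the
# AUC rank is weighted double.

#' Z-standardize a biomarker matrix
#'
#' Standardizes each biomarker (column) over its observed entries with the
#' sample SD (n - 1 denominator), so biomarkers measured in wildly different
#' units become comparable. Missing entries stay missing. A biomarker with
#' zero variance is flagged with a warning and set to 0 at its observed
#' entries.
#'
#' @param matrix numeric patients x biomarkers matrix, `NA` = missing; every
#'   column needs at least one observed value.
#' @return matrix of the same shape; attribute `"constant"` lists degenerate
#'   biomarkers.
#' @export
zscore <- function(matrix) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (any(colSums(!is.na(matrix)) == 0))
    stop("biomarker with no observed values: ",
         paste(colnames(matrix)[colSums(!is.na(matrix)) == 0],
               collapse = ", "))
  mu <- colMeans(matrix, na.rm = TRUE)
  sd <- apply(matrix, 2, stats::sd, na.rm = TRUE)
  constant <- which(is.na(sd) | sd == 0)
  z <- sweep(matrix, 2, mu, "-")
  sd_safe <- sd
  sd_safe[constant] <- 1
  z <- sweep(z, 2, sd_safe, "/")
  if (length(constant)) {
    z[, constant][!is.na(z[, constant])] <- 0
    warning("constant biomarker(s) set to z = 0: ",
            paste(colnames(matrix)[constant], collapse = ", "))
  }
  attr(z, "constant") <- colnames(matrix)[constant]
  z
}

# Split values by a two-level factor after removing missing entries; errors
# if either class ends up empty.
split_two_groups <- function(values, labels, positive) {
  labels <- as.factor(labels)
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- droplevels(labels[keep])
  if (missing(positive) || is.null(positive))
    positive <- levels(labels)[length(levels(labels))]
  a <- values[labels == positive]
  b <- values[labels != positive]
  if (length(a) == 0 || length(b) == 0)
    stop("undefined score: a class is empty after removing missing values")
  list(a = a, b = b)
}

#' ROC area under the curve by the Mann--Whitney identity
#'
#' `AUC = P(X_A > X_B) + 0.5 P(X_A = X_B)` over all between-class pairs,
#' computed from midranks. `oriented = TRUE` returns `max(auc, 1 - auc)`,
#' the direction-free separation used for ranking.
#'
#' @param values numeric vector (missing allowed, removed pairwise with
#'   labels).
#' @param labels two-class labels; `positive` names the class whose larger
#'   values push AUC above 0.5 (default: last factor level).
#' @param positive positive-class label.
#' @param oriented return `max(auc, 1 - auc)` instead of the raw AUC.
#' @return scalar in \[0, 1\] (oriented: \[0.5, 1\]).
#' @export
roc_auc <- function(values, labels, positive = NULL, oriented = FALSE) {
  g <- split_two_groups(values, labels, positive)
  n1 <- length(g$a); n0 <- length(g$b)
  r <- rank(c(g$a, g$b))
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (oriented) max(auc, 1 - auc) else auc
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact-distribution p when both groups have at most 8 observations and the
#' pooled values are tie-free; otherwise the normal approximation with tie
#' and continuity corrections.
#'
#' @inheritParams roc_auc
#' @return p-value in (0, 1\].
#' @export
rank_sum_p <- function(values, labels, positive = NULL) {
  g <- split_two_groups(values, labels, positive)
  ties <- anyDuplicated(c(g$a, g$b)) > 0
  use_exact <- !ties && length(g$a) <= 8 && length(g$b) <= 8
  stats::wilcox.test(g$a, g$b, alternative = "two.sided",
                     exact = use_exact, correct = TRUE)$p.value
}

#' Standardized log fold-change
#'
#' Difference of standardized group means, `mean(z_A) - mean(z_B)`, with A
#' the group of interest (older / frailer / the infiltrate category under
#' test) and B the reference: on a log-like standardized scale the ratio of
#' groups becomes a subtraction, and a positive value means the biomarker is
#' higher in the group of interest.
#'
#' @param values_z z-scored values (missing allowed).
#' @inheritParams roc_auc
#' @return signed scalar.
#' @export
standardized_fc <- function(values_z, labels, positive = NULL) {
  g <- split_two_groups(values_z, labels, positive)
  mean(g$a) - mean(g$b)
}

#' Rank biomarkers by the composite AUC / p-value / log-FC score
#'
#' Scores each biomarker of a z-scored matrix against a two-class label:
#' oriented ROC-AUC (descending), Wilcoxon rank-sum p (ascending) and
#' absolute standardized log fold-change (descending) are each converted to
#' ranks (average ranks on ties), and combined as
#' `composite = 2 * rank_auc + rank_p + rank_fc` — the AUC weighted double.
#' The final rank orders by composite, breaking ties by oriented AUC and
#' then by name so the ordering is reproducible. Biomarkers for which a
#' class is empty after missing-value removal are excluded with a message.
#'
#' @param z z-scored patients x biomarkers matrix (see [zscore()]).
#' @param labels two-class labels aligned with the rows.
#' @param positive group-of-interest label (default: last factor level).
#' @return data.frame sorted by `final_rank` with columns `name`, `auc`
#'   (oriented), `p_value`, `log_fc`, `rank_auc`, `rank_p`, `rank_fc`,
#'   `composite`, `final_rank`.
#' @export
rank_biomarkers <- function(z, labels, positive = NULL) {
  stopifnot(is.matrix(z), nrow(z) == length(labels))
  labels <- as.factor(labels)
  if (is.null(positive)) positive <- levels(labels)[nlevels(labels)]
  nm <- colnames(z)
  score_one <- function(j) {
    tryCatch(c(auc = roc_auc(z[, j], labels, positive, oriented = TRUE),
               p = rank_sum_p(z[, j], labels, positive),
               fc = standardized_fc(z[, j], labels, positive)),
             error = function(e) c(auc = NA_real_, p = NA_real_,
                                   fc = NA_real_))
  }
  sc <- t(vapply(seq_len(ncol(z)), score_one, numeric(3)))
  bad <- which(is.na(sc[, "auc"]))
  if (length(bad)) {
    message("excluded from ranking (undefined score): ",
            paste(nm[bad], collapse = ", "))
    sc <- sc[-bad, , drop = FALSE]
    nm <- nm[-bad]
  }
  if (nrow(sc) == 0) stop("no biomarker could be scored")
  rank_auc <- rank(-sc[, "auc"], ties.method = "average")
  rank_p <- rank(sc[, "p"], ties.method = "average")
  rank_fc <- rank(-abs(sc[, "fc"]), ties.method = "average")
  composite <- 2 * rank_auc + rank_p + rank_fc
  ord <- order(composite, -sc[, "auc"], nm)
  out <- data.frame(name = nm, auc = sc[, "auc"], p_value = sc[, "p"],
                    log_fc = sc[, "fc"], rank_auc = rank_auc,
                    rank_p = rank_p, rank_fc = rank_fc,
                    composite = composite, stringsAsFactors = FALSE)
  out <- out[ord, ]
  out$final_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' One-vs-rest labels for a three-class contrast
#'
#' Recodes a multi-class label as `category` vs `"rest"`, the form in which
#' individual biomarkers are ranked for each infiltrate category.
#'
#' @param labels factor or character vector.
#' @param category the class of interest.
#' @return factor with levels `c("rest", category)`; `NA` preserved.
#' @export
one_vs_rest <- function(labels, category) {
  labels <- as.character(labels)
  if (!category %in% labels[!is.na(labels)])
    stop("category not present in labels: ", category)
  out <- ifelse(is.na(labels), NA_character_,
                ifelse(labels == category, category, "rest"))
  factor(out, levels = c("rest", category))
}
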