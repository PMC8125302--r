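# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: the AUC oracle enumerates between-class pairs, the
# Wilcoxon oracle enumerates label assignments, and the posterior oracle
# evaluates the shared-covariance Gaussian densities directly.

# AUC as (concordant + 0.5 * tied) / all between-class pairs.
brute_force_auc <- function(values, is_positive) {
  a <- values[is_positive]
  b <- values[!is_positive]
  s <- 0
  for (x in a) for (z in b) s <- s + (x > z) + 0.5 * (x == z)
  s / (length(a) * length(b))
}

# Two-sided exact rank-sum p by enumerating all C(n, m) equally likely
# assignments of m of the n pooled ranks to group A.
enumerate_rank_sum_p <- function(a, b) {
  v <- c(a, b)
  m <- length(a)
  r <- rank(v)
  w_obs <- sum(r[seq_len(m)])
  ws <- apply(utils::combn(length(v), m), 2, function(ix) sum(r[ix]))
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# Posterior by direct evaluation of the k Gaussian densities with the
# model's shared covariance and priors.
density_quotient_posterior <- function(model, x) {
  S <- model$pooled_cov
  S_inv <- solve(S)
  log_det <- determinant(S, logarithm = TRUE)$modulus
  k <- length(model$class_labels)
  log_num <- sapply(seq_len(k), function(c) {
    d <- sweep(x, 2, model$means[c, ])
    -0.5 * rowSums((d %*% S_inv) * d) - 0.5 * log_det +
      log(model$priors[c])
  })
  log_num <- matrix(log_num, nrow = nrow(x))
  num <- exp(log_num - apply(log_num, 1, max))
  num / rowSums(num)
}

# Small cohort config used by several tests: fast to generate, same
# grouping structure as the default.
small_config <- function(seed, n_biomarkers = 10, ...) {
  synthetic_config(n_young = 34, n_old = 31, n_fit = 19, n_frail = 10,
                   n_biomarkers = n_biomarkers, block_missing = list(),
                   seed = seed, ...)
}

# Random labelled instance with class-separated Gaussian features,
# resampled until every class has >= 2 members.
random_lda_instance <- function(n, p, k) {
  repeat {
    y <- factor(sample(letters[seq_len(k)], n, replace = TRUE))
    if (all(table(y) >= 2)) break
  }
  x <- matrix(stats::rnorm(n * p), n, p) + as.integer(y)
  list(x = x, y = y)
}
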