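# Linear discriminant classifier used to score biomarker panels: Gaussian
# classes with a shared (pooled) covariance, empirical priors, posterior
# probabilities via the softmax of the linear discriminant functions, and
# the resubstitution accuracy / residual-probability loss metrics.

#' Fit a linear discriminant model
#'
#' Equal-covariance Gaussian classifier. The pooled within-class covariance
#' uses the n - k denominator; priors are the empirical class frequencies.
#' Discriminant scores are
#' `delta_c(x) = x' S^-1 mu_c - 0.5 mu_c' S^-1 mu_c + log pi_c`
#' and posteriors are their softmax. Discriminant axes (`scalings`, at most
#' `min(k - 1, p)`) come from the eigen-decomposition of
#' `S^-1 B` with `B` the prior-weighted between-class scatter, computed via
#' the symmetric whitened form; axis signs are fixed deterministically.
#'
#' If the pooled covariance is singular at `ridge = 0`, the fit is retried
#' with `ridge = 1e-6 * trace(S) / p` and a warning.
#'
#' @param x numeric samples x features matrix without missing values.
#' @param y class labels (2 or 3 classes; each with >= 2 samples).
#' @param ridge nonnegative diagonal regularization added to the pooled
#'   covariance.
#' @return object of class `senopanel_lda` with elements `class_labels`,
#'   `means`, `pooled_cov`, `priors`, `scalings`, `grand_mean`,
#'   `ridge_used`.
#' @export
fit_lda <- function(x, y, ridge = 0) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("x must not contain missing values (complete cases ",
                     "are enforced upstream)")
  y <- droplevels(as.factor(y))
  if (anyNA(y)) stop("y must not contain missing labels")
  if (nrow(x) != length(y)) stop("nrow(x) must equal length(y)")
  k <- nlevels(y)
  if (k < 2) stop("need at least 2 classes")
  cnt <- table(y)
  if (any(cnt < 2)) stop("every class needs >= 2 samples")
  if (ridge < 0) stop("ridge must be >= 0")
  n <- nrow(x); p <- ncol(x)
  if (n - k < 1) stop("too few samples for the pooled covariance")

  means <- do.call(rbind, lapply(levels(y), function(l)
    colMeans(x[y == l, , drop = FALSE])))
  rownames(means) <- levels(y)
  centered <- x - means[as.integer(y), , drop = FALSE]
  S <- crossprod(centered) / (n - k)
  S <- S + diag(ridge, p)

  ch <- tryCatch(chol(S), error = function(e) NULL)
  ridge_used <- ridge
  if (is.null(ch)) {
    if (ridge > 0) stop("pooled covariance singular even with ridge")
    ridge_used <- 1e-6 * sum(diag(S)) / p
    if (ridge_used <= 0) ridge_used <- 1e-6
    warning(sprintf("singular pooled covariance; refitting with ridge %.3g",
                    ridge_used))
    S <- S + diag(ridge_used, p)
    ch <- chol(S)
  }
  S_inv <- chol2inv(ch)

  priors <- as.numeric(cnt) / n
  names(priors) <- levels(y)
  grand_mean <- colSums(means * priors)

  # whitened between-class scatter: symmetric eigenproblem
  eS <- eigen(S, symmetric = TRUE)
  S_isqrt <- eS$vectors %*% (t(eS$vectors) / sqrt(pmax(eS$values,
                                                       .Machine$double.eps)))
  dm <- sweep(means, 2, grand_mean)
  B <- crossprod(dm * sqrt(priors))
  M <- S_isqrt %*% B %*% S_isqrt
  eM <- eigen((M + t(M)) / 2, symmetric = TRUE)
  m <- min(k - 1, p)
  scal <- S_isqrt %*% eM$vectors[, seq_len(m), drop = FALSE]
  for (j in seq_len(m)) { # deterministic sign: largest-|.| loading positive
    i <- which.max(abs(scal[, j]))
    if (scal[i, j] < 0) scal[, j] <- -scal[, j]
  }
  colnames(scal) <- paste0("LD", seq_len(m))

  structure(list(class_labels = levels(y), means = means, pooled_cov = S,
                 priors = priors, scalings = scal, grand_mean = grand_mean,
                 S_inv = S_inv, ridge_used = ridge_used, n = n),
            class = "senopanel_lda")
}

#' Predict posteriors, classes and discriminant coordinates
#'
#' @param object a fitted [fit_lda()] model.
#' @param newdata samples x features matrix with the model's feature count.
#' @param ... unused.
#' @return object of class `senopanel_prediction`: `posterior` (rows sum to
#'   1), `class` (argmax posterior; ties go to the first class in label
#'   order), `ld` (centered data projected on the discriminant axes).
#' @export
predict.senopanel_lda <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  storage.mode(x) <- "double"
  if (ncol(x) != ncol(object$means))
    stop("newdata has ", ncol(x), " columns; model expects ",
         ncol(object$means))
  A <- object$S_inv %*% t(object$means)            # p x k
  const <- -0.5 * colSums(t(object$means) * A) + log(object$priors)
  delta <- x %*% A + matrix(const, nrow(x), length(const), byrow = TRUE)
  delta_s <- delta - apply(delta, 1, max)
  post <- exp(delta_s)
  post <- post / rowSums(post)
  colnames(post) <- object$class_labels
  cls <- object$class_labels[max.col(post, ties.method = "first")]
  ld <- sweep(x, 2, object$grand_mean) %*% object$scalings
  structure(list(posterior = post,
                 class = factor(cls, levels = object$class_labels),
                 ld = ld),
            class = "senopanel_prediction")
}

#' Classification accuracy (percent)
#'
#' Fraction of samples whose predicted class equals the true class, as a
#' percentage: `(TP + TN) / (P + N)` for two classes, the overall fraction
#' correct for three.
#'
#' @param pred a `senopanel_prediction` (or a vector of predicted labels).
#' @param y true labels.
#' @return percent in \[0, 100\].
#' @export
accuracy <- function(pred, y) {
  lab <- if (inherits(pred, "senopanel_prediction")) pred$class else pred
  if (length(lab) == 0 || length(y) == 0) stop("empty input")
  if (length(lab) != length(y)) stop("length mismatch")
  100 * mean(as.character(lab) == as.character(y))
}

#' Residual-probability loss (percent)
#'
#' Mean, over samples, of the posterior probability the model assigns to
#' the *wrong* classes — i.e. `100 * mean(1 - P(true class | x))`. Zero for
#' perfect probabilistic predictions; can stay well above zero even at 100%
#' accuracy when posteriors are not confident.
#'
#' @param pred a `senopanel_prediction`.
#' @param y true labels (must all appear among the model's classes).
#' @return percent in \[0, 100\].
#' @export
residual_loss <- function(pred, y) {
  stopifnot(inherits(pred, "senopanel_prediction"))
  if (length(y) == 0) stop("empty input")
  if (nrow(pred$posterior) != length(y)) stop("length mismatch")
  idx <- match(as.character(y), colnames(pred$posterior))
  if (anyNA(idx)) stop("true label not among model classes")
  p_true <- pred$posterior[cbind(seq_along(idx), idx)]
  100 * mean(1 - p_true)
}
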