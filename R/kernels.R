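#' Two-sided Fisher exact test on a 2x2 table
#'
#' The two-sided p-value is the sum, over all tables sharing the observed
#' margins, of every hypergeometric table probability not exceeding the
#' observed table's probability (up to a relative slack of 1e-7). A table
#' with a zero row or column margin carries no information and returns
#' `p_value = 1` with `degenerate = TRUE`.
#'
#' @param tbl A 2x2 matrix of non-negative integer counts, or a length-4
#'   vector `c(a, b, c, d)` filled by row.
#' @return A one-row tibble with columns `p_value`, `odds_ratio` (conditional
#'   MLE, `NA` for degenerate tables) and `degenerate`.
#' @examples
#' fisher_exact_2x2(c(15, 23, 2, 27))
#' @export
fisher_exact_2x2 <- function(tbl) {
  tbl <- as_contingency(tbl)
  if (any(rowSums(tbl) == 0) || any(colSums(tbl) == 0)) {
    return(tibble(p_value = 1, odds_ratio = NA_real_, degenerate = TRUE))
  }
  ft <- stats::fisher.test(tbl)
  tibble(p_value = ft$p.value, odds_ratio = unname(ft$estimate), degenerate = FALSE)
}

as_contingency <- function(tbl) {
  if (is.vector(tbl) && length(tbl) == 4L) {
    tbl <- matrix(tbl, 2, 2, byrow = TRUE)
  }
  if (!is.matrix(tbl) || !all(dim(tbl) == c(2, 2))) {
    abort("`tbl` must be a 2x2 matrix or a length-4 count vector.")
  }
  if (any(!is.finite(tbl)) || any(tbl < 0) || any(tbl != round(tbl))) {
    abort("Contingency counts must be finite non-negative integers.")
  }
  if (sum(tbl) == 0) abort("Contingency table total must be positive.")
  tbl
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must all lie in [0, 1].")
  }
  stats::p.adjust(p, method = "BH")
}

#' Two-sample t test
#'
#' Pooled-variance (Student) test by default, matching the convention used
#' for the M1/M2 differential-expression comparisons; Welch available by flag.
#' Both groups constant at the same value returns `statistic = 0, p_value = 1`
#' (no evidence either way); constant groups at different values are an error
#' because the statistic is unbounded.
#'
#' @param x,y Numeric vectors, each with at least 2 values.
#' @param welch Use the Welch unequal-variance form.
#' @return One-row tibble: `statistic`, `p_value`, `diff_means` (mean(x) - mean(y)).
#' @export
two_sample_t <- function(x, y, welch = FALSE) {
  if (length(x) < 2 || length(y) < 2) abort("Each group needs at least 2 values.")
  if (any(!is.finite(x)) || any(!is.finite(y))) abort("Inputs must be finite.")
  d <- mean(x) - mean(y)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (d == 0) return(tibble(statistic = 0, p_value = 1, diff_means = 0))
    abort("Both groups are constant with different means: t statistic undefined.")
  }
  tt <- stats::t.test(x, y, var.equal = !welch)
  tibble(statistic = unname(tt$statistic), p_value = tt$p.value, diff_means = d)
}

#' Correlation with p-value
#'
#' `spearman_cor()` computes Spearman's rho via midranks with the
#' t-approximation p-value (the form used by the surrogate voting filter);
#' `pearson_cor()` is the product-moment correlation used against continuous
#' TAM counts.
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @return One-row tibble with `estimate` and `p_value`.
#' @export
spearman_cor <- function(x, y) {
  check_cor_input(x, y)
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    abort("Correlation undefined for a constant vector.")
  }
  rho <- stats::cor(rx, ry)
  tibble(estimate = rho, p_value = cor_t_pvalue(rho, length(x)))
}

#' @rdname spearman_cor
#' @export
pearson_cor <- function(x, y) {
  check_cor_input(x, y)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("Correlation undefined for a constant vector.")
  }
  r <- stats::cor(x, y)
  tibble(estimate = r, p_value = cor_t_pvalue(r, length(x)))
}

check_cor_input <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3) abort("Correlation requires at least 3 pairs.")
  if (any(!is.finite(x)) || any(!is.finite(y))) abort("Inputs must be finite.")
  invisible(NULL)
}

cor_t_pvalue <- function(r, n) {
  r <- min(1, max(-1, r))
  if (abs(r) == 1) return(0)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Probability that a randomly chosen positive outscores a randomly chosen
#' negative, with ties counted one half: `U / (n_pos * n_neg)` where U is the
#' midrank Mann-Whitney statistic.
#'
#' @param scores Numeric scores, higher = more positive-like.
#' @param labels Logical (`TRUE` = positive) or a factor/character vector with
#'   `positive` naming the positive level.
#' @param positive Positive label when `labels` is not logical.
#' @return A single AUC value in \[0, 1\].
#' @export
auc_mann_whitney <- function(scores, labels, positive = "HIGH") {
  pos <- as_positive(labels, positive)
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    abort("AUC undefined: both label classes must be present.")
  }
  r <- rank(scores)
  u <- sum(r[pos]) - n_pos * (n_pos + 1) / 2
  u / (n_pos * n_neg)
}

as_positive <- function(labels, positive) {
  if (is.logical(labels)) return(labels)
  as.character(labels) == positive
}

#' Youden-optimal dichotomization threshold
#'
#' Candidate thresholds are midpoints between consecutive distinct sorted
#' scores plus -Inf/+Inf guards; the classification rule is
#' `score > threshold -> positive`. Returns the candidate maximizing
#' J = sensitivity + specificity - 1, ties broken by the smallest threshold.
#' When every score is identical only the guards remain; J = 0 and the result
#' is flagged degenerate.
#'
#' @inheritParams auc_mann_whitney
#' @return One-row tibble: `threshold`, `j` (Youden index), `degenerate`.
#' @export
youden_threshold <- function(scores, labels, positive = "HIGH") {
  pos <- as_positive(labels, positive)
  if (!any(pos) || all(pos)) abort("Youden threshold requires both classes.")
  s <- sort(unique(scores))
  cand <- c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf)
  j <- vapply(cand, function(thr) {
    sens <- mean(scores[pos] > thr)
    spec <- mean(scores[!pos] <= thr)
    sens + spec - 1
  }, numeric(1))
  best <- which.max(j)  # which.max returns the first (smallest threshold) tie
  tibble(
    threshold = cand[best],
    j = j[best],
    degenerate = length(s) == 1
  )
}

#' Non-negative least squares
#'
#' Minimizes ||Xw - y||^2 subject to w >= 0, no intercept (the surrogate
#' score is a pure weighted probe sum). Solved by the Lawson-Hanson active-set
#' algorithm; the Karush-Kuhn-Tucker conditions are verified on the returned
#' solution.
#'
#' @param X Numeric matrix, n rows (observations) x k columns (features),
#'   n >= k >= 1.
#' @param y Numeric response of length n.
#' @param tol KKT feasibility tolerance.
#' @return List with `weights` (length k, named from `colnames(X)`),
#'   `residual_norm`, `kkt_ok`, `rank_deficient`.
#' @export
nnls_fit <- function(X, y, tol = 1e-8) {
  X <- as.matrix(X)
  if (!is.numeric(X) || any(!is.finite(X))) abort("`X` must be a finite numeric matrix.")
  if (length(y) != nrow(X)) abort("`y` must have one value per row of `X`.")
  if (any(!is.finite(y))) abort("`y` must be finite.")
  if (ncol(X) < 1 || nrow(X) < ncol(X)) abort("Need n >= k >= 1.")
  fit <- pracma::lsqnonneg(X, as.numeric(y))
  w <- fit$x
  names(w) <- colnames(X)
  grad <- drop(crossprod(X, X %*% w - y))  # KKT: grad >= 0, grad[w > 0] == 0
  scale <- max(1, sum(abs(crossprod(X, y))))
  kkt_ok <- all(grad >= -tol * scale) && all(abs(grad[w > 0]) <= tol * scale)
  list(
    weights = w,
    residual_norm = sqrt(sum((X %*% w - y)^2)),
    kkt_ok = kkt_ok,
    rank_deficient = qr(X)$rank < ncol(X)
  )
}
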