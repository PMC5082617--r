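#' Confusion-matrix metrics
#'
#' Accuracy, precision, recall and F-measure (harmonic mean of precision and
#' recall) of binary predictions. The positive class defaults to 1. F is
#' defined as 0 when precision + recall = 0.
#'
#' @param y_true,y_pred equal-length binary vectors (0/1, logical, or the
#'   same two values).
#' @param positive the positive class value. Default `1`.
#' @return Named numeric vector: `accuracy`, `precision`, `recall`,
#'   `f_measure`, all in `[0, 1]`.
#' @export
confusion_metrics <- function(y_true, y_pred, positive = 1) {
  stopifnot(length(y_true) == length(y_pred))
  tp <- sum(y_true == positive & y_pred == positive)
  fp <- sum(y_true != positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  acc <- mean(y_true == y_pred)
  pr <- if (tp + fp > 0) tp / (tp + fp) else 0
  re <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (pr + re > 0) 2 * pr * re / (pr + re) else 0
  c(accuracy = acc, precision = pr, recall = re, f_measure = f)
}

#' Mutual information between true and predicted labels
#'
#' `MI = sum_{c_hat, c} p(c_hat, c) * log2( p(c_hat, c) / (p(c_hat) p(c)) )`
#' over the empirical joint distribution, with `0 * log 0 := 0`. For binary
#' labels MI is at most 1 bit, attained by a perfect (or perfectly
#' anti-correlated) prediction on balanced labels.
#'
#' @inheritParams confusion_metrics
#' @return A list with `bits` (MI in bits) and `percent` (`100 * bits`,
#'   i.e. percent of the 1-bit maximum).
#' @export
mutual_information <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  n <- length(y_true)
  joint <- table(factor(y_pred, levels = sort(unique(c(y_true, y_pred)))),
                 factor(y_true, levels = sort(unique(c(y_true, y_pred))))) / n
  ph <- rowSums(joint); pc <- colSums(joint)
  mi <- 0
  for (i in seq_along(ph)) {
    for (j in seq_along(pc)) {
      pij <- joint[i, j]
      if (pij > 0) mi <- mi + pij * log2(pij / (ph[i] * pc[j]))
    }
  }
  mi <- max(mi, 0)
  list(bits = mi, percent = 100 * mi)
}

#' Empirical AUC of predicted probabilities
#'
#' Rank-based area under the ROC curve of the positive-class probability
#' against the truth; tied probabilities count 1/2.
#'
#' @param y_true binary truth vector (0/1 or logical).
#' @param prob numeric scores or probabilities for the positive class.
#' @param positive the positive class value. Default `1`.
#' @return AUC in `[0, 1]`.
#' @export
classifier_auc <- function(y_true, prob, positive = 1) {
  stopifnot(length(y_true) == length(prob))
  pos <- y_true == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    stop("AUC is undefined when only one class is present", call. = FALSE)
  }
  r <- rank(prob)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Two-sided Mann-Whitney rank-sum comparison of two result sets
#'
#' Tests the null hypothesis that the two sets come from distributions with
#' equal location. For `m + n <= 12` observations the p-value is exact, by
#' enumerating all assignments of the pooled midranks; otherwise the
#' tie-corrected normal approximation to the U statistic is used (no
#' continuity correction).
#'
#' @param a,b numeric vectors (each of length >= 2), e.g. two sets of
#'   repeated cross-validation accuracies.
#' @return Two-sided p-value in `(0, 1]`.
#' @export
#' @examples
#' mann_whitney_compare(c(1, 2, 3), c(4, 5, 6))  # exact 2/20 = 0.1
mann_whitney_compare <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  m <- length(a); n <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  mu <- m * n / 2
  if (m + n <= 12L) {
    combos <- utils::combn(m + n, m)
    dev_obs <- abs(u_obs - mu)
    u_all <- colSums(matrix(r[combos], nrow = m)) - m * (m + 1) / 2
    p <- mean(abs(u_all - mu) >= dev_obs - 1e-12)
  } else {
    N <- m + n
    tt <- table(pooled)
    tie <- sum(tt^3 - tt) / (N * (N - 1))
    v <- m * n / 12 * ((N + 1) - tie)
    if (v <= 0) return(1)
    z <- (u_obs - mu) / sqrt(v)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  p
}
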