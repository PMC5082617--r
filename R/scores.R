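#' Per-class summary of one gene's expression values
#'
#' @param x1,x2 numeric vectors of values in class 1 and class 2
#'   (each of length >= 2).
#' @return A list with class means `mu1`, `mu2`, unbiased (n-1 denominator)
#'   standard deviations `sigma1`, `sigma2`, and sizes `n1`, `n2`.
#' @export
class_summary <- function(x1, x2) {
  if (length(x1) < 2L || length(x2) < 2L) {
    stop("each class needs at least two samples", call. = FALSE)
  }
  list(mu1 = mean(x1), mu2 = mean(x2),
       sigma1 = stats::sd(x1), sigma2 = stats::sd(x2),
       n1 = length(x1), n2 = length(x2))
}

# guards shared by the normal-theory scores
.var_floor <- 1e-8
.t_cap <- 1e8

#' Absolute two-sample t statistic
#'
#' `|mu1 - mu2| / sqrt(sigma1^2/n1 + sigma2^2/n2)` (Welch denominator).
#' Larger values indicate stronger class separation. If both class variances
#' are zero the score is 0 for equal means and capped at `1e8` otherwise.
#'
#' @param s a [class_summary()].
#' @return Non-negative scalar.
#' @export
t_score <- function(s) {
  se2 <- s$sigma1^2 / s$n1 + s$sigma2^2 / s$n2
  if (se2 <= 0) {
    return(if (s$mu1 == s$mu2) 0 else .t_cap)
  }
  min(abs(s$mu1 - s$mu2) / sqrt(se2), .t_cap)
}

#' Symmetric Kullback-Leibler (entropy) score
#'
#' For per-class normal fits, the symmetrized relative entropy
#' `0.5 * (s1^2/s2^2 + s2^2/s1^2 - 2 + (1/s1^2 + 1/s2^2) * (mu1 - mu2)^2)`.
#' Zero iff the two classes share mean and variance. Variances are floored
#' at `1e-8` so constant classes stay finite.
#'
#' @inheritParams t_score
#' @return Non-negative scalar.
#' @export
entropy_score <- function(s) {
  v1 <- max(s$sigma1^2, .var_floor)
  v2 <- max(s$sigma2^2, .var_floor)
  0.5 * (v1 / v2 + v2 / v1 - 2 + (1 / v1 + 1 / v2) * (s$mu1 - s$mu2)^2)
}

#' Bhattacharyya distance between per-class normal fits
#'
#' `0.25 * log(0.25 * (s1^2/s2^2 + s2^2/s1^2 + 2)) +
#'  0.25 * (mu1 - mu2)^2 / (s1^2 + s2^2)`.
#' Zero iff the class distributions coincide. Variances floored at `1e-8`.
#'
#' @inheritParams t_score
#' @return Non-negative scalar.
#' @export
bhattacharyya_score <- function(s) {
  v1 <- max(s$sigma1^2, .var_floor)
  v2 <- max(s$sigma2^2, .var_floor)
  0.25 * log(0.25 * (v1 / v2 + v2 / v1 + 2)) +
    0.25 * (s$mu1 - s$mu2)^2 / (v1 + v2)
}

# midrank sum of the smaller group plus its null moments (tie-corrected)
wilcoxon_parts <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  pooled <- c(x1, x2)
  r <- rank(pooled)                       # midranks
  smaller_first <- n1 <= n2
  ns <- if (smaller_first) n1 else n2
  W <- if (smaller_first) sum(r[seq_len(n1)]) else sum(r[n1 + seq_len(n2)])
  n <- n1 + n2
  EW <- ns * (n + 1) / 2
  tt <- table(pooled)
  tie_term <- sum(tt^3 - tt) / (n * (n - 1))
  VW <- n1 * n2 / 12 * ((n + 1) - tie_term)
  list(W = W, EW = EW, VW = VW)
}

#' Absolute standardized Wilcoxon rank-sum score
#'
#' The rank sum `W` of the smaller group over the pooled midranked sample is
#' standardized by its null moments, `|W - E[W]| / sd[W]`, with the
#' tie-corrected variance. Invariant under strictly monotone transforms of
#' the values. Returns 0 when all pooled values are identical.
#'
#' @param x1,x2 numeric value vectors for the two classes (lengths >= 2).
#' @return Non-negative scalar.
#' @export
wilcoxon_score <- function(x1, x2) {
  p <- wilcoxon_parts(x1, x2)
  if (p$VW <= 0) return(0)
  abs(p$W - p$EW) / sqrt(p$VW)
}

#' Folded empirical AUC score
#'
#' The empirical probability that a class-2 value exceeds a class-1 value
#' (ties count 1/2), folded as `max(AUC, 1 - AUC)` so both directions of
#' regulation score high. 0.5 means complete overlap, 1 perfect separation.
#'
#' @inheritParams wilcoxon_score
#' @return Scalar in `[0.5, 1]`.
#' @export
auc_score <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  r <- rank(c(x1, x2))
  u2 <- sum(r[n1 + seq_len(n2)]) - n2 * (n2 + 1) / 2
  auc <- u2 / (n1 * n2)
  max(auc, 1 - auc)
}

#' Score every gene on the five filter criteria
#'
#' Computes, per gene, the absolute t statistic, symmetric KL entropy,
#' Bhattacharyya distance, standardized Wilcoxon rank sum, and folded
#' empirical AUC, from its (transformed) expression values split by class.
#' These five columns are the criteria later aggregated by grey relational
#' analysis.
#'
#' @param values genes-by-samples numeric matrix (typically log2 CPM from
#'   [voom_transform()]).
#' @param labels a [label_vector].
#' @param check if `TRUE` (default), raise an error naming the criterion if
#'   any score column is constant across genes, since min-max normalization
#'   downstream would degenerate.
#' @return Numeric matrix, genes x 5, columns
#'   `t`, `entropy`, `bhattacharyya`, `wilcoxon`, `auc`; all entries finite
#'   and non-negative.
#' @export
score_genes <- function(values, labels, check = TRUE) {
  stopifnot(inherits(labels, "label_vector"))
  values <- as.matrix(values)
  cls <- labels$labels
  if (length(cls) != ncol(values)) {
    stop("labels and value matrix disagree on sample count", call. = FALSE)
  }
  i1 <- which(cls == 0L); i2 <- which(cls == 1L)
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2L || n2 < 2L) stop("each class needs >= 2 samples", call. = FALSE)
  x1 <- values[, i1, drop = FALSE]
  x2 <- values[, i2, drop = FALSE]

  mu1 <- rowMeans(x1); mu2 <- rowMeans(x2)
  v1 <- rowSums((x1 - mu1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - mu2)^2) / (n2 - 1)

  se2 <- v1 / n1 + v2 / n2
  tsc <- ifelse(se2 > 0, abs(mu1 - mu2) / sqrt(pmax(se2, 1e-300)),
                ifelse(mu1 == mu2, 0, .t_cap))
  tsc <- pmin(tsc, .t_cap)

  fv1 <- pmax(v1, .var_floor); fv2 <- pmax(v2, .var_floor)
  esc <- 0.5 * (fv1 / fv2 + fv2 / fv1 - 2 +
                  (1 / fv1 + 1 / fv2) * (mu1 - mu2)^2)
  bsc <- 0.25 * log(0.25 * (fv1 / fv2 + fv2 / fv1 + 2)) +
    0.25 * (mu1 - mu2)^2 / (fv1 + fv2)

  n <- n1 + n2
  ranks <- t(apply(values, 1L, rank))
  smaller <- if (n1 <= n2) i1 else i2
  ns <- length(smaller)
  W <- rowSums(ranks[, smaller, drop = FALSE])
  EW <- ns * (n + 1) / 2
  tie_term <- apply(values, 1L, function(v) {
    tt <- table(v)
    sum(tt^3 - tt)
  }) / (n * (n - 1))
  VW <- n1 * n2 / 12 * ((n + 1) - tie_term)
  wsc <- ifelse(VW > 0, abs(W - EW) / sqrt(pmax(VW, 1e-300)), 0)

  u2 <- rowSums(ranks[, i2, drop = FALSE]) - n2 * (n2 + 1) / 2
  auc <- u2 / (n1 * n2)
  asc <- pmax(auc, 1 - auc)

  out <- cbind(t = tsc, entropy = esc, bhattacharyya = bsc,
               wilcoxon = wsc, auc = asc)
  rownames(out) <- rownames(values)
  if (check) {
    rng <- apply(out, 2L, function(col) diff(range(col)))
    if (any(rng == 0)) {
      stop("criterion column(s) constant across genes: ",
           paste(colnames(out)[rng == 0], collapse = ", "), call. = FALSE)
    }
  }
  out
}
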