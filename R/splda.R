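## Sparse Poisson linear discriminant analysis on raw counts: per-class
## gene profiles d_kj soft-thresholded toward 1, Poisson log-likelihood
## discriminant, and size factors by total count, median ratio, or 75th
## percentile.

#' Size factors for sPLDA
#'
#' Estimates per-sample sequencing-depth normalizers from a training count
#' matrix, and optionally for test count profiles using training-derived
#' references.
#'
#' * `total`: `s_i = X_i. / X..` (training factors sum to 1); a test profile
#'   gets `s* = sum(x*) / X..`.
#' * `median_ratio`: `m_i` is the median over reference genes (those with
#'   strictly positive counts in all training samples) of
#'   `X_ij / geomean_j`; `s_i = m_i / sum(m)`. Test profiles reuse the
#'   training geometric means.
#' * `quantile`: `q_i` is the 75th percentile of sample `i`'s counts
#'   (linear interpolation between order statistics); `s_i = q_i / sum(q)`;
#'   `s* = q* / sum(q)`.
#'
#' @param counts genes-by-samples matrix of training counts, or a
#'   [count_matrix].
#' @param method `"total"`, `"median_ratio"`, or `"quantile"`.
#' @param test optional genes-by-samples matrix (or vector, one profile) of
#'   test counts.
#' @return A list with `train` (positive numeric vector, one per training
#'   sample) and, when `test` is given, `test` (one per test profile).
#' @export
size_factors <- function(counts,
                         method = c("total", "median_ratio", "quantile"),
                         test = NULL) {
  method <- match.arg(method)
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  counts <- as.matrix(counts)
  if (!is.null(test)) {
    test <- if (is.null(dim(test))) matrix(test, ncol = 1L) else as.matrix(test)
    if (nrow(test) != nrow(counts)) {
      stop("test profiles must have the same genes as training", call. = FALSE)
    }
  }
  if (method == "total") {
    tot <- sum(counts)
    cs <- colSums(counts)
    if (any(cs <= 0)) stop("zero-count training sample", call. = FALSE)
    s <- cs / tot
    st <- if (!is.null(test)) colSums(test) / tot
  } else if (method == "median_ratio") {
    ref <- rowSums(counts > 0) == ncol(counts)
    if (!any(ref)) {
      stop("no gene has positive counts in all training samples; ",
           "use the total-count method", call. = FALSE)
    }
    geo <- exp(rowMeans(log(counts[ref, , drop = FALSE])))
    m <- apply(counts[ref, , drop = FALSE] / geo, 2L, stats::median)
    if (any(m <= 0)) stop("non-positive median ratio", call. = FALSE)
    s <- m / sum(m)
    st <- if (!is.null(test)) {
      apply(test[ref, , drop = FALSE] / geo, 2L, stats::median) / sum(m)
    }
  } else {
    q <- apply(counts, 2L, stats::quantile, probs = 0.75, names = FALSE)
    if (any(q <= 0)) stop("zero 75th percentile in training sample(s)",
                          call. = FALSE)
    s <- q / sum(q)
    st <- if (!is.null(test)) {
      apply(test, 2L, stats::quantile, probs = 0.75, names = FALSE) / sum(q)
    }
  }
  out <- list(train = s)
  if (!is.null(test)) out$test <- st
  out
}

#' Soft-thresholded class/gene Poisson profile estimates
#'
#' For class `k` and gene `j`, with `a = X_{C_k j} + beta` (class count plus
#' pseudocount) and `b = sum_{i in C_k} s_i * g_j + beta` (expected class
#' count under the null), the estimate is `a/b` shrunk toward 1 by `rho/b`:
#' `a/b - rho/b` when `b(a/b - 1) > rho`, `a/b + rho/b` when
#' `b(1 - a/b) > rho`, and exactly 1 otherwise. Genes with all `d_kj = 1`
#' take no part in classification, so `rho` controls sparsity.
#'
#' @param counts genes-by-samples training counts.
#' @param labels a [label_vector] (or 0/1 integer vector).
#' @param si per-training-sample size factors.
#' @param beta positive pseudocount. Default 1.
#' @param rho non-negative soft-threshold tuning parameter. Default 0.
#' @return A 2-by-genes matrix of positive estimates `d_kj` (rows = classes).
#' @export
estimate_dkj <- function(counts, labels, si, beta = 1, rho = 0) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  cls <- if (inherits(labels, "label_vector")) labels$labels else labels
  stopifnot(beta > 0, rho >= 0, length(si) == ncol(counts))
  gj <- rowSums(counts)
  d <- matrix(NA_real_, 2L, nrow(counts),
              dimnames = list(NULL, rownames(counts)))
  for (k in 0:1) {
    ik <- which(cls == k)
    a <- rowSums(counts[, ik, drop = FALSE]) + beta
    b <- sum(si[ik]) * gj + beta
    ratio <- a / b
    excess <- b * (ratio - 1)
    dk <- ifelse(excess > rho, ratio - rho / b,
                 ifelse(-excess > rho, ratio + rho / b, 1))
    d[k + 1L, ] <- dk
  }
  d
}

#' Fit a sparse Poisson linear discriminant classifier
#'
#' Models counts in class `k` as Poisson with mean `s_i * g_j * d_kj`, where
#' `g_j` is the gene's total training count, `s_i` a size factor, and `d_kj`
#' the soft-thresholded class profile of [estimate_dkj()]. Operates directly
#' on raw counts (no transformation).
#'
#' @param cm a [count_matrix] or genes-by-samples count matrix (training).
#' @param labels a [label_vector].
#' @param size_factor size-factor method, see [size_factors()].
#' @param rho non-negative soft threshold; larger values use fewer genes.
#' @param beta positive pseudocount. Default 1.
#' @param priors class prior probabilities summing to 1. Default equal.
#' @return An object of class `splda` with elements `dkj`, `gj`, `si`,
#'   `rho`, `beta`, `priors`, `size_factor`, and the training references
#'   needed to compute test size factors.
#' @export
#' @examples
#' sim <- simulate_counts(n_genes = 30, n_per_class = c(5, 5), seed = 1)
#' fit <- splda(sim$counts, sim$labels, rho = 0)
#' predict(fit, sim$counts$counts[, 1:2])$class
splda <- function(cm, labels,
                  size_factor = c("total", "median_ratio", "quantile"),
                  rho = 0, beta = 1, priors = c(0.5, 0.5)) {
  size_factor <- match.arg(size_factor)
  counts <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  stopifnot(inherits(labels, "label_vector"),
            length(priors) == 2L, all(priors > 0),
            abs(sum(priors) - 1) < 1e-8)
  si <- size_factors(counts, size_factor)$train
  dkj <- estimate_dkj(counts, labels$labels, si, beta = beta, rho = rho)
  structure(list(dkj = dkj, gj = rowSums(counts), si = si, rho = rho,
                 beta = beta, priors = priors, size_factor = size_factor,
                 class_names = labels$class_names,
                 train_counts = counts),
            class = "splda")
}

#' Classify count profiles with a fitted sPLDA model
#'
#' Assigns each test profile to the class maximizing
#' `sum_j x*_j log d_kj - s* sum_j g_j d_kj + log pi_k`. Ties break toward
#' the lower class index.
#'
#' @param object a fitted [splda()] model.
#' @param newdata genes-by-samples count matrix (or a single profile vector)
#'   over the training genes.
#' @param ... unused.
#' @return A list with `class` (character labels), `scores` (samples-by-2
#'   discriminant matrix), and `prob` (softmax of the scores, probability of
#'   the second class).
#' @export
predict.splda <- function(object, newdata, ...) {
  x <- if (is.null(dim(newdata))) matrix(newdata, ncol = 1L)
       else as.matrix(newdata)
  if (nrow(x) != length(object$gj)) {
    stop("newdata has ", nrow(x), " genes; model expects ",
         length(object$gj), call. = FALSE)
  }
  sstar <- size_factors(object$train_counts, object$size_factor,
                        test = x)$test
  scores <- matrix(NA_real_, ncol(x), 2L,
                   dimnames = list(colnames(x), object$class_names))
  for (k in 1:2) {
    dk <- object$dkj[k, ]
    scores[, k] <- drop(crossprod(x, log(dk))) -
      sstar * sum(object$gj * dk) + log(object$priors[k])
  }
  cls_idx <- max.col(scores, ties.method = "first")
  delta <- scores[, 2L] - scores[, 1L]
  list(class = object$class_names[cls_idx], scores = scores,
       prob = stats::plogis(delta))
}

#' Number of genes involved in an sPLDA rule
#'
#' A gene takes part in classification iff any of its class profiles
#' `d_kj` differs from 1; soft thresholding with larger `rho` silences more
#' genes.
#'
#' @param object a fitted [splda()] model.
#' @return Integer count of involved genes.
#' @export
involved_features <- function(object) {
  stopifnot(inherits(object, "splda"))
  sum(apply(object$dkj != 1, 2L, any))
}

#' @export
print.splda <- function(x, ...) {
  cat("Sparse Poisson LDA (", x$size_factor, " size factors)\n", sep = "")
  cat("  genes:", length(x$gj), " training samples:", length(x$si), "\n")
  cat("  rho:", x$rho, " beta:", x$beta,
      " involved genes:", involved_features(x), "\n")
  invisible(x)
}

#' Choose the sPLDA soft threshold by cross-validation
#'
#' Runs stratified k-fold cross-validation on the training data over a grid
#' of `rho` values and returns the value maximizing CV accuracy; ties break
#' toward the larger (sparser) `rho`. Also reports, per grid value, how many
#' genes the full-data rule would involve.
#'
#' @inheritParams splda
#' @param grid non-negative `rho` values; by default 0 plus 29 log-spaced
#'   values up to the smallest `rho` that silences every gene.
#' @param folds number of CV folds. Default 5.
#' @param seed integer seed for the fold assignment.
#' @return A list with `rho` (chosen value), `accuracy` (per grid value),
#'   `n_features` (involved-gene count per grid value), and `grid`.
#' @export
splda_tune_rho <- function(cm, labels,
                           size_factor = c("total", "median_ratio", "quantile"),
                           grid = NULL, folds = 5L, seed = 1L, beta = 1) {
  size_factor <- match.arg(size_factor)
  counts <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  cls <- labels$labels
  if (min(table(cls)) < folds) {
    stop("each class needs >= ", folds, " samples for ", folds,
         "-fold tuning", call. = FALSE)
  }
  if (is.null(grid)) {
    si <- size_factors(counts, size_factor)$train
    gj <- rowSums(counts)
    rho_max <- 0
    for (k in 0:1) {
      ik <- which(cls == k)
      a <- rowSums(counts[, ik, drop = FALSE]) + beta
      b <- sum(si[ik]) * gj + beta
      rho_max <- max(rho_max, b * abs(1 - a / b))
    }
    grid <- c(0, exp(seq(log(rho_max * 1e-4), log(rho_max * 1.0001),
                         length.out = 29L)))
  }
  grid <- sort(unique(grid))
  set.seed(seed)
  fold <- integer(length(cls))
  for (k in 0:1) {
    ik <- which(cls == k)
    fold[ik] <- sample(rep_len(seq_len(folds), length(ik)))
  }
  acc <- numeric(length(grid))
  for (g in seq_along(grid)) {
    correct <- 0L
    for (fd in seq_len(folds)) {
      tr <- fold != fd
      fit <- splda(counts[, tr, drop = FALSE],
                   label_vector(cls[tr], class_names = c("0", "1")),
                   size_factor = size_factor, rho = grid[g], beta = beta)
      pred <- predict(fit, counts[, !tr, drop = FALSE])$class
      correct <- correct + sum(pred == as.character(cls[!tr]))
    }
    acc[g] <- correct / length(cls)
  }
  nfeat <- vapply(grid, function(r) {
    involved_features(splda(counts, labels, size_factor = size_factor,
                            rho = r, beta = beta))
  }, integer(1))
  best <- max(which(acc == max(acc)))   # ties -> larger rho (sparser)
  list(rho = grid[best], accuracy = acc, n_features = nfeat, grid = grid)
}
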