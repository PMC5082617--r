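#' Log counts per million
#'
#' Converts read counts to log2 counts per million. An offset keeps zeros
#' finite: `log2((count + offset) / (libsize + 2 * offset) * 1e6)`, where the
#' library size is the column sum of counts. Monotone in the count within a
#' column, so within-sample orderings are preserved.
#'
#' @param cm a [count_matrix], or a plain non-negative matrix with genes in
#'   rows.
#' @param offset positive pseudo-count added to each cell; `2 * offset` is
#'   added to each library size. Default 0.5.
#' @return Numeric matrix of log2-CPM values, same shape and dimnames.
#' @export
log_cpm <- function(cm, offset = 0.5) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  stopifnot(offset > 0)
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("zero library size in column(s): ",
                          paste(which(lib <= 0), collapse = ", "),
                          call. = FALSE)
  t(log2(t(counts + offset) / (lib + 2 * offset) * 1e6))
}

# Least-squares residual sd per gene for a common design across genes.
# values: genes x samples, design: samples x p (full rank).
gene_lm <- function(values, design) {
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) stop("design matrix is not of full rank",
                                    call. = FALSE)
  n <- ncol(values)
  df <- n - qrd$rank
  if (df < 1L) stop("fewer samples than design parameters plus one",
                    call. = FALSE)
  ty <- t(values)
  fitted <- t(qr.fitted(qrd, ty))
  resid <- values - fitted
  sigma <- sqrt(rowSums(resid^2) / df)
  list(fitted = fitted, sigma = sigma, coef = qr.coef(qrd, ty), df = df)
}

#' Fit the mean-variance trend of log-CPM values
#'
#' After regressing each gene's log2-CPM values on the sample-level design,
#' the per-gene points (mean log2 count, sqrt of residual standard deviation)
#' are smoothed with lowess. The returned trend predicts the square-root
#' standard deviation at any mean log2 count, extrapolating flat beyond the
#' data range so predictions stay positive far from the fitted points.
#'
#' @param values genes-by-samples matrix of log2-CPM values.
#' @param design samples-by-parameters model matrix (full rank).
#' @param lib_size per-sample library sizes used to place points on the
#'   log2-count (rather than log2-CPM) scale.
#' @param span lowess span. Default 0.5.
#' @return A list with `trend` (a function mapping mean log2 count to
#'   predicted sqrt standard deviation), and the scatter `x`, `y` it was
#'   fitted to.
#' @export
fit_mean_variance_trend <- function(values, design, lib_size, span = 0.5) {
  if (nrow(values) < 10L) {
    stop("at least 10 genes are needed to fit a mean-variance trend",
         call. = FALSE)
  }
  fit <- gene_lm(values, design)
  sx <- rowMeans(values) + mean(log2(lib_size + 1)) - log2(1e6)
  sy <- sqrt(fit$sigma)
  lo <- stats::lowess(sx, sy, f = span)
  keep <- !duplicated(lo$x)
  trend <- stats::approxfun(lo$x[keep], lo$y[keep], rule = 2)
  list(trend = trend, x = sx, y = sy)
}

#' Transform counts to log-CPM with precision weights
#'
#' The voom-style transformation: counts become log2 counts per million
#' ([log_cpm()]), each gene is regressed on a design of intercept, class and
#' (optionally) batch, the mean-variance trend of the residual standard
#' deviations is fitted with [fit_mean_variance_trend()], and each
#' observation receives the inverse fourth power of its predicted square-root
#' standard deviation as a precision weight. Weighting counteracts the
#' count-data mean-variance dependence so that normal-based statistics can be
#' applied downstream.
#'
#' When `batch` is supplied the design gains one indicator column per extra
#' batch level, so residual variances (hence weights) are estimated net of
#' the batch effect. The values themselves are only adjusted for batch when
#' `remove_batch = TRUE`, which subtracts the fitted batch terms.
#'
#' @param cm a [count_matrix].
#' @param labels a [label_vector] (two classes).
#' @param batch per-sample batch factor; defaults to the batch attached to
#'   `cm`. Pass `NULL` to ignore any attached batch.
#' @param span lowess span for the trend. Default 0.5.
#' @param offset pseudo-count for [log_cpm()]. Default 0.5.
#' @param remove_batch if `TRUE`, subtract fitted batch effects from the
#'   returned values. Default `FALSE`.
#' @return An object of class `voomed`: list with `values` (log2 CPM),
#'   `weights` (strictly positive, same shape), `design`, and `trend`.
#' @export
#' @examples
#' sim <- simulate_counts(n_genes = 50, n_per_class = c(5, 5), seed = 1)
#' v <- voom_transform(sim$counts, sim$labels)
#' range(v$weights)
voom_transform <- function(cm, labels, batch = cm$batch, span = 0.5,
                           offset = 0.5, remove_batch = FALSE) {
  stopifnot(inherits(cm, "count_matrix"), inherits(labels, "label_vector"))
  cls <- labels$labels
  if (length(cls) != ncol(cm$counts)) {
    stop("labels and count matrix disagree on sample count", call. = FALSE)
  }
  dat <- data.frame(class = factor(cls))
  form <- ~class
  if (!is.null(batch)) {
    batch <- factor(batch)
    if (nlevels(batch) > 1L) {
      dat$batch <- batch
      form <- ~ class + batch
    }
  }
  design <- stats::model.matrix(form, dat)
  rownames(design) <- cm$sample_ids

  lib <- colSums(cm$counts)
  values <- log_cpm(cm, offset = offset)
  mv <- fit_mean_variance_trend(values, design, lib, span = span)
  fit <- gene_lm(values, design)
  # predicted log2 count for each observation: fitted log-CPM put back on
  # the count scale of its own library
  fitted_logcount <- fit$fitted +
    matrix(log2((lib + 1) / 1e6), nrow(values), ncol(values), byrow = TRUE)
  pred_sqrt_sd <- pmax(mv$trend(fitted_logcount), 1e-6)
  weights <- matrix(pred_sqrt_sd^(-4), nrow(values), ncol(values),
                    dimnames = dimnames(values))
  if (remove_batch && !is.null(dat$batch)) {
    bcols <- grep("^batch", colnames(design))
    values <- values - t(design[, bcols, drop = FALSE] %*%
                           fit$coef[bcols, , drop = FALSE])
  }
  structure(list(values = values, weights = weights, design = design,
                 trend = mv$trend), class = "voomed")
}

#' @export
print.voomed <- function(x, ...) {
  cat("voomed log2-CPM matrix:", nrow(x$values), "genes x",
      ncol(x$values), "samples\n")
  cat("  design columns:", paste(colnames(x$design), collapse = ", "), "\n")
  cat("  weight range: [", format(min(x$weights), digits = 4), ", ",
      format(max(x$weights), digits = 4), "]\n", sep = "")
  invisible(x)
}
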