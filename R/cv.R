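## Repeated stratified k-fold cross-validation of the full pipeline:
## log-CPM transform, five filter scores, grey relational top-k selection,
## then a GP (or sPLDA) classifier — selection and training confined to the
## training folds by default so test metrics are leakage-free.

stratified_folds <- function(cls, n_folds) {
  fold <- integer(length(cls))
  for (k in unique(cls)) {
    ik <- which(cls == k)
    if (length(ik) < n_folds) {
      stop("class ", k, " has fewer samples (", length(ik),
           ") than folds (", n_folds, ")", call. = FALSE)
    }
    fold[ik] <- sample(rep_len(seq_len(n_folds), length(ik)))
  }
  fold
}

#' Repeated cross-validated evaluation of the selection + classification
#' pipeline
#'
#' Runs `n_repeats` rounds of stratified `n_folds`-fold cross-validation.
#' Within each training fold the counts are transformed to log2 CPM, genes
#' are scored by the five filter criteria ([score_genes()]), the top `k`
#' genes by grey relational grade are selected, and the classifier is
#' trained; predictions are made on the held-out fold. Per repeat, the
#' pooled predictions over all folds yield accuracy, F-measure, AUC and
#' mutual information, each reported as a percentage.
#'
#' Because log2 CPM is computed per sample from its own library size, and
#' scoring/selection/training see only training columns, the default run is
#' leakage-free. `select_in_fold = FALSE` instead selects genes once on all
#' data before the folds (the optimistic variant some studies use).
#'
#' @param cm a [count_matrix].
#' @param labels a [label_vector].
#' @param classifier `"gp"`, `"splda"`, or a function
#'   `f(Xtrain, ytrain, Xtest)` returning positive-class probabilities for
#'   the test rows (samples in rows).
#' @param k number of genes the grey relational ranking selects. Default 10.
#' @param n_repeats repetitions of the whole CV. Default 30.
#' @param n_folds folds per repetition. Default 5.
#' @param seed master seed; per-repeat substream seeds are drawn from it so
#'   results are reproducible and repeats independent.
#' @param select_in_fold nest feature selection inside training folds
#'   (default `TRUE`).
#' @param alpha,weights grey relational parameters, see [gra_rank()].
#' @param gp_opts list of extra arguments to [gp_fit()].
#' @param splda_opts list of extra arguments to [splda()] (e.g. `rho`,
#'   `size_factor`); sPLDA consumes raw counts of the selected genes.
#' @return An object of class `cv_result`: list with `metrics` (repeats x 4
#'   matrix of percentages: `accuracy`, `f_measure`, `auc`, `mi`), `mean`,
#'   `se` (standard error over repeats), and the configuration.
#' @export
#' @examples
#' sim <- simulate_counts(n_genes = 60, n_per_class = c(10, 10),
#'                        de_fraction = 0.1, seed = 7)
#' cv <- cross_validate(sim$counts, sim$labels, k = 5, n_repeats = 2,
#'                      seed = 7)
#' cv$mean
cross_validate <- function(cm, labels, classifier = "gp", k = 10L,
                           n_repeats = 30L, n_folds = 5L, seed = 1L,
                           select_in_fold = TRUE, alpha = 0.5,
                           weights = NULL, gp_opts = list(),
                           splda_opts = list()) {
  stopifnot(inherits(cm, "count_matrix"), inherits(labels, "label_vector"))
  counts <- cm$counts
  cls <- labels$labels
  if (min(table(cls)) < n_folds) {
    stop("each class needs >= ", n_folds, " samples", call. = FALSE)
  }
  values <- log_cpm(cm)
  set.seed(seed)
  repeat_seeds <- sample.int(.Machine$integer.max, n_repeats)

  global_sel <- NULL
  if (!select_in_fold) {
    sc <- score_genes(values, labels)
    global_sel <- select_top_k(sc, k, alpha = alpha,
                               weights = weights)$selected
  }

  fit_predict <- function(sel, tr, te) {
    if (is.function(classifier)) {
      return(classifier(t(values[sel, tr, drop = FALSE]), cls[tr],
                        t(values[sel, te, drop = FALSE])))
    }
    if (classifier == "gp") {
      args <- c(list(X = t(values[sel, tr, drop = FALSE]),
                     y = label_vector(cls[tr], class_names = c("0", "1"))),
                gp_opts)
      fit <- do.call(gp_fit, args)
      predict(fit, t(values[sel, te, drop = FALSE]))
    } else if (classifier == "splda") {
      args <- c(list(cm = counts[sel, tr, drop = FALSE],
                     labels = label_vector(cls[tr],
                                           class_names = c("0", "1"))),
                splda_opts)
      fit <- do.call(splda, args)
      predict(fit, counts[sel, te, drop = FALSE])$prob
    } else {
      stop("unknown classifier: ", classifier, call. = FALSE)
    }
  }

  metrics <- matrix(NA_real_, n_repeats, 4L,
                    dimnames = list(NULL, c("accuracy", "f_measure",
                                            "auc", "mi")))
  for (rep_i in seq_len(n_repeats)) {
    set.seed(repeat_seeds[rep_i])
    fold <- stratified_folds(cls, n_folds)
    prob <- numeric(length(cls))
    for (fd in seq_len(n_folds)) {
      te <- which(fold == fd)
      tr <- which(fold != fd)
      sel <- if (select_in_fold) {
        sc <- score_genes(values[, tr, drop = FALSE],
                          label_vector(cls[tr], class_names = c("0", "1")))
        select_top_k(sc, k, alpha = alpha, weights = weights)$selected
      } else global_sel
      prob[te] <- fit_predict(sel, tr, te)
    }
    pred <- as.integer(prob > 0.5)
    cmx <- confusion_metrics(cls, pred)
    metrics[rep_i, ] <- c(100 * cmx[["accuracy"]],
                          100 * cmx[["f_measure"]],
                          100 * classifier_auc(cls, prob),
                          mutual_information(cls, pred)$percent)
  }
  structure(list(metrics = metrics,
                 mean = colMeans(metrics),
                 se = apply(metrics, 2L, stats::sd) / sqrt(n_repeats),
                 n_repeats = n_repeats, n_folds = n_folds, k = k,
                 classifier = if (is.function(classifier)) "custom"
                              else classifier,
                 select_in_fold = select_in_fold, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d x %d-fold cross-validation (%s classifier, top %d genes%s)\n",
              x$n_repeats, x$n_folds, x$classifier, x$k,
              if (x$select_in_fold) ", selection nested in folds" else ""))
  tab <- data.frame(mean = sprintf("%.2f", x$mean),
                    se = sprintf("%.2f", x$se),
                    row.names = colnames(x$metrics))
  print(tab)
  invisible(x)
}
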