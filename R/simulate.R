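#' Simulate negative-binomial RNA-seq counts with planted differential
#' expression
#'
#' Generates a genes-by-samples count matrix for a two-group design.
#' Baseline per-gene means are drawn log2-uniformly so low and high
#' expressors coexist; per-sample library-size multipliers are
#' log2-uniform; a chosen fraction of genes is differentially expressed
#' between the classes at a fixed log2 fold change, half up- and half
#' down-regulated; counts are negative binomial with
#' `variance = mean + dispersion * mean^2` (`dispersion = 0` gives Poisson).
#' An optional multiplicative batch effect can be applied, assigned either
#' orthogonally to class (default) or confounded with it.
#'
#' @param n_genes number of genes. Default 1000.
#' @param n_per_class length-2 vector of samples per class. Default
#'   `c(40, 40)`.
#' @param de_fraction fraction of genes differentially expressed. Default
#'   0.01.
#' @param log2_fold_change absolute log2 fold change of DE genes. Default 2.
#' @param dispersion NB dispersion `phi` in `var = mu + phi * mu^2`.
#'   Default 0.2.
#' @param baseline_log2_range range of baseline mean expression on the log2
#'   scale. Default `c(1, 8)` (means from 2 to 256 counts).
#' @param libsize_log2_range range of per-sample log2 library-size
#'   multipliers. Default `c(-0.5, 0.5)`.
#' @param batch_effect_log2 log2 multiplicative batch effect applied to
#'   batch-2 samples; 0 (default) disables batches.
#' @param batch_confounded if `TRUE`, batch coincides with class; otherwise
#'   batches alternate within each class. Default `FALSE`.
#' @param seed integer seed; the output is bit-identical for a fixed seed.
#' @return A list with `counts` (a [count_matrix], batch attached when
#'   simulated), `labels` (a [label_vector], classes `"A"`/`"B"`), and
#'   `truth`: `de_genes` (ids), `de_sign` (+1 up in class B, -1 down),
#'   `base_mean`, `lib_mult`, `batch`.
#' @export
#' @examples
#' sim <- simulate_counts(n_genes = 100, n_per_class = c(6, 6), seed = 42)
#' sim$truth$de_genes
simulate_counts <- function(n_genes = 1000L, n_per_class = c(40L, 40L),
                            de_fraction = 0.01, log2_fold_change = 2,
                            dispersion = 0.2,
                            baseline_log2_range = c(1, 8),
                            libsize_log2_range = c(-0.5, 0.5),
                            batch_effect_log2 = 0,
                            batch_confounded = FALSE, seed = NULL) {
  stopifnot(n_genes >= 1, length(n_per_class) == 2L, all(n_per_class >= 2),
            de_fraction >= 0, de_fraction <= 1, dispersion >= 0,
            log2_fold_change >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- sum(n_per_class)
  cls <- rep(0:1, n_per_class)
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  sample_ids <- sprintf("s%03d", seq_len(n))

  base_mean <- 2^stats::runif(n_genes, baseline_log2_range[1],
                              baseline_log2_range[2])
  lib_mult <- 2^stats::runif(n, libsize_log2_range[1], libsize_log2_range[2])

  n_de <- round(de_fraction * n_genes)
  de_idx <- if (n_de > 0) sort(sample.int(n_genes, n_de)) else integer(0)
  de_sign <- rep_len(c(1, -1), n_de)       # half up-, half down-regulated

  lfc <- numeric(n_genes)
  lfc[de_idx] <- log2_fold_change * de_sign

  batch <- NULL
  batch_mult <- rep(1, n)
  if (batch_effect_log2 != 0) {
    batch <- if (batch_confounded) cls else {
      b <- integer(n)
      for (k in 0:1) {
        ik <- which(cls == k)
        b[ik] <- rep_len(0:1, length(ik))
      }
      b
    }
    batch_mult <- 2^(batch_effect_log2 * batch)
    batch <- factor(batch, levels = 0:1, labels = c("b1", "b2"))
  }

  mu <- outer(base_mean, lib_mult * batch_mult) *
    2^(outer(lfc, cls))                    # class B shifted by the fold change
  counts <- if (dispersion > 0) {
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
           n_genes, n)
  } else {
    matrix(stats::rpois(length(mu), lambda = mu), n_genes, n)
  }
  cm <- count_matrix(counts, gene_ids = gene_ids, sample_ids = sample_ids,
                     batch = batch)
  labels <- label_vector(ifelse(cls == 0L, "A", "B"),
                         class_names = c("A", "B"))
  list(counts = cm, labels = labels,
       truth = list(de_genes = gene_ids[de_idx], de_sign = de_sign,
                    base_mean = base_mean, lib_mult = lib_mult,
                    batch = batch))
}

#' Precision and recall of differential-expression recovery
#'
#' @param selected character vector of selected gene ids.
#' @param truth the `truth` element of [simulate_counts()] (or any list with
#'   a `de_genes` character vector).
#' @return A list with `precision`, `recall`, `n_hit`, and `empty_selection`
#'   (flag; precision is reported as 0 for an empty selection).
#' @export
recovery_report <- function(selected, truth) {
  de <- truth$de_genes
  hit <- length(intersect(selected, de))
  empty <- length(selected) == 0L
  list(precision = if (empty) 0 else hit / length(selected),
       recall = if (length(de) == 0L) NA_real_ else hit / length(de),
       n_hit = hit, empty_selection = empty)
}
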