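#' Construct a validated count matrix
#'
#' A `count_matrix` holds a genes-by-samples table of non-negative integer
#' read counts (the number of sequencing fragments assigned to each gene in
#' each sample), together with unique gene and sample identifiers and an
#' optional per-sample batch label.
#'
#' @param counts numeric matrix, genes in rows and samples in columns. All
#'   entries must be finite, non-negative and integer-valued.
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   `rownames(counts)`.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to `colnames(counts)`.
#' @param batch optional per-sample batch labels (character or factor),
#'   recycled never; length must equal the number of samples.
#'
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (integer-valued matrix with dimnames), `gene_ids`, `sample_ids`, `batch`.
#' @export
#' @examples
#' cm <- count_matrix(matrix(0:5, nrow = 3,
#'                           dimnames = list(paste0("g", 1:3), c("s1", "s2"))))
#' dim(cm$counts)
count_matrix <- function(counts, gene_ids = rownames(counts),
                         sample_ids = colnames(counts), batch = NULL) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) {
    stop("counts must be numeric", call. = FALSE)
  }
  if (anyNA(counts) || any(!is.finite(counts))) {
    stop("counts must not contain NA or non-finite values", call. = FALSE)
  }
  if (any(counts < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (any(counts != round(counts))) {
    stop("counts must be integer-valued", call. = FALSE)
  }
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(counts)))
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(ncol(counts)))
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(counts)) {
    stop("length of gene_ids must equal the number of rows", call. = FALSE)
  }
  if (length(sample_ids) != ncol(counts)) {
    stop("length of sample_ids must equal the number of columns", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique", call. = FALSE)
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique", call. = FALSE)
  if (!is.null(batch)) {
    if (length(batch) != ncol(counts)) {
      stop("batch must have one label per sample", call. = FALSE)
    }
    batch <- factor(batch)
  }
  storage.mode(counts) <- "double"   # exact for counts below 2^53
  dimnames(counts) <- list(gene_ids, sample_ids)
  structure(list(counts = counts, gene_ids = gene_ids,
                 sample_ids = sample_ids, batch = batch),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  cat("  total counts:", sum(x$counts), "\n")
  if (!is.null(x$batch)) {
    cat("  batches:", paste(levels(x$batch), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Construct a two-class label vector
#'
#' @param labels per-sample class labels (factor, character or 0/1 numeric)
#'   with exactly two distinct values, both present.
#' @param class_names optional length-2 character vector naming the classes;
#'   the first name maps to code 0, the second to code 1.
#'
#' @return An object of class `label_vector`: a list with integer `labels`
#'   in `{0, 1}` and `class_names`.
#' @export
label_vector <- function(labels, class_names = NULL) {
  f <- if (is.null(class_names)) factor(labels)
       else factor(labels, levels = class_names)
  if (anyNA(f)) stop("labels contain NA or values outside class_names",
                     call. = FALSE)
  if (nlevels(f) != 2L) {
    stop("exactly two classes are required, got ", nlevels(f), call. = FALSE)
  }
  if (!all(tabulate(f, 2L) > 0L)) {
    stop("both classes must be present", call. = FALSE)
  }
  structure(list(labels = as.integer(f) - 1L, class_names = levels(f)),
            class = "label_vector")
}

#' @export
print.label_vector <- function(x, ...) {
  n <- tabulate(x$labels + 1L, 2L)
  cat("label_vector:", x$class_names[1], "(", n[1], ") vs ",
      x$class_names[2], "(", n[2], ")\n")
  invisible(x)
}

read_table_checked <- function(path, dialect = c("tsv", "csv"), header = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (dialect == "tsv") "\t" else ","
  utils::read.table(path, header = header, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "\"", comment.char = "")
}

#' Read a count matrix from a delimited text file
#'
#' The first column holds gene identifiers, the header row holds sample
#' identifiers. Cells must be non-negative integers; the file is rejected
#' otherwise.
#'
#' @param path file path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return A [count_matrix].
#' @export
read_count_matrix <- function(path, dialect = c("tsv", "csv")) {
  tab <- read_table_checked(path, dialect)
  if (ncol(tab) < 2L) {
    stop("malformed count table: need a gene-id column and >= 1 sample",
         call. = FALSE)
  }
  gene_ids <- as.character(tab[[1L]])
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(mat)) {
    stop("malformed count table: non-numeric cells", call. = FALSE)
  }
  count_matrix(mat, gene_ids = gene_ids, sample_ids = colnames(tab)[-1L])
}

#' Write a count matrix to a delimited text file
#'
#' Inverse of [read_count_matrix()]: integers are written exactly, so
#' write-then-read round-trips bit-exactly.
#'
#' @param cm a [count_matrix].
#' @param path output file path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(cm, path, dialect = c("tsv", "csv")) {
  stopifnot(inherits(cm, "count_matrix"))
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  tab <- data.frame(gene_id = cm$gene_ids, cm$counts, check.names = FALSE)
  utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop genes with zero counts in all samples
#'
#' @param cm a [count_matrix].
#' @return A [count_matrix] with exactly the rows having at least one
#'   positive count, in the original order.
#' @export
filter_zero_genes <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  keep <- rowSums(cm$counts) > 0
  if (!any(keep)) stop("all genes have zero counts in every sample",
                       call. = FALSE)
  count_matrix(cm$counts[keep, , drop = FALSE],
               gene_ids = cm$gene_ids[keep],
               sample_ids = cm$sample_ids, batch = cm$batch)
}

#' Read per-sample class labels
#'
#' Reads a two-column table (sample id, class) and aligns the labels to a
#' given sample order by id, so file row order is irrelevant.
#'
#' @param path file path to a two-column table.
#' @param sample_ids character vector giving the target sample order (e.g.
#'   `cm$sample_ids`); every id must appear in the file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return A [label_vector] aligned to `sample_ids`.
#' @export
read_labels <- function(path, sample_ids, dialect = c("tsv", "csv")) {
  tab <- read_table_checked(path, dialect)
  if (ncol(tab) != 2L) {
    stop("label file must have exactly two columns (sample_id, class)",
         call. = FALSE)
  }
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids)) stop("duplicate sample ids in label file",
                               call. = FALSE)
  idx <- match(sample_ids, ids)
  if (anyNA(idx)) {
    stop("label file is missing samples: ",
         paste(sample_ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  label_vector(as.character(tab[[2L]])[idx])
}

#' Read per-sample batch labels
#'
#' Same format as [read_labels()] but any number (>= 1) of batch levels is
#' allowed.
#'
#' @inheritParams read_labels
#' @return A factor of batch labels aligned to `sample_ids`.
#' @export
read_batch <- function(path, sample_ids, dialect = c("tsv", "csv")) {
  tab <- read_table_checked(path, dialect)
  if (ncol(tab) != 2L) {
    stop("batch file must have exactly two columns (sample_id, batch)",
         call. = FALSE)
  }
  ids <- as.character(tab[[1L]])
  idx <- match(sample_ids, ids)
  if (anyNA(idx)) {
    stop("batch file is missing samples: ",
         paste(sample_ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  factor(as.character(tab[[2L]])[idx])
}

#' Write a per-gene score table
#'
#' @param scores numeric matrix with gene ids as rownames and one named
#'   column per criterion.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path) {
  tab <- data.frame(gene_id = rownames(scores), scores, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
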