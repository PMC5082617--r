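#' Grey relational generating (min-max normalization)
#'
#' Translates raw criterion scores into comparability sequences in `[0, 1]`.
#' Larger-is-better columns map through `(y - min) / (max - min)`;
#' smaller-is-better columns through `(max - y) / (max - min)`. Each column
#' then spans exactly `[0, 1]`, with 1 the most desirable value.
#'
#' @param scores genes-by-criteria numeric matrix.
#' @param directions character vector, one of `"larger"` or `"smaller"` per
#'   column (recycled if length 1). Default: all `"larger"`.
#' @return Matrix of the same shape with values in `[0, 1]`.
#' @export
grey_generate <- function(scores, directions = "larger") {
  scores <- as.matrix(scores)
  directions <- rep_len(match.arg(directions, c("larger", "smaller"),
                                  several.ok = TRUE), ncol(scores))
  out <- scores
  for (j in seq_len(ncol(scores))) {
    y <- scores[, j]
    rng <- max(y) - min(y)
    if (rng == 0) {
      stop("criterion column ", j,
           if (!is.null(colnames(scores))) paste0(" (", colnames(scores)[j], ")"),
           " is constant; min-max normalization is undefined", call. = FALSE)
    }
    out[, j] <- if (directions[j] == "larger") (y - min(y)) / rng
                else (max(y) - y) / rng
  }
  out
}

#' Grey relational coefficients
#'
#' Measures how close each comparability value is to the all-ones reference
#' sequence: `delta = (Dmin + alpha * Dmax) / (Dij + alpha * Dmax)`, where
#' `Dij = |1 - x_ij|` and `Dmin`, `Dmax` are taken over the whole matrix.
#' The distinguishing coefficient `alpha` compresses or expands the
#' coefficient range. If every cell equals 1, all coefficients are defined
#' as 1.
#'
#' @param x comparability matrix from [grey_generate()], entries in `[0, 1]`.
#' @param alpha distinguishing coefficient in `[0, 1]`. Default 0.5.
#' @return Matrix of coefficients in `(0, 1]`.
#' @export
grey_coefficient <- function(x, alpha = 0.5) {
  x <- as.matrix(x)
  stopifnot(alpha >= 0, alpha <= 1)
  if (any(x < -1e-12) || any(x > 1 + 1e-12)) {
    stop("comparability values must lie in [0, 1]", call. = FALSE)
  }
  delta <- abs(1 - x)
  dmin <- min(delta); dmax <- max(delta)
  if (dmax == 0) {
    return(matrix(1, nrow(x), ncol(x), dimnames = dimnames(x)))
  }
  (dmin + alpha * dmax) / (delta + alpha * dmax)
}

#' Grey relational grades
#'
#' The weighted mean of a gene's grey relational coefficients: the degree of
#' similarity between its comparability sequence and the ideal reference.
#'
#' @param coeffs coefficient matrix from [grey_coefficient()].
#' @param weights non-negative weights, one per criterion, summing to 1
#'   (tolerance 1e-12).
#' @return Numeric vector of grades in `(0, 1]`, one per gene.
#' @export
grey_grade <- function(coeffs, weights) {
  coeffs <- as.matrix(coeffs)
  if (length(weights) != ncol(coeffs)) {
    stop("need one weight per criterion", call. = FALSE)
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-12) {
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  }
  drop(coeffs %*% weights)
}

#' Rank genes by grey relational analysis
#'
#' Aggregates a genes-by-criteria score table into one grade per gene:
#' min-max normalization ([grey_generate()]), coefficients against the
#' all-ones reference ([grey_coefficient()]), then a weighted mean
#' ([grey_grade()]). Genes are ranked by descending grade; ties keep the
#' original gene order (stable sort), so the ranking is deterministic.
#'
#' @param scores genes-by-criteria numeric matrix, e.g. from
#'   [score_genes()].
#' @param alpha distinguishing coefficient. Default 0.5.
#' @param weights criterion weights summing to 1; default equal.
#' @param directions per-criterion `"larger"`/`"smaller"`; default all
#'   `"larger"` (all five filter scores are higher-is-more-discriminative).
#' @return An object of class `gra_result`: list with `grades`, `order`
#'   (gene indices by descending grade), `rank` (rank of each gene),
#'   `normalized` (comparability matrix), `coefficients`, `alpha`, `weights`.
#' @export
#' @examples
#' sc <- cbind(t = c(3, 1, 2), entropy = c(9, 1, 4))
#' rownames(sc) <- paste0("g", 1:3)
#' gra_rank(sc, weights = c(0.5, 0.5))
gra_rank <- function(scores, alpha = 0.5, weights = NULL,
                     directions = "larger") {
  scores <- as.matrix(scores)
  if (is.null(weights)) weights <- rep(1 / ncol(scores), ncol(scores))
  x <- grey_generate(scores, directions)
  co <- grey_coefficient(x, alpha)
  grades <- grey_grade(co, weights)
  names(grades) <- rownames(scores)
  ord <- order(-grades)            # radix sort: stable, ties keep input order
  rk <- integer(length(grades)); rk[ord] <- seq_along(ord)
  structure(list(grades = grades, order = ord, rank = rk,
                 normalized = x, coefficients = co,
                 alpha = alpha, weights = weights),
            class = "gra_result")
}

#' @export
print.gra_result <- function(x, n = 10L, ...) {
  cat("Grey relational ranking of", length(x$grades), "genes",
      sprintf("(alpha = %g)\n", x$alpha))
  top <- x$order[seq_len(min(n, length(x$grades)))]
  ids <- names(x$grades)
  if (is.null(ids)) ids <- as.character(seq_along(x$grades))
  cat("Top genes:\n")
  print(data.frame(gene = ids[top], grade = round(x$grades[top], 5),
                   row.names = NULL))
  invisible(x)
}

#' @export
plot.gra_result <- function(x, ...) {
  graphics::plot(sort(x$grades, decreasing = TRUE), type = "h",
                 xlab = "gene rank", ylab = "grey relational grade", ...)
  invisible(x)
}

#' Select the top-k genes by grey relational grade
#'
#' @inheritParams gra_rank
#' @param k number of genes to select, `1 <= k <= nrow(scores)`.
#' @return A list with `selected` (gene ids, or indices when `scores` has no
#'   rownames, in descending-grade order) and `result` (the full
#'   [gra_rank()] object).
#' @export
select_top_k <- function(scores, k, alpha = 0.5, weights = NULL,
                         directions = "larger") {
  scores <- as.matrix(scores)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > nrow(scores) ||
      k != round(k)) {
    stop("k must be an integer in [1, number of genes]", call. = FALSE)
  }
  res <- gra_rank(scores, alpha = alpha, weights = weights,
                  directions = directions)
  top <- res$order[seq_len(k)]
  ids <- rownames(scores)
  list(selected = if (is.null(ids)) top else ids[top], result = res)
}
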