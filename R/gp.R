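## Gaussian process binary classification with Laplace approximate inference.
## Squared-exponential kernel (isotropic or ARD), logistic likelihood, zero
## prior mean; hyperparameters optimized on the approximate log marginal
## likelihood.

# Gauss-Hermite nodes/weights (physicists' convention) via Golub-Welsch.
gauss_hermite <- function(n) {
  i <- seq_len(n - 1L)
  off <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- off
  J[cbind(i + 1L, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = sqrt(pi) * e$vectors[1L, ]^2)
}

# squared distances per dimension folded with length-scales
se_kernel <- function(X1, X2, log_ell, log_sf) {
  ell <- exp(log_ell)
  sf2 <- exp(2 * log_sf)
  if (length(ell) == 1L) ell <- rep(ell, ncol(X1))
  A <- sweep(X1, 2L, ell, "/")
  B <- sweep(X2, 2L, ell, "/")
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sf2 * exp(-0.5 * pmax(d2, 0))
}

# Newton iteration for the Laplace approximation (logistic likelihood).
# y in {-1, +1}. Returns posterior mode quantities and the approximate
# log marginal likelihood.
laplace_mode <- function(K, y, maxit = 100L, tol = 1e-10) {
  n <- length(y)
  f <- rep(0, n)
  obj_old <- -Inf
  for (it in seq_len(maxit)) {
    p <- stats::plogis(f)
    W <- p * (1 - p)
    sW <- sqrt(W)
    B <- diag(n) + (sW %o% sW) * K
    L <- chol(B)
    dlp <- (y + 1) / 2 - p
    b <- W * f + dlp
    a <- b - sW * backsolve(L, forwardsolve(t(L), sW * (K %*% b)))
    f <- drop(K %*% a)
    loglik <- -sum(log1p(exp(-y * f)))
    obj <- -0.5 * sum(a * f) + loglik
    if (abs(obj - obj_old) < tol) break
    obj_old <- obj
  }
  p <- stats::plogis(f)
  W <- p * (1 - p)
  sW <- sqrt(W)
  L <- chol(diag(n) + (sW %o% sW) * K)
  dlp <- (y + 1) / 2 - p
  loglik <- -sum(log1p(exp(-y * f)))
  logZ <- -0.5 * sum(a * f) + loglik - sum(log(diag(L)))
  list(f = f, a = a, dlp = dlp, sW = sW, L = L, log_marginal = logZ)
}

build_K <- function(X, log_ell, log_sf, jitter) {
  K <- se_kernel(X, X, log_ell, log_sf)
  K + diag(jitter * mean(diag(K)) + 1e-12, nrow(X))
}

#' Fit a Gaussian process binary classifier
#'
#' Places a zero-mean Gaussian process prior with squared-exponential
#' covariance on a latent function, squashed through the logistic likelihood.
#' The non-Gaussian posterior is approximated by Laplace's method (a Gaussian
#' centred at the posterior mode found by Newton iteration), and kernel
#' hyperparameters (log length-scales, log signal amplitude) are optimized by
#' BFGS on the approximate log marginal likelihood. Inputs are standardized
#' per feature with training statistics before entering the kernel.
#'
#' @param X samples-by-features numeric matrix (rows = samples).
#' @param y class labels: a [label_vector], a factor, or a vector with two
#'   distinct values. The second level is the "positive" class whose
#'   probability [predict.gp_class()] reports.
#' @param kernel `"ard"` (default, one length-scale per feature) or `"iso"`
#'   (a single shared length-scale).
#' @param optimize if `TRUE` (default), optimize hyperparameters; if the
#'   optimizer fails the initial values are kept with a warning.
#' @param init_log_ell,init_log_sf initial log length-scale(s) and log signal
#'   amplitude. Defaults 0 (unit scales, natural after standardization).
#' @param maxit BFGS iteration cap. Default 25.
#' @param jitter relative diagonal jitter for numerical stability.
#'   Default 1e-8.
#' @param standardize standardize columns using training mean/sd.
#'   Default `TRUE`.
#' @return An object of class `gp_class` with the fitted mode, Cholesky
#'   factors needed for prediction, `hyp` (named log hyperparameters), and
#'   `log_marginal`, the Laplace approximate log marginal likelihood.
#' @export
#' @examples
#' X <- matrix(c(-2, -1, 1, 2), ncol = 1)
#' fit <- gp_fit(X, c("a", "a", "b", "b"), optimize = FALSE)
#' predict(fit, X)
gp_fit <- function(X, y, kernel = c("ard", "iso"), optimize = TRUE,
                   init_log_ell = 0, init_log_sf = 0, maxit = 25L,
                   jitter = 1e-8, standardize = TRUE) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  if (anyNA(X) || any(!is.finite(X))) {
    stop("non-finite values in X", call. = FALSE)
  }
  if (inherits(y, "label_vector")) {
    class_names <- y$class_names
    yf <- ifelse(y$labels == 1L, 1, -1)
  } else {
    f <- factor(y)
    if (nlevels(f) != 2L) stop("y must have exactly two classes",
                               call. = FALSE)
    class_names <- levels(f)
    yf <- ifelse(as.integer(f) == 2L, 1, -1)
  }
  if (length(yf) != nrow(X)) stop("X and y disagree on sample count",
                                  call. = FALSE)
  if (length(unique(yf)) < 2L) stop("both classes must appear in training",
                                    call. = FALSE)
  if (standardize) {
    center <- colMeans(X)
    scale <- apply(X, 2L, stats::sd)
    scale[scale == 0] <- 1
  } else {
    center <- rep(0, ncol(X)); scale <- rep(1, ncol(X))
  }
  Xs <- sweep(sweep(X, 2L, center), 2L, scale, "/")

  d_ell <- if (kernel == "ard") ncol(X) else 1L
  hyp0 <- c(rep_len(init_log_ell, d_ell), init_log_sf)

  neg_logZ <- function(hyp) {
    K <- build_K(Xs, hyp[seq_len(d_ell)], hyp[d_ell + 1L], jitter)
    lz <- tryCatch(laplace_mode(K, yf)$log_marginal, error = function(e) -Inf)
    if (!is.finite(lz)) return(1e10)
    -lz
  }
  hyp <- hyp0
  if (optimize) {
    opt <- tryCatch(
      stats::optim(hyp0, neg_logZ, method = "BFGS",
                   control = list(maxit = maxit)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) {
      warning("hyperparameter optimization failed; keeping initial values",
              call. = FALSE)
    } else {
      hyp <- opt$par
    }
  }
  K <- build_K(Xs, hyp[seq_len(d_ell)], hyp[d_ell + 1L], jitter)
  mode <- laplace_mode(K, yf)
  structure(list(X = Xs, y = yf, class_names = class_names,
                 kernel = kernel, hyp = hyp, d_ell = d_ell,
                 center = center, scale = scale, jitter = jitter,
                 mode = mode, log_marginal = mode$log_marginal),
            class = "gp_class")
}

#' Predict class probabilities from a fitted GP classifier
#'
#' Computes the Laplace-approximate latent predictive mean and variance at
#' each new point and averages the logistic likelihood over that Gaussian by
#' 20-point Gauss-Hermite quadrature.
#'
#' @param object a fitted [gp_fit()] model.
#' @param newdata samples-by-features matrix with the same feature count as
#'   training.
#' @param type `"prob"` (default) for probabilities of the positive (second)
#'   class, or `"class"` for hard labels at threshold 0.5.
#' @param ... unused.
#' @return Numeric vector of probabilities in `(0, 1)`, or a character vector
#'   of class names.
#' @export
predict.gp_class <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  Xs <- as.matrix(newdata)
  if (ncol(Xs) != ncol(object$X)) {
    stop("newdata has ", ncol(Xs), " features; model expects ",
         ncol(object$X), call. = FALSE)
  }
  Xs <- sweep(sweep(Xs, 2L, object$center), 2L, object$scale, "/")
  le <- object$hyp[seq_len(object$d_ell)]
  ls <- object$hyp[object$d_ell + 1L]
  kstar <- se_kernel(object$X, Xs, le, ls)      # n_train x n_new
  mu <- drop(crossprod(kstar, object$mode$dlp))
  v <- forwardsolve(t(object$mode$L), object$mode$sW * kstar)
  s2 <- pmax(exp(2 * ls) - colSums(v^2), 1e-12)
  gh <- gauss_hermite(20L)
  p <- numeric(length(mu))
  for (q in seq_along(gh$x)) {
    p <- p + gh$w[q] * stats::plogis(mu + sqrt(2 * s2) * gh$x[q])
  }
  p <- p / sqrt(pi)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  if (type == "prob") p else object$class_names[(p > 0.5) + 1L]
}

#' @export
print.gp_class <- function(x, ...) {
  cat("Gaussian process classifier (Laplace inference, logistic likelihood)\n")
  cat("  training samples:", nrow(x$X), " features:", ncol(x$X),
      " kernel:", x$kernel, "\n")
  cat("  classes:", paste(x$class_names, collapse = " vs "), "\n")
  cat("  approx. log marginal likelihood:",
      format(x$log_marginal, digits = 6), "\n")
  invisible(x)
}

#' @export
summary.gp_class <- function(object, ...) {
  cat("Gaussian process binary classifier\n")
  print(object)
  ell <- exp(object$hyp[seq_len(object$d_ell)])
  cat("  length-scales:", paste(format(ell, digits = 4), collapse = ", "),
      "\n")
  cat("  signal sd:", format(exp(object$hyp[object$d_ell + 1L]),
                             digits = 4), "\n")
  ptrain <- predict(object, sweep(sweep(object$X, 2L, object$scale, "*"),
                                  2L, -object$center))
  acc <- mean((ptrain > 0.5) == (object$y > 0))
  cat("  training accuracy:", format(acc, digits = 4), "\n")
  invisible(object)
}
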