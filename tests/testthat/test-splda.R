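test_that("total-count size factors normalize by the training grand total", {
  counts <- cbind(s1 = c(1, 2, 3), s2 = c(10, 20, 24))  # totals 6 and 54
  sf <- size_factors(counts, "total")
  expect_equal(sf$train, c(s1 = 0.1, s2 = 0.9), ignore_attr = TRUE)
  expect_equal(sum(sf$train), 1)
  # a test profile equal to a training sample gets that sample's factor
  sf2 <- size_factors(counts, "total", test = counts[, 1])
  expect_equal(sf2$test, 0.1)
  set.seed(101)
  m <- matrix(rpois(50, 20), 10, 5)
  expect_equal(sum(size_factors(m, "total")$train), 1)
})

test_that("median-ratio size factors use all-positive reference genes", {
  a <- c(4, 8, 2)
  counts <- cbind(s1 = a, s2 = a)
  expect_equal(size_factors(counts, "median_ratio")$train, c(0.5, 0.5),
               ignore_attr = TRUE)
  counts2 <- cbind(s1 = a, s2 = 2 * a)
  sf <- size_factors(counts2, "median_ratio")$train
  expect_equal(sf[2] / sf[1], 2, ignore_attr = TRUE)
  # genes with a zero are excluded from the reference set: factors match a
  # scalar recomputation on the positive rows only
  counts3 <- rbind(counts2, c(0, 100))
  sf3 <- size_factors(counts3, "median_ratio")$train
  expect_equal(sf3, sf, ignore_attr = TRUE)
  expect_error(size_factors(cbind(c(1, 0), c(0, 1)), "median_ratio"),
               "total-count")
})

test_that("quantile size factors use the 75th percentile with linear
           interpolation", {
  x <- 0:7    # 75th percentile = 5.25 by linear interpolation
  counts <- cbind(s1 = x, s2 = x)
  expect_equal(size_factors(counts, "quantile")$train, c(0.5, 0.5),
               ignore_attr = TRUE)
  counts2 <- cbind(s1 = x, s2 = 2L * x)
  sf <- size_factors(counts2, "quantile")$train
  expect_equal(sf, c(5.25, 10.5) / 15.75, ignore_attr = TRUE)
  sft <- size_factors(counts2, "quantile", test = x)$test
  expect_equal(sft, 5.25 / 15.75)
})

test_that("profile estimates follow the three soft-threshold branches", {
  set.seed(102)
  sim <- simulate_counts(n_genes = 40, n_per_class = c(4, 4),
                         de_fraction = 0.2, seed = 102)
  counts <- sim$counts$counts
  cls <- sim$labels$labels
  si <- size_factors(counts, "total")$train
  gj <- rowSums(counts)
  for (rho in c(0, 0.5, 3, 25)) {
    d <- estimate_dkj(counts, cls, si, beta = 1, rho = rho)
    for (k in 0:1) {
      ik <- which(cls == k)
      for (j in seq(1, 40, by = 7)) {
        a <- sum(counts[j, ik]) + 1
        b <- sum(si[ik]) * gj[j] + 1
        expected <- if (b * (a / b - 1) > rho) a / b - rho / b
                    else if (b * (1 - a / b) > rho) a / b + rho / b
                    else 1
        expect_equal(d[k + 1, j], expected, tolerance = 1e-12,
                     ignore_attr = TRUE)
      }
    }
    # soft threshold never crosses 1
    d0 <- estimate_dkj(counts, cls, si, beta = 1, rho = 0)
    expect_true(all(sign(d - 1) == sign(d0 - 1) | d == 1))
  }
  # rho = 0 is exactly a/b
  d0 <- estimate_dkj(counts, cls, si, beta = 1, rho = 0)
  ik <- which(cls == 0)
  expect_equal(d0[1, ], (rowSums(counts[, ik]) + 1) /
                 (sum(si[ik]) * gj + 1), ignore_attr = TRUE)
})

test_that("the discriminant rule reproduces the one-gene worked example", {
  model <- structure(list(dkj = matrix(c(2, 0.5), 2, 1), gj = 1,
                          si = 1, rho = 0, beta = 1, priors = c(0.5, 0.5),
                          size_factor = "total",
                          class_names = c("c1", "c2"),
                          train_counts = matrix(3, 1, 1)),
                     class = "splda")
  pred <- predict(model, 3)   # s* = 3/3 = 1
  # Poisson log-likelihood parts: (3 log 2 - 2, 3 log 0.5 - 0.5); the equal
  # prior adds log(1/2) to both
  expect_equal(unname(pred$scores[1, ]) - log(0.5),
               c(3 * log(2) - 2, 3 * log(0.5) - 0.5), tolerance = 1e-12)
  expect_identical(pred$class, "c1")
})

test_that("an all-ones profile ties and breaks toward the first class, and
           mirrored fixtures classify symmetrically", {
  null_model <- structure(list(dkj = matrix(1, 2, 3), gj = c(5, 5, 5),
                               si = c(0.5, 0.5), rho = 0, beta = 1,
                               priors = c(0.5, 0.5), size_factor = "total",
                               class_names = c("c1", "c2"),
                               train_counts = matrix(5, 3, 2)),
                          class = "splda")
  pred <- predict(null_model, c(1, 2, 3))
  expect_equal(diff(pred$scores[1, ]), 0, ignore_attr = TRUE)
  expect_identical(pred$class, "c1")

  # mirrored two-class fixture: mirrored test points get mirrored labels
  counts <- cbind(a1 = c(30, 5), a2 = c(28, 6), b1 = c(5, 30), b2 = c(6, 28))
  rownames(counts) <- c("g1", "g2")
  lab <- label_vector(c("A", "A", "B", "B"))
  fit <- splda(counts, lab, rho = 0)
  p1 <- predict(fit, cbind(c(40, 4), c(4, 40)))
  expect_identical(p1$class, c("A", "B"))
  # consistently permuting gene rows in training and test changes nothing
  fitm <- splda(counts[c(2, 1), ], lab, rho = 0)
  p2 <- predict(fitm, cbind(c(40, 4), c(4, 40))[c(2, 1), ])
  expect_identical(p2$class, p1$class)
})

test_that("involved-feature counts are non-increasing in rho and vanish
           beyond the maximal threshold", {
  sim <- simulate_counts(n_genes = 60, n_per_class = c(6, 6),
                         de_fraction = 0.2, seed = 103)
  lab <- sim$labels
  counts <- sim$counts$counts
  si <- size_factors(counts, "total")$train
  gj <- rowSums(counts)
  rho_max <- 0
  for (k in 0:1) {
    ik <- which(lab$labels == k)
    a <- rowSums(counts[, ik]) + 1
    b <- sum(si[ik]) * gj + 1
    rho_max <- max(rho_max, b * abs(1 - a / b))
  }
  grid <- seq(0, rho_max * 1.01, length.out = 12)
  nf <- vapply(grid, function(r) {
    involved_features(splda(counts, lab, rho = r))
  }, integer(1))
  expect_true(all(diff(nf) <= 0))
  expect_identical(nf[length(nf)], 0L)
  # brute-force recount at one interior rho
  r <- grid[5]
  d <- estimate_dkj(counts, lab$labels, si, beta = 1, rho = r)
  cnt <- 0L
  for (j in seq_len(ncol(d))) if (d[1, j] != 1 || d[2, j] != 1) cnt <- cnt + 1L
  expect_identical(involved_features(splda(counts, lab, rho = r)), cnt)
})

test_that("rho tuning returns a singleton grid unchanged and picks sparser
           ties", {
  sim <- simulate_counts(n_genes = 50, n_per_class = c(10, 10),
                         de_fraction = 0.2, log2_fold_change = 3, seed = 104)
  tuned <- splda_tune_rho(sim$counts, sim$labels, grid = 2.5, folds = 5,
                          seed = 1)
  expect_equal(tuned$rho, 2.5)
  tuned2 <- splda_tune_rho(sim$counts, sim$labels, folds = 5, seed = 1)
  expect_true(tuned2$rho %in% tuned2$grid)
  expect_true(all(diff(tuned2$n_features) <= 0))
  # ties break toward the larger rho
  best_acc <- max(tuned2$accuracy)
  expect_identical(tuned2$rho,
                   max(tuned2$grid[tuned2$accuracy == best_acc]))
})
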