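test_that("t score matches hand-derived values and is label-symmetric", {
  s <- class_summary(c(1, 2, 3), c(4, 5, 6))
  expect_equal(t_score(s), 3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(t_score(class_summary(c(4, 5, 6), c(1, 2, 3))), t_score(s))
  expect_equal(t_score(class_summary(c(2, 2, 2), c(2, 2, 2))), 0)
  # zero pooled variance with unequal means hits the cap, not an error
  expect_equal(t_score(class_summary(c(1, 1), c(2, 2))), 1e8)
})

test_that("entropy score matches hand-derived values", {
  mk <- function(mu1, mu2, s1, s2)
    list(mu1 = mu1, mu2 = mu2, sigma1 = s1, sigma2 = s2, n1 = 3, n2 = 3)
  expect_equal(entropy_score(mk(1, 1, 2, 2)), 0)
  expect_equal(entropy_score(mk(0, 1, 1, 1)), 1, tolerance = 1e-12)
  expect_equal(entropy_score(mk(3, 3, 2, 1)), 1.125, tolerance = 1e-12)
})

test_that("Bhattacharyya score matches hand-derived values", {
  mk <- function(mu1, mu2, s1, s2)
    list(mu1 = mu1, mu2 = mu2, sigma1 = s1, sigma2 = s2, n1 = 3, n2 = 3)
  expect_equal(bhattacharyya_score(mk(0, 0, 1, 1)), 0)
  expect_equal(bhattacharyya_score(mk(0, 2, 1, 1)), 0.5, tolerance = 1e-12)
  expect_equal(bhattacharyya_score(mk(1, 1, 2, 1)),
               0.25 * log(0.25 * (4 + 0.25 + 2)), tolerance = 1e-12)
})

test_that("Wilcoxon score uses smaller-group midrank sum with tie-corrected
           moments", {
  expect_equal(wilcoxon_score(c(1, 2, 3), c(4, 5, 6)),
               4.5 / sqrt(5.25), tolerance = 1e-12)
  # W = 1 + 3 = 4, E[W] = 5, var = n1 n2 (N + 1) / 12 = 5/3
  expect_equal(wilcoxon_score(c(1, 3), c(2, 4)),
               1 / sqrt(5 / 3), tolerance = 1e-12)
  # rank invariance: adding a constant changes nothing
  expect_equal(wilcoxon_score(c(1, 3) + 7, c(2, 4) + 7),
               wilcoxon_score(c(1, 3), c(2, 4)))
  expect_equal(wilcoxon_score(c(5, 5, 5), c(5, 5)), 0)
  # label symmetry
  set.seed(1)
  a <- rnorm(5); b <- rnorm(7)
  expect_equal(wilcoxon_score(a, b), wilcoxon_score(b, a))
})

test_that("AUC score equals the pairwise concordance count, folded", {
  expect_equal(auc_score(c(1, 2), c(5, 6)), 1)
  expect_equal(auc_score(c(1, 3), c(2, 4)), 0.75)
  expect_equal(auc_score(c(1, 2, 3), c(1, 2, 3)), 0.5)
  # down-regulation folds to the same score
  expect_equal(auc_score(c(5, 6), c(1, 2)), 1)
  # identity with the Mann-Whitney U statistic on random samples
  set.seed(2)
  for (i in 1:20) {
    x1 <- sample(1:8, 5, replace = TRUE)
    x2 <- sample(1:8, 6, replace = TRUE)
    u <- 0
    for (a in x1) for (b in x2) u <- u + (b > a) + 0.5 * (b == a)
    raw <- u / (length(x1) * length(x2))
    expect_equal(auc_score(x1, x2), max(raw, 1 - raw), tolerance = 1e-12)
  }
})

test_that("score_genes matches per-gene scalar recomputation and its
           invariances", {
  sim <- simulate_counts(n_genes = 200, n_per_class = c(6, 8),
                         de_fraction = 0.1, seed = 71)
  v <- log_cpm(sim$counts)
  lab <- sim$labels
  tab <- score_genes(v, lab)
  expect_true(all(is.finite(tab)) && all(tab >= 0))
  i1 <- which(lab$labels == 0); i2 <- which(lab$labels == 1)
  for (g in seq(1, 200, by = 13)) {
    s <- class_summary(v[g, i1], v[g, i2])
    expect_equal(tab[g, "t"], t_score(s), tolerance = 1e-10)
    expect_equal(tab[g, "entropy"], entropy_score(s), tolerance = 1e-10)
    expect_equal(tab[g, "bhattacharyya"], bhattacharyya_score(s),
                 tolerance = 1e-10)
    expect_equal(tab[g, "wilcoxon"], wilcoxon_score(v[g, i1], v[g, i2]),
                 tolerance = 1e-10)
    expect_equal(tab[g, "auc"], auc_score(v[g, i1], v[g, i2]),
                 tolerance = 1e-12)
  }

  # swapping class labels leaves every score unchanged
  swapped <- label_vector(ifelse(lab$labels == 0, "B", "A"),
                          class_names = c("A", "B"))
  expect_equal(score_genes(v, swapped), tab, tolerance = 1e-10)

  # permuting samples together with labels leaves the table unchanged
  set.seed(72)
  perm <- sample(ncol(v))
  labp <- label_vector(lab$class_names[lab$labels + 1][perm],
                       class_names = lab$class_names)
  expect_equal(score_genes(v[, perm], labp), tab, tolerance = 1e-10)

  # monotone transform invariance of the rank-based scores
  tab2 <- score_genes(exp(v / 4), lab)
  expect_equal(tab2[, "wilcoxon"], tab[, "wilcoxon"], tolerance = 1e-10)
  expect_equal(tab2[, "auc"], tab[, "auc"], tolerance = 1e-12)
  # shift invariance of the normal-theory scores
  tab3 <- score_genes(v + 5, lab)
  expect_equal(tab3[, c("t", "entropy", "bhattacharyya")],
               tab[, c("t", "entropy", "bhattacharyya")], tolerance = 1e-8)
})

test_that("a separated gene dominates a class-identical one on all criteria", {
  vals <- rbind(g1 = c(1, 2, 3, 11, 12, 13),
                g2 = c(4, 5, 6, 4, 5, 6))
  # extra filler genes so no criterion column is constant
  set.seed(73)
  vals <- rbind(vals, matrix(rnorm(60), nrow = 10,
                             dimnames = list(paste0("f", 1:10), NULL)))
  lab <- label_vector(rep(c("A", "B"), each = 3))
  tab <- score_genes(vals, lab)
  expect_true(all(tab["g1", ] > tab["g2", ]))
})

test_that("a constant criterion column raises a named error", {
  vals <- rbind(c(1, 1, 1, 2, 2, 2), c(3, 3, 3, 4, 4, 4))
  lab <- label_vector(rep(c("A", "B"), each = 3))
  expect_error(score_genes(vals, lab), "constant")
})
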