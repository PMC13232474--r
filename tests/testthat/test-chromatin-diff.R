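# Normalization, Spearman clustering, PERMANOVA, PCA and the NB test.

test_that("size-factor normalization identities hold", {
  m <- matrix(c(10, 20, 30, 10, 20, 30), 3, 2,
              dimnames = list(NULL, c("s1", "s2")))
  expect_equal(normalize_counts(m), m)  # equal totals: identity
  # uniformly doubling one sample restores it after normalization
  m2 <- cbind(s1 = c(10, 20, 30), s2 = 2 * c(10, 20, 30))
  norm <- normalize_counts(m2)
  sf2 <- 120 / exp(mean(log(c(60, 120))))
  expect_equal(norm[, "s2"], c(s1 = 10, 20, 30)[1:3] * 2 / sf2,
               ignore_attr = TRUE)
  expect_equal(unname(norm[, "s2"] / norm[, "s1"]), rep(1, 3))
  # single sample: s = 1
  expect_equal(normalize_counts(cbind(a = c(1, 2))), cbind(a = c(1, 2)))
  expect_error(normalize_counts(cbind(s1 = c(1, 2), bad = c(0, 0))), "bad")
})

test_that("log2 variant applies log2(x + 1)", {
  m <- cbind(s1 = c(0, 3), s2 = c(1, 2))
  expect_equal(normalize_counts(m, log2 = TRUE),
               log2(normalize_counts(m) + 1))
})

test_that("Spearman clustering merges duplicates first and is rank-invariant", {
  set.seed(1)
  base <- matrix(rnorm(40), 10, 4,
                 dimnames = list(NULL, paste0("s", 1:4)))
  base[, 2] <- base[, 1]                 # duplicate sample
  res <- correlation_clustering(base, k = 2)
  expect_equal(res$D["s1", "s2"], 0)
  expect_equal(res$tree$merge[1, ], c(-1, -2))  # merged first
  # monotone transform of a sample leaves D unchanged
  tr <- base
  tr[, 3] <- exp(tr[, 3])
  expect_equal(correlation_clustering(tr, k = 2)$D, res$D)
  expect_error(correlation_clustering(cbind(s1 = rep(1, 5),
                                            s2 = rnorm(5)), k = 2),
               "constant")
})

test_that("clustering recovers three well-separated planted groups", {
  sim <- small_cohort(seed = 2, n_peaks = 800, n_genes = 300,
                      n_diff_peaks_per_subtype = 80)
  norm <- normalize_counts(sim$peaks, log2 = TRUE)
  res <- correlation_clustering(norm, k = 3)
  truth <- sim$truth$subtype_of_sample[names(res$labels)]
  # labels are a relabeling of the truth: contingency rows are pure
  tab <- table(res$labels, truth)
  expect_equal(sum(apply(tab, 1, max)), length(truth))
})

test_that("PERMANOVA matches the brute-force oracle and vegan", {
  set.seed(4)
  x <- matrix(rnorm(24), 12, 2)
  x[1:4, ] <- x[1:4, ] + 3
  D <- as.matrix(dist(x))
  lab <- rep(c("a", "b", "c"), each = 4)
  res <- permanova(D, lab, n_perm = 499, seed = 9)
  expect_equal(res$F, oracle_permanova_F(D, lab))
  skip_if_not_installed("vegan")
  ad <- vegan::adonis2(stats::as.dist(D) ~ g,
                       data = data.frame(g = lab), permutations = 99)
  expect_equal(res$F, ad$F[1], tolerance = 1e-10)
})

test_that("exhaustive PERMANOVA agrees with full enumeration", {
  set.seed(5)
  x <- matrix(rnorm(12), 6, 2)
  x[1:2, ] <- x[1:2, ] + 2
  D <- as.matrix(dist(x))
  lab <- rep(c("a", "b", "c"), each = 2)
  res <- permanova(D, lab, exact = TRUE)
  f_all <- vapply(oracle_permutations(1:6), function(ord)
    oracle_permanova_F(D, lab[ord]), numeric(1))
  expect_equal(res$n_perm, factorial(6))
  expect_equal(res$p, mean(f_all >= oracle_permanova_F(D, lab) - 1e-12))
})

test_that("well-separated groups attain the minimal permutation p", {
  set.seed(6)
  x <- matrix(rnorm(40, sd = 0.01), 20, 2)
  x[1:10, ] <- x[1:10, ] + 100
  D <- as.matrix(dist(x))
  res <- permanova(D, rep(c("a", "b"), each = 10), n_perm = 999, seed = 3)
  expect_equal(res$p, 1 / 1000)
})

test_that("PERMANOVA F is invariant to scaling D and to relabeling", {
  set.seed(7)
  D <- as.matrix(dist(matrix(rnorm(20), 10, 2)))
  lab <- rep(c("a", "b"), each = 5)
  f1 <- permanova(D, lab, n_perm = 9, seed = 1)$F
  expect_equal(permanova(3.7 * D, lab, n_perm = 9, seed = 1)$F, f1)
  relab <- c(a = "x", b = "y")[lab]
  expect_equal(permanova(D, relab, n_perm = 9, seed = 1)$F, f1)
  expect_error(permanova(matrix(0, 6, 6), rep(c("a", "b"), 3), 9),
               "degenerate")
  expect_error(permanova(D, rep("a", 10), 9), "2 groups")
})

test_that("PCA matches a dense eigendecomposition and basic identities", {
  set.seed(8)
  m <- matrix(rnorm(20), 5, 4, dimnames = list(NULL, paste0("s", 1:4)))
  res <- pca_samples(m)
  expect_equal(sum(res$var_fraction), 1)
  # components are orthogonal
  cp <- crossprod(res$coordinates)
  expect_equal(cp[upper.tri(cp)], rep(0, sum(upper.tri(cp))),
               tolerance = 1e-8)
  # eigenvalues of the centered covariance reproduce the variances
  xc <- t(m) - colMeans(t(m))[col(t(m))]
  xc <- scale(t(m), center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(xc) / (ncol(m) - 1))$values
  expect_equal(res$var_fraction, (ev / sum(ev))[seq_along(res$var_fraction)],
               tolerance = 1e-8)
  # collinear samples: PC1 carries everything
  col_m <- outer(c(1, 2, 3), c(1, 2, 3, 4))
  colnames(col_m) <- paste0("s", 1:4)
  expect_equal(pca_samples(col_m)$var_fraction[1], 1)
})

test_that("NB test handles degenerate features and group swaps", {
  set.seed(9)
  m <- matrix(rnbinom(80 * 8, size = 20, mu = 50), 80, 8)
  m[1, ] <- 0                            # all-zero feature
  rownames(m) <- paste0("f", 1:80)
  d <- nb_differential(m, 1:4, 5:8)
  expect_equal(d$log2fc[1], 0)
  expect_equal(d$p[1], 1)
  expect_true(all(d$padj >= d$p - 1e-12 & d$padj <= 1))
  # BH is monotone: sorting by p sorts by padj
  expect_true(all(diff(d$padj[order(d$p)]) >= -1e-12))
  # swapping groups flips the sign, keeps p
  d2 <- nb_differential(m, 5:8, 1:4)
  expect_equal(d2$log2fc, -d$log2fc)
  expect_equal(d2$p, d$p)
  expect_error(nb_differential(m, 1:4, 4:8), "overlap")
  expect_error(nb_differential(m, 1, 2:5), ">= 2 samples")
})

test_that("differential filter applies inclusive padj and strict lfc bounds", {
  t <- data.frame(feature_id = c("a", "b", "c", "d", "e"),
                  log2fc = c(1, 0.5, -2, 0.51, -0.5),
                  p = rep(0.001, 5),
                  padj = c(0.05, 0.01, 0.0500000, 0.051, 0.01))
  fs <- filter_differential(t, padj_max = 0.05, min_abs_lfc = 0.5)
  expect_true("a" %in% fs$a_up)        # padj exactly 0.05 retained
  expect_false("b" %in% fs$a_up)       # |lfc| exactly 0.5 excluded
  expect_true("c" %in% fs$b_up)
  expect_false("d" %in% fs$a_up)       # padj just above threshold
  expect_false("e" %in% fs$b_up)
  empty <- filter_differential(t[0, ], 0.05, 0.5)
  expect_length(empty$a_up, 0)
  expect_length(empty$b_up, 0)
})
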