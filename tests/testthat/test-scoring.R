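# Enrichment scores, module scores and the classification rules.

test_that("enrichment score matches the explicit-walk oracle", {
  set.seed(1)
  genes <- paste0("g", sprintf("%02d", 1:30))
  x <- rnorm(30)
  ex <- matrix(x, 30, 1, dimnames = list(genes, "s1"))
  for (k in c(2, 5, 10)) {
    set <- sample(genes, k)
    expect_equal(unname(ss_enrichment_score(ex, set)),
                 oracle_es(x, genes, set))
  }
})

test_that("degenerate set covering all genes hits its analytic maximum", {
  genes <- paste0("g", 1:6)
  x <- c(5, 4, 3, 2, 1, 0)
  ex <- matrix(x, 6, 1, dimnames = list(genes, "s1"))
  # no decrements: ES = sum_j w_j * (N - j + 1) / N with all genes members
  w <- (6:1)^0.25
  w <- w / sum(w)
  expect_equal(unname(ss_enrichment_score(ex, genes)),
               sum(w * (6:1)) / 6)
})

test_that("moving a set gene to a better rank never decreases the score", {
  set.seed(2)
  for (i in 1:100) {
    n <- sample(10:40, 1)
    genes <- sprintf("g%03d", 1:n)
    x <- rnorm(n)
    set <- sample(genes, sample(2:5, 1))
    es0 <- unname(ss_enrichment_score(matrix(x, n, 1,
                                             dimnames = list(genes, "s")),
                                      set))
    # swap one set gene's expression with a higher-expressed non-member
    gi <- which(genes %in% set)[1]
    better <- which(!genes %in% set & x > x[gi])
    if (!length(better)) next
    j <- better[which.max(x[better])]
    x2 <- x
    x2[c(gi, j)] <- x2[c(j, gi)]
    es1 <- unname(ss_enrichment_score(matrix(x2, n, 1,
                                             dimnames = list(genes, "s")),
                                      set))
    expect_gte(es1, es0 - 1e-12)
  }
})

test_that("scores are invariant to gene order and need set overlap", {
  set.seed(3)
  genes <- paste0("g", 1:20)
  ex <- matrix(rnorm(40), 20, 2, dimnames = list(genes, c("a", "b")))
  set <- c("g3", "g7", "g11")
  perm <- sample(20)
  expect_equal(ss_enrichment_score(ex[perm, ], set),
               ss_enrichment_score(ex, set))
  expect_equal(module_score(ex[perm, ], set, seed = 5),
               module_score(ex, set, seed = 5))
  expect_error(ss_enrichment_score(ex, c("nope1", "nope2")), "absent")
})

test_that("module score recovers a planted uniform shift exactly", {
  # one bin; all non-set genes constant across cells, set genes shifted
  genes <- paste0("g", 1:30)
  cells <- matrix(1, 30, 3, dimnames = list(genes, c("c1", "c2", "c3")))
  set <- c("g1", "g2")
  cells[set, "c2"] <- 1 + 0.7
  sc <- module_score(cells, set, n_bins = 1, seed = 11)
  expect_equal(unname(sc["c2"]), 0.7)
  expect_equal(unname(sc["c1"]), 0)
  # constant matrix scores 0 everywhere
  expect_equal(unname(module_score(matrix(2, 30, 3,
                                          dimnames = list(genes, 1:3)),
                                   set, seed = 1)),
               rep(0, 3))
  # same seed, same controls
  set.seed(4)
  big <- matrix(rpois(3000, 5), 100, 30,
                dimnames = list(sprintf("h%03d", 1:100), NULL))
  expect_identical(module_score(big, c("h001", "h050"), seed = 7),
                   module_score(big, c("h001", "h050"), seed = 7))
})

test_that("bulk quartile rule labels ceil(N/4) at each extreme", {
  sc <- data.frame(unit_id = paste0("u", 1:8), delta = 8:1)
  lab <- classify_bulk_quartile(sc)
  expect_equal(unname(lab[paste0("u", 1:2)]), rep("LLI-like", 2))
  expect_equal(unname(lab[paste0("u", 7:8)]), rep("BL", 2))
  expect_equal(unname(lab[paste0("u", 3:6)]), rep("intermediate", 4))
  # N = 4: exactly one of each extreme
  lab4 <- classify_bulk_quartile(data.frame(unit_id = letters[1:4],
                                            delta = c(3, 1, 4, 2)))
  expect_equal(sum(lab4 == "LLI-like"), 1)
  expect_equal(sum(lab4 == "BL"), 1)
  expect_equal(unname(lab4["c"]), "LLI-like")
  # ties are resolved by unit id, deterministically
  tied <- data.frame(unit_id = c("b", "a", "d", "c"), delta = rep(0, 4))
  labt <- classify_bulk_quartile(tied)
  expect_equal(unname(labt["a"]), "LLI-like")
  expect_equal(unname(labt["d"]), "BL")
  expect_error(classify_bulk_quartile(data.frame(unit_id = "x", delta = 1)),
               "at least 4")
})

test_that("bulk sign rule is strict on both sides", {
  sc <- data.frame(unit_id = c("a", "b", "c"), delta = c(0.3, -0.3, 0))
  lab <- classify_bulk_sign(sc)
  expect_equal(unname(lab), c("LLI-like", "BL-like", "intermediate"))
})

test_that("quartile and sign rules agree on extremes of symmetric deltas", {
  for (sd in 1:20) {
    d <- withr::with_seed(sd, {
      half <- rexp(10) + 0.01
      sample(c(half, -half))  # symmetric about 0, no zeros
    })
    sc <- data.frame(unit_id = sprintf("u%02d", 1:20), delta = d)
    q <- classify_bulk_quartile(sc)
    s <- classify_bulk_sign(sc)
    expect_true(all(s[q == "LLI-like"] == "LLI-like"))
    expect_true(all(s[q == "BL"] == "BL-like"))
  }
})

test_that("single-cell quantile rule demands exactly one threshold hit", {
  sc <- rbind(c(10, 0, 0), c(10, 10, 0), c(0, 0, 0), c(1, 1, 1),
              c(0, 10, 0), c(2, 1, 0), c(1, 2, 0), c(3, 0, 1))
  dimnames(sc) <- list(paste0("c", 1:8), c("LLI", "BL", "MP"))
  lab <- classify_cells_quantile(sc, q = 0.75)
  expect_equal(unname(lab["c1"]), "LLI")        # only LLI threshold met
  expect_equal(unname(lab["c2"]), "unidentified")  # both met
  expect_equal(unname(lab["c3"]), "unidentified")  # none met
  # identical scores: every cell meets every threshold -> unidentified
  same <- matrix(1, 5, 3, dimnames = list(paste0("c", 1:5),
                                          c("LLI", "BL", "MP")))
  expect_true(all(classify_cells_quantile(same) == "unidentified"))
  expect_error(classify_cells_quantile(sc[1:3, ]), "at least 4")
})

test_that("marker argmax assignment follows canonical CAF markers", {
  mks <- unlist(caf_markers())
  genes <- c(mks, "other1", "other2")
  cells <- matrix(0, length(genes), 3,
                  dimnames = list(genes, c("c1", "c2", "c3")))
  cells["FN1", "c1"] <- 10                     # only FN1 among markers
  cells["other1", "c2"] <- 5                   # all markers zero
  cells["C3", "c3"] <- 8
  lab <- assign_marker_subtype(cells)
  expect_equal(unname(lab["c1"]), "myCAF")
  expect_equal(unname(lab["c2"]), "unassigned")
  expect_equal(unname(lab["c3"]), "iCAF")
})

test_that("marker assignment recovers planted CAF mixtures", {
  rec <- vapply(1:5, function(sd) {
    sc <- simulate_single_cells(sim_config(seed = sd,
                                           n_cells_per_type = 100))
    lab <- assign_marker_subtype(sc$counts)
    caf <- names(sc$truth$cell_labels)[sc$truth$cell_labels %in%
                                         names(caf_markers())]
    mean(lab[caf] == sc$truth$cell_labels[caf])
  }, numeric(1))
  expect_gte(median(rec), 0.95)
})

test_that("M1/M2 scoring flags undefined ratios and is deterministic", {
  genes <- c(m1_markers(), m2_markers(), paste0("bg", 1:30))
  ncell <- 12
  cells <- matrix(rpois(length(genes) * ncell, 2), length(genes), ncell,
                  dimnames = list(genes, paste0("c", 1:ncell)))
  cells[m2_markers(), ] <- cells[m2_markers(), ] + 50  # everyone M2
  res <- m1_m2_scores(cells, seed = 3,
                      sample_of = setNames(rep("s1", ncell),
                                           paste0("c", 1:ncell)))
  expect_true(res$ratio$undefined)
  expect_true(all(res$scores$diff > 0))
  res2 <- m1_m2_scores(cells, seed = 3)
  expect_identical(res$scores, res2$scores)
  expect_error(m1_m2_scores(cells, m1_set = c("CD80", "CD163")), "disjoint")
})

test_that("planted tumor subtypes classify correctly end to end", {
  sc <- simulate_single_cells(sim_config(seed = 21, n_cells_per_type = 80,
                                         dropout_rate = 0))
  tumor <- names(sc$truth$cell_labels)[sc$truth$cell_labels %in%
                                         c("LLI", "BL", "MP")]
  expr <- log1p(sc$counts[, tumor])
  scores <- vapply(sc$truth$signatures, function(g)
    module_score(expr, g, seed = 5), numeric(length(tumor)))
  # dropout-free strong separation: all LLI cells outrank all BL cells
  lli <- sc$truth$cell_labels[tumor] == "LLI"
  bl <- sc$truth$cell_labels[tumor] == "BL"
  expect_gt(min(scores[lli, "LLI"]), max(scores[bl, "LLI"]))
  lab <- classify_cells_quantile(scores, q = 0.75)
  agree <- mean(lab[lab != "unidentified"] ==
                  sc$truth$cell_labels[tumor][lab != "unidentified"])
  expect_gt(agree, 0.95)
})
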