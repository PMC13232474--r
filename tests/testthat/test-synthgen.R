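# Generators: determinism, planted-effect identities, geometry of the
# planted ground truth.

test_that("generators are byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 7, n_peaks = 300, n_genes = 200,
                    n_diff_peaks_per_subtype = 20, n_cells_per_type = 20,
                    n_cells_atac = 20, fragments_per_cell = 50,
                    image_size = 64, near_radius = 10, far_min = 28,
                    n_points_per_cat = 50)
  expect_identical(simulate_bulk_cohort(cfg), simulate_bulk_cohort(cfg))
  expect_identical(simulate_single_cells(cfg), simulate_single_cells(cfg))
  expect_identical(simulate_fragments(cfg), simulate_fragments(cfg))
  expect_identical(simulate_ihc_image(cfg), simulate_ihc_image(cfg))
  expect_identical(simulate_spatial(cfg), simulate_spatial(cfg))
  lab <- rep(c("LLI", "BL"), each = 10)
  expect_identical(simulate_survival(lab, cfg), simulate_survival(lab, cfg))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(dropout_rate = 1), "dropout_rate")
  expect_error(sim_config(lib_size_range = c(10, 5)), "lib_size_range")
  expect_error(sim_config(n_peaks = 0), "positive count")
  expect_error(sim_config(image_size = 32), "image_size")
  expect_error(sim_config(cnv_segments = data.frame(
    chrom = "chrS1", start = 0, end = 1e6, copy_ratio = -1)), "copy_ratio")
  expect_error(sim_config(cnv_segments = data.frame(
    chrom = c("chrS1", "chrS1"), start = c(0, 5e5), end = c(1e6, 2e6),
    copy_ratio = c(2, 2))), "overlapping")
})

test_that("planted bulk fold change matches the NB mean identity", {
  # ~500 planted peaks pooled over the three subtypes, 6+6 contrast each
  sim <- small_cohort(seed = 3, n_diff_peaks_per_subtype = 170)
  tr <- sim$truth
  norm <- normalize_counts(sim$peaks)
  ratios <- unlist(lapply(c("LLI", "BL", "MP"), function(s) {
    own <- names(tr$subtype_of_sample)[tr$subtype_of_sample == s]
    other <- names(tr$subtype_of_sample)[tr$subtype_of_sample !=
                                           s][seq_along(own)]
    log2(rowMeans(norm[tr$diff_peak_ids[[s]], own]) /
           rowMeans(norm[tr$diff_peak_ids[[s]], other]))
  }))
  expect_gte(length(ratios), 500)
  expect_lt(abs(mean(ratios) - 6), 0.3)
})

test_that("zero planted effect gives equal group means", {
  sim <- small_cohort(seed = 5, planted_lfc = 0, n_peaks = 500,
                      n_genes = 300, n_diff_peaks_per_subtype = 30)
  tr <- sim$truth
  norm <- normalize_counts(sim$peaks)
  lli <- names(tr$subtype_of_sample)[tr$subtype_of_sample == "LLI"]
  bl <- names(tr$subtype_of_sample)[tr$subtype_of_sample == "BL"]
  r <- log2(rowMeans(norm[, lli]) / rowMeans(norm[, bl]))
  expect_lt(abs(mean(r)), 0.1)
})

test_that("fragment densities track planted copy ratio and GC bias", {
  # neutral genome, flat bias: bin densities equal in expectation
  cfg0 <- sim_config(seed = 2, cnv_segments = data.frame(
    chrom = character(0), start = numeric(0), end = numeric(0),
    copy_ratio = numeric(0)))
  fr0 <- simulate_fragments(cfg0)
  cov0 <- offtarget_coverage(fr0$fragments, fr0$bins, fr0$peaks)
  d0 <- cov0$density[!cov0$masked, 1]
  expect_lt(stats::sd(d0) / mean(d0), 0.2)  # Poisson-level spread only

  # planted gain: mean density about twice the neutral level
  fr <- simulate_fragments(sim_config(seed = 2))
  cov <- offtarget_coverage(fr$fragments, fr$bins, fr$peaks)
  tr <- fr$truth$cnv_log2_of_bin
  ok <- !cov$masked
  gain_ratio <- mean(cov$density[tr > 0.5 & ok, 1]) /
    mean(cov$density[tr == 0 & ok, 1])
  expect_lt(abs(gain_ratio - 2), 0.15)

  # steep quadratic GC bias, no CNV: density tracks the planted bias curve
  cfgg <- sim_config(seed = 2, cnv_segments = cfg0$cnv_segments,
                     gc_bias_coeffs = c(0.2, 0, 2))
  frg <- simulate_fragments(cfgg)
  covg <- offtarget_coverage(frg$fragments, frg$bins, frg$peaks)
  okg <- !covg$masked
  gb <- frg$truth$gc[okg]
  expected <- 0.2 + 2 * gb^2
  expect_gt(stats::cor(covg$density[okg, 1], expected), 0.8)
})

test_that("IHC generator plants the marker geometry it promises", {
  cfg <- sim_config(seed = 4, image_size = 128, n_nuclei = 0, noise_sd = 0)
  im <- simulate_ihc_image(cfg)
  # without nuclei/noise the blue>red filter removes no marker pixel
  mk0 <- im$truth$marker_zone_masks$KRT5 | im$truth$marker_zone_masks$KRT20
  expect_identical(remove_blue_pixels(im$rgb, mk0), mk0)
  # near marker median distance < far marker by the configured gap
  d5 <- median(im$truth$true_distances$KRT5)
  d20 <- median(im$truth$true_distances$KRT20)
  expect_lt(d5, cfg$near_radius)
  expect_gte(d20, cfg$far_min - cfg$blob_radius)
  # swapped config reverses the ordering
  im_sw <- simulate_ihc_image(cfg, swap_markers = TRUE)
  expect_gt(median(im_sw$truth$true_distances$KRT5),
            median(im_sw$truth$true_distances$KRT20))
  expect_error(simulate_ihc_image(sim_config(seed = 4, vessel_width = 0)),
               "vessel")
})

test_that("survival generator: null is null and degenerate censoring errors", {
  lab <- rep(c("LLI", "BL"), each = 60)
  p_null <- vapply(1:40, function(sd)
    logrank_test(simulate_survival(lab, sim_config(seed = sd,
                                                   hazard_ratio = 1)))$p,
    numeric(1))
  # p roughly uniform: KS-style sanity on mean and spread
  expect_gt(mean(p_null), 0.3)
  expect_lt(mean(p_null), 0.7)
  expect_error(simulate_survival(c(a1 = "weird"), sim_config(seed = 1)),
               "unknown label")
  # everything censored -> downstream log-rank is undefined and says so
  sv <- simulate_survival(lab, sim_config(seed = 2, censor_max = 1e-9))
  expect_true(all(sv$event == 0))
  expect_error(logrank_test(sv), "no observed events")
})

test_that("log-rank detects a planted hazard ratio of 3", {
  lab <- rep(c("LLI", "BL"), each = 200)
  p <- vapply(1:100, function(sd)
    logrank_test(simulate_survival(lab, sim_config(seed = sd)))$p,
    numeric(1))
  expect_gte(mean(p < 0.01), 0.95)
})
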