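#' Simulation configuration for the synthetic study cohort
#'
#' Builds the single configuration object consumed by all `simulate_*()`
#' generators. Defaults describe a three-subtype (LLI / BL / MP) cohort with
#' strongly planted differential enhancers and linked differential genes,
#' negative-binomial counts with library-size variation, single-cell mixtures
#' of tumor and microenvironment populations, scATAC fragment sets with
#' planted copy-number segments and GC-dependent coverage bias, dual-marker
#' IHC images and subtype-dependent progression hazards.
#'
#' @param n_samples_per_subtype bulk samples per subtype (>= 2).
#' @param n_peaks total H3K27ac peaks in the bulk peak matrix.
#' @param n_genes total genes in the annotation / expression matrix.
#' @param n_diff_peaks_per_subtype planted differential peaks per subtype;
#'   every planted peak is placed near the TSS of one planted signature gene.
#' @param n_signature_genes planted signature genes per subtype.
#' @param n_decoy_genes per subtype, genes given the planted expression fold
#'   change but no nearby differential peak (they must be rejected during
#'   signature derivation).
#' @param planted_lfc log2 fold change planted on differential peaks and
#'   their linked genes.
#' @param nb_dispersion negative-binomial dispersion phi (variance
#'   mu + phi * mu^2); 0 gives Poisson counts.
#' @param lib_size_range length-2 positive increasing vector of total-count
#'   bounds; per-sample totals are drawn uniformly inside it.
#' @param n_cells_per_type cells per population in the single-cell generator.
#' @param dropout_rate per-entry zeroing probability in the single-cell
#'   matrix, in [0, 1).
#' @param cell_lfc log2 overexpression of signature/marker genes in their
#'   own cell population.
#' @param chrom_sizes named vector of synthetic chromosome lengths (bp).
#' @param bin_size genome bin width in bp for the CNV generator/caller.
#' @param cnv_segments data.frame (chrom, start, end, copy_ratio) of planted
#'   copy-number segments; must not overlap; copy_ratio > 0.
#' @param gc_bias_coeffs polynomial coefficients (intercept first) mapping GC
#'   fraction to relative coverage; must stay positive on [0, 1].
#' @param n_cells_atac barcodes in the fragment generator.
#' @param fragments_per_cell expected off-target fragments per barcode.
#' @param n_atac_peaks,atac_peak_width accessibility peaks emitted alongside
#'   the off-target fragments (on-target fragments are generated inside them).
#' @param frac_on_target expected fraction of on-target fragments.
#' @param image_size IHC image side in pixels (>= 64).
#' @param vessel_width width in pixels of the vessel band along the left
#'   image edge.
#' @param near_radius,far_min pixel distances from the vessel defining where
#'   near-vessel and distal marker blobs are planted.
#' @param n_blobs_per_marker,blob_radius marker blob count and radius.
#' @param n_nuclei hematoxylin-stained nuclei drawn on the image.
#' @param noise_sd Gaussian RGB noise standard deviation.
#' @param n_points_per_cat points per category in the spatial generator.
#' @param attraction_radius radius (same units as coordinates) within which
#'   the attracted target category is planted around anchor points.
#' @param field width/height of the spatial rectangle.
#' @param hazard_ratio LLI-vs-BL progression hazard ratio.
#' @param base_hazard baseline exponential event hazard (per month).
#' @param censor_max upper bound of the uniform censoring time (months).
#' @param seed integer seed from which every generator derives its RNG state.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples_per_subtype = 6,
                       n_peaks = 2000,
                       n_genes = 1200,
                       n_diff_peaks_per_subtype = 60,
                       n_signature_genes = 15,
                       n_decoy_genes = 8,
                       planted_lfc = 6,
                       nb_dispersion = 0.05,
                       lib_size_range = c(150000, 300000),
                       n_cells_per_type = 200,
                       dropout_rate = 0.3,
                       cell_lfc = 4,
                       chrom_sizes = c(chrS1 = 200e6, chrS2 = 200e6,
                                       chrS3 = 200e6),
                       bin_size = 1e6,
                       cnv_segments = data.frame(
                         chrom = c("chrS2", "chrS3"),
                         start = c(0, 170e6),
                         end = c(30e6, 200e6),
                         copy_ratio = c(2, 0.5)
                       ),
                       gc_bias_coeffs = c(1, 0, 0),
                       n_cells_atac = 200,
                       fragments_per_cell = 500,
                       n_atac_peaks = 500,
                       atac_peak_width = 500,
                       frac_on_target = 0.2,
                       image_size = 256,
                       vessel_width = 20,
                       near_radius = 30,
                       far_min = 90,
                       n_blobs_per_marker = 40,
                       blob_radius = 3,
                       n_nuclei = 150,
                       noise_sd = 8,
                       n_points_per_cat = 300,
                       attraction_radius = 20,
                       field = c(1000, 1000),
                       hazard_ratio = 3,
                       base_hazard = 0.02,
                       censor_max = 120,
                       seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  counts <- c("n_samples_per_subtype", "n_peaks", "n_genes",
              "n_diff_peaks_per_subtype", "n_signature_genes",
              "n_decoy_genes", "n_cells_per_type", "n_cells_atac",
              "n_atac_peaks", "image_size", "n_points_per_cat")
  for (nm in counts) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1L || cfg[[nm]] <= 0)
      stop("config error: '", nm, "' must be a positive count", call. = FALSE)
  }
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1)
    stop("config error: dropout_rate must be in [0, 1)", call. = FALSE)
  if (cfg$nb_dispersion < 0)
    stop("config error: nb_dispersion must be >= 0", call. = FALSE)
  ls <- cfg$lib_size_range
  if (length(ls) != 2L || any(ls <= 0) || ls[1] > ls[2])
    stop("config error: lib_size_range bounds must be positive and ordered",
         call. = FALSE)
  if (cfg$image_size < 64)
    stop("config error: image_size must be >= 64", call. = FALSE)
  seg <- cfg$cnv_segments
  if (nrow(seg)) {
    if (any(seg$copy_ratio <= 0))
      stop("config error: copy_ratio must be > 0", call. = FALSE)
    if (any(!seg$chrom %in% names(cfg$chrom_sizes)))
      stop("config error: cnv_segments on unknown chromosome", call. = FALSE)
    if (any(seg$end > cfg$chrom_sizes[seg$chrom]) || any(seg$start < 0))
      stop("config error: cnv_segments outside chromosome bounds",
           call. = FALSE)
    for (ch in unique(seg$chrom)) {
      s <- seg[seg$chrom == ch, , drop = FALSE]
      s <- s[order(s$start), , drop = FALSE]
      if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
        stop("config error: overlapping cnv_segments", call. = FALSE)
    }
  }
  gb <- gc_bias_fun(cfg$gc_bias_coeffs)
  if (any(gb(seq(0, 1, by = 0.01)) <= 0))
    stop("config error: gc_bias_coeffs must be positive on [0, 1]",
         call. = FALSE)
  if (cfg$hazard_ratio <= 0)
    stop("config error: hazard_ratio must be > 0", call. = FALSE)
  invisible(cfg)
}

# polynomial gc -> relative coverage, intercept-first coefficients
gc_bias_fun <- function(coeffs) {
  force(coeffs)
  function(g) {
    out <- rep(0, length(g))
    for (i in seq_along(coeffs)) out <- out + coeffs[i] * g^(i - 1L)
    out
  }
}

# every generator draws from a private stream derived from the single seed;
# offsets keep the streams distinct while byte-reproducible
sim_seed <- function(cfg, offset) {
  (as.integer(cfg$seed) + offset) %% .Machine$integer.max
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed", x$seed, "|",
      x$n_samples_per_subtype, "samples/subtype,",
      x$n_peaks, "peaks,", x$n_genes, "genes, planted lfc",
      x$planted_lfc, "\n")
  invisible(x)
}
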