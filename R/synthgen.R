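# Synthetic-data generators. Every generator derives its RNG stream from the
# single cfg$seed (via sim_seed offsets) so a fixed seed gives byte-identical
# output, and each returns a `truth` element carrying the planted ground
# truth used by the test-suite oracles.

rnb <- function(n, mu, phi) {
  if (phi > 0) stats::rnbinom(n, size = 1 / phi, mu = mu)
  else stats::rpois(n, lambda = mu)
}

# deterministic gene annotation: TSS laid out on a jittered grid across the
# synthetic chromosomes; spacing >> peak placement jitter, so a planted peak's
# nearest TSS is always its own gene
make_gene_annotation <- function(cfg) {
  total <- sum(cfg$chrom_sizes)
  spacing <- total / cfg$n_genes
  pos0 <- (seq_len(cfg$n_genes) - 0.5) * spacing
  jitter <- stats::runif(cfg$n_genes, -0.2, 0.2) * spacing
  pos <- pmin(pmax(round(pos0 + jitter), 1), total - 1)
  offsets <- c(0, cumsum(as.numeric(cfg$chrom_sizes)))
  chrom_idx <- findInterval(pos, offsets, rightmost.closed = TRUE,
                            left.open = TRUE)
  data.frame(
    gene_id = sprintf("gene_%04d", seq_len(cfg$n_genes)),
    chrom = names(cfg$chrom_sizes)[chrom_idx],
    tss = pos - offsets[chrom_idx],
    strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Simulate a bulk three-subtype cohort with planted differential peaks
#'
#' Generates an H3K27ac-style peak-by-sample count matrix, a matched
#' gene-by-sample expression count matrix and a gene annotation. Counts are
#' negative binomial with mean `s_j * q_g * 2^lfc` where the planted log2
#' fold change applies to a peak/gene in samples of its own subtype.
#' Each planted differential peak sits within 400 kb (in fact within 10 kb)
#' of the TSS of a planted signature gene carrying the same fold change;
#' per subtype, `n_decoy_genes` extra genes carry the expression fold change
#' without any nearby differential peak.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `peaks` ([peak_matrix()]), `expr`
#'   (gene-by-sample integer matrix), `annotation` (gene_id, chrom, tss,
#'   strand), and `truth` (subtype_of_sample, diff_peak_ids,
#'   signature_genes, decoy_genes, peak_gene map).
#' @export
simulate_bulk_cohort <- function(cfg) {
  validate_sim_config(cfg)
  if (cfg$n_samples_per_subtype < 2)
    stop("config error: need n_samples_per_subtype >= 2")
  subtypes <- c("LLI", "BL", "MP")
  withr::with_seed(sim_seed(cfg, 101L), {
    n <- cfg$n_samples_per_subtype
    sample_ids <- as.vector(vapply(subtypes, function(s)
      sprintf("%s_%02d", s, seq_len(n)), character(n)))
    subtype_of_sample <- stats::setNames(rep(subtypes, each = n), sample_ids)

    ann <- make_gene_annotation(cfg)
    n_special <- cfg$n_signature_genes + cfg$n_decoy_genes
    if (3L * n_special > cfg$n_genes)
      stop("config error: n_genes too small for planted gene sets")
    special <- sample(ann$gene_id, 3L * n_special)
    signature_genes <- decoy_genes <- list()
    for (i in seq_along(subtypes)) {
      block <- special[((i - 1L) * n_special + 1L):(i * n_special)]
      signature_genes[[subtypes[i]]] <- block[seq_len(cfg$n_signature_genes)]
      decoy_genes[[subtypes[i]]] <- block[-seq_len(cfg$n_signature_genes)]
    }

    # planted differential peaks: each within 10 kb of its signature gene TSS
    n_diff_total <- 3L * cfg$n_diff_peaks_per_subtype
    if (n_diff_total > cfg$n_peaks)
      stop("config error: n_peaks too small for planted differential peaks")
    peak_rows <- vector("list", cfg$n_peaks)
    peak_gene <- character(0)
    diff_peak_ids <- stats::setNames(vector("list", 3L), subtypes)
    k <- 0L
    for (s in subtypes) {
      host <- rep_len(signature_genes[[s]], cfg$n_diff_peaks_per_subtype)
      ids <- character(cfg$n_diff_peaks_per_subtype)
      for (j in seq_len(cfg$n_diff_peaks_per_subtype)) {
        k <- k + 1L
        g <- ann[ann$gene_id == host[j], ]
        center <- g$tss + round(stats::runif(1, -10000, 10000))
        center <- min(max(center, 501), cfg$chrom_sizes[[g$chrom]] - 501)
        id <- sprintf("peak_%05d", k)
        peak_rows[[k]] <- data.frame(chrom = g$chrom, start = center - 500,
                                     end = center + 500, id = id,
                                     stringsAsFactors = FALSE)
        peak_gene[id] <- g$gene_id
        ids[j] <- id
      }
      diff_peak_ids[[s]] <- ids
    }
    # background peaks anywhere in the genome
    n_bg <- cfg$n_peaks - n_diff_total
    bg_chrom <- sample(names(cfg$chrom_sizes), n_bg, replace = TRUE,
                       prob = cfg$chrom_sizes / sum(cfg$chrom_sizes))
    bg_center <- floor(stats::runif(n_bg, 501,
                                    cfg$chrom_sizes[bg_chrom] - 501))
    for (j in seq_len(n_bg)) {
      k <- k + 1L
      peak_rows[[k]] <- data.frame(chrom = bg_chrom[j],
                                   start = bg_center[j] - 500,
                                   end = bg_center[j] + 500,
                                   id = sprintf("peak_%05d", k),
                                   stringsAsFactors = FALSE)
    }
    peaks <- do.call(rbind, peak_rows)

    # NB counts: mean = s_j * q_g * 2^(lfc if feature differential for the
    # sample's subtype)
    q_peak <- stats::rgamma(cfg$n_peaks, shape = 4, scale = 25)
    q_gene <- stats::rgamma(cfg$n_genes, shape = 4, scale = 25)
    n_samp <- length(sample_ids)
    s_peak <- stats::runif(n_samp, cfg$lib_size_range[1],
                           cfg$lib_size_range[2]) / sum(q_peak)
    s_gene <- stats::runif(n_samp, cfg$lib_size_range[1],
                           cfg$lib_size_range[2]) / sum(q_gene)

    lfc_peak <- matrix(0, cfg$n_peaks, n_samp,
                       dimnames = list(peaks$id, sample_ids))
    lfc_gene <- matrix(0, cfg$n_genes, n_samp,
                       dimnames = list(ann$gene_id, sample_ids))
    for (s in subtypes) {
      cols <- subtype_of_sample == s
      lfc_peak[diff_peak_ids[[s]], cols] <- cfg$planted_lfc
      lfc_gene[c(signature_genes[[s]], decoy_genes[[s]]), cols] <-
        cfg$planted_lfc
    }
    mu_peak <- (q_peak %o% s_peak) * 2^lfc_peak
    mu_gene <- (q_gene %o% s_gene) * 2^lfc_gene
    counts_peak <- matrix(rnb(length(mu_peak), mu_peak, cfg$nb_dispersion),
                          nrow = cfg$n_peaks,
                          dimnames = dimnames(lfc_peak))
    counts_gene <- matrix(rnb(length(mu_gene), mu_gene, cfg$nb_dispersion),
                          nrow = cfg$n_genes,
                          dimnames = dimnames(lfc_gene))

    list(
      peaks = peak_matrix(peaks, counts_peak, sample_ids),
      expr = counts_gene,
      annotation = ann,
      truth = list(subtype_of_sample = subtype_of_sample,
                   diff_peak_ids = diff_peak_ids,
                   signature_genes = signature_genes,
                   decoy_genes = decoy_genes,
                   peak_gene = peak_gene)
    )
  })
}

#' Simulate a single-cell expression mixture of tumor and TME populations
#'
#' Cells are drawn for the three tumor subtypes (overexpressing their
#' signature genes), the five CAF subtypes (overexpressing their canonical
#' marker), M1/M2 macrophages (overexpressing their marker sets) and an
#' unstructured "other" population. Counts are Poisson around a gene
#' baseline, boosted by `2^cell_lfc` for a population's program genes, with
#' per-entry dropout.
#'
#' @param cfg a [sim_config()].
#' @param signatures optional named list (LLI/BL/MP) of signature gene
#'   vectors; when `NULL`, planted sets are drawn from the synthetic gene
#'   universe.
#' @return list with `counts` (gene-by-cell matrix), and `truth`
#'   (`cell_labels` named by barcode, `signatures` used).
#' @export
simulate_single_cells <- function(cfg, signatures = NULL) {
  validate_sim_config(cfg)
  withr::with_seed(sim_seed(cfg, 202L), {
    markers <- unique(c(unlist(caf_markers()), m1_markers(), m2_markers()))
    genes <- c(sprintf("gene_%04d", seq_len(cfg$n_genes)), markers)
    if (is.null(signatures)) {
      picked <- sample(sprintf("gene_%04d", seq_len(cfg$n_genes)),
                       3L * cfg$n_signature_genes)
      signatures <- list(
        LLI = picked[seq_len(cfg$n_signature_genes)],
        BL = picked[cfg$n_signature_genes + seq_len(cfg$n_signature_genes)],
        MP = picked[2L * cfg$n_signature_genes +
                      seq_len(cfg$n_signature_genes)]
      )
    }
    if (any(!lengths(signatures)) || !all(unlist(signatures) %in% genes))
      stop("config error: empty or unknown signature sets")

    programs <- c(signatures, caf_markers(),
                  list(M1 = m1_markers(), M2 = m2_markers(), other = NULL))
    types <- names(programs)
    n_cells <- cfg$n_cells_per_type * length(types)
    barcodes <- sprintf("BC%05d", seq_len(n_cells))
    labels <- stats::setNames(rep(types, each = cfg$n_cells_per_type),
                              barcodes)

    base_mu <- stats::setNames(stats::rgamma(length(genes), shape = 2,
                                             scale = 2), genes)
    counts <- matrix(0L, length(genes), n_cells,
                     dimnames = list(genes, barcodes))
    mu_mat <- matrix(0, length(genes), n_cells)
    for (ty in types) {
      cols <- which(labels == ty)
      mu <- base_mu
      prog <- programs[[ty]]
      if (length(prog)) mu[prog] <- mu[prog] * 2^cfg$cell_lfc
      mu_mat[, cols] <- mu
      counts[, cols] <- stats::rpois(length(genes) * length(cols),
                                     lambda = rep(mu, length(cols)))
    }
    if (cfg$dropout_rate > 0) {
      # technical zeros are mean-dependent: highly expressed genes are
      # essentially never dropped, as in real droplet data
      p_drop <- cfg$dropout_rate * exp(-0.1 * mu_mat)
      keep <- stats::rbinom(length(counts), 1L, 1 - p_drop)
      counts <- counts * keep
      dimnames(counts) <- list(genes, barcodes)
    }
    list(counts = counts,
         truth = list(cell_labels = labels, signatures = signatures))
  })
}

#' Simulate scATAC fragments with planted copy-number segments and GC bias
#'
#' Off-target fragments are generated per 1 Mb genome bin with expected
#' count proportional to `copy_ratio * gc_bias(GC) * effective window`;
#' on-target fragments are additionally emitted inside accessibility peaks.
#' Per-bin GC fractions are drawn once from Beta(20, 20).
#'
#' @param cfg a [sim_config()].
#' @return list with `fragments` (chrom, start, end, barcode; sorted),
#'   `bins` (a [make_bins()] table with GC and effective length), `peaks`
#'   (BED-like data.frame) and `truth` (`cnv_log2_of_bin`, `gc`,
#'   `barcodes`).
#' @export
simulate_fragments <- function(cfg) {
  validate_sim_config(cfg)
  withr::with_seed(sim_seed(cfg, 303L), {
    # accessibility peaks
    pk_chrom <- sample(names(cfg$chrom_sizes), cfg$n_atac_peaks,
                       replace = TRUE,
                       prob = cfg$chrom_sizes / sum(cfg$chrom_sizes))
    half <- ceiling(cfg$atac_peak_width / 2)
    pk_center <- floor(stats::runif(cfg$n_atac_peaks, half + 1,
                                    cfg$chrom_sizes[pk_chrom] - half - 1))
    peaks <- data.frame(chrom = pk_chrom, start = pk_center - half,
                        end = pk_center + half,
                        id = sprintf("apeak_%04d", seq_len(cfg$n_atac_peaks)),
                        stringsAsFactors = FALSE)
    peaks <- peaks[order(peaks$chrom, peaks$start), ]

    gc <- stats::rbeta(n_bins_of(cfg), 20, 20)
    bins <- make_bins(cfg$chrom_sizes, cfg$bin_size, gc_source = gc,
                      peaks = peaks)

    # per-bin expected off-target count
    ratio <- bin_copy_ratio(bins, cfg$cnv_segments)
    gb <- gc_bias_fun(cfg$gc_bias_coeffs)
    w <- ratio * gb(bins$gc) * bins$effective_length
    total_off <- cfg$n_cells_atac * cfg$fragments_per_cell
    lambda <- total_off * w / sum(w)
    n_b <- stats::rpois(length(lambda), lambda)

    barcodes <- sprintf("CB%04d", seq_len(cfg$n_cells_atac))
    frag_len <- 100L
    frags <- vector("list", length(n_b) + 1L)
    for (b in which(n_b > 0)) {
      # off-target: uniform midpoints in the bin, rejecting peak overlaps
      mid <- draw_offtarget_midpoints(n_b[b], bins$start[b], bins$end[b],
                                      peaks[peaks$chrom == bins$chrom[b], ])
      frags[[b]] <- data.frame(chrom = bins$chrom[b],
                               start = pmax(mid - frag_len %/% 2L, 0L),
                               end = mid + frag_len %/% 2L,
                               barcode = sample(barcodes, n_b[b],
                                                replace = TRUE),
                               stringsAsFactors = FALSE)
    }
    # on-target fragments inside peaks
    n_on <- stats::rpois(1, total_off * cfg$frac_on_target /
                              (1 - cfg$frac_on_target))
    if (n_on > 0) {
      pk <- sample.int(nrow(peaks), n_on, replace = TRUE)
      mid <- floor(stats::runif(n_on, peaks$start[pk] + 1, peaks$end[pk] - 1))
      frags[[length(frags)]] <- data.frame(
        chrom = peaks$chrom[pk],
        start = pmax(mid - frag_len %/% 2L, 0L),
        end = mid + frag_len %/% 2L,
        barcode = sample(barcodes, n_on, replace = TRUE),
        stringsAsFactors = FALSE)
    }
    fragments <- do.call(rbind, frags[!vapply(frags, is.null, logical(1))])
    fragments <- fragments[order(fragments$chrom, fragments$start), ]
    rownames(fragments) <- NULL

    list(fragments = fragments, bins = bins, peaks = peaks,
         truth = list(cnv_log2_of_bin = log2(ratio), gc = bins$gc,
                      barcodes = barcodes))
  })
}

n_bins_of <- function(cfg) {
  sum(ceiling(cfg$chrom_sizes / cfg$bin_size))
}

# true per-bin copy ratio: a bin takes a segment's ratio when its midpoint
# falls inside the segment, 1 elsewhere
bin_copy_ratio <- function(bins, segments) {
  ratio <- rep(1, nrow(bins))
  if (!nrow(segments)) return(ratio)
  mid <- (bins$start + bins$end) / 2
  for (i in seq_len(nrow(segments))) {
    hit <- bins$chrom == segments$chrom[i] & mid >= segments$start[i] &
      mid < segments$end[i]
    ratio[hit] <- segments$copy_ratio[i]
  }
  ratio
}

draw_offtarget_midpoints <- function(n, start, end, chrom_peaks) {
  mid <- floor(stats::runif(n, start, end))
  if (nrow(chrom_peaks)) {
    for (iter in 1:50) {
      inside <- rep(FALSE, length(mid))
      for (j in seq_len(nrow(chrom_peaks)))
        inside <- inside | (mid >= chrom_peaks$start[j] &
                              mid < chrom_peaks$end[j])
      if (!any(inside)) break
      mid[inside] <- floor(stats::runif(sum(inside), start, end))
    }
  }
  mid
}

#' Simulate a dual-marker IHC image with a vessel mask
#'
#' Produces an RGB image on a light background with DAB-brown (R > B)
#' marker blobs — one marker planted within `near_radius` pixels of the
#' vessel band, the other beyond `far_min` — plus hematoxylin-blue (B > R)
#' nuclei and Gaussian noise. The vessel is a band along the left edge.
#'
#' @param cfg a [sim_config()].
#' @param swap_markers when `TRUE` the two markers trade zones (KRT20 near
#'   the vessel instead of KRT5).
#' @return list with `rgb` (H x W x 3 array in 0..255), `vessel` (logical
#'   matrix), and `truth` (`marker_zone_masks`, `true_distances` in pixels).
#' @export
simulate_ihc_image <- function(cfg, swap_markers = FALSE) {
  validate_sim_config(cfg)
  if (cfg$vessel_width < 1)
    stop("config error: vessel mask empty (vessel_width < 1)")
  if (cfg$vessel_width + cfg$far_min + cfg$blob_radius + 2 >= cfg$image_size)
    stop("config error: far marker zone does not fit inside image_size")
  withr::with_seed(sim_seed(cfg, 404L), {
    S <- cfg$image_size
    dab <- c(150, 90, 60)
    hema <- c(70, 80, 160)
    bgc <- c(235, 230, 228)
    img <- array(0, dim = c(S, S, 3))
    for (ch in 1:3) img[, , ch] <- bgc[ch]

    vessel <- matrix(FALSE, S, S)
    vessel[, seq_len(cfg$vessel_width)] <- TRUE

    paint_disks <- function(img, centers, radius, col) {
      for (i in seq_len(nrow(centers))) {
        r0 <- centers[i, 1]; c0 <- centers[i, 2]
        rr <- max(1, r0 - radius):min(S, r0 + radius)
        cc <- max(1, c0 - radius):min(S, c0 + radius)
        for (r in rr) for (cl in cc)
          if ((r - r0)^2 + (cl - c0)^2 <= radius^2)
            img[r, cl, ] <- col
      }
      img
    }
    disk_mask <- function(centers, radius) {
      m <- matrix(FALSE, S, S)
      for (i in seq_len(nrow(centers))) {
        r0 <- centers[i, 1]; c0 <- centers[i, 2]
        rr <- max(1, r0 - radius):min(S, r0 + radius)
        cc <- max(1, c0 - radius):min(S, c0 + radius)
        for (r in rr) for (cl in cc)
          if ((r - r0)^2 + (cl - c0)^2 <= radius^2) m[r, cl] <- TRUE
      }
      m
    }

    if (cfg$n_nuclei > 0) {
      nuc <- cbind(sample.int(S, cfg$n_nuclei, replace = TRUE),
                   sample.int(S, cfg$n_nuclei, replace = TRUE))
      img <- paint_disks(img, nuc, 2, hema)
    }

    vw <- cfg$vessel_width
    rad <- cfg$blob_radius
    near_d <- stats::runif(cfg$n_blobs_per_marker, rad + 2, cfg$near_radius)
    far_max <- S - vw - rad - 2
    far_d <- stats::runif(cfg$n_blobs_per_marker, cfg$far_min, far_max)
    near_centers <- cbind(sample.int(S, cfg$n_blobs_per_marker, TRUE),
                          vw + round(near_d))
    far_centers <- cbind(sample.int(S, cfg$n_blobs_per_marker, TRUE),
                         vw + round(far_d))
    if (swap_markers) {
      tmp <- near_centers; near_centers <- far_centers; far_centers <- tmp
    }
    # KRT5 blobs are the vessel-proximal marker (unless swapped)
    img <- paint_disks(img, near_centers, rad, dab)
    img <- paint_disks(img, far_centers, rad, dab)
    krt5_mask <- disk_mask(near_centers, rad)
    krt20_mask <- disk_mask(far_centers, rad) & !krt5_mask

    if (cfg$noise_sd > 0)
      img <- img + array(stats::rnorm(length(img), 0, cfg$noise_sd),
                         dim = dim(img))
    img <- pmin(pmax(img, 0), 255)

    # vessel is a full-height band: distance of pixel column c is c - vw
    col_of <- function(mask) which(mask, arr.ind = TRUE)[, 2]
    true_dist <- list(KRT5 = pmax(col_of(krt5_mask) - vw, 0),
                      KRT20 = pmax(col_of(krt20_mask) - vw, 0))
    list(rgb = img, vessel = vessel,
         truth = list(marker_zone_masks = list(KRT5 = krt5_mask,
                                               KRT20 = krt20_mask),
                      true_distances = true_dist))
  })
}

#' Simulate a spatial cell table with one attracted category
#'
#' Points are scattered uniformly in a rectangle; when `attract` is `TRUE`
#' the target category is planted within `attraction_radius` of randomly
#' chosen anchor points, so its co-occurrence ratio around anchors exceeds 1
#' at short range.
#'
#' @param cfg a [sim_config()].
#' @param anchor_cat,target_cat category names for anchors and the
#'   attracted target.
#' @param other_cats uniformly scattered remaining categories.
#' @param attract disable to obtain a fully uniform (null) table.
#' @return data.frame with columns `x`, `y`, `label`.
#' @export
simulate_spatial <- function(cfg, anchor_cat = "MP", target_cat = "myCAF",
                             other_cats = c("iCAF", "apCAF", "other"),
                             attract = TRUE) {
  validate_sim_config(cfg)
  withr::with_seed(sim_seed(cfg, 505L), {
    n <- cfg$n_points_per_cat
    W <- cfg$field[1]; H <- cfg$field[2]
    unif <- function(cat) data.frame(x = stats::runif(n, 0, W),
                                     y = stats::runif(n, 0, H),
                                     label = cat)
    anchors <- unif(anchor_cat)
    others <- do.call(rbind, lapply(other_cats, unif))
    if (attract) {
      host <- sample.int(n, n, replace = TRUE)
      ang <- stats::runif(n, 0, 2 * pi)
      rr <- cfg$attraction_radius * sqrt(stats::runif(n))
      target <- data.frame(
        x = pmin(pmax(anchors$x[host] + rr * cos(ang), 0), W),
        y = pmin(pmax(anchors$y[host] + rr * sin(ang), 0), H),
        label = target_cat)
    } else {
      target <- unif(target_cat)
    }
    out <- rbind(anchors, target, others)
    rownames(out) <- NULL
    out
  })
}

#' Simulate progression survival times with class-dependent hazards
#'
#' Event times are exponential with hazard `base_hazard` for BL-type units
#' and `base_hazard * hazard_ratio` for LLI-type units; censoring is
#' independent Uniform(0, `censor_max`).
#'
#' @param labels named vector mapping unit id to class; classes containing
#'   "LLI" take the elevated hazard, classes containing "BL" the baseline.
#' @param cfg a [sim_config()].
#' @return data.frame with `unit_id`, `time` (months), `event` (0/1),
#'   `group`.
#' @export
simulate_survival <- function(labels, cfg) {
  validate_sim_config(cfg)
  is_lli <- grepl("LLI", labels)
  is_bl <- grepl("BL", labels)
  if (any(!is_lli & !is_bl))
    stop("unknown label(s): ",
         paste(unique(labels[!is_lli & !is_bl]), collapse = ", "))
  withr::with_seed(sim_seed(cfg, 606L), {
    h <- ifelse(is_lli, cfg$base_hazard * cfg$hazard_ratio, cfg$base_hazard)
    t_event <- stats::rexp(length(labels), rate = h)
    t_cens <- stats::runif(length(labels), 0, cfg$censor_max)
    data.frame(unit_id = if (is.null(names(labels)))
                 sprintf("u%03d", seq_along(labels)) else names(labels),
               time = pmin(t_event, t_cens),
               event = as.integer(t_event <= t_cens),
               group = as.character(labels),
               stringsAsFactors = FALSE)
  })
}
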