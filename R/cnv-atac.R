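# Copy-number inference from off-target scATAC fragments: 1 Mb genome bins
# with GC annotation and peak-corrected effective windows, off-target
# coverage densities, GC-matched background averaging and log2 fold changes.

#' Tile a genome into GC-annotated bins with effective window sizes
#'
#' Half-open bins of `bin_size` bp tile each chromosome; terminal partial
#' bins keep their true length. The effective length of a bin is its length
#' minus the bases covered by accessibility peaks (fragments inside peaks
#' are on-target and excluded from coverage, so the denominator shrinks
#' accordingly). GC per bin comes from a numeric table or from windowing a
#' set of sequences; bins with missing GC are masked.
#'
#' @param chrom_sizes named vector of chromosome lengths (bp).
#' @param bin_size bin width in bp (default 1 Mb).
#' @param gc_source either a numeric vector of per-bin GC fractions (in bin
#'   order; NA masks a bin), or named character/DNAStringSet sequences to
#'   window (GC = G+C fraction of each bin's sequence).
#' @param peaks optional BED-like data.frame (`chrom`, `start`, `end`) used
#'   to compute effective lengths; `NULL` leaves them at the bin length.
#' @return data.frame of class `genome_bins`: `chrom`, `start`, `end`,
#'   `gc`, `effective_length`, `masked`.
#' @export
make_bins <- function(chrom_sizes, bin_size = 1e6, gc_source = NULL,
                      peaks = NULL) {
  stopifnot(bin_size > 0)
  rows <- lapply(names(chrom_sizes), function(ch) {
    size <- chrom_sizes[[ch]]
    starts <- seq(0, size - 1, by = bin_size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + bin_size, size),
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, rows)
  n <- nrow(bins)
  gc <- rep(NA_real_, n)
  if (is.numeric(gc_source)) {
    stopifnot(length(gc_source) == n)
    gc <- as.numeric(gc_source)
  } else if (!is.null(gc_source)) {
    seqs <- gc_source
    if (is.character(seqs) && length(seqs) == 1 && file.exists(seqs))
      seqs <- Biostrings::readDNAStringSet(seqs)
    if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
    for (i in seq_len(n)) {
      ch <- bins$chrom[i]
      if (!ch %in% names(seqs)) next
      sq <- seqs[[ch]]
      to <- min(bins$end[i], length(sq))
      if (bins$start[i] + 1 > to) next
      win <- Biostrings::subseq(sq, bins$start[i] + 1, to)
      gc[i] <- sum(Biostrings::letterFrequency(win, c("G", "C"))) /
        length(win)
    }
  }
  eff <- bins$end - bins$start
  if (!is.null(peaks) && nrow(peaks)) {
    bg <- GenomicRanges::GRanges(bins$chrom,
                                 IRanges::IRanges(bins$start + 1, bins$end))
    pg <- GenomicRanges::reduce(GenomicRanges::GRanges(
      peaks$chrom, IRanges::IRanges(peaks$start + 1, peaks$end)))
    ov <- GenomicRanges::findOverlaps(bg, pg)
    if (length(ov)) {
      inter <- IRanges::pintersect(bg[S4Vectors::queryHits(ov)],
                                   pg[S4Vectors::subjectHits(ov)])
      cov <- tapply(IRanges::width(inter), S4Vectors::queryHits(ov), sum)
      eff[as.integer(names(cov))] <- eff[as.integer(names(cov))] - cov
    }
  }
  bins$gc <- gc
  bins$effective_length <- pmax(eff, 0)
  bins$masked <- is.na(gc)
  class(bins) <- c("genome_bins", "data.frame")
  bins
}

#' Off-target fragment coverage per genome bin
#'
#' Fragments whose midpoint lies inside any accessibility peak are discarded
#' (off-target only); the rest are assigned to the bin containing their
#' midpoint (half-open: a midpoint exactly on a boundary belongs to the
#' right-hand bin). Density is fragment count per effective kilobase. Bins
#' whose effective length is below 10% of the modal bin size are masked.
#'
#' @param frags data.frame (`chrom`, `start`, `end`, `barcode`).
#' @param bins a [make_bins()] table.
#' @param peaks BED-like data.frame of accessibility peaks (may be empty).
#' @param unit `"pseudobulk"` (one column), `"cell"` (column per barcode)
#'   or `"cluster"` (requires `cluster_of`).
#' @param cluster_of named vector barcode -> cluster, required for
#'   `unit = "cluster"`.
#' @return list of class `coverage_table`: `bins`, `density` (bins x
#'   units; NA for masked bins), `masked`.
#' @export
offtarget_coverage <- function(frags, bins, peaks,
                               unit = c("pseudobulk", "cell", "cluster"),
                               cluster_of = NULL) {
  unit <- match.arg(unit)
  if (unit == "cluster" && is.null(cluster_of))
    stop("unit 'cluster' requires a barcode-to-cluster map")
  mid <- floor((frags$start + frags$end) / 2)

  # drop on-target fragments (midpoint inside a peak)
  if (!is.null(peaks) && nrow(peaks)) {
    mg <- GenomicRanges::GRanges(frags$chrom, IRanges::IRanges(mid + 1,
                                                               mid + 1))
    pg <- GenomicRanges::GRanges(peaks$chrom,
                                 IRanges::IRanges(peaks$start + 1,
                                                  peaks$end))
    on <- IRanges::overlapsAny(mg, pg)
    frags <- frags[!on, , drop = FALSE]
    mid <- mid[!on]
  }

  # half-open bin containment of the midpoint
  bin_idx <- rep(NA_integer_, length(mid))
  for (ch in unique(bins$chrom)) {
    rows <- which(bins$chrom == ch)
    fr <- which(frags$chrom == ch)
    if (!length(fr)) next
    j <- findInterval(mid[fr], bins$start[rows])
    ok <- j >= 1 & mid[fr] < bins$end[rows][pmax(j, 1)]
    bin_idx[fr[ok]] <- rows[j[ok]]
  }
  keep <- !is.na(bin_idx)
  frags <- frags[keep, , drop = FALSE]
  bin_idx <- bin_idx[keep]

  units <- switch(unit,
                  pseudobulk = "pseudobulk",
                  cell = sort(unique(frags$barcode)),
                  cluster = sort(unique(as.character(cluster_of))))
  unit_of <- switch(unit,
                    pseudobulk = rep("pseudobulk", nrow(frags)),
                    cell = frags$barcode,
                    cluster = as.character(cluster_of[frags$barcode]))
  counts <- matrix(0, nrow(bins), length(units),
                   dimnames = list(NULL, units))
  tab <- table(factor(bin_idx, levels = seq_len(nrow(bins))),
               factor(unit_of, levels = units))
  counts[] <- as.numeric(tab)

  mode_size <- max(bins$end - bins$start)
  masked <- bins$masked | bins$effective_length < 0.1 * mode_size
  density <- counts / (bins$effective_length / 1000)
  density[masked, ] <- NA_real_
  structure(list(bins = bins, density = density, masked = masked),
            class = "coverage_table")
}

#' GC-matched background coverage per bin
#'
#' For each unmasked bin, the `k` unmasked bins (excluding the bin itself)
#' with the smallest absolute GC difference are selected (ties broken by
#' genomic order) and their mean density, per unit, is the background.
#'
#' @param cov a [offtarget_coverage()] result.
#' @param k number of GC-matched bins to average (default 100).
#' @return matrix (bins x units) of background densities; NA for masked
#'   bins.
#' @export
gc_matched_background <- function(cov, k = 100) {
  bins <- cov$bins
  good <- which(!cov$masked)
  if (length(good) < k + 1)
    stop("need at least ", k + 1, " unmasked bins (have ", length(good),
         ")")
  B <- matrix(NA_real_, nrow(bins), ncol(cov$density),
              dimnames = dimnames(cov$density))
  gc <- bins$gc
  for (b in good) {
    others <- setdiff(good, b)
    sel <- others[order(abs(gc[others] - gc[b]), others)][seq_len(k)]
    B[b, ] <- colMeans(cov$density[sel, , drop = FALSE])
  }
  B
}

#' CNV log2 fold changes against the GC-matched background
#'
#' `F_b = log2((c_b + eps) / (B_b + eps))`; the pseudo-density `eps`
#' (default 1 fragment per effective Mb = 0.001 per kb) keeps the ratio
#' finite in sparse per-cell mode. Masked bins propagate as NA.
#'
#' @param cov a [offtarget_coverage()] result.
#' @param B background matrix from [gc_matched_background()].
#' @param eps pseudo-density in fragments per effective kb.
#' @return matrix (bins x units) of log2 fold changes.
#' @export
cnv_fold_change <- function(cov, B, eps = 0.001) {
  stopifnot(all(dim(cov$density) == dim(B)))
  base::log2((cov$density + eps) / (B + eps))
}

#' Full CNV calling pipeline from fragments
#'
#' Convenience wrapper: off-target coverage, GC-matched background, log2
#' fold changes.
#'
#' @inheritParams offtarget_coverage
#' @inheritParams gc_matched_background
#' @inheritParams cnv_fold_change
#' @param drop_chroms optional chromosomes (e.g. sex chromosomes) whose
#'   bins are masked before background matching.
#' @return list with `coverage`, `background`, `log2fc`, `bins`.
#' @export
call_cnv <- function(frags, bins, peaks, unit = "pseudobulk",
                     cluster_of = NULL, k = 100, eps = 0.001,
                     drop_chroms = NULL) {
  cov <- offtarget_coverage(frags, bins, peaks, unit = unit,
                            cluster_of = cluster_of)
  if (!is.null(drop_chroms)) {
    drop <- cov$bins$chrom %in% drop_chroms
    cov$masked <- cov$masked | drop
    cov$density[drop, ] <- NA_real_
  }
  B <- gc_matched_background(cov, k = k)
  list(coverage = cov, background = B,
       log2fc = cnv_fold_change(cov, B, eps = eps), bins = cov$bins)
}
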