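#' Peak-by-sample count matrix with genomic intervals
#'
#' @param peaks data.frame with columns `chrom`, `start`, `end`, `id`
#'   (0-based half-open intervals).
#' @param counts non-negative integer matrix, one row per peak, one column
#'   per sample; rownames are set to the peak ids.
#' @param sample_ids character vector of sample names.
#' @return An object of class `peak_matrix`.
#' @export
peak_matrix <- function(peaks, counts, sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (nrow(peaks) != nrow(counts))
    stop("config error: peaks and counts have inconsistent dimensions")
  if (length(sample_ids) != ncol(counts))
    stop("config error: sample_ids and counts have inconsistent dimensions")
  if (anyDuplicated(peaks$id)) stop("peak ids must be unique")
  if (any(peaks$start >= peaks$end)) stop("peak intervals need start < end")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  rownames(counts) <- peaks$id
  colnames(counts) <- sample_ids
  structure(list(peaks = peaks, counts = counts, sample_ids = sample_ids),
            class = "peak_matrix")
}

#' @export
print.peak_matrix <- function(x, ...) {
  cat("<peak_matrix>", nrow(x$counts), "peaks x",
      ncol(x$counts), "samples\n")
  invisible(x)
}

#' @export
dim.peak_matrix <- function(x) dim(x$counts)

# Accept either a peak_matrix or a plain matrix wherever only counts matter.
count_matrix_of <- function(m) {
  if (inherits(m, "peak_matrix")) m$counts else as.matrix(m)
}

#' Subtype gene signature with derivation provenance
#'
#' @param subtype one of `"LLI"`, `"BL"`, `"MP"`.
#' @param genes ordered character vector (strongest fold change first).
#' @param table data.frame with one row per gene: `gene_id`, `log2fc`,
#'   `padj`, `peak_id` (the supporting differential peak).
#' @param truncated logical flag set when fewer candidates than the
#'   requested size were available.
#' @return An object of class `signature`.
#' @export
signature_set <- function(subtype, genes, table, truncated = FALSE) {
  stopifnot(length(genes) == nrow(table), all(genes == table$gene_id))
  structure(list(subtype = subtype, genes = genes, size = length(genes),
                 table = table, truncated = truncated),
            class = "signature")
}

#' @export
print.signature <- function(x, ...) {
  cat("<signature>", x$subtype, "-", x$size, "genes",
      if (x$truncated) "(truncated: fewer candidates than requested)" else "",
      "\n")
  invisible(x)
}
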