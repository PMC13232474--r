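# Readers and writers for the standard interchange formats: BED peaks,
# TSV / MatrixMarket count matrices, 10x-style fragment TSV, GMT gene
# sets, PNG images/masks and plain TSV tables.

#' Read and write peak intervals as BED
#'
#' BED is 0-based half-open; peak data.frames in this package use the same
#' convention, so coordinates round-trip unchanged.
#'
#' @param peaks data.frame with `chrom`, `start`, `end`, `id`.
#' @param path file path.
#' @return `read_bed()` returns the peak data.frame.
#' @export
write_bed <- function(peaks, path) {
  gr <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start + 1, peaks$end),
                               name = peaks$id)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             id = if (!is.null(gr$name)) gr$name else
               sprintf("peak_%05d", seq_along(gr)),
             stringsAsFactors = FALSE)
}

#' Read and write count matrices as TSV
#'
#' First column `feature` holds rownames; remaining columns are samples.
#'
#' @param counts numeric matrix with dimnames.
#' @param path file path.
#' @return `read_counts_tsv()` returns the matrix.
#' @export
write_counts_tsv <- function(counts, path) {
  dt <- data.table::data.table(feature = rownames(counts))
  dt <- cbind(dt, data.table::as.data.table(counts))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1]]
  m
}

#' Read and write count matrices in MatrixMarket format
#'
#' Writes `<prefix>.mtx` plus `<prefix>.rows.txt` / `<prefix>.cols.txt`
#' with the dimension names.
#'
#' @param counts numeric matrix with dimnames.
#' @param prefix path prefix (no extension).
#' @return `read_counts_mtx()` returns the dense matrix.
#' @export
write_counts_mtx <- function(counts, prefix) {
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE),
                  paste0(prefix, ".mtx"))
  writeLines(rownames(counts), paste0(prefix, ".rows.txt"))
  writeLines(colnames(counts), paste0(prefix, ".cols.txt"))
  invisible(prefix)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(prefix) {
  m <- as.matrix(Matrix::readMM(paste0(prefix, ".mtx")))
  rownames(m) <- readLines(paste0(prefix, ".rows.txt"))
  colnames(m) <- readLines(paste0(prefix, ".cols.txt"))
  m
}

#' Read and write fragment records in 10x fragments layout
#'
#' Tab-separated `chrom  start  end  barcode  count` (0-based half-open),
#' sorted by chromosome then start, no header. Reading accepts 4 or 5
#' columns.
#'
#' @param frags data.frame with `chrom`, `start`, `end`, `barcode` and
#'   optionally `count`.
#' @param path file path (plain TSV; bgzip-able).
#' @return `read_fragments()` returns the data.frame.
#' @export
write_fragments <- function(frags, path) {
  if (is.null(frags$count)) frags$count <- 1L
  frags <- frags[order(frags$chrom, frags$start), ]
  data.table::fwrite(frags[, c("chrom", "start", "end", "barcode", "count")],
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_fragments
#' @export
read_fragments <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE)
  names(dt) <- c("chrom", "start", "end", "barcode",
                 "count")[seq_len(ncol(dt))]
  as.data.frame(dt)
}

#' Read and write gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Reading uses the standard GMT parser.
#'
#' @param sets named list of gene vectors, or a list of
#'   [signature_set()] objects.
#' @param path file path.
#' @return `read_gmt()` returns a named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    g <- sets[[nm]]
    if (inherits(g, "signature")) g <- g$genes
    paste(c(nm, "na", g), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Read and write 8-bit RGB images and binary masks as PNG
#'
#' @param img H x W x 3 array in 0..255 (values are rounded to 8 bit), or
#'   a logical matrix for masks.
#' @param path file path.
#' @return readers return the array (0..255) or logical matrix.
#' @export
write_png_rgb <- function(img, path) {
  png::writePNG(round(img) / 255, path)
  invisible(path)
}

#' @rdname write_png_rgb
#' @export
read_png_rgb <- function(path) {
  png::readPNG(path) * 255
}

#' @rdname write_png_rgb
#' @export
write_png_mask <- function(img, path) {
  png::writePNG(matrix(as.numeric(img), nrow(img)), path)
  invisible(path)
}

#' @rdname write_png_rgb
#' @export
read_png_mask <- function(path) {
  png::readPNG(path) > 0.5
}

#' Read and write plain TSV tables (spatial points, survival, scores)
#'
#' @param df data.frame.
#' @param path file path.
#' @return `read_tsv_table()` returns the data.frame.
#' @export
write_tsv_table <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}
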