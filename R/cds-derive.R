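# Chromatin-derived score (CDS) signature derivation: peak-to-gene linkage
# by nearest TSS, candidate selection by joint enhancer/expression evidence,
# and the 5..25 signature-size scan.

#' Link peaks to their nearest gene within a distance cap
#'
#' Each peak is assigned the gene whose TSS minimizes the distance to the
#' peak midpoint on the same chromosome, provided that distance is at most
#' `max_dist` (inclusive). Equidistant ties break toward the
#' lexicographically smallest gene id; unlinked peaks are dropped.
#'
#' @param peaks data.frame (`chrom`, `start`, `end`, `id`) or a
#'   [peak_matrix()].
#' @param ann gene annotation data.frame (`gene_id`, `chrom`, `tss`).
#' @param max_dist maximum midpoint-to-TSS distance in bp (default 400 kb).
#' @return data.frame with `peak_id`, `gene_id`, `distance`.
#' @export
link_peaks_to_genes <- function(peaks, ann, max_dist = 400000) {
  if (inherits(peaks, "peak_matrix")) peaks <- peaks$peaks
  if (!nrow(ann)) stop("empty gene annotation")
  out <- vector("list", nrow(peaks))
  mid <- (peaks$start + peaks$end) / 2
  for (ch in unique(peaks$chrom)) {
    g <- ann[ann$chrom == ch, , drop = FALSE]
    pk <- which(peaks$chrom == ch)
    if (!nrow(g)) next
    for (i in pk) {
      d <- abs(mid[i] - g$tss)
      dmin <- min(d)
      if (dmin > max_dist) next
      cand <- g$gene_id[d == dmin]
      out[[i]] <- data.frame(peak_id = peaks$id[i],
                             gene_id = min(cand), distance = dmin,
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(peak_id = character(0), gene_id = character(0),
                      distance = numeric(0))
  rownames(res) <- NULL
  res
}

#' Derive one subtype signature from differential peaks and expression
#'
#' Candidate genes must be up in the subtype with expression
#' `log2fc > lfc_min` (strict), `padj < padj_max` (strict), and have at
#' least one linked subtype-specific differential peak. Candidates are
#' ranked by decreasing |log2fc| (ties by gene id) and the top `size` are
#' returned; if fewer candidates exist, all are returned with the
#' signature's `truncated` flag set.
#'
#' @param diff_peaks character vector of subtype-specific differential peak
#'   ids (e.g. the `a_up` set from [filter_differential()]).
#' @param diff_expr expression differential table oriented subtype-vs-rest
#'   (positive log2fc = up in the subtype).
#' @param links peak-to-gene table from [link_peaks_to_genes()].
#' @param subtype signature label (`"LLI"`, `"BL"`, `"MP"`).
#' @param lfc_min expression |log2fc| threshold (5 for LLI/BL, 2 for MP).
#' @param padj_max adjusted p ceiling (strict).
#' @param size signature size (default 15 genes).
#' @return a [signature_set()].
#' @export
derive_signature <- function(diff_peaks, diff_expr, links, subtype,
                             lfc_min, padj_max = 0.05, size = 15) {
  stopifnot(lfc_min > 0, size >= 1)
  linked <- links[links$peak_id %in% diff_peaks, , drop = FALSE]
  cand <- diff_expr[diff_expr$log2fc > lfc_min &
                      diff_expr$padj < padj_max &
                      diff_expr$feature_id %in% linked$gene_id, ,
                    drop = FALSE]
  cand <- cand[order(-abs(cand$log2fc), cand$feature_id), , drop = FALSE]
  peak_of <- linked$peak_id[match(cand$feature_id, linked$gene_id)]
  tab <- data.frame(gene_id = cand$feature_id, log2fc = cand$log2fc,
                    padj = cand$padj, peak_id = peak_of,
                    stringsAsFactors = FALSE)
  truncated <- nrow(tab) < size
  if (truncated)
    warning("subtype ", subtype, ": only ", nrow(tab),
            " candidate genes for requested size ", size)
  tab <- utils::head(tab, size)
  rownames(tab) <- NULL
  signature_set(subtype, tab$gene_id, tab, truncated = truncated)
}

#' Enforce disjoint gene sets across subtype signatures
#'
#' A gene claimed by several signatures is kept only in the one where its
#' |log2fc| is largest (ties toward the earlier signature in the list); the
#' dropped assignments are recorded in each signature's `conflicts` field.
#'
#' @param sigs named list of [signature_set()] objects.
#' @return the list with conflicting genes removed.
#' @export
enforce_disjoint_signatures <- function(sigs) {
  genes <- unlist(lapply(sigs, `[[`, "genes"), use.names = FALSE)
  dup <- unique(genes[duplicated(genes)])
  for (g in dup) {
    best <- NULL
    best_lfc <- -Inf
    for (nm in names(sigs)) {
      tb <- sigs[[nm]]$table
      if (g %in% tb$gene_id) {
        lfc <- abs(tb$log2fc[tb$gene_id == g])
        if (lfc > best_lfc) { best <- nm; best_lfc <- lfc }
      }
    }
    for (nm in setdiff(names(sigs), best)) {
      tb <- sigs[[nm]]$table
      if (g %in% tb$gene_id) {
        sigs[[nm]]$conflicts <- c(sigs[[nm]]$conflicts, g)
        keep <- tb$gene_id != g
        sigs[[nm]]$table <- tb[keep, , drop = FALSE]
        sigs[[nm]]$genes <- sigs[[nm]]$genes[sigs[[nm]]$genes != g]
        sigs[[nm]]$size <- length(sigs[[nm]]$genes)
      }
    }
  }
  sigs
}

#' Scan signature sizes and pick the most accurate
#'
#' For each size, every subtype's candidate ranking is truncated to that
#' size, all samples are scored by the single-sample enrichment statistic,
#' classified by argmax score, and accuracy against the provided labels is
#' computed (scores are per-sample, so leave-one-out accuracy equals this
#' value). Returns the accuracy-maximizing size; ties break toward the
#' smallest size. Sizes exceeding a subtype's candidate count are scored
#' with the available genes and flagged.
#'
#' @param candidates named list: subtype -> ranked candidate gene vector.
#' @param expr normalized expression matrix (genes x samples).
#' @param labels named vector of true subtype labels per sample.
#' @param sizes candidate signature sizes (default 5:25).
#' @param alpha rank weight exponent for scoring.
#' @return list with `size` (chosen), `accuracy` (data.frame size,
#'   accuracy, flagged).
#' @export
select_signature_size <- function(candidates, expr, labels, sizes = 5:25,
                                  alpha = 0.25) {
  stopifnot(length(unique(labels)) >= 2)
  labels <- labels[colnames(expr)]
  acc <- data.frame(size = sizes, accuracy = NA_real_, flagged = FALSE)
  for (r in seq_along(sizes)) {
    s <- sizes[r]
    sets <- lapply(candidates, function(g) utils::head(g, s))
    acc$flagged[r] <- any(lengths(candidates) < s)
    scores <- vapply(sets, function(gs)
      ss_enrichment_score(expr, gs, alpha = alpha), numeric(ncol(expr)))
    pred <- colnames(scores)[max.col(scores, ties.method = "first")]
    acc$accuracy[r] <- mean(pred == labels)
  }
  best <- acc$size[which.max(acc$accuracy)]  # which.max takes first = smallest
  list(size = best, accuracy = acc)
}

#' End-to-end CDS derivation from a bulk cohort
#'
#' Runs the full derivation: differential peaks (LLI vs BL for the two URO
#' subtypes, MP vs pooled URO) filtered at `padj <= 0.05`, `|log2fc| > 0.5`;
#' differential expression under the same contrasts; nearest-TSS peak-gene
#' linkage within 400 kb; candidate selection at expression `|log2fc| > 5`
#' (LLI/BL) or `> 2` (MP) with `padj < 0.05`; 15 genes per subtype;
#' disjointness enforced by larger |log2fc|.
#'
#' @param peaks a [peak_matrix()].
#' @param expr gene-by-sample count matrix.
#' @param annotation gene annotation (`gene_id`, `chrom`, `tss`).
#' @param subtype_of named vector mapping sample id to LLI/BL/MP.
#' @param size genes per signature.
#' @param lfc_min named thresholds per subtype.
#' @return named list of [signature_set()] objects (LLI, BL, MP).
#' @export
derive_cds <- function(peaks, expr, annotation, subtype_of, size = 15,
                       lfc_min = c(LLI = 5, BL = 5, MP = 2)) {
  samples_of <- function(s) names(subtype_of)[subtype_of == s]
  links <- link_peaks_to_genes(peaks, annotation)
  contrasts <- list(
    LLI = list(a = samples_of("LLI"), b = samples_of("BL")),
    BL = list(a = samples_of("BL"), b = samples_of("LLI")),
    MP = list(a = samples_of("MP"),
              b = c(samples_of("LLI"), samples_of("BL")))
  )
  sigs <- list()
  for (s in names(contrasts)) {
    ct <- contrasts[[s]]
    dp <- filter_differential(nb_differential(peaks, ct$a, ct$b))$a_up
    de <- nb_differential(expr, ct$a, ct$b)
    sigs[[s]] <- derive_signature(dp, de, links, s,
                                  lfc_min = lfc_min[[s]], size = size)
  }
  enforce_disjoint_signatures(sigs)
}
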