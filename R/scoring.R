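# Signature scoring and classification: rank-walk single-sample enrichment,
# binned-control module scores, bulk quartile/sign rules, the single-cell
# quantile rule, marker-based TME typing and M1/M2 polarization scoring.

#' Single-sample enrichment score (rank-walk statistic)
#'
#' Per sample, genes are ranked by expression descending (ties broken by
#' gene id). Walking down the list, set members add a rank weight
#' `r^alpha` (r = N for the top gene, 1 for the bottom) normalized by the
#' ideal member weight sum (the k best positions), and non-members subtract
#' `1/(N - k)`. The score is the sum of the running sum over all positions,
#' scaled by `1/N`. Normalizing by the ideal rather than the realized
#' member weights keeps the score strictly monotone under rank improvement
#' of any member and comparable across samples.
#'
#' @param expr matrix (genes x samples) with gene ids as rownames.
#' @param gene_set character vector; must intersect the measured genes.
#' @param alpha rank weight exponent (default 0.25).
#' @return named numeric vector of per-sample scores.
#' @export
ss_enrichment_score <- function(expr, gene_set, alpha = 0.25) {
  expr <- as.matrix(expr)
  genes <- rownames(expr)
  if (is.null(genes)) stop("expression matrix needs gene rownames")
  present <- intersect(gene_set, genes)
  if (!length(present))
    stop("gene set fully absent from matrix: ",
         paste(utils::head(gene_set, 10), collapse = ", "))
  n <- length(genes)
  k <- length(present)
  member <- genes %in% present
  dec <- if (n > k) 1 / (n - k) else 0
  w_ideal <- sum((n:(n - k + 1))^alpha)
  apply(expr, 2, function(x) {
    ord <- order(-x, genes)
    memb_o <- member[ord]
    r <- n:1
    w <- numeric(n)
    w[memb_o] <- r[memb_o]^alpha / w_ideal
    w[!memb_o] <- -dec
    sum(cumsum(w)) / n
  })
}

#' Module score with expression-binned control genes
#'
#' Genes are placed into `n_bins` equal-frequency bins by average expression
#' across cells. For each signature gene, `n_ctrl` control genes are sampled
#' (seeded, with replacement) from the non-signature genes of its bin (or the
#' nearest non-empty bin). The per-cell score is the mean expression of the
#' signature genes minus the mean expression of the pooled controls.
#'
#' @param cells matrix (genes x cells).
#' @param gene_set signature genes (must be present in the matrix).
#' @param n_bins number of equal-frequency average-expression bins.
#' @param n_ctrl control genes sampled per signature gene.
#' @param seed RNG seed for control sampling.
#' @return named numeric vector of per-cell scores.
#' @export
module_score <- function(cells, gene_set, n_bins = 25, n_ctrl = 100,
                         seed = 1) {
  cells <- as.matrix(cells)
  stopifnot(n_bins >= 1)
  genes <- rownames(cells)
  if (!all(gene_set %in% genes))
    stop("gene set members absent from matrix: ",
         paste(setdiff(gene_set, genes), collapse = ", "))
  avg <- rowMeans(cells)
  n <- length(avg)
  bin <- ceiling(n_bins * rank(avg, ties.method = "first") / n)
  is_set <- genes %in% gene_set
  ctrl <- withr::with_seed(seed, {
    unlist(lapply(which(is_set), function(i) {
      pool <- which(bin == bin[i] & !is_set)
      if (!length(pool)) {
        # nearest non-empty bin (ties toward the lower bin)
        cand_bins <- sort(unique(bin[!is_set]))
        nb <- cand_bins[order(abs(cand_bins - bin[i]), cand_bins)][1]
        pool <- which(bin == nb & !is_set)
      }
      pool[sample.int(length(pool), n_ctrl, replace = TRUE)]
    }))
  })
  set_mean <- colMeans(cells[is_set, , drop = FALSE])
  ctrl_mean <- colMeans(cells[ctrl, , drop = FALSE])
  set_mean - ctrl_mean
}

#' Quartile classification of bulk samples by score delta
#'
#' Samples are ranked by `delta = score_LLI - score_BL` descending (rank
#' ties broken by unit id). The top `ceil(N/4)` samples are labelled
#' `LLI-like`, the bottom `ceil(N/4)` labelled `BL`, the middle
#' `intermediate`.
#'
#' @param scores data.frame with columns `unit_id` and `delta`.
#' @return named character vector of labels (in input order).
#' @export
classify_bulk_quartile <- function(scores) {
  n <- nrow(scores)
  if (n < 4) stop("need at least 4 samples for quartile classification")
  ord <- order(-scores$delta, scores$unit_id)
  q <- ceiling(n / 4)
  lab <- rep("intermediate", n)
  lab[ord[seq_len(q)]] <- "LLI-like"
  lab[ord[(n - q + 1):n]] <- "BL"
  stats::setNames(lab, scores$unit_id)
}

#' Sign classification of bulk samples by score delta
#'
#' `delta > 0` is `LLI-like`, `delta < 0` is `BL-like`, `delta = 0` is
#' `intermediate` (both quoted inequalities are strict).
#'
#' @param scores data.frame with columns `unit_id` and `delta`.
#' @return named character vector of labels.
#' @export
classify_bulk_sign <- function(scores) {
  lab <- ifelse(scores$delta > 0, "LLI-like",
                ifelse(scores$delta < 0, "BL-like", "intermediate"))
  stats::setNames(lab, scores$unit_id)
}

#' Quantile classification of single cells by subtype scores
#'
#' Per subtype, a threshold is set at the `q`-quantile (type 7) of that
#' subtype's scores across cells. A cell is labelled with a subtype iff its
#' score meets that subtype's threshold and no other subtype's threshold is
#' met; cells meeting zero or two-plus thresholds are `unidentified`.
#'
#' @param scores matrix or data.frame (cells x subtypes) of scores, cell
#'   ids as rownames.
#' @param q quantile level of the per-subtype threshold (default 0.75).
#' @return named character vector of labels.
#' @export
classify_cells_quantile <- function(scores, q = 0.75) {
  stopifnot(q > 0, q < 1)
  scores <- as.matrix(scores)
  if (nrow(scores) < 4) stop("need at least 4 cells")
  thr <- apply(scores, 2, stats::quantile, probs = q, type = 7)
  met <- sweep(scores, 2, thr, ">=")
  n_met <- rowSums(met)
  lab <- rep("unidentified", nrow(scores))
  one <- n_met == 1
  lab[one] <- colnames(scores)[max.col(met[one, , drop = FALSE])]
  stats::setNames(lab, rownames(scores))
}

#' Marker-based cell subtype assignment
#'
#' Marker genes are z-scored across cells; each cell is labelled with the
#' subtype maximizing the mean scaled expression of its markers. Ties and
#' cells with zero expression across all markers are `unassigned`.
#'
#' @param cells matrix (genes x cells).
#' @param marker_map named list: subtype -> marker gene vector (defaults to
#'   the canonical CAF markers, see [caf_markers()]).
#' @return named character vector of labels.
#' @export
assign_marker_subtype <- function(cells, marker_map = caf_markers()) {
  cells <- as.matrix(cells)
  markers <- unlist(marker_map, use.names = FALSE)
  if (!all(markers %in% rownames(cells)))
    stop("marker gene(s) absent: ",
         paste(setdiff(markers, rownames(cells)), collapse = ", "))
  mx <- cells[markers, , drop = FALSE]
  mu <- rowMeans(mx)
  sdv <- apply(mx, 1, stats::sd)
  z <- (mx - mu) / ifelse(sdv > 0, sdv, 1)
  sc <- t(vapply(marker_map, function(g)
    colMeans(z[g, , drop = FALSE]), numeric(ncol(cells))))
  lab <- character(ncol(cells))
  for (j in seq_len(ncol(cells))) {
    if (all(mx[, j] == 0)) { lab[j] <- "unassigned"; next }
    top <- which(sc[, j] == max(sc[, j]))
    lab[j] <- if (length(top) == 1) names(marker_map)[top] else "unassigned"
  }
  stats::setNames(lab, colnames(cells))
}

#' M1/M2 macrophage polarization scores and per-sample ratio
#'
#' Computes M1 and M2 module scores per cell and, when a barcode-to-sample
#' map is given, the per-sample ratio `#cells(M2 > M1) / #cells(M1 > M2)`
#' (flagged undefined when the denominator is 0). Two samples can be
#' compared by a rank-sum test on the per-cell `M2 - M1` difference.
#'
#' @param cells matrix (genes x cells).
#' @param m1_set,m2_set disjoint marker sets (defaults [m1_markers()] /
#'   [m2_markers()]).
#' @param seed RNG seed passed to [module_score()].
#' @param sample_of optional named vector barcode -> sample id.
#' @return list with `scores` (data.frame barcode, m1, m2, diff) and
#'   `ratio` (data.frame sample, n_m2, n_m1, ratio, undefined) when
#'   `sample_of` is given.
#' @export
m1_m2_scores <- function(cells, m1_set = m1_markers(), m2_set = m2_markers(),
                         seed = 1, sample_of = NULL) {
  if (length(intersect(m1_set, m2_set)))
    stop("M1 and M2 sets must be disjoint")
  m1 <- module_score(cells, m1_set, seed = seed)
  m2 <- module_score(cells, m2_set, seed = seed + 1L)
  scores <- data.frame(barcode = colnames(cells), m1 = m1, m2 = m2,
                       diff = m2 - m1, row.names = NULL,
                       stringsAsFactors = FALSE)
  out <- list(scores = scores)
  if (!is.null(sample_of)) {
    sm <- sample_of[scores$barcode]
    rt <- do.call(rbind, lapply(split(scores, sm), function(d) {
      n2 <- sum(d$m2 > d$m1); n1 <- sum(d$m1 > d$m2)
      data.frame(sample = sm[match(d$barcode[1], scores$barcode)],
                 n_m2 = n2, n_m1 = n1,
                 ratio = if (n1 > 0) n2 / n1 else Inf,
                 undefined = n1 == 0, stringsAsFactors = FALSE)
    }))
    rownames(rt) <- NULL
    out$ratio <- rt
  }
  out
}

#' Score samples against CDS signatures and assemble a score table
#'
#' @param expr normalized expression matrix (genes x samples).
#' @param sigs named list of [signature_set()] objects or plain gene
#'   vectors (needs at least `LLI` and `BL` for the delta).
#' @param alpha rank weight exponent.
#' @return data.frame with `unit_id`, one `score_*` column per signature
#'   and `delta = score_LLI - score_BL`.
#' @export
score_table <- function(expr, sigs, alpha = 0.25) {
  sets <- lapply(sigs, function(s) if (inherits(s, "signature")) s$genes
                 else s)
  sc <- vapply(sets, function(g)
    ss_enrichment_score(expr, g, alpha = alpha), numeric(ncol(expr)))
  out <- data.frame(unit_id = colnames(expr), sc, row.names = NULL,
                    stringsAsFactors = FALSE)
  names(out)[-1] <- paste0("score_", names(sets))
  if (all(c("score_LLI", "score_BL") %in% names(out)))
    out$delta <- out$score_LLI - out$score_BL
  out
}
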