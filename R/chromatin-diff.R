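# Differential chromatin analysis: library-size normalization, Spearman
# correlation clustering, PERMANOVA cluster validation, PCA and a
# negative-binomial Wald test with the study's filtering thresholds.

#' Library-size normalization of a count matrix
#'
#' Size factor `s_j = total_j / geometric mean(totals)`; normalized value is
#' `count / s_j`. With `log2 = TRUE` returns `log2(normalized + 1)`.
#'
#' @param m a [peak_matrix()] or a plain count matrix (features x samples).
#' @param log2 return log2(normalized + 1) instead of the linear scale.
#' @return numeric matrix of normalized values (same dimnames).
#' @export
normalize_counts <- function(m, log2 = FALSE) {
  counts <- count_matrix_of(m)
  totals <- colSums(counts)
  if (any(totals <= 0)) {
    bad <- colnames(counts)[totals <= 0]
    if (is.null(bad)) bad <- which(totals <= 0)
    stop("sample(s) with zero total counts: ", paste(bad, collapse = ", "))
  }
  s <- totals / exp(mean(log(totals)))
  norm <- sweep(counts, 2, s, "/")
  if (log2) base::log2(norm + 1) else norm
}

size_factors <- function(counts) {
  totals <- colSums(counts)
  totals / exp(mean(log(totals)))
}

#' Hierarchical clustering of samples on Spearman correlation distance
#'
#' Distance `D_ij = 1 - Spearman rho(sample i, sample j)` (average ranks for
#' ties), average-linkage tree, cut into `k` cluster labels.
#'
#' @param m normalized matrix (features x samples).
#' @param k number of clusters to cut the tree into.
#' @return list of class `cluster_result` with elements `tree` (hclust),
#'   `labels` (named integer vector), and `D` (distance matrix).
#' @export
correlation_clustering <- function(m, k) {
  m <- count_matrix_of(m)
  if (ncol(m) < k) stop("need at least k samples")
  if (nrow(m) < 2) stop("need at least 2 features")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop("constant sample vector(s): Spearman correlation undefined for ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  D <- 1 - stats::cor(m, method = "spearman")
  tree <- stats::hclust(stats::as.dist(D), method = "average")
  labels <- stats::cutree(tree, k = k)
  structure(list(tree = tree, labels = labels, D = D),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result>", length(x$labels), "samples,",
      length(unique(x$labels)), "clusters\n")
  invisible(x)
}

permanova_F <- function(d2, idx_groups, n, a) {
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (idx in idx_groups) {
    ng <- length(idx)
    ss_within <- ss_within + sum(d2[idx, idx][upper.tri(diag(ng))]) / ng
  }
  ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
}

#' PERMANOVA test of multivariate group separation
#'
#' One-way permutational multivariate analysis of variance on a distance
#' matrix: `SS_total = sum_{i<j} D_ij^2 / N`,
#' `SS_within = sum_g sum_{i<j in g} D_ij^2 / n_g`,
#' `F = ((SS_total - SS_within)/(a-1)) / (SS_within/(N-a))`. The p-value is
#' `(1 + #{F_perm >= F_obs}) / (n_perm + 1)` over seeded free permutations of
#' the sample labels, or the exact enumeration fraction when
#' `exact = TRUE` (N <= 9).
#'
#' @param D symmetric distance matrix (or `dist`).
#' @param labels group label per sample.
#' @param n_perm number of label permutations (ignored when `exact`).
#' @param seed RNG seed for the permutations.
#' @param exact enumerate all N! label orderings instead of sampling.
#' @return list with `F`, `p`, `n_perm`.
#' @export
permanova <- function(D, labels, n_perm = 999, seed = 1, exact = FALSE) {
  D <- as.matrix(D)
  n <- nrow(D)
  stopifnot(length(labels) == n)
  labels <- as.character(labels)
  tab <- table(labels)
  a <- length(tab)
  if (a < 2 || any(tab < 2))
    stop("need >= 2 groups each with >= 2 members")
  if (all(D == 0)) stop("degenerate distance matrix: F undefined")
  d2 <- D^2
  groups_of <- function(lab) split(seq_len(n), lab)
  f_obs <- permanova_F(d2, groups_of(labels), n, a)
  if (exact) {
    if (n > 9) stop("exact enumeration limited to N <= 9")
    perms <- all_permutations(n)
    f_all <- vapply(perms, function(ord)
      permanova_F(d2, groups_of(labels[ord]), n, a), numeric(1))
    p <- mean(f_all >= f_obs - 1e-12)
    n_used <- length(perms)
  } else {
    if (n_perm < 1) stop("n_perm must be >= 1")
    f_perm <- withr::with_seed(seed, {
      vapply(seq_len(n_perm), function(i)
        permanova_F(d2, groups_of(sample(labels)), n, a), numeric(1))
    })
    p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (n_perm + 1)
    n_used <- n_perm
  }
  list(F = f_obs, p = p, n_perm = n_used)
}

# all permutations of 1..n as a list (n! entries; used for exact PERMANOVA)
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) {
    for (s in sub) {
      k <- k + 1L
      rest <- seq_len(n)[-i]
      out[[k]] <- c(i, rest[s])
    }
  }
  out
}

#' Principal component analysis of samples
#'
#' Projects samples on the eigenvectors of the feature-centered covariance.
#'
#' @param m normalized matrix (features x samples).
#' @return list with `coordinates` (samples x components) and
#'   `var_fraction` (per-component variance fractions, summing to 1).
#' @export
pca_samples <- function(m) {
  m <- count_matrix_of(m)
  if (ncol(m) < 2) stop("need at least 2 samples")
  fit <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  v <- fit$sdev^2
  list(coordinates = fit$x, var_fraction = v / sum(v))
}

#' Negative-binomial Wald test for differential features
#'
#' Size-factor-normalized group means; dispersion by method of moments per
#' group, pooled with degree-of-freedom weights (floored at 1e-8);
#' `log2fc = log2((mean_a + 0.5) / (mean_b + 0.5))`; Wald statistic
#' `log2fc / SE` with delta-method SE from the NB variance
#' `mu + phi * mu^2`; two-sided normal p; Benjamini-Hochberg adjustment over
#' all tested features.
#'
#' @param m a [peak_matrix()] or count matrix.
#' @param group_a,group_b disjoint sample id (or column index) vectors,
#'   each of length >= 2. `log2fc > 0` means higher in `group_a`.
#' @return data.frame with columns `feature_id`, `log2fc`, `p`, `padj`,
#'   `mean_a`, `mean_b`.
#' @export
nb_differential <- function(m, group_a, group_b) {
  counts <- count_matrix_of(m)
  ia <- resolve_samples(counts, group_a)
  ib <- resolve_samples(counts, group_b)
  if (length(intersect(ia, ib)) > 0) stop("groups overlap")
  if (length(ia) < 2 || length(ib) < 2)
    stop("need >= 2 samples per group")
  sub <- counts[, c(ia, ib), drop = FALSE]
  norm <- normalize_counts(sub)
  xa <- norm[, seq_along(ia), drop = FALSE]
  xb <- norm[, length(ia) + seq_along(ib), drop = FALSE]
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  phi_a <- ifelse(ma > 0, (va - ma) / ma^2, 0)
  phi_b <- ifelse(mb > 0, (vb - mb) / mb^2, 0)
  phi <- pmax(((na - 1) * phi_a + (nb - 1) * phi_b) / (na + nb - 2), 1e-8)
  lfc <- base::log2((ma + 0.5) / (mb + 0.5))
  var_ma <- (ma + phi * ma^2) / na
  var_mb <- (mb + phi * mb^2) / nb
  se <- sqrt(var_ma / (ma + 0.5)^2 + var_mb / (mb + 0.5)^2) / log(2)
  z <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * stats::pnorm(-abs(z))
  allzero <- ma == 0 & mb == 0
  p[allzero] <- 1
  lfc[allzero] <- 0
  ids <- rownames(counts)
  if (is.null(ids)) ids <- sprintf("feature_%05d", seq_len(nrow(counts)))
  data.frame(feature_id = ids, log2fc = lfc, p = p,
             padj = stats::p.adjust(p, method = "BH"),
             mean_a = ma, mean_b = mb,
             row.names = NULL, stringsAsFactors = FALSE)
}

resolve_samples <- function(counts, group) {
  if (is.numeric(group)) return(as.integer(group))
  idx <- match(group, colnames(counts))
  if (anyNA(idx)) stop("unknown sample id(s): ",
                       paste(group[is.na(idx)], collapse = ", "))
  idx
}

#' Threshold a differential table into subtype-specific feature sets
#'
#' Retains features with `padj <= padj_max` (inclusive) and
#' `|log2fc| > min_abs_lfc` (strict), split by fold-change sign.
#'
#' @param t a differential table from [nb_differential()].
#' @param padj_max adjusted p-value ceiling (inclusive).
#' @param min_abs_lfc absolute log2 fold-change floor (exclusive).
#' @return list with `a_up` and `b_up` character vectors of feature ids.
#' @export
filter_differential <- function(t, padj_max = 0.05, min_abs_lfc = 0.5) {
  stopifnot(is.finite(padj_max), is.finite(min_abs_lfc))
  keep <- t$padj <= padj_max & abs(t$log2fc) > min_abs_lfc
  keep[is.na(keep)] <- FALSE
  list(a_up = t$feature_id[keep & t$log2fc > 0],
       b_up = t$feature_id[keep & t$log2fc < 0])
}
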