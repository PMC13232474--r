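# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

# small bulk cohort for pipeline tests (fast: ~0.5 s)
small_cohort <- function(seed = 1, ...) {
  simulate_bulk_cohort(sim_config(seed = seed, ...))
}

# tiny peak matrix with explicit counts
tiny_peak_matrix <- function(counts) {
  n <- nrow(counts)
  peaks <- data.frame(chrom = "chrS1",
                      start = seq(0, by = 2000, length.out = n),
                      end = seq(1000, by = 2000, length.out = n),
                      id = sprintf("pk%02d", seq_len(n)))
  peak_matrix(peaks, counts,
              sample_ids = colnames(counts) %||%
                sprintf("s%02d", seq_len(ncol(counts))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent brute-force nearest-vessel distances (O(N*M) scan)
brute_force_distances <- function(marker, vessel) {
  mp <- which(marker, arr.ind = TRUE)
  vp <- which(vessel, arr.ind = TRUE)
  apply(mp, 1, function(p)
    sqrt(min((p[1] - vp[, 1])^2 + (p[2] - vp[, 2])^2)))
}

# independent rank-walk enrichment score (explicit loop, oracle for
# ss_enrichment_score)
oracle_es <- function(x, genes, set, alpha = 0.25) {
  ord <- order(-x, genes)
  n <- length(x)
  memb <- genes[ord] %in% set
  k <- sum(memb)
  r <- n:1
  w_ideal <- sum((n:(n - k + 1))^alpha)
  w <- ifelse(memb, r^alpha / w_ideal, if (n > k) -1 / (n - k) else 0)
  run <- 0
  total <- 0
  for (j in seq_len(n)) {
    run <- run + w[j]
    total <- total + run
  }
  total / n
}

# independent PERMANOVA pseudo-F via explicit double loops
oracle_permanova_F <- function(D, labels) {
  D <- as.matrix(D)
  n <- nrow(D)
  a <- length(unique(labels))
  ss_t <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) ss_t <- ss_t + D[i, j]^2
  ss_t <- ss_t / n
  ss_w <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    ng <- length(idx)
    s <- 0
    if (ng > 1)
      for (i in 1:(ng - 1)) for (j in (i + 1):ng)
        s <- s + D[idx[i], idx[j]]^2
    ss_w <- ss_w + s / ng
  }
  ((ss_t - ss_w) / (a - 1)) / (ss_w / (n - a))
}

# recursive permutation enumeration (independent of the package's)
oracle_permutations <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in oracle_permutations(v[-i]))
      out[[length(out) + 1]] <- c(v[i], p)
  out
}
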