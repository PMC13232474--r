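# IHC image pipeline: moment-preserving (Tsai) thresholding of the stain
# channel, removal of hematoxylin-dominated pixels, exact Euclidean
# distances to the vascular stroma, rank-sum comparison and H-scores.

#' Stain-oriented grayscale conversion
#'
#' `255 - mean(R, G, B)`, so dark stain becomes high-valued and the
#' moment-preserving threshold selects it as foreground.
#'
#' @param rgb H x W x 3 array with intensities in 0..255.
#' @return numeric H x W matrix.
#' @export
ihc_gray <- function(rgb) {
  255 - (rgb[, , 1] + rgb[, , 2] + rgb[, , 3]) / 3
}

#' Moment-preserving (Tsai) threshold
#'
#' Finds the two-level image preserving the first three gray-level moments
#' of the input histogram (256 integer bins); the below-threshold class
#' fraction `p0` follows from the moment equations, and the split point is
#' the gray level whose cumulative histogram fraction is closest to `p0`
#' (ties toward the lower level). Pixels at or above the returned threshold
#' (split point + 1) are foreground.
#'
#' @param gray numeric matrix of intensities in 0..255.
#' @return list with `threshold` (first foreground level), `mask` (logical
#'   matrix, `gray >= threshold` after integer binning), `p_background`
#'   (moment-preserving background fraction).
#' @export
moments_threshold <- function(gray) {
  g <- pmin(pmax(round(gray), 0), 255)
  if (min(g) == max(g)) stop("constant image: threshold undefined")
  h <- tabulate(as.integer(g) + 1L, nbins = 256L)
  p <- h / sum(h)
  i <- 0:255
  m1 <- sum(i * p); m2 <- sum(i^2 * p); m3 <- sum(i^3 * p)
  cd <- m2 - m1^2
  c0 <- (-m2^2 + m1 * m3) / cd
  c1 <- (m1 * m2 - m3) / cd
  disc <- sqrt(max(c1^2 - 4 * c0, 0))
  z0 <- 0.5 * (-c1 - disc)
  z1 <- 0.5 * (-c1 + disc)
  p0 <- (z1 - m1) / (z1 - z0)
  cum <- cumsum(p)
  split <- i[which.min(abs(cum - p0))]  # which.min takes the lower level
  thr <- split + 1
  list(threshold = thr, mask = matrix(g >= thr, nrow(gray), ncol(gray)),
       p_background = p0)
}

#' Remove hematoxylin-dominated pixels from a stain mask
#'
#' Pixels with strictly higher blue than red intensity (hematoxylin-stained
#' nuclei) are removed; ties are retained. Idempotent.
#'
#' @param rgb H x W x 3 array in 0..255.
#' @param mask logical H x W matrix of stain-positive pixels.
#' @return logical matrix.
#' @export
remove_blue_pixels <- function(rgb, mask) {
  stopifnot(all(dim(mask) == dim(rgb)[1:2]))
  mask & !(rgb[, , 3] > rgb[, , 1])
}

#' Detect marker-positive pixels in a dual-stained IHC image
#'
#' Thresholds the stain-oriented grayscale with [moments_threshold()] and
#' removes blue-dominated (nuclear) pixels with [remove_blue_pixels()].
#'
#' @param rgb H x W x 3 array in 0..255.
#' @return logical marker mask with the threshold stored in
#'   `attr(, "threshold")`.
#' @export
detect_marker_pixels <- function(rgb) {
  th <- moments_threshold(ihc_gray(rgb))
  m <- remove_blue_pixels(rgb, th$mask)
  attr(m, "threshold") <- th$threshold
  m
}

#' Distance from each marker-positive pixel to the nearest vessel pixel
#'
#' Exact Euclidean center-to-center distances (computed with a distance
#' transform, identical to a brute-force nearest-neighbor scan), scaled by
#' the pixel size.
#'
#' @param marker logical H x W marker mask.
#' @param vessel logical H x W vessel mask (must be non-empty).
#' @param pixel_size physical size of one pixel (e.g. um/pixel).
#' @return data.frame of class `distance_table` with `row`, `col`,
#'   `distance`; marker pixels inside the vessel get distance 0.
#' @export
distance_to_vessel <- function(marker, vessel, pixel_size = 1) {
  stopifnot(all(dim(marker) == dim(vessel)))
  if (!any(vessel)) stop("empty vessel mask")
  pix <- which(marker, arr.ind = TRUE)
  if (!nrow(pix)) {
    out <- data.frame(row = integer(0), col = integer(0),
                      distance = numeric(0))
    class(out) <- c("distance_table", "data.frame")
    return(out)
  }
  dm <- EBImage::distmap(matrix(as.numeric(!vessel), nrow(vessel)),
                         metric = "euclidean")
  dm <- matrix(as.numeric(dm), nrow(vessel))
  out <- data.frame(row = pix[, 1], col = pix[, 2],
                    distance = dm[pix] * pixel_size)
  class(out) <- c("distance_table", "data.frame")
  out
}

#' Rank-sum comparison of two marker distance distributions
#'
#' Two-sided Wilcoxon rank-sum test: exact enumeration of all
#' `choose(n1+n2, n1)` group assignments when both samples have at most 8
#' observations (ties handled through average ranks), otherwise the
#' tie-corrected normal approximation with continuity correction.
#'
#' @param d1,d2 `distance_table`s or numeric vectors.
#' @return list with `U` (Mann-Whitney statistic of the first sample),
#'   `p`, `method`.
#' @export
compare_marker_distances <- function(d1, d2) {
  x <- if (is.data.frame(d1)) d1$distance else as.numeric(d1)
  y <- if (is.data.frame(d2)) d2$distance else as.numeric(d2)
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("empty distance set")
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  u_obs <- w_obs - n1 * (n1 + 1) / 2
  if (n1 <= 8 && n2 <= 8) {
    combs <- utils::combn(n1 + n2, n1)
    w_all <- colSums(matrix(r[combs], nrow = n1))
    p <- min(1, 2 * min(mean(w_all <= w_obs + 1e-9),
                        mean(w_all >= w_obs - 1e-9)))
    list(U = u_obs, p = p, method = "exact enumeration")
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = TRUE))
    list(U = unname(wt$statistic), p = wt$p.value,
         method = "normal approximation (tie-corrected)")
  }
}

#' H-score from nuclear staining intensity percentages
#'
#' `H = 3 * pct_strong + 2 * pct_moderate + 1 * pct_weak`, in [0, 300].
#'
#' @param pct_strong,pct_moderate,pct_weak percentages of nuclei staining
#'   at intensity 3, 2 and 1; must sum to at most 100 (the negative
#'   fraction completes the total).
#' @return numeric H-score.
#' @export
h_score <- function(pct_strong, pct_moderate, pct_weak) {
  pcts <- c(pct_strong, pct_moderate, pct_weak)
  if (any(pcts < 0)) stop("percentages must be non-negative")
  if (sum(pcts) > 100 + 1e-9)
    stop("staining percentages sum to more than 100")
  3 * pct_strong + 2 * pct_moderate + 1 * pct_weak
}
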