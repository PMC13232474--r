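# Radial co-occurrence of a target cell category around anchor cells.

#' Co-occurrence curve of a target category around anchor cells
#'
#' For each distance annulus `[r_i, r_{i+1})`, all non-anchor points lying
#' within that annulus of at least one anchor point are pooled (presence
#' semantics: each point counts once per annulus), and the conditional
#' frequency of the target category among them is divided by the global
#' frequency of the target among non-anchor points. A pair-counting mode
#' (every anchor-point pair counted) is available by flag. Empty annuli are
#' flagged `NA`, not interpolated.
#'
#' @param t data.frame with columns `x`, `y`, `label`.
#' @param anchor_cat anchor category (its points are never pooled).
#' @param target_cat category whose enrichment is measured.
#' @param radii strictly increasing annulus edges starting at 0; default is
#'   0 followed by 10 log-spaced edges up to the 90th percentile of
#'   anchor-to-point distances.
#' @param mode `"presence"` (default) or `"pairs"`.
#' @return data.frame of class `cooc_curve`: `r_lo`, `r_hi`, `n` (pooled
#'   points or pairs), `cond_freq`, `ratio`.
#' @export
co_occurrence <- function(t, anchor_cat, target_cat, radii = NULL,
                          mode = c("presence", "pairs")) {
  mode <- match.arg(mode)
  stopifnot(all(c("x", "y", "label") %in% names(t)),
            all(is.finite(t$x)), all(is.finite(t$y)))
  is_anchor <- t$label == anchor_cat
  if (!any(is_anchor)) stop("no anchor points with label '", anchor_cat, "'")
  others <- t[!is_anchor, , drop = FALSE]
  if (!any(others$label == target_cat))
    stop("no non-anchor points with label '", target_cat, "'")
  anchors <- t[is_anchor, , drop = FALSE]

  # anchors x others distance matrix
  dx <- outer(anchors$x, others$x, "-")
  dy <- outer(anchors$y, others$y, "-")
  D <- sqrt(dx^2 + dy^2)

  if (is.null(radii)) {
    rmax <- stats::quantile(D, 0.9, names = FALSE)
    radii <- c(0, exp(seq(log(rmax / 30), log(rmax), length.out = 10)))
  }
  if (radii[1] != 0 || any(diff(radii) <= 0))
    stop("radii must strictly increase from 0")

  global <- mean(others$label == target_cat)
  nb <- length(radii) - 1
  out <- data.frame(r_lo = radii[-length(radii)], r_hi = radii[-1],
                    n = NA_real_, cond_freq = NA_real_, ratio = NA_real_)
  is_target <- others$label == target_cat
  for (i in seq_len(nb)) {
    in_ann <- D >= radii[i] & D < radii[i + 1]
    if (mode == "presence") {
      hit <- colSums(in_ann) > 0
      out$n[i] <- sum(hit)
      if (out$n[i] > 0) out$cond_freq[i] <- mean(is_target[hit])
    } else {
      out$n[i] <- sum(in_ann)
      if (out$n[i] > 0)
        out$cond_freq[i] <- sum(in_ann[, is_target, drop = FALSE]) /
          out$n[i]
    }
  }
  out$ratio <- out$cond_freq / global
  class(out) <- c("cooc_curve", "data.frame")
  out
}
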