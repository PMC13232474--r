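# Association and survival statistics linking subtype labels to external
# classifications and progression outcomes.

#' Cross-tabulate two label vectors over their shared units
#'
#' @param labels_a,labels_b named vectors (unit id -> label). Units missing
#'   from either vector are dropped; the drop count is recorded in
#'   `attr(, "n_dropped")`.
#' @return contingency table (class `table`).
#' @export
cross_tab <- function(labels_a, labels_b) {
  shared <- intersect(names(labels_a), names(labels_b))
  if (!length(shared)) stop("no overlapping unit ids")
  n_dropped <- length(union(names(labels_a), names(labels_b))) -
    length(shared)
  tab <- table(a = as.character(labels_a[shared]),
               b = as.character(labels_b[shared]))
  attr(tab, "n_dropped") <- n_dropped
  tab
}

#' Pearson chi-square test of independence
#'
#' `X^2 = sum (O - E)^2 / E` with `df = (r-1)(c-1)` and an upper-tail
#' chi-square p-value; no continuity correction.
#'
#' @param t r x c contingency table of non-negative counts.
#' @return list with `statistic`, `df`, `p`.
#' @export
chi_square_test <- function(t) {
  t <- as.matrix(t)
  if (sum(t) <= 0) stop("empty table")
  expected <- outer(rowSums(t), colSums(t)) / sum(t)
  if (any(expected == 0))
    stop("zero expected count; consider collapsing categories")
  ct <- suppressWarnings(stats::chisq.test(t, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Kaplan-Meier survival estimate per group
#'
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over event times; censored
#' subjects leave the risk set after their time (events before censorings
#' at tied times).
#'
#' @param s data.frame with columns `time`, `event` (0/1) and optionally
#'   `group`.
#' @return data.frame with `group`, `time`, `n_risk`, `n_event`, `surv`.
#' @export
km_estimate <- function(s) {
  if (any(s$time < 0)) stop("negative survival time")
  if (is.null(s$group)) s$group <- "all"
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = s)
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) rep("all", length(sm$time))
         else sub("^group=", "", as.character(sm$strata))
  data.frame(group = grp, time = sm$time, n_risk = sm$n.risk,
             n_event = sm$n.event, surv = sm$surv,
             stringsAsFactors = FALSE)
}

#' Log-rank test comparing survival between groups
#'
#' Observed-minus-expected events summed over event times with
#' hypergeometric variance; chi-square p with `df = #groups - 1`.
#'
#' @param s data.frame with columns `time`, `event`, `group`.
#' @return list with `statistic`, `df`, `p`.
#' @export
logrank_test <- function(s) {
  if (any(s$time < 0)) stop("negative survival time")
  groups <- unique(s$group)
  if (length(groups) < 2) stop("need >= 2 groups")
  if (any(table(factor(s$group, levels = groups)) == 0))
    stop("group with no subjects")
  if (sum(s$event) == 0)
    stop("log-rank undefined: no observed events")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = s)
  df <- length(groups) - 1
  list(statistic = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE))
}
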