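# Inferential toolkit: one-sided Wilcoxon rank-sum, BH FDR, Spearman
# correlation, median split, Kaplan-Meier curves and the log-rank test.

#' One-sided unpaired Wilcoxon rank-sum test
#'
#' Exact p by enumeration when `n_x + n_y <= 12` and there are no ties;
#' otherwise the normal approximation with tie and continuity corrections.
#'
#' @param x,y non-empty numeric samples.
#' @param alternative `"greater"` (x tends larger) or `"less"`.
#' @return list with `U` (the rank-sum statistic for `x`), `p`, and
#'   `method` (`"exact"` or `"normal_approx"`).
#' @export
wilcoxon_one_sided <- function(x, y, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stopf("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 12) && !ties
  ht <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact,
                correct = TRUE))
  list(U = unname(ht$statistic), p = ht$p.value,
       method = if (exact) "exact" else "normal_approx")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement; order-preserving with
#' the input.
#'
#' @param pvalues numeric vector of p-values in [0,1].
#' @return adjusted p-values, same order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Spearman rank correlation
#'
#' Rank-based Pearson correlation with average ranks for ties; exact
#' permutation p for `n <= 9` without ties, t approximation otherwise.
#'
#' @param x,y numeric vectors, `n >= 3`, neither constant.
#' @return list with `rho` and `p` (two-sided).
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) stopf("need n >= 3 paired values")
  if (sd(x) == 0 || sd(y) == 0) stopf("constant input vector; rho undefined")
  ht <- suppressWarnings(cor.test(x, y, method = "spearman",
                                  exact = length(x) <= 9))
  list(rho = unname(ht$estimate), p = ht$p.value)
}

#' Median split into high/low groups
#'
#' Scores at or above the median go to `"high"`, the rest to `"low"` (ties
#' at the median are assigned high; recorded in the result).
#'
#' @param scores numeric vector, `n >= 2`, not all identical.
#' @return list with `group` (character vector, same order), `median`,
#'   `tie_rule`.
#' @export
median_split <- function(scores) {
  if (length(scores) < 2) stopf("need at least 2 scores")
  if (length(unique(scores)) < 2) stopf("all scores identical; split impossible")
  m <- median(scores)
  list(group = ifelse(scores >= m, "high", "low"), median = m,
       tie_rule = "ties at the median are assigned to 'high'")
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit survival estimates with right censoring per group, the
#' risk/event table at each distinct event time, and the standard
#' (unweighted) 1-df log-rank chi-square. With no events in either group
#' the test is degenerate and `p = 1` is returned with a warning.
#'
#' @param records data.frame with `time` (> 0, months), `event` (0/1) and
#'   `group` (two levels, e.g. high/low).
#' @return list with `curves` (data.frame: `group`, `time`, `n_risk`,
#'   `n_event`, `survival`), `chisq`, `df`, `p`.
#' @export
km_logrank <- function(records) {
  stopifnot(all(c("time", "event", "group") %in% names(records)))
  if (any(records$time <= 0)) stopf("survival times must be positive")
  if (!all(records$event %in% c(0, 1))) stopf("event must be 0/1")
  groups <- unique(records$group)
  if (length(groups) != 2) stopf("need exactly 2 groups, have %d", length(groups))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = records)
  sm <- summary(fit, censored = TRUE)
  strata <- if (is.null(sm$strata)) rep(groups[1], length(sm$time)) else
    sub("^group=", "", as.character(sm$strata))
  curves <- data.frame(group = strata, time = sm$time, n_risk = sm$n.risk,
                       n_event = sm$n.event, survival = sm$surv,
                       stringsAsFactors = FALSE)
  if (sum(records$event) == 0) {
    warnf("no events in either group; log-rank is degenerate, p = 1")
    return(list(curves = curves, chisq = 0, df = 1L, p = 1))
  }
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group,
                            data = records)
  p <- stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  list(curves = curves, chisq = unname(sd_$chisq), df = 1L, p = p)
}
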