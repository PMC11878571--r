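# Paired longitudinal statistics: Wilcoxon signed-rank tests on
# early-vs-late residuals/Z-scores/burden counts, Cohen's d on the paired
# differences, Kruskal-Wallis subgroup comparisons, and the one-sample t
# for the affected-lobe z-of-z.

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on `late - early`. Zero differences are
#' dropped before ranking (Wilcoxon's original treatment). The exact
#' null distribution is used for n <= 25 without ties in the absolute
#' differences; otherwise the normal approximation with tie correction and
#' continuity correction.
#'
#' @param early,late Equal-length numeric vectors of paired observations.
#' @param exact Force exact (`TRUE`) or approximate (`FALSE`); default
#'   `NULL` chooses exact when n <= 25 and there are no ties.
#' @return List with `statistic` (V, sum of positive ranks), `p_value`,
#'   `n` (pairs used after zero removal), `exact`.
#' @export
paired_wilcoxon <- function(early, late, exact = NULL) {
  if (length(early) != length(late))
    stop("early/late must have equal length", call. = FALSE)
  d <- late - early
  if (any(!is.finite(d))) stop("non-finite paired differences", call. = FALSE)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("degenerate pairs: all differences are zero",
                    call. = FALSE)
  if (n < 5L)
    warning("fewer than 5 nonzero paired differences (n = ", n, ")",
            call. = FALSE)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0L
  use_exact <- if (is.null(exact)) n <= 25L && !ties else isTRUE(exact)
  if (use_exact && ties)
    stop("exact signed-rank distribution is unavailable with tied ranks",
         call. = FALSE)
  if (use_exact) {
    p <- min(1, 2 * min(psignrank(v, n), 1 - psignrank(v - 1, n)))
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  list(statistic = v, p_value = p, n = n, exact = use_exact)
}

#' Cohen's d for paired samples
#'
#' `mean(late - early) / sd(late - early)`, with the sample SD (n - 1
#' denominator) of the difference scores. The `average_sd` variant divides
#' instead by the mean of the two marginal SDs.
#'
#' @inheritParams paired_wilcoxon
#' @param denominator `"difference_sd"` (default) or `"average_sd"`.
#' @return Scalar d (positive when late exceeds early).
#' @export
cohens_d_paired <- function(early, late,
                            denominator = c("difference_sd", "average_sd")) {
  denominator <- match.arg(denominator)
  if (length(early) != length(late) || length(early) < 2L)
    stop("need at least 2 pairs of equal length", call. = FALSE)
  d <- late - early
  s <- if (denominator == "difference_sd") sd(d)
       else (sd(early) + sd(late)) / 2
  if (s == 0) stop("zero standard deviation: d undefined", call. = FALSE)
  mean(d) / s
}

#' Kruskal-Wallis subgroup comparison
#'
#' Rank-based test of whether per-patient changes differ by a clinical
#' subgroup label (e.g. histopathology, seizure freedom). Groups with
#' fewer than 2 members are dropped with a warning.
#'
#' @param changes Numeric vector of per-patient changes.
#' @param labels Grouping labels, same length.
#' @return List with `p_value`, `statistic` (H), `df`, `groups_used`.
#' @export
subgroup_kruskal <- function(changes, labels) {
  keep <- is.finite(changes) & !is.na(labels)
  changes <- changes[keep]; labels <- as.character(labels[keep])
  sizes <- table(labels)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warning("dropping subgroup(s) with < 2 members: ",
            paste(small, collapse = ", "), call. = FALSE)
    keep2 <- !(labels %in% small)
    changes <- changes[keep2]; labels <- labels[keep2]
  }
  if (length(unique(labels)) < 2L)
    stop("need at least 2 usable subgroups", call. = FALSE)
  kt <- kruskal.test(changes, factor(labels))
  list(p_value = kt$p.value, statistic = unname(kt$statistic),
       df = unname(kt$parameter), groups_used = sort(unique(labels)))
}

#' One-sample t-test
#'
#' Two-sided t-test of the mean of `values` against `mu`.
#'
#' @param values Numeric vector, length >= 2, nonzero SD.
#' @param mu Null mean (default 0).
#' @return List with `mean`, `p_value`, `statistic`, `df`.
#' @export
one_sample_t <- function(values, mu = 0) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  if (sd(values) == 0) stop("zero standard deviation", call. = FALSE)
  tt <- t.test(values, mu = mu)
  list(mean = mean(values), p_value = tt$p.value,
       statistic = unname(tt$statistic), df = unname(tt$parameter))
}

# Paired comparison wrapped into one tidy row; degenerate inputs (all-zero
# differences, zero SD) yield NA p/d rather than aborting a whole run.
paired_comparison_row <- function(metric, early, late, alpha,
                                  d_denominator = "difference_sd",
                                  exact = NULL) {
  p <- tryCatch(paired_wilcoxon(early, late, exact = exact)$p_value,
                error = function(e) NA_real_, warning = function(w) {
                  suppressWarnings(paired_wilcoxon(early, late,
                                                   exact = exact)$p_value)
                })
  d <- tryCatch(cohens_d_paired(early, late, denominator = d_denominator),
                error = function(e) NA_real_)
  data.frame(metric = metric, n_pairs = length(early),
             median_early = median(early), median_late = median(late),
             p_value = p, cohens_d = d,
             significant = !is.na(p) & p < alpha,
             stringsAsFactors = FALSE)
}
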