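#' Exact two-tailed binomial intraset concordance test
#'
#' Tests whether the split of significantly affected genes into up- and
#' down-regulated counts departs from a fair coin: the exact two-tailed
#' binomial p value at p = 0.5, defined as twice the smaller tail probability
#' and capped at 1 (at p = 0.5 this coincides with the
#' equal-or-smaller-likelihood definition).
#'
#' @param n_up,n_down nonnegative counts; their sum must be at least 1.
#' @return the concordance p value P_c in (0, 1].
#' @export
binomial_pc <- function(n_up, n_down) {
  stopifnot(length(n_up) == 1, length(n_down) == 1,
            n_up >= 0, n_down >= 0)
  n <- n_up + n_down
  if (n < 1) stop("n_up + n_down must be at least 1")
  lower <- stats::pbinom(n_up, n, 0.5)
  upper <- stats::pbinom(n_up - 1, n, 0.5, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

#' Two-tailed Mann-Whitney interset discordance test
#'
#' Compares the log-ratio distributions of two data layers with a two-tailed
#' rank-sum test: exact enumeration when the smaller sample has at most
#' `exact_max` values and there are no ties, otherwise the normal
#' approximation with tie correction.
#'
#' @param a,b numeric vectors (e.g. log2 GF/C ratios of two layers).
#' @param exact_max largest minimum-sample size for the exact branch.
#' @return the discordance p value P_MW in (0, 1].
#' @export
mannwhitney_pmw <- function(a, b, exact_max = 8L) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  r <- rank(c(a, b))
  u <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  if (isTRUE(all.equal(u, length(a) * length(b) / 2))) return(1)
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- min(length(a), length(b)) <= exact_max && !ties
  res <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = use_exact,
                       correct = !use_exact))
  min(1, res$p.value)
}
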