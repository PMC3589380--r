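# Nonparametric inference layer: label-permutation tests for classifier
# accuracy, Wilcoxon signed-rank, Fisher combination, exact binomial tests.

#' Label-permutation test for a classifier score
#'
#' Builds the null distribution of a test score by retraining with permuted
#' training labels: `fitAndScore` is called once per permutation with a
#' shuffled copy of `labels` and must return the resulting test score (test
#' labels untouched). The p-value uses the add-one estimator
#' `p = (1 + #\{null >= observed\}) / (nPerm + 1)`, which is never zero and
#' is invariant to any monotone transform of the score.
#'
#' @param observed the score obtained with the true training labels.
#' @param labels the training labels to permute.
#' @param fitAndScore function taking one argument (a permuted label
#'   vector) and returning a numeric score.
#' @param nPerm number of permutations (the study-scale convention is 500;
#'   calibration suites scale down to 99).
#' @param seed integer seed or `NULL`.
#' @return list of class `"permutationResult"` with `observed`, `nullDraws`
#'   (length `nPerm`) and `pValue` in `(0, 1]`.
#' @export
permutationTest <- function(observed, labels, fitAndScore, nPerm = 500,
                            seed = NULL) {
  if (nPerm < 1) stop("nPerm must be at least 1")
  stopifnot(is.function(fitAndScore), is.finite(observed))
  null_draws <- .with_seed(seed, function()
    vapply(seq_len(nPerm), function(i) fitAndScore(sample(labels)), 0))
  res <- list(observed = observed, nullDraws = null_draws,
              pValue = (1 + sum(null_draws >= observed)) / (nPerm + 1))
  class(res) <- "permutationResult"
  res
}

#' @export
print.permutationResult <- function(x, ...) {
  cat(sprintf("Permutation test: observed %.4g, null mean %.4g (n = %d), p = %.4g\n",
              x$observed, mean(x$nullDraws), length(x$nullDraws), x$pValue))
  invisible(x)
}

#' Wilcoxon signed-rank test
#'
#' Two-sided paired test on `a - b` (or on `a` alone when `b` is missing).
#' Zero differences are dropped; if all differences are zero the p-value is
#' defined as 1. The null distribution is exact (via the signed-rank tail
#' function) for up to 25 non-zero untied differences, and a normal
#' approximation with tie correction otherwise.
#'
#' @param a,b paired numeric vectors of equal length.
#' @return two-sided p-value.
#' @export
wilcoxonSignedRank <- function(a, b = NULL) {
  d <- if (is.null(b)) as.numeric(a) else {
    if (length(a) != length(b)) stop("a and b must have equal length")
    as.numeric(a) - as.numeric(b)
  }
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0L
  if (n <= 25L && !ties) {
    p <- 2 * min(psignrank(W, n), psignrank(W - 1, n, lower.tail = FALSE))
    return(min(1, p))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  z <- (W - mu) / sqrt(sig2)
  min(1, 2 * pnorm(-abs(z)))
}

#' Fisher's method for combining p-values
#'
#' Refers `X = -2 * sum(log(p_i))` to a chi-square distribution with `2k`
#' degrees of freedom (upper tail). Inputs must lie in `(0, 1]`; a zero
#' p-value is an error (combine add-one permutation p-values, which are
#' never zero).
#'
#' @param p numeric vector of p-values.
#' @return combined p-value.
#' @export
fisherCombine <- function(p) {
  p <- as.numeric(p)
  if (!length(p)) stop("no p-values to combine")
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}

#' Exact binomial test
#'
#' Exact tail probability of `k` successes in `n` Bernoulli trials with
#' success probability `p0`; the default alternative is the upper tail
#' `P(X >= k)`, the conservative check that a classifier labels more than a
#' chance fraction of an unbalanced test set as the positive class.
#'
#' @param k number of successes, `0 <= k <= n`.
#' @param n number of trials.
#' @param p0 null success probability.
#' @param alternative `"greater"`, `"less"` or `"two.sided"`.
#' @return p-value.
#' @export
binomialTest <- function(k, n, p0 = 0.5,
                         alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(k) != 1 || length(n) != 1 || is.na(k) || is.na(n) ||
      k < 0 || n < 1 || k > n || k != round(k) || n != round(n))
    stop("need integer counts with 0 <= k <= n")
  binom.test(k, n, p = p0, alternative = alternative)$p.value
}
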