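## Shared statistical kernels. All group comparisons in the package funnel
## through these so the exact-vs-approximate policy is applied in one place
## and recorded in the returned TestResult.

newTestResult <- function(statistic, pValue, method, n, exact) {
  new("TestResult", statistic = as.numeric(statistic),
      pValue = min(1, as.numeric(pValue)), method = method,
      n = as.integer(n), exact = exact)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sample rank-sum test, the group-comparison test used throughout the
#' network statistics. The exact null distribution is enumerated when the
#' smaller sample has at most 25 observations and no ties are present;
#' otherwise a tie-corrected normal approximation with continuity correction
#' is used. The crossover is recorded in the `exact` slot of the result.
#'
#' @param x,y numeric samples.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return a [TestResult-class].
#' @export
wilcoxonRankSum <- function(x, y, alternative = "two.sided") {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (length(unique(c(x, y))) == 1)   # fully degenerate: no evidence either way
    return(newTestResult(length(x) * length(y) / 2, 1, "wilcoxon_rank_sum",
                         c(length(x), length(y)), TRUE))
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- min(length(x), length(y)) <= 25 && !ties
  res <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                       correct = TRUE))
  newTestResult(res$statistic, res$p.value, "wilcoxon_rank_sum",
                c(length(x), length(y)), exact)
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Used by the singleton bootstrap, where active and inactive counts come
#' from the same genome. Zero differences are dropped (and reported); the
#' exact distribution is enumerated for at most 20 non-zero differences
#' without tied magnitudes.
#'
#' @param d numeric vector of paired differences.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return a [TestResult-class].
#' @export
wilcoxonSignedRank <- function(d, alternative = "two.sided") {
  if (!length(d)) stop("empty difference vector")
  nZero <- sum(d == 0)
  d <- d[d != 0]
  if (!length(d)) {
    warning("all paired differences are zero; p = 1")
    return(newTestResult(0, 1, "wilcoxon_signed_rank", 0L, TRUE))
  }
  if (nZero) message("dropped ", nZero, " zero difference(s)")
  exact <- length(d) <= 20 && anyDuplicated(abs(d)) == 0
  res <- suppressWarnings(
    stats::wilcox.test(d, alternative = alternative, exact = exact,
                       correct = TRUE))
  newTestResult(res$statistic, res$p.value, "wilcoxon_signed_rank",
                length(d), exact)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided hypergeometric tail-sum p-value; used for cryptic-hit
#' enrichment of a cluster against the rest of the network.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return a [TestResult-class].
#' @export
fisherExact2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!identical(dim(tab), c(2L, 2L))) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("cells must be non-negative integers")
  p <- stats::fisher.test(tab)$p.value
  newTestResult(tab[1, 1], p, "fisher_exact", as.integer(rowSums(tab)), TRUE)
}

#' Rand index between two partitions
#'
#' The fraction of node pairs on which the two partitions agree: together in
#' both, or apart in both. Computed from the contingency table of cluster
#' co-membership, so it scales to large networks while matching the
#' all-pairs definition exactly.
#'
#' @param p1,p2 [Partition-class] objects (or named membership vectors)
#'   over the same node set.
#' @return a number in \[0, 1\]; 1 iff the partitions are identical.
#' @export
randIndex <- function(p1, p2) {
  m1 <- if (is(p1, "Partition")) p1@membership else p1
  m2 <- if (is(p2, "Partition")) p2@membership else p2
  if (!setequal(names(m1), names(m2)))
    stop("partitions cover different node sets")
  m2 <- m2[names(m1)]
  n <- length(m1)
  if (n < 2) return(1)
  tab <- table(m1, m2)
  sumSq <- sum(tab^2)
  a <- sum(rowSums(tab)^2)
  b <- sum(colSums(tab)^2)
  together <- (sumSq - n) / 2
  apart <- (n^2 - a - b + sumSq) / 2
  (together + apart) / choose(n, 2)
}

#' Group comparison of a per-node statistic
#'
#' Two-sided Wilcoxon rank-sum on a numeric statistic between the two levels
#' of a logical grouping column, used for the genome-level and group-level
#' degree/weighted-degree/singleton comparisons.
#'
#' @param statTable data.frame with one row per genome (or per collapsed
#'   group) containing `grouping` and `statistic` columns.
#' @param grouping name of a logical column (e.g. `"has_dnmt"`, `"has_piwi"`).
#' @param statistic name of a numeric column (e.g. `"degree"`,
#'   `"weighted_degree"`, `"n_singletons"`).
#' @return list with the two samples (`inGroup`, `outGroup`) and `test`, a
#'   [TestResult-class].
#' @export
groupComparison <- function(statTable, grouping, statistic) {
  checkColumns(statTable, c(grouping, statistic), "statistic table")
  g <- statTable[[grouping]]
  if (anyNA(g)) stop("grouping column contains NA")
  x <- statTable[[statistic]][g]
  y <- statTable[[statistic]][!g]
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 members (got ", length(x), " and ",
         length(y), ")")
  list(inGroup = x, outGroup = y,
       test = wilcoxonRankSum(x, y))
}
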