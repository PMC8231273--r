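## Group comparisons: exact Wilcoxon rank-sum tests with per-section values
## as the experimental unit, and one-way ANOVA from summary statistics.

## Rank sums of group A over all C(n, nA) assignments of the pooled
## mid-ranks. Used by the exact p-value; ties are handled by construction
## because the enumeration permutes the observed (possibly tied) ranks.
.enumerateRankSums <- function(ranks, nA) {
  combos <- utils::combn(length(ranks), nA)
  colSums(matrix(ranks[combos], nrow = nA))
}

#' Exact Wilcoxon rank-sum test
#'
#' Rank-sum test with mid-ranks for ties. For combined sample sizes up to
#' \code{maxExact} (default 20) the two-sided p-value is computed by full
#' enumeration of all \code{choose(nA + nB, nA)} group assignments of the
#' observed ranks: p = min(1, 2 min(P(W <= w), P(W >= w))), the doubled
#' smaller tail. \code{twoSided = "deviation"} instead doubles nothing and
#' uses P(|W - E W| >= |w - E W|). Larger samples fall back to the
#' tie-corrected normal approximation.
#'
#' @param a,b numeric vectors of per-animal (per-section) values.
#' @param statisticName label carried into the result.
#' @param twoSided \code{"doubled-tail"} (default) or \code{"deviation"}.
#' @param maxExact largest combined n for which full enumeration is used.
#' @return A \linkS4class{GroupComparison}.
#' @examples
#' pValue(wilcoxonRankSumExact(1:5, 6:10))  # 2/252
#' @export
wilcoxonRankSumExact <- function(a, b, statisticName = "value",
                                 twoSided = c("doubled-tail", "deviation"),
                                 maxExact = 20L) {
  twoSided <- match.arg(twoSided)
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  if (anyNA(a) || anyNA(b)) stop("missing values in group data")
  nA <- length(a); n <- nA + length(b)
  r <- rank(c(a, b))  # mid-ranks for ties
  w <- sum(r[seq_len(nA)])
  eps <- 1e-9
  if (n <= maxExact) {
    W <- .enumerateRankSums(r, nA)
    if (twoSided == "doubled-tail") {
      p <- min(1, 2 * min(mean(W <= w + eps), mean(W >= w - eps)))
    } else {
      e <- mean(W)
      p <- mean(abs(W - e) >= abs(w - e) - eps)
    }
    method <- "exact"
  } else {
    e <- nA * (n + 1) / 2
    ties <- table(r)
    sig2 <- nA * (n - nA) / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (w - e) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal-approx"
  }
  new("GroupComparison", statisticName = statisticName, groupA = a,
      groupB = b, rankSum = w, pTwoSided = p, method = method)
}

#' One-way ANOVA from group summary statistics
#'
#' Reconstructs the one-way ANOVA F test from per-group means, sample
#' standard deviations and sizes: between-group sum of squares
#' \eqn{SSB = \sum n_i (\bar x_i - \bar x)^2}, within-group
#' \eqn{SSW = \sum (n_i - 1) s_i^2}, \eqn{F = (SSB/(k-1)) / (SSW/(N-k))},
#' p from the upper tail of \eqn{F_{k-1, N-k}}. Identical to running
#' \code{aov} on any raw data matching the summaries.
#'
#' @param means,sds,ns numeric vectors (equal length >= 2) of group means,
#'   sample SDs and sizes (each n >= 2).
#' @return \code{list(F =, p =, df = c(k - 1, N - k))}.
#' @examples
#' ## birth weights 3.41 +/- 0.21, 2.73 +/- 0.23, 3.20 +/- 0.52 (n = 5 each)
#' anovaOnewayFromSummary(c(3.41, 2.73, 3.20), c(0.21, 0.23, 0.52),
#'                        c(5, 5, 5))
#' @export
anovaOnewayFromSummary <- function(means, sds, ns) {
  k <- length(means)
  if (k < 2L || length(sds) != k || length(ns) != k)
    stop("need equal-length means, sds and ns for at least 2 groups")
  if (any(ns < 2L)) stop("each group needs n >= 2")
  if (any(sds < 0)) stop("standard deviations must be >= 0")
  N <- sum(ns)
  grand <- sum(ns * means) / N
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((ns - 1) * sds^2)
  if (ssw <= 0) stop("zero pooled within-group variance")
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = f, p = stats::pf(f, k - 1, N - k, lower.tail = FALSE),
       df = c(k - 1, N - k))
}

#' Tukey HSD pairwise comparisons from summary statistics
#'
#' Post hoc pairwise comparisons after \code{\link{anovaOnewayFromSummary}},
#' using the studentized-range distribution with the pooled within-group
#' variance. Provided as the conventional post hoc companion of the one-way
#' ANOVA; other post hoc procedures would give different p-values.
#'
#' @inheritParams anovaOnewayFromSummary
#' @return data.frame with one row per group pair: difference of means and
#'   adjusted p-value.
#' @export
tukeyHsdFromSummary <- function(means, sds, ns) {
  k <- length(means)
  if (k < 2L) stop("need at least two groups")
  N <- sum(ns)
  msw <- sum((ns - 1) * sds^2) / (N - k)
  pairs <- utils::combn(k, 2)
  res <- apply(pairs, 2L, function(ij) {
    i <- ij[1L]; j <- ij[2L]
    se <- sqrt(msw / 2 * (1 / ns[i] + 1 / ns[j]))
    q <- abs(means[i] - means[j]) / se
    c(diff = means[i] - means[j],
      pAdj = stats::ptukey(q, k, N - k, lower.tail = FALSE))
  })
  data.frame(groupA = pairs[1L, ], groupB = pairs[2L, ],
             diff = res["diff", ], pAdj = res["pAdj", ])
}

#' Compare clump statistics between two groups of sections
#'
#' Collects the per-section clump count and median clump size and runs one
#' exact Wilcoxon rank-sum test per statistic (count, median size).
#'
#' @param groupA,groupB lists of \linkS4class{ClumpSet}s (>= 2 sections
#'   each), or numeric vectors of already-collected per-section statistics
#'   are not accepted -- pass ClumpSets so both statistics stay paired.
#' @param ... passed to \code{\link{wilcoxonRankSumExact}}.
#' @return \code{list(count =, medianSize =)} of
#'   \linkS4class{GroupComparison}s.
#' @export
compareClumpStats <- function(groupA, groupB, ...) {
  collect <- function(g, what) vapply(g, function(cs) {
    s <- clumpSummary(cs); as.numeric(s[[what]])
  }, numeric(1))
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("need at least 2 sections per group")
  cntA <- collect(groupA, "count"); cntB <- collect(groupB, "count")
  medA <- collect(groupA, "medianSizePx"); medB <- collect(groupB, "medianSizePx")
  if (anyNA(medA) || anyNA(medB))
    stop("a section has no clumps: median clump size undefined")
  list(count = wilcoxonRankSumExact(cntA, cntB, "clump count", ...),
       medianSize = wilcoxonRankSumExact(medA, medB,
                                         "median clump size (px)", ...))
}

#' Compare distance-to-border bins between two groups
#'
#' One exact Wilcoxon rank-sum test per distance bin on the per-animal bin
#' fractions (or counts). No multiplicity adjustment is applied; the
#' per-bin p-values are reported raw.
#'
#' @param groupA,groupB lists of \linkS4class{DistanceProfile}s sharing the
#'   same bin edges.
#' @param use \code{"fractions"} (default) or \code{"counts"}.
#' @param ... passed to \code{\link{wilcoxonRankSumExact}}.
#' @return List of \linkS4class{GroupComparison}s, one per bin, named by
#'   bin interval.
#' @export
compareDistanceBins <- function(groupA, groupB,
                                use = c("fractions", "counts"), ...) {
  use <- match.arg(use)
  edges <- groupA[[1L]]@binEdgesMm
  for (p in c(groupA, groupB))
    if (!isTRUE(all.equal(p@binEdgesMm, edges)))
      stop("profiles do not share bin edges")
  get <- function(p, k)
    if (use == "fractions") p@binFractions[k] else as.numeric(p@binCounts[k])
  nb <- length(edges) - 1L
  out <- lapply(seq_len(nb), function(k) {
    a <- vapply(groupA, get, numeric(1), k)
    b <- vapply(groupB, get, numeric(1), k)
    wilcoxonRankSumExact(a, b, sprintf("fraction at %g-%g mm",
                                       edges[k], edges[k + 1L]), ...)
  })
  stats::setNames(out, sprintf("%g-%g", edges[-length(edges)], edges[-1L]))
}
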