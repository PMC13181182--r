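#' Binomial likelihood machinery for methylation segmentation
#'
#' Methylated counts at a CpG site are modelled as Binomial(t + c, p) where
#' c and t are methylated and unmethylated read counts. These functions
#' evaluate maximum-likelihood rates and profile log-likelihoods used as the
#' merge cost during clustering. The binomial coefficient is omitted
#' throughout: it cancels in every likelihood-ratio difference.
#'
#' @name likelihoods
NULL

# x * log(x) with the 0 * log(0) := 0 convention; vectorized
xlogx <- function(x) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * log(x[pos])
  out
}

# profile log-likelihood from per-sample pooled count sums:
#   sum_j [ C_j log p_j + T_j log(1 - p_j) ]  at  p_j = C_j / (C_j + T_j)
#     = sum_j [ C_j log C_j + T_j log T_j - (C_j + T_j) log(C_j + T_j) ]
# zero-coverage samples contribute 0. Integer-exact in the sums, so the
# value is independent of how the sums were accumulated.
ll_from_sums <- function(cs, ts) {
  sum(xlogx(cs)) + sum(xlogx(ts)) - sum(xlogx(cs + ts))
}

check_sites <- function(data, sites, what = "sites") {
  if (length(sites) == 0) abort(paste0(what, " must be non-empty"))
  if (anyNA(sites) || any(sites < 1) || any(sites > n_sites(data))) {
    abort(paste0(what, " contains indices outside the count set"))
  }
  if (anyDuplicated(sites)) abort(paste0(what, " contains duplicate indices"))
  invisible(sites)
}

#' Per-site methylation rate MLE (beta-value)
#'
#' @param meth,unmeth Methylated / unmethylated read counts (vectors or
#'   matrices of matching shape).
#' @return `meth / (meth + unmeth)`, with `NA` where total coverage is zero
#'   (the rate is undefined; callers decide how to handle it).
#' @examples
#' site_rate_mle(3, 7)   # 0.3
#' site_rate_mle(0, 0)   # NA: no reads
#' @export
site_rate_mle <- function(meth, unmeth) {
  if (any(meth < 0, na.rm = TRUE) || any(unmeth < 0, na.rm = TRUE)) {
    abort("counts must be >= 0")
  }
  tot <- meth + unmeth
  out <- meth / tot
  out[tot == 0] <- NA_real_
  out
}

#' Pooled methylation rate MLE over a set of sites
#'
#' For a set of sites S the per-sample pooled rate is
#' `sum(c) / sum(t + c)` over the member sites.
#'
#' @param data A [meth_set()].
#' @param sites Integer vector of site (row) indices.
#' @param sample Optional sample index or name; default all samples.
#' @return Numeric vector of pooled rates (one per requested sample), `NA`
#'   where the pooled coverage is zero.
#' @export
pooled_rate_mle <- function(data, sites, sample = NULL) {
  stopifnot(inherits(data, "meth_set"))
  check_sites(data, sites)
  cs <- colSums(data$meth[sites, , drop = FALSE])
  ts <- colSums(data$unmeth[sites, , drop = FALSE])
  rate <- site_rate_mle(cs, ts)
  names(rate) <- data$samples
  if (!is.null(sample)) rate <- rate[sample]
  rate
}

#' Profile log-likelihood of a site set
#'
#' The binomial log-likelihood of all counts in the site set, evaluated at
#' the per-sample pooled MLE, without the combinatorial coefficient:
#' `sum_{i in S} sum_j [c_ij log p_Sj + t_ij log(1 - p_Sj)]`.
#' Zero-coverage cells contribute zero.
#'
#' @inheritParams pooled_rate_mle
#' @return A scalar `<= 0`.
#' @export
segment_log_likelihood <- function(data, sites) {
  stopifnot(inherits(data, "meth_set"))
  check_sites(data, sites)
  ll_from_sums(colSums(data$meth[sites, , drop = FALSE]),
               colSums(data$unmeth[sites, , drop = FALSE]))
}

#' Negative log-likelihood ratio between two site sets
#'
#' The merge cost `nLLR(A, B) = -logL(A u B) + logL(A) + logL(B)`, each
#' profile log-likelihood evaluated at its own pooled per-sample MLE. It is
#' non-negative (a pooled fit cannot beat separate fits) and zero exactly
#' when the pooled MLEs of A and B agree wherever coverage exists.
#'
#' @param data A [meth_set()].
#' @param a,b Disjoint, non-empty integer vectors of site indices.
#' @return A scalar `>= 0`.
#' @export
nllr <- function(data, a, b) {
  check_sites(data, a, "a")
  check_sites(data, b, "b")
  if (length(intersect(a, b)) > 0) abort("site sets must be disjoint")
  # non-negative by MLE optimality; clamp float cancellation at the bound
  max(0, segment_log_likelihood(data, a) + segment_log_likelihood(data, b) -
        segment_log_likelihood(data, c(a, b)))
}

#' Genomic distance penalty
#'
#' A heavy-tailed penalty on the genomic gap between two clusters: the
#' negative log-density of a Student's t distribution with one degree of
#' freedom (a standard Cauchy) evaluated at `delta_bp / scale`. Merging
#' across chromosomes is forbidden (`Inf`). The penalty is strictly
#' increasing in distance, with minimum `log(pi)` at zero distance.
#'
#' @param delta_bp Non-negative gap in base pairs.
#' @param same_chrom Are the clusters on the same chromosome?
#' @param scale Distance scale in bp dividing `delta_bp` before the Cauchy
#'   density is evaluated (default 100).
#' @return `log(pi) + log1p((delta_bp / scale)^2)`, or `Inf` across
#'   chromosomes. Vectorized over `delta_bp` and `same_chrom`.
#' @examples
#' distance_penalty(0)    # log(pi)
#' distance_penalty(100)  # log(2 * pi)
#' @export
distance_penalty <- function(delta_bp, same_chrom = TRUE, scale = 100) {
  if (any(delta_bp < 0)) abort("delta_bp must be >= 0")
  if (scale <= 0) abort("scale must be > 0")
  out <- log(pi) + log1p((delta_bp / scale)^2)
  out[!same_chrom] <- Inf
  out
}

#' Dissimilarity between two site clusters
#'
#' The full merge cost: `nllr(a, b)` plus the genomic [distance_penalty()]
#' at the minimum absolute coordinate difference between any site of `a`
#' and any site of `b` (for genomically adjacent clusters, the gap between
#' the facing boundary sites). Infinite across chromosomes.
#'
#' @inheritParams nllr
#' @param scale Distance scale passed to [distance_penalty()].
#' @export
dissimilarity <- function(data, a, b, scale = 100) {
  check_sites(data, a, "a")
  check_sites(data, b, "b")
  chr_a <- unique(data$chrom[a])
  chr_b <- unique(data$chrom[b])
  if (length(chr_a) > 1 || length(chr_b) > 1) {
    abort("a cluster must lie on a single chromosome")
  }
  if (!identical(chr_a, chr_b)) return(Inf)
  delta <- min(abs(outer(data$pos[a], data$pos[b], "-")))
  nllr(data, a, b) + distance_penalty(delta, TRUE, scale)
}
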