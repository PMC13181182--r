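# Independent from-scratch oracles used to verify the likelihood machinery,
# the incremental clustering, and the Fisher/BH statistics. These deliberately
# re-derive everything from raw counts via the textbook formulas, sharing no
# code path with the implementation they check.

# random count set on one or more chromosomes
random_meth_set <- function(m, n, n_chrom = 1, max_depth = 30, p_zero = 0.1,
                            pos_range = 1e5) {
  chrom <- sort(rep_len(paste0("chr", seq_len(n_chrom)), m))
  pos <- unlist(lapply(split(seq_len(m), chrom), function(i) {
    sort(sample.int(pos_range, length(i)))
  }), use.names = FALSE)
  depth <- matrix(rpois(m * n, max_depth / 2), m, n)
  depth[matrix(runif(m * n) < p_zero, m, n)] <- 0L
  p <- matrix(rbeta(m * n, 0.5, 0.5), m, n)
  meth <- matrix(rbinom(m * n, as.vector(depth), as.vector(p)), m, n)
  new_meth_set(meth, depth - meth, chrom, pos, sprintf("s%d", seq_len(n)))
}

# Eq.-style profile log-likelihood: per-sample pooled rate, then
# sum of c*log(p) + t*log(1-p) over every site, 0*log(0) dropped
oracle_loglik <- function(data, sites) {
  tot <- 0
  for (j in seq_len(n_samples(data))) {
    cs <- sum(data$meth[sites, j]); ts <- sum(data$unmeth[sites, j])
    if (cs + ts == 0) next
    p <- cs / (cs + ts)
    cvec <- data$meth[sites, j]; tvec <- data$unmeth[sites, j]
    if (any(cvec > 0)) tot <- tot + sum(cvec[cvec > 0]) * log(p)
    if (any(tvec > 0)) tot <- tot + sum(tvec[tvec > 0]) * log(1 - p)
  }
  tot
}

oracle_nllr <- function(data, a, b) {
  -oracle_loglik(data, c(a, b)) + oracle_loglik(data, a) + oracle_loglik(data, b)
}

oracle_dissimilarity <- function(data, a, b, scale = 100) {
  if (!identical(unique(data$chrom[a]), unique(data$chrom[b]))) return(Inf)
  delta <- min(abs(outer(data$pos[a], data$pos[b], "-")))
  oracle_nllr(data, a, b) - log(stats::dt(delta / scale, df = 1))
}

# quadratic from-scratch agglomeration: every step re-evaluates every
# adjacent pair's dissimilarity from raw counts; leftmost pair wins ties
oracle_dendrogram <- function(data, chrom, scale = 100) {
  idx <- which(data$chrom == chrom)
  clusters <- as.list(seq_along(idx))
  bounds <- integer(0); costs <- numeric(0)
  while (length(clusters) > 1) {
    k <- length(clusters)
    cost_k <- vapply(seq_len(k - 1), function(i) {
      oracle_dissimilarity(data, idx[clusters[[i]]], idx[clusters[[i + 1]]],
                           scale)
    }, numeric(1))
    i <- which(cost_k == min(cost_k))[1]  # adjacent pairs are in genomic order
    bounds <- c(bounds, tail(clusters[[i]], 1))
    costs <- c(costs, cost_k[i])
    clusters[[i]] <- c(clusters[[i]], clusters[[i + 1]])
    clusters[[i + 1]] <- NULL
  }
  list(boundary = bounds, cost = costs)
}

# two-sided Fisher p by exhaustive hypergeometric enumeration over all
# tables with the observed margins (standard "sum of tables at most as
# probable" convention, with the usual 1 + 1e-7 relative slack)
oracle_fisher_p <- function(a, b, cc, d) {
  m1 <- a + b; m2 <- cc + d; c1 <- a + cc
  lo <- max(0, c1 - m2); hi <- min(c1, m1)
  probs <- stats::dhyper(lo:hi, m1, m2, c1)
  obs <- stats::dhyper(a, m1, m2, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up: q_(i) = min over j >= i of p_(j) * m / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  pmin(q_sorted, 1)[order(o)]
}
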