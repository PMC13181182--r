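#' Build the per-chromosome merge dendrogram
#'
#' Starts from every CpG site as a singleton cluster and repeatedly merges
#' the genomically adjacent pair with the smallest [dissimilarity()]
#' (binomial nLLR plus distance penalty), until one cluster remains. Only
#' adjacent clusters on the same chromosome are merge candidates, so every
#' intermediate cluster is a contiguous genomic interval. Ties are broken
#' toward the leftmost candidate pair.
#'
#' Cluster count sums are integers, so the incrementally maintained pooled
#' counts (and hence every merge cost) are exactly what a from-scratch
#' re-evaluation of the raw counts would give.
#'
#' @param data A [meth_set()].
#' @param chrom Chromosome label to segment.
#' @param distance_scale Scale (bp) of the genomic distance penalty.
#' @return A `meth_dendrogram`: merge table (`step`, `left`, `right`,
#'   `new_id`, `cost`, `nllr`, `boundary`), leaf count and bookkeeping.
#'   Leaves are numbered 1..m in genomic order; merged clusters m+1, ... in
#'   merge order. `boundary` is the inter-CpG boundary (index of the site to
#'   its left, within the chromosome) removed by the merge.
#' @export
build_dendrogram <- function(data, chrom, distance_scale = 100) {
  stopifnot(inherits(data, "meth_set"))
  idx <- chrom_sites(data, chrom)
  m <- length(idx)
  n <- n_samples(data)
  pos <- as.numeric(data$pos[idx])
  meth <- data$meth[idx, , drop = FALSE]
  unmeth <- data$unmeth[idx, , drop = FALSE]
  n_obs <- sum(meth + unmeth > 0)

  n_id <- 2L * m - 1L
  Cs <- matrix(0, n_id, n); Ts <- matrix(0, n_id, n)
  Cs[1:m, ] <- meth; Ts[1:m, ] <- unmeth
  ll <- numeric(n_id)
  for (i in seq_len(m)) ll[i] <- ll_from_sums(Cs[i, ], Ts[i, ])
  lpos <- numeric(n_id); rpos <- numeric(n_id)
  lpos[1:m] <- pos; rpos[1:m] <- pos
  rsite <- integer(n_id); rsite[1:m] <- seq_len(m)

  nxt <- integer(n_id); prv <- integer(n_id)
  nxt[1:m] <- c(seq_len(m)[-1], 0L); prv[1:m] <- c(0L, seq_len(m)[-m])

  pair_cost <- function(a, b) {
    nl <- max(0, ll[a] + ll[b] -
                ll_from_sums(Cs[a, ] + Cs[b, ], Ts[a, ] + Ts[b, ]))
    c(nl + log(pi) + log1p(((lpos[b] - rpos[a]) / distance_scale)^2), nl)
  }

  dvec <- rep(Inf, n_id)   # cost of merging cluster id with its right neighbor
  nvec <- rep(NA_real_, n_id)
  if (m > 1) {
    for (i in seq_len(m - 1L)) {
      pc <- pair_cost(i, i + 1L)
      dvec[i] <- pc[1]; nvec[i] <- pc[2]
    }
  }

  n_merge <- m - 1L
  mg_left <- integer(n_merge); mg_right <- integer(n_merge)
  mg_new <- integer(n_merge); mg_cost <- numeric(n_merge)
  mg_nllr <- numeric(n_merge); mg_bound <- integer(n_merge)

  for (q in seq_len(n_merge)) {
    mn <- min(dvec)
    cand <- which(dvec == mn)
    j <- if (length(cand) > 1L) cand[which.min(lpos[cand])] else cand
    r <- nxt[j]
    new <- m + q
    mg_left[q] <- j; mg_right[q] <- r; mg_new[q] <- new
    mg_cost[q] <- dvec[j]; mg_nllr[q] <- nvec[j]; mg_bound[q] <- rsite[j]

    Cs[new, ] <- Cs[j, ] + Cs[r, ]
    Ts[new, ] <- Ts[j, ] + Ts[r, ]
    ll[new] <- ll_from_sums(Cs[new, ], Ts[new, ])
    lpos[new] <- lpos[j]; rpos[new] <- rpos[r]; rsite[new] <- rsite[r]

    p <- prv[j]; s <- nxt[r]
    prv[new] <- p; nxt[new] <- s
    if (p > 0L) nxt[p] <- new
    if (s > 0L) prv[s] <- new
    dvec[j] <- Inf; dvec[r] <- Inf
    if (p > 0L) {
      pc <- pair_cost(p, new)
      dvec[p] <- pc[1]; nvec[p] <- pc[2]
    }
    if (s > 0L) {
      pc <- pair_cost(new, s)
      dvec[new] <- pc[1]; nvec[new] <- pc[2]
    }
  }

  structure(
    list(
      chrom = chrom,
      leaf_count = m,
      merges = tibble(
        step = seq_len(n_merge), left = mg_left, right = mg_right,
        new_id = mg_new, cost = mg_cost, nllr = mg_nllr, boundary = mg_bound
      ),
      site_offset = idx[1] - 1L,
      positions = data$pos[idx],
      n_obs = n_obs,
      leaf_ll_sum = sum(ll[1:m]),
      distance_scale = distance_scale
    ),
    class = "meth_dendrogram"
  )
}

#' @export
print.meth_dendrogram <- function(x, ...) {
  cat(sprintf("<meth_dendrogram> %s: %d leaves, %d merges\n",
              x$chrom, x$leaf_count, nrow(x$merges)))
  invisible(x)
}

#' @export
tidy.meth_dendrogram <- function(x, ...) x$merges

# segments tibble from within-chromosome segment index ranges
make_segments <- function(data, chrom, starts, ends) {
  idx <- chrom_sites(data, chrom)
  offset <- idx[1] - 1L
  csC <- c(0, cumsum(rowSums(data$meth[idx, , drop = FALSE])))
  csT <- c(0, cumsum(rowSums(data$unmeth[idx, , drop = FALSE])))
  segC <- csC[ends + 1] - csC[starts]
  segT <- csT[ends + 1] - csT[starts]
  tot <- segC + segT
  tibble(
    chrom = chrom,
    start = data$pos[offset + starts],
    end = data$pos[offset + ends],
    length_bp = data$pos[offset + ends] - data$pos[offset + starts] + 1L,
    n_cpgs = ends - starts + 1L,
    first_site = offset + starts,
    last_site = offset + ends,
    mean_methylation = ifelse(tot > 0, segC / tot, NA_real_),
    coherent = NA,
    coherence_pvalue = NA_real_
  )
}

#' Cut a dendrogram into k segments
#'
#' Undoes the last `k - 1` merges, leaving exactly `k` contiguous, disjoint
#' clusters that cover the chromosome. Cuts are nested: the cut at `k - 1`
#' merges exactly one adjacent pair of the cut at `k`.
#'
#' @param dendrogram A `meth_dendrogram` from [build_dendrogram()].
#' @param k Number of segments, `1 <= k <= leaf_count`.
#' @param data The [meth_set()] the dendrogram was built from.
#' @return A segments tibble (`chrom`, `start`, `end`, `length_bp`,
#'   `n_cpgs`, `first_site`, `last_site`, `mean_methylation`, plus empty
#'   coherence columns).
#' @export
cut_dendrogram <- function(dendrogram, k, data) {
  stopifnot(inherits(dendrogram, "meth_dendrogram"))
  m <- dendrogram$leaf_count
  if (length(k) != 1 || is.na(k) || k < 1 || k > m) {
    abort(sprintf("k must be in [1, %d]", m))
  }
  k <- as.integer(k)
  removed <- dendrogram$merges$boundary[seq_len(m - k)]
  keep <- sort(setdiff(seq_len(max(m - 1L, 0L)), removed))
  starts <- c(1L, keep + 1L)
  ends <- c(keep, m)
  make_segments(data, dendrogram$chrom, starts, ends)
}

#' BIC of a segmentation
#'
#' `-2 * sum(logL_S) + k * n * log(N_obs)` where the sum runs over segments,
#' `k` is the segment count, `n` the sample count, and `N_obs` the number of
#' site-sample cells with coverage on the segmented chromosome(s)
#' (multi-chromosome input scores each chromosome and sums). Parameters are
#' counted as one pooled rate per segment per sample.
#'
#' @param data A [meth_set()].
#' @param segments A segments tibble partitioning the sites of each
#'   chromosome it touches.
#' @return A scalar; smaller is better.
#' @export
bic_score <- function(data, segments) {
  stopifnot(inherits(data, "meth_set"), is.data.frame(segments))
  n <- n_samples(data)
  total <- 0
  for (ch in unique(segments$chrom)) {
    seg <- dplyr::filter(segments, .data$chrom == ch) |>
      dplyr::arrange(.data$first_site)
    idx <- chrom_sites(data, ch)
    covered <- unlist(purrr::map2(seg$first_site, seg$last_site, seq))
    if (!identical(as.integer(covered), as.integer(idx))) {
      abort(paste0("segments do not partition the sites of ", ch))
    }
    ll <- sum(purrr::map2_dbl(
      seg$first_site, seg$last_site,
      function(a, b) segment_log_likelihood(data, a:b)
    ))
    n_obs <- sum(data$meth[idx, , drop = FALSE] +
                   data$unmeth[idx, , drop = FALSE] > 0)
    total <- total + (-2 * ll + nrow(seg) * n * log(max(n_obs, 1)))
  }
  total
}

#' BIC path along the merge sequence and the selected cut
#'
#' Evaluates the BIC at every cut `k = 1..leaf_count` along the merge path
#' (the log-likelihood drops by exactly the merge's nLLR at each step, so
#' the whole path costs one cumulative sum) and returns the minimizing `k`,
#' ties broken toward fewer segments.
#'
#' @inheritParams cut_dendrogram
#' @return A list with `k` (selected), `bic` (value at `k`) and `path`
#'   (tibble `k`, `loglik`, `bic`).
#' @export
select_k_bic <- function(dendrogram, data) {
  stopifnot(inherits(dendrogram, "meth_dendrogram"))
  m <- dendrogram$leaf_count
  n <- n_samples(data)
  # loglik at k = m, m-1, ..., 1
  ll_path <- c(dendrogram$leaf_ll_sum,
               dendrogram$leaf_ll_sum - cumsum(dendrogram$merges$nllr))
  ks <- m:1
  bic <- -2 * ll_path + ks * n * log(max(dendrogram$n_obs, 1))
  path <- tibble(k = ks, loglik = ll_path, bic = bic) |>
    dplyr::arrange(.data$k)
  k_sel <- path$k[which.min(path$bic)]  # first min => smallest k on ties
  list(k = k_sel, bic = min(path$bic), path = path)
}

#' Segment a methylation count set
#'
#' Runs the full segmentation: each chromosome is clustered independently
#' with [build_dendrogram()], the cut is chosen by BIC (default) or fixed at
#' `k` segments per chromosome, and the per-chromosome segment tables are
#' concatenated in genomic order. The algorithm is deterministic.
#'
#' @param data A [meth_set()].
#' @param resolution `"bic"` (default) or `"k"` for a fixed segment count.
#' @param k Segments per chromosome when `resolution = "k"`; chromosomes
#'   with fewer sites than `k` get one segment per site.
#' @param distance_scale Scale (bp) of the genomic distance penalty.
#' @param keep_dendrograms Keep the merge trees in the result (allows
#'   re-cutting at other resolutions without recomputation).
#' @return A `meth_segmentation`: segment tibble plus per-chromosome segment
#'   counts and BIC bookkeeping. Use [tidy()] for the segment table,
#'   [glance()] for a one-row summary, [test_coherence()] to fill the
#'   coherence columns.
#' @examples
#' sim <- simulate_methylation(n_sites = 200, n_segments = 3, seed = 1)
#' seg <- segment_methylation(sim$data)
#' tidy(seg)
#' @export
segment_methylation <- function(data, resolution = c("bic", "k"), k = NULL,
                                distance_scale = 100,
                                keep_dendrograms = TRUE) {
  stopifnot(inherits(data, "meth_set"))
  resolution <- match.arg(resolution)
  if (resolution == "k" && (is.null(k) || k < 1)) {
    abort("resolution = \"k\" requires a positive k")
  }
  chroms <- chromosomes(data)
  dends <- list()
  seg_list <- list()
  k_per_chrom <- integer(0)
  bic_per_chrom <- numeric(0)
  for (ch in chroms) {
    dend <- build_dendrogram(data, ch, distance_scale)
    if (resolution == "bic") {
      sel <- select_k_bic(dend, data)
      k_ch <- sel$k
      bic_ch <- sel$bic
    } else {
      k_ch <- min(as.integer(k), dend$leaf_count)
      bic_ch <- select_k_bic(dend, data)$path |>
        dplyr::filter(.data$k == k_ch) |>
        dplyr::pull(.data$bic)
    }
    seg_list[[ch]] <- cut_dendrogram(dend, k_ch, data)
    k_per_chrom[ch] <- k_ch
    bic_per_chrom[ch] <- bic_ch
    if (keep_dendrograms) dends[[ch]] <- dend
  }
  segments <- dplyr::bind_rows(seg_list)
  segments$segment_id <- sprintf("seg_%05d", seq_len(nrow(segments)))
  segments <- dplyr::relocate(segments, "segment_id")
  structure(
    list(
      segments = segments,
      k_per_chrom = k_per_chrom,
      bic_per_chrom = bic_per_chrom,
      bic = sum(bic_per_chrom),
      resolution = resolution,
      distance_scale = distance_scale,
      samples = data$samples,
      n_sites = n_sites(data),
      dendrograms = if (keep_dendrograms) dends else NULL
    ),
    class = "meth_segmentation"
  )
}

#' @export
print.meth_segmentation <- function(x, ...) {
  cat(sprintf(
    "<meth_segmentation> %d segments over %d CpG sites (%d chromosome(s))\n",
    nrow(x$segments), x$n_sites, length(x$k_per_chrom)
  ))
  cat(sprintf("  resolution: %s; total BIC %.2f\n", x$resolution, x$bic))
  if (!all(is.na(x$segments$coherent))) {
    cat(sprintf("  coherent segments: %d of %d\n",
                sum(x$segments$coherent, na.rm = TRUE), nrow(x$segments)))
  }
  invisible(x)
}

#' Predicted breakpoints of a segmentation
#'
#' Breakpoints are the inter-CpG boundaries separating adjacent segments,
#' indexed by the within-chromosome position of the CpG site on their left.
#'
#' @param x A `meth_segmentation` or a segments tibble.
#' @return Tibble with `chrom` and `boundary`.
#' @export
segmentation_breakpoints <- function(x) {
  segments <- if (inherits(x, "meth_segmentation")) x$segments else x
  segments |>
    dplyr::arrange(.data$chrom, .data$first_site) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(boundary = .data$last_site - min(.data$first_site) + 1L) |>
    dplyr::filter(dplyr::row_number() < dplyr::n()) |>
    dplyr::ungroup() |>
    dplyr::select("chrom", "boundary") |>
    dplyr::arrange(.data$chrom, .data$boundary)
}

#' Segment-by-sample pooled methylation rates
#'
#' One row per segment, one column per sample, cells the pooled per-sample
#' MLE rate over the segment's CpG sites (`NA` where the sample has no
#' coverage in the segment).
#'
#' @param segmentation A `meth_segmentation` (or segments tibble).
#' @param data The underlying [meth_set()].
#' @return A tibble with `segment_id` and one numeric column per sample.
#' @export
segment_rates <- function(segmentation, data) {
  segments <- if (inherits(segmentation, "meth_segmentation")) {
    segmentation$segments
  } else {
    segmentation
  }
  rates <- purrr::map2(
    segments$first_site, segments$last_site,
    function(a, b) pooled_rate_mle(data, a:b)
  )
  mat <- do.call(rbind, rates)
  out <- as_tibble(as.data.frame(mat))
  names(out) <- data$samples
  dplyr::bind_cols(
    tibble(segment_id = segments$segment_id %||% sprintf(
      "seg_%05d", seq_len(nrow(segments))
    )),
    out
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
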