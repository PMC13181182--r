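#' Likelihood-ratio test of within-segment coherence
#'
#' Tests whether all CpG sites of a segment share a common methylation level
#' (per sample; the pattern across samples is unconstrained). The common
#' model M0 pools all sites per sample; the separate model M1 gives every
#' site its own per-sample rate. The statistic `2 (logL_M1 - logL_M0)` is
#' referred to the upper tail of a chi-squared distribution with `r - 1`
#' degrees of freedom (`r` = number of CpGs; `df_mode = "per_sample"` uses
#' the full nesting count `n_eff * (r - 1)` with `n_eff` the samples having
#' any coverage in the segment). Segments with `p > alpha` are flagged
#' coherently methylated.
#'
#' @param data A [meth_set()].
#' @param sites Integer vector of site indices forming the segment
#'   (contiguous for genomic segments, but any set is accepted).
#' @param alpha Significance level for the coherence flag (default 0.05).
#' @param df_mode `"paper"` (default, `df = r - 1`) or `"per_sample"`
#'   (`df = n_eff * (r - 1)`).
#' @return A one-row tibble: `lrt_statistic`, `df`, `p_value`, `coherent`.
#' @examples
#' ms <- meth_set(tibble::tibble(
#'   chrom = "chr1", pos = c(10, 20), sample = "s1",
#'   meth = c(5, 0), unmeth = c(0, 5)
#' ))
#' coherence_test(ms, 1:2)  # strongly non-coherent
#' @export
coherence_test <- function(data, sites, alpha = 0.05,
                           df_mode = c("paper", "per_sample")) {
  stopifnot(inherits(data, "meth_set"))
  df_mode <- match.arg(df_mode)
  check_sites(data, sites, "segment sites")
  r <- length(sites)
  meth <- data$meth[sites, , drop = FALSE]
  unmeth <- data$unmeth[sites, , drop = FALSE]
  n_eff <- sum(colSums(meth + unmeth) > 0)
  df <- if (df_mode == "paper") r - 1L else n_eff * (r - 1L)
  if (df == 0L) {
    return(tibble(lrt_statistic = 0, df = 0L, p_value = 1, coherent = TRUE))
  }
  ll_m0 <- ll_from_sums(colSums(meth), colSums(unmeth))
  # M1: each site its own rate; per-site profile likelihoods add up
  ll_m1 <- sum(xlogx(meth)) + sum(xlogx(unmeth)) - sum(xlogx(meth + unmeth))
  stat <- max(0, 2 * (ll_m1 - ll_m0))
  p <- pchisq(stat, df = df, lower.tail = FALSE)
  tibble(lrt_statistic = stat, df = as.integer(df), p_value = p,
         coherent = p > alpha)
}

#' Flag coherently methylated segments of a segmentation
#'
#' Runs [coherence_test()] on every segment and fills the `coherent` and
#' `coherence_pvalue` columns of the segment table. No multiple-testing
#' correction is applied to the flag (the raw `p > alpha` rule).
#'
#' @param segmentation A `meth_segmentation` from [segment_methylation()].
#' @param data The underlying [meth_set()].
#' @inheritParams coherence_test
#' @return The segmentation with coherence columns filled.
#' @export
test_coherence <- function(segmentation, data, alpha = 0.05,
                           df_mode = c("paper", "per_sample")) {
  stopifnot(inherits(segmentation, "meth_segmentation"))
  df_mode <- match.arg(df_mode)
  res <- purrr::map2(
    segmentation$segments$first_site, segmentation$segments$last_site,
    function(a, b) coherence_test(data, a:b, alpha, df_mode)
  ) |> dplyr::bind_rows()
  segmentation$segments$coherent <- res$coherent
  segmentation$segments$coherence_pvalue <- res$p_value
  segmentation$coherence_alpha <- alpha
  segmentation$coherence_df_mode <- df_mode
  segmentation
}
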