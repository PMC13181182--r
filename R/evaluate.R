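#' Compare predicted against true breakpoints
#'
#' Breakpoints are inter-CpG boundaries, indexed by the within-chromosome
#' position of the site on their left. Predicted breakpoints are matched
#' one-to-one to truth (greedily, nearest first) within `tolerance_bp`
#' measured between the positions of the boundary sites; the default
#' tolerance 0 requires exact boundary identity. Unmatched truth
#' breakpoints are *lost*, unmatched predictions *gained*; boundaries in
#' neither set are the candidate negatives (the universe is every inter-CpG
#' boundary within the chromosome).
#'
#' @param truth_bps Sorted integer vector of true boundary indices.
#' @param predicted_bps Sorted integer vector of predicted boundary indices.
#' @param site_positions Genomic positions of the chromosome's CpG sites
#'   (defines the boundary universe; needed for `tolerance_bp > 0`).
#' @param tolerance_bp Matching tolerance in bp (default 0 = exact).
#' @return A one-row `breakpoint_comparison` tibble: `preserved`, `lost`,
#'   `gained`, `candidate_negatives`.
#' @examples
#' compare_breakpoints(5, c(5, 9), site_positions = seq(1, 1100, by = 100))
#' @export
compare_breakpoints <- function(truth_bps, predicted_bps, site_positions,
                                tolerance_bp = 0) {
  if (is.unsorted(truth_bps, strictly = TRUE) ||
        is.unsorted(predicted_bps, strictly = TRUE)) {
    abort("breakpoints must be strictly sorted")
  }
  n_boundaries <- length(site_positions) - 1L
  if (length(c(truth_bps, predicted_bps)) > 0 &&
        (any(c(truth_bps, predicted_bps) < 1) ||
           any(c(truth_bps, predicted_bps) > n_boundaries))) {
    abort("breakpoint indices outside the inter-CpG boundary universe")
  }
  if (tolerance_bp == 0) {
    preserved <- length(intersect(truth_bps, predicted_bps))
  } else {
    # greedy one-to-one: smallest site-position distances matched first
    pairs <- tidyr::expand_grid(t = truth_bps, p = predicted_bps) |>
      dplyr::mutate(dist = abs(site_positions[.data$t] -
                                 site_positions[.data$p])) |>
      dplyr::filter(.data$dist <= tolerance_bp) |>
      dplyr::arrange(.data$dist, .data$t, .data$p)
    used_t <- used_p <- integer(0)
    preserved <- 0L
    for (i in seq_len(nrow(pairs))) {
      if (!(pairs$t[i] %in% used_t) && !(pairs$p[i] %in% used_p)) {
        used_t <- c(used_t, pairs$t[i])
        used_p <- c(used_p, pairs$p[i])
        preserved <- preserved + 1L
      }
    }
  }
  lost <- length(truth_bps) - preserved
  gained <- length(predicted_bps) - preserved
  negatives <- n_boundaries - (preserved + lost + gained)
  out <- tibble(preserved = preserved, lost = lost, gained = gained,
                candidate_negatives = negatives)
  class(out) <- c("breakpoint_comparison", class(out))
  out
}

#' Breakpoint recovery metrics
#'
#' Sensitivity `= preserved / (preserved + lost)`, precision
#' `= preserved / (preserved + gained)`, specificity
#' `= negatives / (negatives + gained)` over the inter-CpG boundary
#' universe, and `F1 = 2 P S / (P + S)`. Denominator-zero cases are `NA`;
#' `F1` is 0 when both precision and sensitivity are 0.
#'
#' @param cmp A `breakpoint_comparison` from [compare_breakpoints()].
#' @return A one-row tibble: `sensitivity`, `specificity`, `precision`,
#'   `f1`.
#' @export
breakpoint_metrics <- function(cmp) {
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- rate(cmp$preserved, cmp$preserved + cmp$lost)
  prec <- rate(cmp$preserved, cmp$preserved + cmp$gained)
  spec <- rate(cmp$candidate_negatives,
               cmp$candidate_negatives + cmp$gained)
  f1 <- if (is.na(sens) || is.na(prec)) {
    NA_real_
  } else if (sens + prec == 0) {
    0
  } else {
    2 * prec * sens / (prec + sens)
  }
  tibble(sensitivity = sens, specificity = spec, precision = prec, f1 = f1)
}

#' Percentile bootstrap confidence interval of a mean
#'
#' Resamples the per-replicate values with replacement and takes
#' percentile bounds of the resampled means.
#'
#' @param values Numeric vector, one value per replicate dataset.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional integer seed.
#' @return Named numeric `c(low, high)`.
#' @export
bootstrap_ci <- function(values, n_boot = 1000, level = 0.95, seed = NULL) {
  values <- values[!is.na(values)]
  if (length(values) == 0) abort("at least one value is required")
  run <- function() {
    means <- purrr::map_dbl(seq_len(n_boot), function(i) {
      mean(sample(values, length(values), replace = TRUE))
    })
    a <- (1 - level) / 2
    q <- quantile(means, c(a, 1 - a), names = FALSE, type = 7)
    c(low = q[1], high = q[2])
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Run the noise-robustness experiment
#'
#' Segments every noisy replicate, compares its breakpoints to the ground
#' truth, and summarizes recovery metrics per noise amplitude with
#' percentile-bootstrap confidence intervals. Also reports the relative
#' proportions of preserved, lost and gained breakpoints per amplitude.
#'
#' @param collection A `noise_collection` from [noise_collection()], or the
#'   baseline [meth_set()] (then `truth`, `eta_grid`, `n_replicates` and
#'   `master_seed` are used to generate replicates on the fly).
#' @param truth A `meth_truth` (ignored when `collection` is a
#'   `noise_collection`).
#' @param eta_grid,n_replicates,master_seed Passed to [noise_collection()]
#'   when replicates are generated here.
#' @param tolerance_bp Breakpoint matching tolerance.
#' @param n_boot Bootstrap resamples for the 95% CIs.
#' @param distance_scale Passed to [segment_methylation()].
#' @return A `noise_robustness` object: `per_replicate` tibble (eta, k,
#'   counts and metrics) and `summary` tibble (per eta: mean metrics with
#'   CI bounds, breakpoint category proportions).
#' @export
evaluate_noise_robustness <- function(collection, truth = NULL,
                                      eta_grid = seq(5, 120, by = 5),
                                      n_replicates = 20, master_seed = 1,
                                      tolerance_bp = 0, n_boot = 1000,
                                      distance_scale = 100) {
  if (!inherits(collection, "noise_collection")) {
    stopifnot(inherits(collection, "meth_set"), inherits(truth, "meth_truth"))
    collection <- noise_collection(collection, truth, eta_grid,
                                   n_replicates, master_seed)
  }
  truth <- collection$truth
  truth_b <- truth$breakpoints
  per_rep <- purrr::pmap(
    collection$seeds,
    function(eta, k, seed) {
      ms <- collection$replicates[[sprintf("eta%g_k%d", eta, k)]]
      seg <- segment_methylation(ms, distance_scale = distance_scale,
                                 keep_dendrograms = FALSE)
      pred <- segmentation_breakpoints(seg)$boundary
      cmp <- compare_breakpoints(truth_b, pred, ms$pos, tolerance_bp)
      dplyr::bind_cols(tibble(eta = eta, k = k), cmp,
                       breakpoint_metrics(cmp))
    }
  ) |> dplyr::bind_rows()

  boot_seed <- derive_seed(collection$master_seed, 0)
  summarise_metric <- function(d, col) {
    ci <- bootstrap_ci(d[[col]], n_boot = n_boot, seed = boot_seed)
    tibble(
      "{col}" := mean(d[[col]], na.rm = TRUE),
      "{col}_low" := ci[["low"]], "{col}_high" := ci[["high"]]
    )
  }
  summary <- per_rep |>
    dplyr::group_split(.data$eta) |>
    purrr::map(function(d) {
      tot <- sum(d$preserved + d$lost + d$gained)
      dplyr::bind_cols(
        tibble(
          eta = d$eta[1], n_replicates = nrow(d),
          prop_preserved = sum(d$preserved) / tot,
          prop_lost = sum(d$lost) / tot,
          prop_gained = sum(d$gained) / tot
        ),
        summarise_metric(d, "sensitivity"),
        summarise_metric(d, "specificity"),
        summarise_metric(d, "precision"),
        summarise_metric(d, "f1")
      )
    }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$eta)

  structure(list(per_replicate = per_rep, summary = summary,
                 tolerance_bp = tolerance_bp),
            class = "noise_robustness")
}

#' @export
print.noise_robustness <- function(x, ...) {
  cat(sprintf("<noise_robustness> %d replicates over %d noise amplitudes\n",
              nrow(x$per_replicate), nrow(x$summary)))
  print(dplyr::select(x$summary, "eta", "sensitivity", "precision", "f1",
                      "prop_gained"))
  invisible(x)
}

#' Shannon entropy of a beta-value distribution
#'
#' Base-2 entropy of the histogram of beta-values over `n_bins` equal-width
#' bins on \[0, 1\]; empty bins contribute zero. Lower entropy means the
#' values concentrate in fewer methylation states.
#'
#' @param beta_values Numeric vector of values in \[0, 1\] (`NA` dropped).
#' @param n_bins Number of histogram bins (default 20).
#' @return A scalar in `[0, log2(n_bins)]`.
#' @export
beta_entropy <- function(beta_values, n_bins = 20) {
  x <- beta_values[!is.na(beta_values)]
  if (length(x) == 0) abort("at least one finite value is required")
  if (any(x < 0 | x > 1)) abort("beta values must lie in [0, 1]")
  bin <- pmin(findInterval(x, seq(0, 1, length.out = n_bins + 1),
                           rightmost.closed = TRUE), n_bins)
  p <- tabulate(bin, nbins = n_bins) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}
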