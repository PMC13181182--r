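#' Simulate a piecewise-constant WGBS baseline dataset
#'
#' Generates a ground-truth dataset for robustness experiments: the
#' chromosome is split into `n_segments` blocks of CpG sites; each block
#' gets one methylation rate per sample, drawn from a bimodal
#' Beta(0.3, 0.3) (mimicking the U-shaped beta-value distribution of real
#' methylomes) and redrawn until neighbouring blocks differ by at least
#' `min_rate_gap` in mean absolute per-sample rate; inter-CpG gaps are
#' geometric with mean `gap_mean` bp (minimum 2 bp); per-cell read depth is
#' Poisson(`depth_mean`) and methylated counts are Binomial(depth, rate).
#'
#' Defaults give the desk-scale profile used throughout the package's
#' evaluation harness: 2,000 CpGs, 10 segments, 5 samples, depth 30.
#'
#' @param n_sites Number of CpG sites.
#' @param n_samples Number of samples.
#' @param n_segments Number of true segments (`<= n_sites`).
#' @param depth_mean Mean read depth per site-sample cell (Poisson); 0 gives
#'   an all-zero-coverage dataset (a valid edge case).
#' @param min_rate_gap Minimum mean absolute per-sample rate difference
#'   between neighbouring segments (default 0.3); set 0 to disable.
#' @param min_segment_sites Minimum CpGs per true segment (default 20,
#'   capped at `floor(n_sites / n_segments)`).
#' @param rate_sampler Function `(n) -> n` rates in \[0, 1\] for one
#'   segment's samples; default `rbeta(n, 0.3, 0.3)`.
#' @param gap_mean Mean inter-CpG gap in bp (geometric, minimum 2).
#' @param chrom Chromosome label for the simulated sites.
#' @param sample_ids Optional sample names.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return A list with `data` (a [meth_set()]) and `truth` (a `meth_truth`:
#'   `breakpoints` = site indices after which a new segment starts,
#'   `rates` = segments x samples matrix, `site_segment` = per-site segment
#'   index, plus positions and chromosome label).
#' @examples
#' sim <- simulate_methylation(n_sites = 100, n_segments = 2, seed = 42)
#' sim$truth$breakpoints
#' @export
simulate_methylation <- function(n_sites = 2000, n_samples = 5,
                                 n_segments = 10, depth_mean = 30,
                                 min_rate_gap = 0.3,
                                 min_segment_sites = 20,
                                 rate_sampler = function(n) rbeta(n, 0.3, 0.3),
                                 gap_mean = 100, chrom = "chr1",
                                 sample_ids = NULL, seed = NULL) {
  if (n_sites < 1 || n_samples < 1) abort("need >= 1 site and sample")
  if (n_segments < 1 || n_segments > n_sites) {
    abort("n_segments must be in [1, n_sites]")
  }
  if (depth_mean < 0) abort("depth_mean must be >= 0")
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("s%02d", seq_len(n_samples))
  }
  run <- function() {
    min_len <- max(1L, min(min_segment_sites, n_sites %/% n_segments))
    repeat {
      bps <- sort(sample(n_sites - 1L, n_segments - 1L))
      lens <- diff(c(0L, bps, n_sites))
      if (all(lens >= min_len)) break
    }
    rates <- matrix(NA_real_, n_segments, n_samples)
    for (s in seq_len(n_segments)) {
      repeat {
        r <- rate_sampler(n_samples)
        if (s == 1 || min_rate_gap <= 0 ||
              mean(abs(r - rates[s - 1, ])) >= min_rate_gap) {
          rates[s, ] <- r
          break
        }
      }
    }
    gaps <- 2L + rgeom(n_sites - 1L, prob = 1 / (gap_mean - 1))
    pos <- cumsum(c(1L, gaps))
    site_segment <- rep(seq_len(n_segments), times = diff(c(0L, bps, n_sites)))
    p_true <- rates[site_segment, , drop = FALSE]
    depth <- matrix(rpois(n_sites * n_samples, depth_mean),
                    n_sites, n_samples)
    meth <- matrix(rbinom(n_sites * n_samples, as.vector(depth),
                          as.vector(p_true)),
                   n_sites, n_samples)
    data <- new_meth_set(meth, depth - meth, rep(chrom, n_sites), pos,
                         sample_ids)
    truth <- structure(
      list(chrom = chrom, breakpoints = as.integer(bps), rates = rates,
           site_segment = site_segment, positions = pos),
      class = "meth_truth"
    )
    list(data = data, truth = truth)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.meth_truth <- function(x, ...) {
  cat(sprintf("<meth_truth> %s: %d segments over %d sites\n",
              x$chrom, nrow(x$rates), length(x$site_segment)))
  invisible(x)
}

#' True breakpoints of a simulated dataset
#'
#' @param truth A `meth_truth` from [simulate_methylation()].
#' @return Tibble with `chrom` and `boundary` (within-chromosome index of
#'   the CpG left of each true segment boundary).
#' @export
true_breakpoints <- function(truth) {
  stopifnot(inherits(truth, "meth_truth"))
  tibble(chrom = truth$chrom, boundary = truth$breakpoints)
}

#' Inject graded noise into a baseline dataset
#'
#' Implements a mixture noise model parameterized by an amplitude
#' `eta_percent`: with `w = eta_percent / 100`, every site-sample cell's
#' generative rate becomes `clip((1 - w) p_true + w e, 0, 1)` with
#' `e ~ Uniform(0, 1)` drawn independently per cell, and methylated counts
#' are re-drawn as Binomial(original depth, perturbed rate). Depths are
#' never changed. At `eta = 0` this is a fresh draw at the true rates; at
#' `eta >= 100` the signal weight is `<= 0`, i.e. the methylation states are
#' pure noise (with overshoot clipped for `eta > 100`).
#'
#' @param baseline The baseline [meth_set()] (supplies the depth matrix).
#' @param truth The matching `meth_truth` (supplies the true rates).
#' @param eta_percent Noise amplitude in percent, `>= 0`.
#' @param seed Optional integer seed.
#' @return A [meth_set()] with identical sites, samples and depths.
#' @export
inject_noise <- function(baseline, truth, eta_percent, seed = NULL) {
  stopifnot(inherits(baseline, "meth_set"), inherits(truth, "meth_truth"))
  if (eta_percent < 0) abort("eta_percent must be >= 0")
  depth <- baseline$meth + baseline$unmeth
  p_true <- truth$rates[truth$site_segment, , drop = FALSE]
  w <- eta_percent / 100
  run <- function() {
    eps <- matrix(runif(length(depth)), nrow(depth), ncol(depth))
    p <- pmin(pmax((1 - w) * p_true + w * eps, 0), 1)
    meth <- matrix(rbinom(length(depth), as.vector(depth), as.vector(p)),
                   nrow(depth), ncol(depth))
    new_meth_set(meth, depth - meth, baseline$chrom, baseline$pos,
                 baseline$samples)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# deterministic per-replicate seed: distinct for up to ~260k (eta, k) pairs
derive_seed <- function(master_seed, replicate_index) {
  as.integer((as.numeric(master_seed) + 8191 * replicate_index) %% 2147483647)
}

#' Build a collection of noisy replicate datasets
#'
#' For every noise amplitude in `eta_grid` and every replicate
#' `k = 1..n_replicates`, draws an independent noisy dataset from the
#' baseline via [inject_noise()], with per-replicate seeds derived
#' deterministically from `master_seed` (identical master seeds give
#' byte-identical collections; distinct (eta, k) pairs get distinct seeds).
#'
#' @inheritParams inject_noise
#' @param eta_grid Noise amplitudes in percent (default 5, 10, ..., 120).
#' @param n_replicates Replicates per amplitude (desk-scale default 20).
#' @param master_seed Integer master seed.
#' @return A `noise_collection`: baseline, truth, `replicates` (named list
#'   `eta<eta>_k<k>`) and a `seeds` tibble (`eta`, `k`, `seed`).
#' @export
noise_collection <- function(baseline, truth, eta_grid = seq(5, 120, by = 5),
                             n_replicates = 20, master_seed = 1) {
  if (length(eta_grid) == 0) abort("eta_grid must be non-empty")
  grid <- tidyr::expand_grid(eta = eta_grid, k = seq_len(n_replicates))
  grid$seed <- derive_seed(master_seed, seq_len(nrow(grid)))
  reps <- purrr::pmap(grid, function(eta, k, seed) {
    inject_noise(baseline, truth, eta, seed = seed)
  })
  names(reps) <- sprintf("eta%g_k%d", grid$eta, grid$k)
  structure(
    list(baseline = baseline, truth = truth, replicates = reps,
         seeds = grid, master_seed = master_seed),
    class = "noise_collection"
  )
}

#' @export
print.noise_collection <- function(x, ...) {
  cat(sprintf(
    "<noise_collection> %d replicates (%d amplitudes x %d each)\n",
    length(x$replicates), length(unique(x$seeds$eta)),
    max(x$seeds$k)
  ))
  invisible(x)
}

#' Write a simulated dataset (and truth) to disk
#'
#' Baseline counts go to `<dir>/baseline/` as per-sample Bismark coverage
#' files; the truth table to `<dir>/truth.tsv` (one row per true segment:
#' chromosome, site-index span, position span, then one rate column per
#' sample).
#'
#' @param sim A list with `data` and `truth` as returned by
#'   [simulate_methylation()].
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_bismark(sim$data, file.path(dir, "baseline"))
  tr <- sim$truth
  n_seg <- nrow(tr$rates)
  seg_start <- c(1L, tr$breakpoints + 1L)
  seg_end <- c(tr$breakpoints, length(tr$site_segment))
  rates <- as.data.frame(tr$rates)
  names(rates) <- paste0("rate_", sim$data$samples)
  truth_tab <- dplyr::bind_cols(
    tibble(
      chrom = tr$chrom, segment = seq_len(n_seg),
      first_site = seg_start, last_site = seg_end,
      start_pos = tr$positions[seg_start], end_pos = tr$positions[seg_end]
    ),
    as_tibble(rates)
  )
  readr::write_tsv(truth_tab, file.path(dir, "truth.tsv"), progress = FALSE)
  invisible(dir)
}

#' Read a truth table written by [write_simulation()]
#'
#' @param path Path to `truth.tsv`.
#' @return A `meth_truth`.
#' @export
read_truth <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  rate_cols <- grep("^rate_", names(d), value = TRUE)
  structure(
    list(
      chrom = d$chrom[1],
      breakpoints = as.integer(head(d$last_site, -1)),
      rates = as.matrix(d[rate_cols]),
      site_segment = rep(as.integer(d$segment),
                         times = as.integer(d$last_site - d$first_site + 1)),
      positions = NULL
    ),
    class = "meth_truth"
  )
}
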