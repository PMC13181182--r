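test_that("degenerate dendrograms: one site, two sites", {
  ms1 <- meth_set(tibble::tibble(
    chrom = "chr1", pos = 10, sample = "s1", meth = 3, unmeth = 7
  ))
  d1 <- build_dendrogram(ms1, "chr1")
  expect_equal(nrow(d1$merges), 0)
  expect_error(build_dendrogram(ms1, "chrX"), "no sites")

  ms2 <- meth_set(tibble::tibble(
    chrom = "chr1", pos = c(10, 200), sample = "s1",
    meth = c(3, 9), unmeth = c(7, 1)
  ))
  d2 <- build_dendrogram(ms2, "chr1")
  expect_equal(nrow(d2$merges), 1)
  expect_equal(d2$merges$cost, dissimilarity(ms2, 1, 2), tolerance = 1e-12)
})

test_that("incremental agglomeration equals the quadratic oracle", {
  withr::with_seed(21, {
    for (rep in 1:30) {
      ms <- random_meth_set(m = sample(3:25, 1), n = sample(1:3, 1))
      dend <- build_dendrogram(ms, "chr1")
      orc <- oracle_dendrogram(ms, "chr1")
      expect_identical(dend$merges$boundary, orc$boundary)
      expect_equal(dend$merges$cost, orc$cost, tolerance = 1e-9)
    }
  })
})

test_that("cuts are nested partitions at every resolution", {
  withr::with_seed(22, {
    ms <- random_meth_set(m = 30, n = 2)
  })
  dend <- build_dendrogram(ms, "chr1")
  m <- dend$leaf_count
  expect_error(cut_dendrogram(dend, 0, ms), "k must be")
  expect_error(cut_dendrogram(dend, m + 1, ms), "k must be")

  seg1 <- cut_dendrogram(dend, 1, ms)
  expect_equal(nrow(seg1), 1)
  expect_equal(seg1$n_cpgs, m)
  expect_equal(seg1$start, min(ms$pos))
  expect_equal(seg1$end, max(ms$pos))

  segm <- cut_dendrogram(dend, m, ms)
  expect_equal(nrow(segm), m)
  expect_true(all(segm$n_cpgs == 1))

  prev_bounds <- NULL
  for (k in m:1) {
    seg <- cut_dendrogram(dend, k, ms)
    # partition: contiguous, disjoint, covering, sorted
    expect_equal(nrow(seg), k)
    expect_identical(
      unlist(Map(seq, seg$first_site, seg$last_site)), 1:m
    )
    bounds <- head(seg$last_site, -1)
    if (!is.null(prev_bounds)) {
      # cut at k is obtained from the cut at k+1 by exactly one merge
      expect_true(all(bounds %in% prev_bounds))
      expect_equal(length(setdiff(prev_bounds, bounds)), 1)
    }
    prev_bounds <- bounds
  }
})

test_that("bic_score matches independent recomputation on small instances", {
  withr::with_seed(23, {
    for (rep in 1:20) {
      ms <- random_meth_set(m = sample(4:10, 1), n = 2)
      dend <- build_dendrogram(ms, "chr1")
      k <- sample(n_sites(ms), 1)
      seg <- cut_dendrogram(dend, k, ms)
      ll <- sum(vapply(seq_len(k), function(i) {
        oracle_loglik(ms, seg$first_site[i]:seg$last_site[i])
      }, numeric(1)))
      n_obs <- sum(ms$meth + ms$unmeth > 0)
      expect_equal(bic_score(ms, seg),
                   -2 * ll + k * n_samples(ms) * log(max(n_obs, 1)),
                   tolerance = 1e-9)
    }
  })
  # worked single-cell anchor: one segment, c=3, t=7, N_obs = 1
  ms1 <- meth_set(tibble::tibble(
    chrom = "chr1", pos = 10, sample = "s1", meth = 3, unmeth = 7
  ))
  seg <- cut_dendrogram(build_dendrogram(ms1, "chr1"), 1, ms1)
  expect_equal(bic_score(ms1, seg), -2 * (3 * log(0.3) + 7 * log(0.7)),
               tolerance = 1e-9)
})

test_that("BIC selection equals exhaustive argmin over cuts", {
  withr::with_seed(24, {
    for (rep in 1:10) {
      ms <- random_meth_set(m = 12, n = 2)
      dend <- build_dendrogram(ms, "chr1")
      sel <- select_k_bic(dend, ms)
      exhaustive <- vapply(1:12, function(k) {
        bic_score(ms, cut_dendrogram(dend, k, ms))
      }, numeric(1))
      expect_equal(sel$path$bic[order(sel$path$k)], exhaustive,
                   tolerance = 1e-9)
      expect_equal(sel$k, which.min(exhaustive))
    }
  })
})

test_that("log-likelihood is non-increasing as segments merge", {
  withr::with_seed(25, {
    ms <- random_meth_set(m = 40, n = 2)
  })
  dend <- build_dendrogram(ms, "chr1")
  path <- select_k_bic(dend, ms)$path |> dplyr::arrange(dplyr::desc(k))
  expect_true(all(diff(path$loglik) <= 1e-9))
  expect_true(all(dend$merges$nllr >= -1e-9))
})

test_that("flat data collapses to one segment, a sharp change is found", {
  withr::with_seed(26, {
    m <- 60; n <- 3
    depth <- matrix(rpois(m * n, 30), m, n)
    meth <- matrix(rbinom(m * n, as.vector(depth), 0.4), m, n)
    flat <- new_meth_set(meth, depth - meth, rep("chr1", m),
                         seq(1, by = 50, length.out = m),
                         sprintf("s%d", 1:n))
    seg_flat <- segment_methylation(flat)
    expect_equal(nrow(seg_flat$segments), 1)

    p <- rep(c(0.1, 0.9), each = 50)
    depth2 <- matrix(rpois(100, 30), 100, 1)
    meth2 <- matrix(rbinom(100, as.vector(depth2), p), 100, 1)
    step <- new_meth_set(meth2, depth2 - meth2, rep("chr1", 100),
                         seq(1, by = 50, length.out = 100), "s1")
    seg_step <- segment_methylation(step)
    expect_true(50 %in% head(seg_step$segments$last_site, -1))
  })
})

test_that("chromosomes are segmented independently and deterministically", {
  withr::with_seed(27, {
    ms <- random_meth_set(m = 40, n = 2, n_chrom = 2)
  })
  seg <- segment_methylation(ms)
  # no segment spans chromosomes; segments partition all sites
  expect_identical(
    unlist(Map(seq, seg$segments$first_site, seg$segments$last_site)),
    seq_len(n_sites(ms))
  )
  for (i in seq_len(nrow(seg$segments))) {
    ch <- ms$chrom[seg$segments$first_site[i]:seg$segments$last_site[i]]
    expect_equal(length(unique(ch)), 1)
  }
  # deterministic rerun
  seg2 <- segment_methylation(ms)
  expect_identical(seg$segments, seg2$segments)
  # permuting sample columns leaves the segmentation unchanged
  perm <- c(2, 1)
  ms_p <- new_meth_set(ms$meth[, perm], ms$unmeth[, perm], ms$chrom, ms$pos,
                       ms$samples[perm])
  seg_p <- segment_methylation(ms_p)
  expect_identical(seg$segments$first_site, seg_p$segments$first_site)
})

test_that("fixed-k resolution returns the requested segment count", {
  withr::with_seed(28, {
    ms <- random_meth_set(m = 30, n = 2)
  })
  seg <- segment_methylation(ms, resolution = "k", k = 7)
  expect_equal(nrow(seg$segments), 7)
  expect_error(segment_methylation(ms, resolution = "k"), "requires")
})

test_that("breakpoints are the inter-segment boundaries in site order", {
  withr::with_seed(29, {
    ms <- random_meth_set(m = 20, n = 1, n_chrom = 2)
  })
  seg <- segment_methylation(ms, resolution = "k", k = 3)
  bp <- segmentation_breakpoints(seg)
  expect_equal(nrow(bp), 2 * 2)  # k-1 boundaries per chromosome
  expect_true(all(bp$boundary >= 1 & bp$boundary <= 10 - 1))
})
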