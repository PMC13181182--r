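test_that("breakpoint comparison counts preserved, lost and gained", {
  pos <- seq(1, 1001, by = 100)  # 11 sites, 10 inter-CpG boundaries

  same <- compare_breakpoints(c(3, 7), c(3, 7), pos)
  expect_equal(unlist(same[1, ]), c(preserved = 2, lost = 0, gained = 0,
                                    candidate_negatives = 8))

  disj <- compare_breakpoints(c(3, 7), c(4, 8), pos)
  expect_equal(disj$preserved, 0)

  mix <- compare_breakpoints(5, c(5, 9), pos)
  expect_equal(unlist(mix[1, ]), c(preserved = 1, lost = 0, gained = 1,
                                   candidate_negatives = 8))
  met <- breakpoint_metrics(mix)
  expect_equal(unlist(met[1, ]), c(sensitivity = 1, specificity = 8 / 9,
                                   precision = 0.5, f1 = 2 / 3))

  expect_error(compare_breakpoints(c(7, 3), 5, pos), "sorted")
  expect_error(compare_breakpoints(11, 5, pos), "universe")
})

test_that("tolerance-based matching is one-to-one and greedy by distance", {
  pos <- c(0, 100, 130, 300, 500)  # boundaries indexed 1..4 at sites 1..4
  # truth boundary after site 2 (pos 100); predictions after sites 1 and 3
  cmp <- compare_breakpoints(2, c(1, 3), pos, tolerance_bp = 50)
  expect_equal(cmp$preserved, 1)  # site 3 (30 bp away) matches, site 1 not
  expect_equal(cmp$gained, 1)
  cmp0 <- compare_breakpoints(2, c(1, 3), pos, tolerance_bp = 0)
  expect_equal(cmp0$preserved, 0)
})

test_that("swapping truth and prediction swaps lost/gained and sens/prec", {
  withr::with_seed(61, {
    pos <- sort(sample.int(1e4, 50))
    for (rep in 1:20) {
      t_bp <- sort(sample(49, 5)); p_bp <- sort(sample(49, 8))
      ab <- compare_breakpoints(t_bp, p_bp, pos)
      ba <- compare_breakpoints(p_bp, t_bp, pos)
      expect_equal(ab$preserved, ba$preserved)
      expect_equal(ab$lost, ba$gained)
      expect_equal(ab$gained, ba$lost)
      m_ab <- breakpoint_metrics(ab); m_ba <- breakpoint_metrics(ba)
      expect_equal(m_ab$sensitivity, m_ba$precision)
      expect_equal(m_ab$precision, m_ba$sensitivity)
    }
  })
  # degenerate denominators are NA, all-preserved is all-ones
  none <- compare_breakpoints(integer(0), integer(0), 1:10)
  expect_true(is.na(breakpoint_metrics(none)$sensitivity))
  full <- compare_breakpoints(c(2, 5), c(2, 5), 1:10)
  expect_equal(unlist(breakpoint_metrics(full)[1, ]),
               c(sensitivity = 1, specificity = 1, precision = 1, f1 = 1))
  zero <- compare_breakpoints(2, 5, 1:10)
  expect_equal(breakpoint_metrics(zero)$f1, 0)
})

test_that("bootstrap CI is degenerate, deterministic and variance-sensitive", {
  ci <- bootstrap_ci(rep(0.8, 10), seed = 1)
  expect_equal(unname(ci), c(0.8, 0.8))
  ci1 <- bootstrap_ci(c(0.5, 0.6, 0.9, 0.4), seed = 7)
  ci2 <- bootstrap_ci(c(0.5, 0.6, 0.9, 0.4), seed = 7)
  expect_identical(ci1, ci2)
  expect_true(ci1[["low"]] <= mean(c(0.5, 0.6, 0.9, 0.4)) &&
                ci1[["high"]] >= mean(c(0.5, 0.6, 0.9, 0.4)))
  withr::with_seed(62, {
    narrow <- rnorm(30, 0.5, 0.01)
    wide <- rnorm(30, 0.5, 0.2)
  })
  w_narrow <- diff(unname(bootstrap_ci(narrow, seed = 3)))
  w_wide <- diff(unname(bootstrap_ci(wide, seed = 3)))
  expect_lt(w_narrow, w_wide)
  expect_error(bootstrap_ci(numeric(0)), "at least one")
})

test_that("Fisher p-values equal exhaustive hypergeometric enumeration", {
  # worked table
  seg <- tibble::tibble(
    segment_id = sprintf("s%d", 1:8), chrom = "chr1",
    start = seq(1, 701, 100), end = seq(50, 750, 100),
    first_site = 1:8, last_site = 1:8, length_bp = 50L, n_cpgs = 1L,
    mean_methylation = 0.5,
    coherent = rep(c(TRUE, FALSE), each = 4), coherence_pvalue = 0.5
  )
  # coherent: 3 overlap, 1 not; non-coherent: 1 overlap, 3 not
  ann <- list(cls = tibble::tibble(
    chrom = "chr1", start = c(0, 100, 200, 400), end = c(50, 150, 250, 450)
  ))
  res <- test_enrichment(seg, ann)
  expect_equal(unlist(res[1, c("n_coh_overlap", "n_coh_no",
                               "n_noncoh_overlap", "n_noncoh_no")]),
               c(n_coh_overlap = 3, n_coh_no = 1,
                 n_noncoh_overlap = 1, n_noncoh_no = 3))
  expect_equal(res$p_value, oracle_fisher_p(3, 1, 1, 3), tolerance = 1e-9)
  expect_equal(res$p_value, 0.485714285714286, tolerance = 1e-6)

  # random tables: implementation (via fisher.test) vs enumeration oracle
  withr::with_seed(63, {
    for (rep in 1:100) {
      n <- sample(20:200, 1)
      a <- sample(0:20, 1); b <- sample(0:20, 1)
      cc <- sample(0:20, 1); d <- max(n - a - b - cc, 1)
      if ((a + b) == 0 || (cc + d) == 0 || (a + cc) == 0 || (b + d) == 0) next
      p_impl <- fisher.test(matrix(c(a, cc, b, d), 2))$p.value
      expect_equal(p_impl, oracle_fisher_p(a, b, cc, d), tolerance = 1e-9)
    }
  })
})

test_that("BH adjustment matches the step-up formula and its invariants", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               rep(0.04, 4))
  withr::with_seed(64, {
    for (rep in 1:50) {
      p <- runif(sample(3:12, 1))
      q <- p.adjust(p, method = "BH")
      expect_equal(q, oracle_bh(p), tolerance = 1e-12)
      expect_true(all(q >= p - 1e-15))
      expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone in rank
    }
  })
})

test_that("enrichment handles empty and all-covering annotation classes", {
  seg <- tibble::tibble(
    segment_id = c("a", "b"), chrom = "chr1",
    start = c(1L, 101L), end = c(50L, 150L),
    length_bp = 50L, n_cpgs = 1L, first_site = 1:2, last_site = 1:2,
    mean_methylation = 0.5, coherent = c(TRUE, FALSE),
    coherence_pvalue = c(0.5, 0.01)
  )
  res <- test_enrichment(seg, list(
    empty = tibble::tibble(chrom = character(), start = integer(),
                           end = integer()),
    everywhere = tibble::tibble(chrom = "chr1", start = 0, end = 1000)
  ))
  expect_true(is.na(res$odds_ratio[res$annotation_class == "empty"]))
  expect_equal(res$p_value, c(1, 1))
  expect_false(any(res$significant))
  expect_true(all(res$q_value >= res$p_value))
  expect_error(
    test_enrichment(dplyr::mutate(seg, coherent = NA), list(x = NULL)),
    "coherence"
  )
})

test_that("beta entropy spans 0 to log2(n_bins)", {
  expect_equal(beta_entropy(rep(0.5, 100)), 0)
  uniform <- rep(seq(0.025, 0.975, length.out = 20), each = 5)
  expect_equal(beta_entropy(uniform), log2(20), tolerance = 1e-12)
  expect_error(beta_entropy(numeric(0)), "at least one")
  expect_error(beta_entropy(c(0.5, 1.2)), "\\[0, 1\\]")
  # boundary values land in the end bins
  expect_equal(beta_entropy(c(0, 1)), 1)
})

test_that("noise robustness harness summarizes per amplitude", {
  sim <- simulate_methylation(n_sites = 300, n_samples = 2, n_segments = 3,
                              seed = 65)
  res <- evaluate_noise_robustness(sim$data, sim$truth,
                                   eta_grid = c(10, 110), n_replicates = 2,
                                   master_seed = 66, n_boot = 200)
  expect_equal(nrow(res$per_replicate), 4)
  expect_equal(res$summary$eta, c(10, 110))
  expect_true(all(res$summary$sensitivity_low <= res$summary$sensitivity))
  expect_true(all(res$summary$sensitivity_high >= res$summary$sensitivity))
  props <- res$summary[c("prop_preserved", "prop_lost", "prop_gained")]
  expect_equal(rowSums(as.matrix(props)), c(1, 1), tolerance = 1e-12)
  # heavy noise over-segments: more gained breakpoints than light noise
  expect_gt(res$summary$prop_gained[2], res$summary$prop_gained[1])
  expect_s3_class(tidy(res), "tbl_df")
  expect_equal(glance(res)$n_replicates, 4)
})
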