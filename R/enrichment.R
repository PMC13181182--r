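#' Annotation enrichment of coherently methylated segments
#'
#' For each annotation class, builds the 2x2 table over all segments
#' (coherent vs non-coherent x overlapping vs non-overlapping the class by
#' at least `min_overlap_bp`) and tests enrichment with a two-sided
#' Fisher's exact test. P-values are Benjamini-Hochberg corrected across
#' classes; classes with `q < alpha` are flagged significant. The reported
#' odds ratio is the sample odds ratio `ad / bc`, with a Haldane 0.5
#' continuity correction when any cell is zero.
#'
#' @param segmentation A `meth_segmentation` with coherence flags filled
#'   (see [test_coherence()]), or a segments tibble with `chrom`, `start`,
#'   `end` (1-based inclusive) and logical `coherent`.
#' @param annotations Named list of interval tibbles (`chrom`, `start`
#'   0-based, `end` exclusive, as in BED), or a named character vector of
#'   BED file paths (read via [read_bed_classes()]).
#' @param min_overlap_bp Minimum shared span to count an overlap
#'   (default 1).
#' @param alpha FDR threshold for the `significant` flag (default 0.05).
#' @return An `enrichment_result` tibble, one row per class:
#'   `annotation_class`, cells `n_coh_overlap`, `n_coh_no`, `n_noncoh_overlap`,
#'   `n_noncoh_no`, `odds_ratio`, `p_value`, `q_value`, `significant`.
#' @export
test_enrichment <- function(segmentation, annotations, min_overlap_bp = 1,
                            alpha = 0.05) {
  seg <- segments_of(segmentation)
  if (nrow(seg) == 0) abort("no segments to test")
  if (anyNA(seg$coherent)) {
    abort("segments lack coherence flags; run test_coherence() first")
  }
  if (is.character(annotations)) annotations <- read_bed_classes(annotations)
  if (is.null(names(annotations)) || any(names(annotations) == "")) {
    abort("annotations must be named by class")
  }
  seg_gr <- GenomicRanges::GRanges(
    seg$chrom, IRanges::IRanges(seg$start, seg$end)
  )
  rows <- purrr::imap(annotations, function(ann, class) {
    if (is.null(ann) || nrow(ann) == 0) {
      return(tibble(
        annotation_class = class, n_coh_overlap = 0L,
        n_coh_no = sum(seg$coherent), n_noncoh_overlap = 0L,
        n_noncoh_no = sum(!seg$coherent),
        odds_ratio = NA_real_, p_value = 1
      ))
    }
    ann_gr <- GenomicRanges::GRanges(
      ann$chrom, IRanges::IRanges(ann$start + 1L, ann$end)
    )
    hit <- GenomicRanges::countOverlaps(
      seg_gr, ann_gr, minoverlap = min_overlap_bp
    ) > 0
    a <- sum(seg$coherent & hit); b <- sum(seg$coherent & !hit)
    cc <- sum(!seg$coherent & hit); d <- sum(!seg$coherent & !hit)
    tab <- matrix(c(a, cc, b, d), 2)
    p <- if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      fisher.test(tab)$p.value
    } else {
      1  # no contrast: a margin is empty
    }
    or <- if (any(tab == 0)) {
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
    } else {
      (a * d) / (b * cc)
    }
    tibble(annotation_class = class, n_coh_overlap = a, n_coh_no = b,
           n_noncoh_overlap = cc, n_noncoh_no = d,
           odds_ratio = or, p_value = p)
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(
      q_value = p.adjust(.data$p_value, method = "BH"),
      significant = .data$q_value < alpha
    )
  class(out) <- c("enrichment_result", class(out))
  out
}
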