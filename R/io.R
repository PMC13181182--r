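#' Read per-sample WGBS count files into a meth_set
#'
#' Reads one count file per sample and outer-joins them on (chromosome,
#' position): a CpG absent from a sample becomes a zero-coverage cell.
#' Two dialects are supported, both six tab-separated columns
#' (chrom, start, end, methylation percentage, methylated count,
#' unmethylated count):
#' * `"bismark_cov"` (default): Bismark coverage files, 1-based start.
#' * `"bedgraph6"`: bedGraph-style, 0-based start (converted internally to
#'   the 1-based position of the CpG cytosine).
#' Gzipped files are read transparently.
#'
#' @param files Character vector of file paths; names are used as sample
#'   ids (otherwise the base file name without extension).
#' @param sample_ids Optional explicit sample ids, same length as `files`.
#' @param format `"bismark_cov"` or `"bedgraph6"`; recycled over files.
#' @param min_coverage Drop sites with fewer total reads than this summed
#'   over all samples (default 0 = keep everything).
#' @param chrom_filter Optional character vector restricting chromosomes.
#' @param collapse_strands Sum records at adjacent positions i, i + 1 within
#'   a sample (per-strand CpG records) into the first position.
#' @return A [meth_set()].
#' @export
read_bismark <- function(files, sample_ids = NULL,
                         format = "bismark_cov", min_coverage = 0,
                         chrom_filter = NULL, collapse_strands = FALSE) {
  if (length(files) == 0) abort("at least one input file is required")
  if (is.null(sample_ids)) {
    sample_ids <- names(files)
    if (is.null(sample_ids)) {
      sample_ids <- sub("\\.(cov|bedgraph|bedGraph|txt|tsv)(\\.gz)?$", "",
                        basename(files))
    }
  }
  if (length(sample_ids) != length(files)) {
    abort("sample_ids must match files in length")
  }
  if (anyDuplicated(sample_ids)) abort("duplicate sample ids")
  format <- rep_len(format, length(files))
  if (!all(format %in% c("bismark_cov", "bedgraph6"))) {
    abort("format must be \"bismark_cov\" or \"bedgraph6\"")
  }

  per_sample <- purrr::pmap(
    list(files, sample_ids, format),
    function(path, sid, fmt) {
      parse_count_file(path, sid, fmt, collapse_strands)
    }
  )

  # chromosome naming must be consistent across files (chr1 vs 1 silently
  # breaks the outer join and every distance computation)
  prefixed <- purrr::map_lgl(per_sample,
                             \(d) any(grepl("^chr", unique(d$chrom))))
  bare <- purrr::map_lgl(per_sample,
                         \(d) any(!grepl("^chr", unique(d$chrom))))
  if (any(prefixed) && any(bare)) {
    abort(paste0(
      "inconsistent chromosome naming across files; 'chr'-prefixed: ",
      paste(basename(files[prefixed]), collapse = ", "),
      "; bare: ", paste(basename(files[bare]), collapse = ", ")
    ))
  }

  long <- dplyr::bind_rows(per_sample)
  if (!is.null(chrom_filter)) {
    long <- dplyr::filter(long, .data$chrom %in% chrom_filter)
    if (nrow(long) == 0) abort("chrom_filter removed every record")
  }
  ms <- meth_set(long)
  if (min_coverage > 0) {
    keep <- rowSums(ms$meth + ms$unmeth) >= min_coverage
    if (!any(keep)) abort("min_coverage filter removed every site")
    ms <- new_meth_set(ms$meth[keep, , drop = FALSE],
                       ms$unmeth[keep, , drop = FALSE],
                       ms$chrom[keep], ms$pos[keep], ms$samples)
  }
  ms
}

parse_count_file <- function(path, sample_id, format, collapse_strands) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  d <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "pct", "meth", "unmeth"),
    col_types = readr::cols(
      chrom = readr::col_character(), start = readr::col_double(),
      end = readr::col_double(), pct = readr::col_double(),
      meth = readr::col_double(), unmeth = readr::col_double()
    ),
    progress = FALSE
  )
  probs <- readr::problems(d)
  if (nrow(probs) > 0) {
    abort(sprintf("malformed line %d in %s: %s",
                  probs$row[1], path, probs$expected[1]))
  }
  if (nrow(d) == 0) abort(paste0("empty input file: ", path))
  bad <- which(is.na(d$meth) | is.na(d$unmeth) | d$meth < 0 | d$unmeth < 0 |
                 d$meth != floor(d$meth) | d$unmeth != floor(d$unmeth))
  if (length(bad) > 0) {
    abort(sprintf("invalid counts at line %d of %s", bad[1], path))
  }
  pos <- if (format == "bedgraph6") d$start + 1 else d$start
  out <- tibble(chrom = d$chrom, pos = as.integer(pos),
                sample = sample_id,
                meth = as.integer(d$meth), unmeth = as.integer(d$unmeth)) |>
    dplyr::arrange(.data$chrom, .data$pos)
  dup <- duplicated(out[c("chrom", "pos")])
  if (any(dup)) {
    abort(sprintf("duplicate position %s:%d in %s",
                  out$chrom[dup][1], out$pos[dup][1], path))
  }
  if (collapse_strands) {
    grp <- cumsum(!(out$chrom == dplyr::lag(out$chrom, default = "") &
                      out$pos == dplyr::lag(out$pos, default = -10L) + 1L))
    out <- out |>
      dplyr::mutate(.grp = grp) |>
      dplyr::group_by(.data$.grp) |>
      dplyr::summarise(
        chrom = dplyr::first(.data$chrom), pos = dplyr::first(.data$pos),
        sample = dplyr::first(.data$sample),
        meth = sum(.data$meth), unmeth = sum(.data$unmeth),
        .groups = "drop"
      ) |>
      dplyr::select(-".grp")
  }
  out
}

#' Write a meth_set as per-sample Bismark coverage files
#'
#' One `<sample>.cov` file per sample under `dir`, containing only covered
#' cells (zero-coverage cells are absent, mirroring the outer join on read).
#'
#' @param data A [meth_set()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths (named by sample).
#' @export
write_bismark <- function(data, dir) {
  stopifnot(inherits(data, "meth_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (j in seq_len(n_samples(data))) {
    cov <- data$meth[, j] + data$unmeth[, j]
    keep <- cov > 0
    d <- tibble(
      chrom = data$chrom[keep], start = data$pos[keep],
      end = data$pos[keep],
      pct = 100 * data$meth[keep, j] / cov[keep],
      meth = data$meth[keep, j], unmeth = data$unmeth[keep, j]
    )
    path <- file.path(dir, paste0(data$samples[j], ".cov"))
    readr::write_tsv(d, path, col_names = FALSE, progress = FALSE)
    paths[data$samples[j]] <- path
  }
  invisible(paths)
}

segments_of <- function(x) {
  seg <- if (inherits(x, "meth_segmentation")) x$segments else x
  if (!is.data.frame(seg)) abort("expected a meth_segmentation or segments tibble")
  if (is.null(seg$segment_id) && nrow(seg) > 0) {
    seg$segment_id <- sprintf("seg_%05d", seq_len(nrow(seg)))
  }
  seg
}

#' Write segments as a BED6 file
#'
#' 0-based half-open coordinates: a segment whose member CpGs span 1-based
#' positions `[start, end]` becomes the interval `[start - 1, end)`. Score
#' is `round(1000 * mean_methylation)`.
#'
#' @param segmentation A `meth_segmentation` or segments tibble.
#' @param path Output file.
#' @export
write_segments_bed <- function(segmentation, path) {
  seg <- segments_of(segmentation)
  if (nrow(seg) == 0) {
    file.create(path)
    return(invisible(path))
  }
  bed <- seg |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::transmute(
      chrom = .data$chrom,
      start = .data$start - 1L,
      end = .data$end,
      name = .data$segment_id,
      score = ifelse(is.na(.data$mean_methylation), 0L,
                     as.integer(round(1000 * .data$mean_methylation))),
      strand = "."
    )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write the segment-level summary table
#'
#' TSV with columns segment_id, chrom, start, end, length_bp, n_cpgs,
#' mean_methylation, coherent, coherence_pvalue. Coordinates are 1-based
#' inclusive (stated in a leading comment line).
#'
#' @inheritParams write_segments_bed
#' @export
write_segment_summary <- function(segmentation, path) {
  seg <- segments_of(segmentation)
  out <- dplyr::select(
    seg, "segment_id", "chrom", "start", "end", "length_bp", "n_cpgs",
    "mean_methylation", "coherent", "coherence_pvalue"
  )
  writeLines("# coordinates: 1-based, inclusive", path)
  readr::write_tsv(out, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Read back a segment summary TSV
#'
#' @param path A file written by [write_segment_summary()].
#' @return A segments tibble (without site-index columns).
#' @export
read_segment_summary <- function(path) {
  readr::read_tsv(
    path, comment = "#",
    col_types = readr::cols(
      segment_id = readr::col_character(), chrom = readr::col_character(),
      coherent = readr::col_logical(), .default = readr::col_double()
    ),
    progress = FALSE
  )
}

#' Write the segment-by-sample methylation matrix
#'
#' Rows are segments, columns samples, cells the pooled per-sample rate
#' over the segment (`NA` where a sample has no coverage in the segment).
#'
#' @inheritParams write_segments_bed
#' @param data The underlying [meth_set()].
#' @export
write_segment_matrix <- function(segmentation, data, path) {
  mat <- segment_rates(segmentation, data)
  readr::write_tsv(mat, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read BED annotation files as interval tibbles
#'
#' @param paths Named character vector of BED file paths; names are the
#'   annotation class labels.
#' @return Named list of tibbles with `chrom`, `start` (0-based), `end`
#'   (exclusive).
#' @export
read_bed_classes <- function(paths) {
  if (is.null(names(paths)) || any(names(paths) == "")) {
    names(paths) <- sub("\\.bed(\\.gz)?$", "", basename(paths))
  }
  purrr::map(as.list(paths), function(p) {
    gr <- rtracklayer::import(p, format = "BED")
    tibble(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr)
    )
  })
}
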