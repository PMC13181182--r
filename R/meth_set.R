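#' Build a methylation count set
#'
#' A `meth_set` holds paired methylated / unmethylated read-count matrices
#' over m CpG sites x n samples, together with 1-based genomic coordinates
#' (the position of the CpG cytosine) and chromosome labels. It is the input
#' to all segmentation, coherence and simulation functions. Sites are stored
#' grouped by chromosome with strictly increasing positions.
#'
#' @param x A data frame in long format with columns `chrom`, `pos`,
#'   `sample`, `meth`, `unmeth` (one row per covered site-sample cell;
#'   absent cells become zero coverage).
#' @return An object of class `meth_set`.
#' @examples
#' df <- tibble::tibble(
#'   chrom = "chr1", pos = c(100, 150, 100, 150),
#'   sample = rep(c("a", "b"), each = 2),
#'   meth = c(3, 0, 5, 2), unmeth = c(7, 5, 0, 8)
#' )
#' ms <- meth_set(df)
#' ms
#' @export
meth_set <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "pos", "sample", "meth", "unmeth")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(x) == 0) abort("at least one site-sample record is required")
  if (anyNA(x[need])) abort("NA values are not allowed in count records")
  if (any(x$meth < 0) || any(x$unmeth < 0)) abort("counts must be >= 0")
  dup <- duplicated(x[c("chrom", "pos", "sample")])
  if (any(dup)) abort("duplicate (chrom, pos, sample) records")

  samples <- sort(unique(as.character(x$sample)))
  sites <- dplyr::distinct(x, chrom = as.character(.data$chrom),
                           pos = as.integer(.data$pos)) |>
    dplyr::arrange(.data$chrom, .data$pos)
  m <- nrow(sites)
  n <- length(samples)
  si <- match(paste(x$chrom, x$pos), paste(sites$chrom, sites$pos))
  sj <- match(as.character(x$sample), samples)
  meth <- matrix(0L, m, n)
  unmeth <- matrix(0L, m, n)
  meth[cbind(si, sj)] <- as.integer(x$meth)
  unmeth[cbind(si, sj)] <- as.integer(x$unmeth)
  new_meth_set(meth, unmeth, sites$chrom, sites$pos, samples)
}

#' Low-level meth_set constructor
#'
#' @param meth,unmeth Integer matrices (m sites x n samples) of methylated
#'   and unmethylated read counts.
#' @param chrom Character vector of chromosome labels, length m.
#' @param pos Integer vector of 1-based CpG positions, length m; strictly
#'   increasing within each chromosome.
#' @param samples Character vector of sample identifiers, length n.
#' @return A `meth_set`.
#' @export
new_meth_set <- function(meth, unmeth, chrom, pos, samples) {
  meth <- as.matrix(meth); unmeth <- as.matrix(unmeth)
  storage.mode(meth) <- "integer"
  storage.mode(unmeth) <- "integer"
  m <- nrow(meth); n <- ncol(meth)
  if (m < 1 || n < 1) abort("need at least one site and one sample")
  if (!identical(dim(meth), dim(unmeth))) abort("count matrices must share shape")
  if (length(chrom) != m || length(pos) != m) {
    abort("chrom/pos length must equal the number of sites")
  }
  if (length(samples) != n) abort("samples length must equal the number of columns")
  if (anyNA(meth) || anyNA(unmeth)) abort("counts must not be NA")
  if (any(meth < 0) || any(unmeth < 0)) abort("counts must be >= 0")
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  # grouped by chromosome, strictly increasing positions within each
  r <- rle(chrom)
  if (any(duplicated(r$values))) abort("sites must be grouped by chromosome")
  for (ch in r$values) {
    p <- pos[chrom == ch]
    if (any(diff(p) <= 0)) {
      abort(paste0("positions must be strictly increasing on ", ch))
    }
  }
  structure(
    list(meth = meth, unmeth = unmeth, chrom = chrom, pos = pos,
         samples = as.character(samples)),
    class = "meth_set"
  )
}

#' @export
print.meth_set <- function(x, ...) {
  cov <- x$meth + x$unmeth
  cat(sprintf(
    "<meth_set> %d CpG sites x %d samples on %d chromosome(s)\n",
    n_sites(x), n_samples(x), length(unique(x$chrom))
  ))
  cat(sprintf("  mean coverage %.1f; %.1f%% of cells covered\n",
              mean(cov), 100 * mean(cov > 0)))
  cat("  samples:", paste(head(x$samples, 8), collapse = ", "),
      if (n_samples(x) > 8) "..." else "", "\n")
  invisible(x)
}

#' Number of CpG sites in a meth_set
#' @param x A `meth_set`.
#' @export
n_sites <- function(x) nrow(x$meth)

#' Number of samples in a meth_set
#' @param x A `meth_set`.
#' @export
n_samples <- function(x) ncol(x$meth)

#' @export
dim.meth_set <- function(x) dim(x$meth)

#' Convert a meth_set to a long tibble
#'
#' One row per site-sample cell (including zero-coverage cells), with
#' columns `chrom`, `pos`, `sample`, `meth`, `unmeth`.
#'
#' @param x A `meth_set`.
#' @param ... Unused.
#' @export
as_tibble.meth_set <- function(x, ...) {
  m <- n_sites(x); n <- n_samples(x)
  tibble(
    chrom = rep(x$chrom, times = n),
    pos = rep(x$pos, times = n),
    sample = rep(x$samples, each = m),
    meth = as.integer(x$meth),
    unmeth = as.integer(x$unmeth)
  )
}

#' Per-cell beta-values of a meth_set
#'
#' The beta-value of a site in a sample is the fraction of methylated reads,
#' `meth / (meth + unmeth)`; cells with zero coverage are `NA`.
#'
#' @param data A `meth_set`.
#' @param drop_na Drop zero-coverage cells? Default `TRUE`.
#' @return A numeric vector (column-major over sites within samples).
#' @export
beta_values <- function(data, drop_na = TRUE) {
  stopifnot(inherits(data, "meth_set"))
  b <- as.numeric(site_rate_mle(data$meth, data$unmeth))
  if (drop_na) b <- b[!is.na(b)]
  b
}

# site row indices for one chromosome (contiguous block by construction)
chrom_sites <- function(data, chrom) {
  idx <- which(data$chrom == chrom)
  if (length(idx) == 0) abort(paste0("no sites on chromosome ", chrom))
  idx
}

#' @export
chromosomes <- function(data) UseMethod("chromosomes")

#' Chromosomes present in a meth_set
#' @param data A `meth_set`.
#' @export
chromosomes.meth_set <- function(data) unique(data$chrom)
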