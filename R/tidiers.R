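#' Tidy a segmentation into its segment table
#'
#' @param x A `meth_segmentation`.
#' @param ... Unused.
#' @return The segments tibble (one row per segment).
#' @method tidy meth_segmentation
#' @export
tidy.meth_segmentation <- function(x, ...) x$segments

#' One-row summary of a segmentation
#'
#' @param x A `meth_segmentation`.
#' @param ... Unused.
#' @method glance meth_segmentation
#' @export
glance.meth_segmentation <- function(x, ...) {
  tibble(
    n_segments = nrow(x$segments),
    n_chromosomes = length(x$k_per_chrom),
    n_sites = x$n_sites,
    n_samples = length(x$samples),
    mean_cpgs_per_segment = mean(x$segments$n_cpgs),
    n_coherent = if (all(is.na(x$segments$coherent))) NA_integer_ else
      sum(x$segments$coherent, na.rm = TRUE),
    bic = x$bic,
    resolution = x$resolution
  )
}

#' @method tidy noise_robustness
#' @export
tidy.noise_robustness <- function(x, ...) x$summary

#' @method glance noise_robustness
#' @export
glance.noise_robustness <- function(x, ...) {
  tibble(
    n_amplitudes = nrow(x$summary),
    n_replicates = nrow(x$per_replicate),
    tolerance_bp = x$tolerance_bp,
    min_sensitivity = min(x$summary$sensitivity),
    max_prop_gained = max(x$summary$prop_gained)
  )
}

#' @method tidy enrichment_result
#' @export
tidy.enrichment_result <- function(x, ...) as_tibble(x)

#' Plot segments along the genome
#'
#' Each segment is a horizontal bar at its mean cross-sample methylation,
#' faceted by chromosome; coherent segments (when flagged) are coloured.
#'
#' @param object A `meth_segmentation`.
#' @param ... Unused.
#' @method autoplot meth_segmentation
#' @export
autoplot.meth_segmentation <- function(object, ...) {
  seg <- object$segments
  p <- ggplot2::ggplot(seg, ggplot2::aes(
    x = .data$start, xend = .data$end,
    y = .data$mean_methylation, yend = .data$mean_methylation
  ))
  if (!all(is.na(seg$coherent))) {
    p <- p + ggplot2::geom_segment(
      ggplot2::aes(colour = .data$coherent), linewidth = 1.2
    ) +
      ggplot2::labs(colour = "coherent")
  } else {
    p <- p + ggplot2::geom_segment(linewidth = 1.2)
  }
  p +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "position (bp)", y = "mean methylation") +
    ggplot2::theme_minimal()
}

#' Plot breakpoint-recovery metrics against noise amplitude
#'
#' Mean sensitivity, specificity, precision and F1 per noise amplitude with
#' bootstrap 95% confidence ribbons.
#'
#' @param object A `noise_robustness` from [evaluate_noise_robustness()].
#' @param ... Unused.
#' @method autoplot noise_robustness
#' @export
autoplot.noise_robustness <- function(object, ...) {
  long <- object$summary |>
    dplyr::select("eta", dplyr::matches(
      "^(sensitivity|specificity|precision|f1)")) |>
    tidyr::pivot_longer(
      -"eta", names_to = c("metric", "bound"),
      names_pattern = "^(sensitivity|specificity|precision|f1)(?:_(low|high))?$",
      values_to = "value"
    ) |>
    dplyr::mutate(bound = dplyr::if_else(
      is.na(.data$bound) | .data$bound == "", "point", .data$bound)) |>
    tidyr::pivot_wider(names_from = "bound", values_from = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$eta, .data$point,
                                     colour = .data$metric,
                                     fill = .data$metric)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$low, ymax = .data$high),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "noise amplitude (%)", y = "metric",
                  colour = NULL, fill = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot annotation enrichment odds ratios
#'
#' @param object An `enrichment_result` from [test_enrichment()].
#' @param ... Unused.
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, ...) {
  d <- dplyr::filter(as_tibble(object), !is.na(.data$odds_ratio))
  ggplot2::ggplot(d, ggplot2::aes(
    x = log2(.data$odds_ratio),
    y = stats::reorder(.data$annotation_class, log2(.data$odds_ratio)),
    fill = .data$significant
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "log2 odds ratio (coherent vs non-coherent overlap)",
                  y = NULL, fill = "FDR < 0.05") +
    ggplot2::theme_minimal()
}
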