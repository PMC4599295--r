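# ggplot2 graphics for the main result types

#' Cumulative fold-change curves for targets vs background
#'
#' The classic seed-target repression display: empirical cumulative
#' distributions of log2 fold changes for predicted targets and background
#' genes; a leftward target curve indicates repression.
#'
#' @param log2fc_targets,log2fc_background numeric vectors.
#' @param target_label,background_label legend labels.
#' @return a ggplot.
#' @export
plot_fold_change_shift <- function(log2fc_targets, log2fc_background,
                                   target_label = "seed targets",
                                   background_label = "background") {
  df <- bind_rows(
    tibble(log2fc = log2fc_targets, set = target_label),
    tibble(log2fc = log2fc_background, set = background_label))
  ggplot2::ggplot(df, ggplot2::aes(.data$log2fc, colour = .data$set)) +
    ggplot2::stat_ecdf(linewidth = 0.8) +
    ggplot2::labs(x = "log2 fold change", y = "cumulative fraction",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a target-shift test
#'
#' @param object `mirsight_shift` object (stores only the summary; supply
#'   the vectors to draw the curves).
#' @param log2fc_targets,log2fc_background the vectors the test was run on.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mirsight_shift <- function(object, log2fc_targets,
                                    log2fc_background, ...) {
  plot_fold_change_shift(log2fc_targets, log2fc_background) +
    ggplot2::ggtitle(sprintf("KS D = %.3f, p = %.2g", object$statistic,
                             object$p_value))
}

#' IsomiR end-heterogeneity profile
#'
#' Read-count distribution over (5' offset, 3' end shift) cells per arm;
#' the 3' end shift combines the templated offset and any non-templated
#' tail length.
#'
#' @param calls [classify_reads()] output.
#' @return a ggplot.
#' @export
plot_isomir_profile <- function(calls) {
  x <- calls |>
    filter(.data$arm %in% c("5p", "3p")) |>
    mutate(end3_shift = .data$offset3 + nchar(.data$nta)) |>
    group_by(.data$arm, .data$offset5, .data$end3_shift) |>
    summarise(count = sum(.data$count), .groups = "drop")
  ggplot2::ggplot(x, ggplot2::aes(.data$end3_shift, .data$offset5,
                                  fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~arm) +
    ggplot2::scale_fill_viridis_c(trans = "log10") +
    ggplot2::labs(x = "3' end shift (nt)", y = "5' offset (nt)",
                  fill = "reads") +
    ggplot2::theme_minimal()
}

#' Plot 3'UTR coverage with the proximal/distal split
#'
#' @param coverage per-base coverage tibble for one transcript.
#' @param segments [segment_utr()] output (the matching row is used).
#' @return a ggplot.
#' @export
plot_utr_coverage <- function(coverage, segments) {
  tid <- coverage$transcript_id[1]
  sp <- segments$split[segments$transcript_id == tid][1]
  ggplot2::ggplot(coverage, ggplot2::aes(.data$pos, .data$depth)) +
    ggplot2::geom_area(fill = "grey70") +
    ggplot2::geom_vline(xintercept = sp, linetype = 2, colour = "red") +
    ggplot2::labs(x = "3'UTR position (nt)", y = "coverage (reads/base)",
                  title = tid) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
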