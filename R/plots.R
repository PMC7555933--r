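#' Doughnut chart of edited-read shares
#'
#' One slice per retained miRNA, sized by its share of all edited reads in
#' the group (`doughnut_share`).
#'
#' @param summary An `edited_summary` from [summarize_edited()].
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_doughnut <- function(summary, title = NULL) {
  stopifnot(inherits(summary, "edited_summary"))
  d <- as_tibble(summary) |>
    mutate(mirna_id = factor(.data$mirna_id, levels = .data$mirna_id))
  ggplot2::ggplot(d, ggplot2::aes(x = 2, y = .data$doughnut_share,
                                  fill = .data$mirna_id)) +
    ggplot2::geom_col(width = 1, colour = "white") +
    ggplot2::coord_polar(theta = "y") +
    ggplot2::xlim(0.5, 2.5) +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "miRNA", title = title)
}

#' Per-position mismatch fractions for one miRNA
#'
#' Stacked non-reference base fractions along the mature sequence, with
#' the seed region (positions 2-7) shaded.
#'
#' @param profile A tibble from [mismatch_profile()].
#' @return A ggplot object.
#' @export
plot_mismatch_profile <- function(profile) {
  long <- profile |>
    tidyr::pivot_longer(dplyr::all_of(DNA_BASES), names_to = "base",
                        values_to = "reads") |>
    filter(.data$base != .data$ref_base, .data$coverage > 0) |>
    mutate(fraction = .data$reads / .data$coverage)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$position, y = .data$fraction,
                                     fill = .data$base)) +
    ggplot2::annotate("rect", xmin = 1.5, xmax = 7.5, ymin = -Inf, ymax = Inf,
                      alpha = 0.12, fill = "grey30") +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "position in mature miRNA (1-based; shaded = seed, nt 2-7)",
      y = "non-reference base fraction",
      title = unique(profile$mirna_id)
    ) +
    ggplot2::theme_minimal()
}

#' Signed -log10 p heatmap across DE comparisons
#'
#' @param de_results Named list of [de_test()] results (one per
#'   comparison).
#' @return A ggplot object.
#' @export
plot_de_heatmap <- function(de_results) {
  long <- bind_rows(lapply(names(de_results), function(nm) {
    d <- de_results[[nm]]
    tibble(mirna_id = d$mirna_id, comparison = nm,
           value = sign(d$log2fc) * -log10(pmax(d$p_value, 1e-300)))
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$comparison, y = .data$mirna_id,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "signed -log10 p") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Volcano plot for a DE result
#'
#' Points coloured by the significance tier used in the study figures
#' (red p <= 0.01, orange p <= 0.05, blue p <= 0.1).
#'
#' @param object A `miredit_de` from [de_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.miredit_de <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$log2fc,
                               y = -log10(pmax(.data$p_value, 1e-300)),
                               colour = .data$tier)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(
      red = "#d7191c", orange = "#fdae61", blue = "#2c7bb6", ns = "grey70"
    )) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p", colour = "tier") +
    ggplot2::theme_minimal()
}
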