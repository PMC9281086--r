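#' Plot per-antigen hit counts
#'
#' Bar chart of total and high-affinity hit counts per antigen, faceted by
#' phylum -- the summary view of a scan.
#'
#' @param counts Count tibble from [count_hits()].
#' @return A ggplot object.
#' @export
plot_hit_counts <- function(counts) {
  long <- counts |>
    tidyr::pivot_longer(c("n_total", "n_high_affinity"),
                        names_to = "measure", values_to = "n") |>
    filter(!is.na(.data$n)) |>
    mutate(measure = dplyr::recode(.data$measure,
                                   n_total = "total",
                                   n_high_affinity = "high affinity (<10 nM)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$antigen_name, y = .data$n,
                                     fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~phylum) +
    ggplot2::labs(x = NULL, y = "homologous peptides", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot per-position substitution percentages
#'
#' @param x A [per_position_stats()] object.
#' @param ... Unused.
#' @return A ggplot object (stacked bars per position).
#' @exportS3Method ggplot2::autoplot
autoplot.position_stats <- function(x, ...) {
  df <- tidy(x) |>
    mutate(category = factor(.data$category, levels = rev(SUBSTITUTION_LABELS)))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$position), y = .data$pct,
                                   fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(
      identical = "#2b8cbe", conservative = "#74c476",
      non_conservative = "#636363"
    )) +
    ggplot2::labs(x = "peptide position", y = "% of hits", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Sequence-logo-style plot of a position frequency matrix
#'
#' Letters stacked per position, each letter's height proportional to its
#' frequency scaled by the position's information content (bits), the
#' conventional logo encoding of positional conservation.
#'
#' @param x A [build_pfm()] object.
#' @param min_freq Hide residues below this frequency (default 0.01).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pfm <- function(x, min_freq = 0.01, ...) {
  df <- tidy(x) |>
    filter(.data$freq >= min_freq) |>
    mutate(height = .data$freq * .data$ic) |>
    arrange(.data$position, .data$height) |>
    group_by(.data$position) |>
    mutate(ymax = cumsum(.data$height),
           ymid = .data$ymax - .data$height / 2) |>
    ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$ymid)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$residue,
                                    size = .data$height,
                                    colour = .data$residue),
                       show.legend = FALSE) +
    ggplot2::scale_size_continuous(range = c(1, 8)) +
    ggplot2::scale_x_continuous(breaks = 1:9) +
    ggplot2::labs(x = "peptide position", y = "bits") +
    ggplot2::theme_minimal()
}

#' Plot a peptide contact map
#'
#' Tile plot of which peptide residues contact the HLA molecule and the
#' TCR alpha/beta chains.
#'
#' @param x A [contact_map()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.contact_map <- function(x, ...) {
  df <- as_tibble(x) |>
    tidyr::pivot_longer(c("hla", "tcr_alpha", "tcr_beta"),
                        names_to = "partner", values_to = "contact")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$position),
                                   y = .data$partner,
                                   fill = .data$contact)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#31a354", `FALSE` = "grey92")) +
    ggplot2::labs(x = "peptide position", y = NULL, fill = "contact") +
    ggplot2::theme_minimal()
}

#' Plot an angle comparison
#'
#' Reference vs alternative angle values, identical pairs highlighted.
#'
#' @param x An [compare_angles()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.angle_comparison <- function(x, ...) {
  ggplot2::ggplot(as_tibble(x),
                  ggplot2::aes(x = .data$value_ref, y = .data$value_alt,
                               colour = .data$identical,
                               shape = .data$kind)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#31a354", `FALSE` = "#de2d26")) +
    ggplot2::labs(x = "reference angle (deg)", y = "compared angle (deg)",
                  colour = "identical") +
    ggplot2::theme_minimal()
}
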