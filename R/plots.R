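# Summary figures for the main result types.

#' Bar plot of per-group codon score summaries
#'
#' @param codon_summary Tibble from [aggregate_codon_scores()].
#' @return A ggplot.
#' @export
plot_codon_scores <- function(codon_summary) {
  ggplot2::ggplot(codon_summary,
                  ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem), width = 0.25) +
    ggplot2::labs(x = NULL, y = "mean codon ln(ESE/ESS)") +
    ggplot2::theme_minimal()
}

#' Uridine frequency at acceptor positions -4..-18, by group
#'
#' @param profile Long tibble from [ppt_u_profile()] with a `group` column.
#' @return A ggplot of per-position mean uridine frequency.
#' @export
plot_ppt_profile <- function(profile) {
  df <- profile %>%
    dplyr::filter(!is.na(.data$is_u)) %>%
    dplyr::group_by(.data$group, .data$pos) %>%
    dplyr::summarise(u_freq = mean(.data$is_u), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$u_freq,
                                   colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "position relative to 3'ss", y = "uridine frequency",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Odds-ratio map of the -3 pyrimidine / first-exon-base association
#'
#' @param assoc Tibble from [minus3_association()].
#' @return A ggplot tile map of log2 odds ratios; the most-associated base
#'   per position is outlined.
#' @export
plot_minus3_association <- function(assoc) {
  ggplot2::ggplot(assoc, ggplot2::aes(x = .data$position, y = .data$base,
                                      fill = log2(.data$odds_ratio))) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = dplyr::filter(assoc, .data$most_associated),
                       fill = NA, colour = "red", linewidth = 0.8) +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = "exon position", y = NULL,
                  fill = "log2 OR (-3T vs -3C)") +
    ggplot2::theme_minimal()
}
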