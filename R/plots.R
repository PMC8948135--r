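# ggplot2 visualisations of the result types.

#' Plot a gene order as an annotated strip
#'
#' One tile per gene in reading order, above the axis for plus-strand genes
#' and below for minus-strand genes -- the usual linearised rendering of a
#' circular mitogenome map.
#'
#' @param object A `gene_order`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.gene_order <- function(object, ...) {
  df <- tidy(object)
  df$y <- ifelse(df$strand == "+", 1, -1)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$y / 2,
                                   fill = .data$strand)) +
    ggplot2::geom_tile(height = 0.9, width = 0.92, colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label, y = .data$y),
                       angle = 90, hjust = ifelse(df$y > 0, 0, 1), size = 2.8) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::scale_y_continuous(limits = c(-2.6, 2.6), breaks = NULL) +
    ggplot2::labs(x = "position in reading order", y = NULL, fill = "strand") +
    ggplot2::theme_minimal()
}

#' Plot relative synonymous codon usage
#'
#' Stacked per-family codon bars, the standard RSCU figure of mitogenome
#' papers.
#'
#' @param object An `rscu_table` from [rscu()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.rscu_table <- function(object, ...) {
  df <- filter(object, .data$amino_acid != "*")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$family, y = .data$rscu,
                                   fill = .data$codon)) +
    ggplot2::geom_col(colour = "grey30", linewidth = 0.2, show.legend = FALSE) +
    ggplot2::labs(x = "synonymous family", y = "RSCU") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot intergenic spacers and overlaps around the genome
#'
#' @param object A `spacer_report`.
#' @param ... Ignored.
#' @return A ggplot of the signed gap at each feature junction.
#' @export
autoplot.spacer_report <- function(object, ...) {
  df <- object$records
  df$junction <- factor(paste(df$upstream, df$downstream, sep = "/"),
                        levels = paste(df$upstream, df$downstream, sep = "/"))
  df$kind <- dplyr::case_when(
    df$circular ~ "origin",
    df$gap > 0 ~ "spacer",
    df$gap < 0 ~ "overlap",
    TRUE ~ "abutting"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$junction, y = .data$gap,
                                   fill = .data$kind)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "signed gap (bp)", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}
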