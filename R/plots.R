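# ggplot2 displays for survey results.

#' Plot oxygen-pi contact distance histograms
#'
#' @param x A `tt_survey` object or a [contact_statistics()] tibble.
#' @param bin_width Bin width in Angstrom.
#' @return A ggplot: contact-distance histograms faceted by oxygen kind,
#'   with the 3.5 A cutoff marked.
#' @export
plot_contact_histogram <- function(x, bin_width = 0.1) {
  stats <- if (inherits(x, "tt_survey")) x$stats else x
  h <- dplyr::bind_rows(lapply(seq_len(nrow(stats)), function(i) {
    dplyr::mutate(stats$histogram[[i]], oxy_kind = stats$oxy_kind[i])
  }))
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_left + bin_width / 2,
                                  y = .data$count)) +
    ggplot2::geom_col(width = bin_width, fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 3.5, linetype = "dashed") +
    ggplot2::facet_wrap(~oxy_kind) +
    ggplot2::labs(x = "oxygen–base-plane distance (Å)",
                  y = "contacts") +
    ggplot2::theme_minimal()
}

#' @rdname plot_contact_histogram
#' @param object A `tt_survey` object.
#' @param ... Unused.
#' @export
autoplot.tt_survey <- function(object, ...) plot_contact_histogram(object)

#' Plot a turn count table
#'
#' @param object A `tt_counts` tibble ([aggregate_counts()]).
#' @param ... Unused.
#' @return A ggplot tile map of nonredundant counts, category by sequence
#'   class.
#' @export
autoplot.tt_counts <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$seq_class,
                                       y = .data$category,
                                       fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "sequence class (first/fourth nucleotide)",
                  y = NULL, fill = "count") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
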