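# ggplot2 views of scan, design and ePCR results.

#' Plot per-enzyme CAPS candidate counts
#'
#' Bar chart of candidate counts per enzyme, filled by gained/lost status
#' — the summary used to pick which digests are worth running.
#'
#' @param x A `caps_scan` result (or any candidate tibble with `enzyme`
#'   and `status` columns).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
plot_caps_summary <- function(x, ...) {
  d <- tibble::as_tibble(x)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$enzyme, fill = .data$status)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "enzyme", y = "CAPS candidates", fill = "alt allele") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.caps_scan <- function(object, ...) plot_caps_summary(object, ...)

#' Plot designed product-size distribution
#'
#' @param pairs A [design_primers()] / [primer_table()] tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
plot_product_sizes <- function(pairs, ...) {
  ggplot2::ggplot(tibble::as_tibble(pairs),
                  ggplot2::aes(x = .data$product_size)) +
    ggplot2::geom_histogram(binwidth = 5, boundary = 0) +
    ggplot2::facet_wrap(ggplot2::vars(.data$marker_type)) +
    ggplot2::labs(x = "product size (bp)", y = "primer pairs") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.primer_pairs <- function(object, ...) plot_product_sizes(object, ...)

#' Plot the electronic-PCR specificity screen
#'
#' Bar chart of pairs by predicted amplicon count: 1 is the specific
#' assay class; 0 means the assay fails, more than 1 means it is
#' multi-locus.
#'
#' @param x An [epcr()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
plot_epcr_specificity <- function(x, ...) {
  s <- glance(x)
  ggplot2::ggplot(s, ggplot2::aes(x = factor(.data$n_hits))) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "predicted amplicons per pair", y = "primer pairs") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.epcr_result <- function(object, ...) plot_epcr_specificity(object, ...)
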