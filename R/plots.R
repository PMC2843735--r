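#' Plot a stratified FDR result
#'
#' P-value histograms per stratum with discoveries highlighted; the flat
#' part of each histogram reflects the null (pi0) component the q-value
#' machinery estimates.
#'
#' @param object A `psa_result`.
#' @param bins Number of histogram bins (default 40).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psa_result <- function(object, bins = 40, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$p_value,
                                             fill = .data$discovered)) +
    ggplot2::geom_histogram(bins = bins, boundary = 0) +
    ggplot2::facet_wrap(~stratum, scales = "free_y") +
    ggplot2::scale_fill_manual(
      values = c(`FALSE` = "grey65", `TRUE` = "#c0392b"),
      name = "discovered"
    ) +
    ggplot2::labs(x = "p-value", y = "SNPs") +
    ggplot2::theme_minimal()
}

#' Plot a QC result
#'
#' MAF against exact Hardy-Weinberg p-value with the pass/fail decision;
#' threshold lines show the two inclusive cutoffs.
#'
#' @param object A `qc_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qc_result <- function(object, ...) {
  ggplot2::ggplot(
    tidy(object),
    ggplot2::aes(x = .data$maf, y = .data$hwe_p, colour = .data$pass)
  ) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = object$params$maf_min,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = object$params$hwe_min,
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "#c0392b", `TRUE` = "grey40"), name = "pass"
    ) +
    ggplot2::labs(x = "minor allele frequency",
                  y = "HWE exact p (controls)") +
    ggplot2::theme_minimal()
}

#' P-value histogram of an association scan
#'
#' @param assoc Tibble from [association_scan()] (or any tibble with a
#'   `p_value` column).
#' @param bins Number of bins (default 40).
#' @return A ggplot object.
#' @export
plot_pvalue_histogram <- function(assoc, bins = 40) {
  ggplot2::ggplot(assoc, ggplot2::aes(x = .data$p_value)) +
    ggplot2::geom_histogram(bins = bins, boundary = 0, fill = "grey60") +
    ggplot2::labs(x = "p-value", y = "SNPs") +
    ggplot2::theme_minimal()
}
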