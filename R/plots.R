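#' Plot a ratio association table
#'
#' Effect size against evidence, one point per ratio; ratios whose p-gain
#' clears the threshold are highlighted.
#'
#' @param object An `assoc_tbl`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot assoc_tbl
#' @export
autoplot.assoc_tbl <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  dat$highlight <- if ("p_gain_significant" %in% names(dat)) {
    dat$p_gain_significant
  } else dat$p_bh < 0.05
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$beta,
                                    y = -log10(.data$p_bh),
                                    colour = .data$highlight)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#b2182b",
                                            `FALSE` = "grey55"),
                                 name = "p-gain > 10 × n tests") +
    ggplot2::labs(x = sprintf("SD-change per unit %s", object$outcome[1]),
                  y = "-log10 BH p-value") +
    ggplot2::theme_minimal()
}

#' Plot an enrichment table
#'
#' @param object An `enrichment_tbl` from [lsea()] or [enrichment()].
#' @param alpha BH significance level used for the fill.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot enrichment_tbl
#' @export
autoplot.enrichment_tbl <- function(object, alpha = 0.05, ...) {
  dat <- dplyr::arrange(tibble::as_tibble(object), .data$score)
  dat$set <- factor(dat$set, levels = dat$set)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$score, y = .data$set,
                                    fill = .data$p_bh < alpha)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac",
                                          `FALSE` = "grey70"),
                               name = sprintf("BH p < %.2f", alpha)) +
    ggplot2::labs(x = "correlation-adjusted enrichment score", y = NULL) +
    ggplot2::theme_minimal()
}

#' Manhattan-style plot of mixed-model GWAS results
#'
#' @param object A `gwas_tbl` from [lmm_gwas()].
#' @param threshold Genome-wide significance threshold line.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gwas_tbl
#' @export
autoplot.gwas_tbl <- function(object, threshold = 5e-8, ...) {
  dat <- tibble::as_tibble(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$pos, y = -log10(.data$p),
                                    colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(threshold), linetype = "dashed") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "position", y = "-log10 p") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.spacing = ggplot2::unit(0.1, "lines"))
}

#' Plot cross-cohort concordance of ratio effects
#'
#' @param object A `concordance_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot concordance_report
#' @export
autoplot.concordance_report <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$beta_a, y = .data$beta_b,
                               colour = .data$concordant)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2166ac",
                                            `FALSE` = "#b2182b"),
                                 name = "concordant") +
    ggplot2::labs(x = "beta (cohort A)", y = "beta (cohort B)") +
    ggplot2::theme_minimal()
}
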