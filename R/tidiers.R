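#' Tidy an association table
#'
#' Flattens the nested component results into per-side columns.
#'
#' @param x An `assoc_tbl` from [associate_ratios()] or [fit_association()].
#' @param ... Unused.
#' @return A plain tibble.
#' @method tidy assoc_tbl
#' @export
tidy.assoc_tbl <- function(x, ...) {
  if ("components" %in% names(x)) {
    return(tibble::as_tibble(flatten_assoc(x)))
  }
  tibble::as_tibble(x)
}

#' @rdname tidy.assoc_tbl
#' @method glance assoc_tbl
#' @export
glance.assoc_tbl <- function(x, ...) {
  tibble::tibble(
    n_targets = nrow(x),
    n_significant = sum(x$p_bh < 0.05),
    n_pgain_significant = if ("p_gain_significant" %in% names(x)) {
      sum(x$p_gain_significant)
    } else NA_integer_,
    outcome = x$outcome[1]
  )
}

#' Summaries of a mixed-model variance-component fit
#'
#' @param x An `lmm_fit` from [fit_lmm_reml()].
#' @param ... Unused.
#' @return One-row tibble with the variance components, heritability and
#'   restricted log-likelihood.
#' @method glance lmm_fit
#' @export
glance.lmm_fit <- function(x, ...) {
  tibble::tibble(sigma_g2 = x$sigma_g2, sigma_e2 = x$sigma_e2,
                 delta = x$delta, h2 = x$h2, loglik = x$loglik, n = x$n)
}

#' Summaries of a GWAS result table
#'
#' The genomic inflation factor lambda is the median association
#' chi-squared over its null expectation.
#'
#' @param x A `gwas_tbl` from [lmm_gwas()].
#' @param ... Unused.
#' @return One-row tibble with variant counts, hit counts and lambda.
#' @method glance gwas_tbl
#' @export
glance.gwas_tbl <- function(x, ...) {
  chisq <- (x$beta / x$se)^2
  tibble::tibble(
    n_variants = nrow(x),
    n_significant = sum(x$significant),
    min_p = min(x$p),
    lambda_gc = median(chisq) / stats::qchisq(0.5, df = 1)
  )
}

#' @rdname glance.gwas_tbl
#' @method tidy gwas_tbl
#' @export
tidy.gwas_tbl <- function(x, ...) tibble::as_tibble(x)

#' Tidy and summarise a concordance report
#'
#' @param x A `concordance_report` from [concordance()].
#' @param ... Unused.
#' @return `tidy()` gives the per-ratio merged table; `glance()` the counts
#'   and beta correlation.
#' @method tidy concordance_report
#' @export
tidy.concordance_report <- function(x, ...) x$table

#' @rdname tidy.concordance_report
#' @method glance concordance_report
#' @export
glance.concordance_report <- function(x, ...) {
  tibble::tibble(n_shared = x$n_shared, n_concordant = x$n_concordant,
                 beta_correlation = x$beta_correlation, policy = x$policy)
}
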