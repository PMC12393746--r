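#' Covariate-adjusted species correlation matrix
#'
#' Pearson correlation of OLS residuals of standardized log2 species
#' abundances after regressing out covariates. With no covariates this is
#' the plain correlation matrix.
#'
#' @param dataset A `lipidomics` object (biological samples only are used).
#' @param cohort Covariate tibble with `sample_id`.
#' @param covariates Covariate column names; may be empty.
#' @return Species x species correlation matrix (unit diagonal, symmetric).
#' @export
residual_correlation <- function(dataset, cohort, covariates = c("age", "sex")) {
  bio <- intersect(dataset$samples$sample_id[!dataset$samples$is_pqc &
                                               !dataset$samples$is_reference],
                   cohort$sample_id)
  conc <- dataset$concentrations[bio, , drop = FALSE]
  conc[!is.na(conc) & conc <= 0] <- NA_real_
  logm <- scale(log2(conc))
  covs <- as.matrix(cohort[match(bio, cohort$sample_id), covariates, drop = FALSE])
  cc <- complete.cases(logm, covs)
  logm <- logm[cc, , drop = FALSE]

  if (length(covariates)) {
    X <- cbind(1, covs[cc, , drop = FALSE])
    resid <- logm - X %*% solve(crossprod(X), crossprod(X, logm))
  } else {
    resid <- scale(logm, scale = FALSE)
  }
  zero_var <- apply(resid, 2, sd) == 0
  if (any(zero_var)) {
    stop("zero residual variance for: ",
         paste(colnames(resid)[zero_var], collapse = ", "), call. = FALSE)
  }
  cmat <- cor(resid)
  diag(cmat) <- 1
  (cmat + t(cmat)) / 2
}

#' Build structural lipid sets from annotations
#'
#' Default set collection: one set per lipid class, ether/plasmalogen
#' subclass groupings, and feature sets (omega-3, omega-6, sn-resolved
#' lyso species).
#'
#' @param annotations Species annotation tibble.
#' @param min_size Drop sets with fewer members.
#' @return Tibble with columns `set`, `category`, and list-column `members`.
#' @export
build_lipid_sets <- function(annotations, min_size = 2L) {
  class_sets <- annotations |>
    dplyr::group_by(set = .data$class_code) |>
    dplyr::summarise(members = list(.data$species_name), .groups = "drop") |>
    dplyr::mutate(category = "class")
  sub <- tibble::tibble(
    set = c("alkenyl (plasmalogen)", "alkyl ether", "omega-3", "omega-6"),
    category = c("subclass", "subclass", "PUFA-feature", "PUFA-feature"),
    members = list(
      annotations$species_name[annotations$linkage == "alkenyl"],
      annotations$species_name[annotations$linkage == "alkyl"],
      annotations$species_name[annotations$omega_series == "n-3"],
      annotations$species_name[annotations$omega_series == "n-6"]
    )
  )
  out <- dplyr::bind_rows(class_sets, sub)
  out[lengths(out$members) >= min_size, c("set", "category", "members")]
}

#' Correlation-adjusted lipid set enrichment
#'
#' The enrichment score of a set is the sum of its members' association
#' t-statistics divided by the square root of the sum of the
#' covariate-adjusted correlation matrix restricted to the set. Under the
#' null the squared score tends to a chi-squared distribution with one
#' degree of freedom, which supplies the p-value; the adjustment keeps the
#' test calibrated for arbitrarily correlated sets, where a naive
#' sqrt(set size) denominator does not.
#'
#' @param t_stats Named numeric vector of per-species association
#'   t-statistics (from [fit_association()] on the species matrix).
#' @param corr Residual correlation matrix covering all set members.
#' @param sets Set tibble from [build_lipid_sets()] or with the same shape.
#' @param naive If `TRUE`, use the uncorrected sqrt(n) denominator
#'   (miscalibrated for correlated sets; provided for comparison).
#' @return An `enrichment_tbl` tibble: set, category, n_lipids, score, p,
#'   p_bh.
#' @export
enrichment <- function(t_stats, corr, sets, naive = FALSE) {
  out <- purrr::map_dfr(seq_len(nrow(sets)), function(i) {
    members <- sets$members[[i]]
    missing <- setdiff(members, names(t_stats))
    if (length(missing)) {
      stop("t-statistics missing for: ", paste(head(missing, 5), collapse = ", "),
           call. = FALSE)
    }
    denom2 <- if (naive) length(members) else {
      sum(corr[members, members, drop = FALSE])
    }
    if (denom2 <= 0) {
      stop("degenerate correlation denominator for set '", sets$set[i], "'",
           call. = FALSE)
    }
    score <- sum(t_stats[members]) / sqrt(denom2)
    tibble::tibble(set = sets$set[i],
                   category = sets$category[i] %||% NA_character_,
                   n_lipids = length(members), score = score,
                   p = pchisq(score^2, df = 1, lower.tail = FALSE))
  })
  out$p_bh <- bh_adjust(out$p)
  class(out) <- c("enrichment_tbl", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write lipid set tables
#'
#' Sets are stored long: one row per (set, species) with a category
#' column.
#'
#' @param path File path (TSV with columns set, category, species).
#' @return For the reader, a set tibble as produced by
#'   [build_lipid_sets()].
#' @export
read_lipid_sets <- function(path) {
  long <- read_delim_auto(path)
  long |>
    dplyr::group_by(.data$set, .data$category) |>
    dplyr::summarise(members = list(.data$species), .groups = "drop")
}

#' @rdname read_lipid_sets
#' @param sets Set tibble to write.
#' @export
write_lipid_sets <- function(sets, path) {
  long <- tibble::tibble(
    set = rep(sets$set, lengths(sets$members)),
    category = rep(sets$category, lengths(sets$members)),
    species = unlist(sets$members)
  )
  readr::write_tsv(long, path, progress = FALSE)
  invisible(path)
}

#' Lipid set enrichment against an outcome
#'
#' Orchestrates the enrichment stage: per-species association t-statistics
#' (standardized log2 abundances, identical covariate adjustment),
#' covariate-adjusted residual correlations, and correlation-adjusted
#' enrichment scores with chi-squared (1 df) p-values and BH adjustment
#' across sets.
#'
#' @inheritParams residual_correlation
#' @param outcome Outcome column name.
#' @param sets Set tibble; default built from the dataset annotations.
#' @return An `enrichment_tbl` tibble.
#' @export
lsea <- function(dataset, cohort, outcome = "WC",
                 covariates = c("age", "sex"), sets = NULL) {
  if (is.null(sets)) sets <- build_lipid_sets(dataset$annotations)
  bio <- intersect(dataset$samples$sample_id[!dataset$samples$is_pqc &
                                               !dataset$samples$is_reference],
                   cohort$sample_id)
  conc <- dataset$concentrations[bio, , drop = FALSE]
  conc[!is.na(conc) & conc <= 0] <- NA_real_
  logm <- scale(log2(conc))
  fit <- fit_association(logm, cohort, outcome, covariates)
  t_stats <- setNames(fit$t, fit$target)
  corr <- residual_correlation(dataset, cohort, covariates)
  enrichment(t_stats, corr, sets)
}
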