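target_matrix <- function(targets) {
  if (inherits(targets, "ratio_matrix")) return(targets$values)
  if (is.data.frame(targets)) {
    m <- as.matrix(targets[, -1, drop = FALSE])
    rownames(m) <- as.character(targets[[1]])
    return(m)
  }
  stopifnot(is.matrix(targets))
  targets
}

#' Covariate-adjusted linear association
#'
#' Ordinary least squares of each target column on an outcome plus
#' covariates (complete cases per fit). The reported beta is the outcome
#' coefficient — the SD-change of the standardized target per unit of the
#' outcome — with a two-sided t-test p-value and Benjamini-Hochberg
#' adjustment across the target family.
#'
#' @param targets A `ratio_matrix`, a samples x targets numeric matrix with
#'   sample ids as rownames, or a data frame whose first column is the
#'   sample id.
#' @param cohort Covariate tibble with a `sample_id` column.
#' @param outcome Name of the outcome column in `cohort` (e.g. `"WC"`).
#' @param covariates Character vector of adjustment covariates.
#' @return A tibble of class `assoc_tbl`: target, outcome, beta, se, t, p,
#'   p_bh, n_used.
#' @export
fit_association <- function(targets, cohort, outcome = "WC",
                            covariates = c("age", "sex")) {
  y_mat <- target_matrix(targets)
  design_cols <- c(outcome, covariates)
  stopifnot(all(design_cols %in% names(cohort)))
  idx <- match(rownames(y_mat), cohort$sample_id)
  keep_samples <- !is.na(idx)
  y_mat <- y_mat[keep_samples, , drop = FALSE]
  covs <- as.matrix(cohort[idx[keep_samples], design_cols])

  out <- purrr::map_dfr(seq_len(ncol(y_mat)), function(j) {
    y <- y_mat[, j]
    cc <- complete.cases(y, covs)
    X <- cbind(`(Intercept)` = 1, covs[cc, , drop = FALSE])
    n <- sum(cc)
    if (n <= ncol(X) + 1) {
      stop("too few complete cases for target '", colnames(y_mat)[j], "'",
           call. = FALSE)
    }
    if (sd(X[, outcome]) == 0) {
      stop("outcome '", outcome, "' is constant in the complete cases",
           call. = FALSE)
    }
    fit <- lm.fit(X, y[cc])
    rss <- sum(fit$residuals^2)
    df <- n - fit$rank
    xtx_inv <- chol2inv(fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank),
                                  drop = FALSE])
    se_all <- sqrt(diag(xtx_inv) * rss / df)
    names(se_all) <- colnames(X)[fit$qr$pivot[seq_len(fit$rank)]]
    beta <- fit$coefficients[outcome]
    se <- se_all[outcome]
    tval <- beta / se
    tibble::tibble(target = colnames(y_mat)[j], outcome = outcome,
                   beta = unname(beta), se = unname(se), t = unname(tval),
                   p = 2 * pt(-abs(tval), df), n_used = n)
  })
  out$p_bh <- bh_adjust(out$p)
  class(out) <- c("assoc_tbl", class(out))
  out
}

#' The p-gain statistic
#'
#' The gain in association strength from using a ratio instead of its
#' component lipids: the smaller of the component p-values divided by the
#' ratio's p-value. The gain is deemed significant when it exceeds ten
#' times the number of tests performed (ratios tested, or in the GWAS
#' context, significant SNPs for the ratio).
#'
#' @param ratio_p P-value of the ratio association, in (0, 1].
#' @param component_ps Numeric vector of component p-values, in (0, 1].
#' @param n_tests Number of tests defining the significance threshold.
#' @return List with `value` and `significant`.
#' @examples
#' p_gain(4.30e-68, c(4.31e-22, 3.36e-35), n_tests = 82)
#' @export
p_gain <- function(ratio_p, component_ps, n_tests) {
  stopifnot(length(ratio_p) == 1, n_tests >= 1)
  if (ratio_p == 0) {
    stop("ratio p-value of exactly 0; clamp to the smallest representable ",
         "value upstream", call. = FALSE)
  }
  if (any(c(ratio_p, component_ps) < 0) || any(c(ratio_p, component_ps) > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  value <- min(component_ps) / ratio_p
  list(value = value, significant = value > p_gain_threshold(n_tests))
}

#' @rdname p_gain
#' @export
p_gain_threshold <- function(n_tests) 10 * n_tests

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment (monotone, capped at 1);
#' delegates to [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  p.adjust(p, method = "BH")
}

standardized_component_matrix <- function(dataset, definitions, samples = NULL) {
  conc <- dataset$concentrations
  if (!is.null(samples)) conc <- conc[samples, , drop = FALSE]
  conc[!is.na(conc) & conc <= 0] <- NA_real_
  sides <- tibble::tibble(
    ratio = rep(definitions$label, 2),
    side = rep(c("numerator", "denominator"), each = nrow(definitions)),
    members = c(definitions$numerator_species, definitions$denominator_species)
  )
  sides$component <- vapply(sides$members, function(m) {
    paste(sort(m), collapse = "|")
  }, character(1))
  uniq <- sides[!duplicated(sides$component), ]
  comp_mat <- vapply(uniq$members, function(members) {
    sub <- conc[, members, drop = FALSE]
    s <- rowSums(sub, na.rm = TRUE)
    s[rowSums(!is.na(sub)) == 0 | s <= 0] <- NA_real_
    scale(log2(s))[, 1]
  }, numeric(nrow(conc)))
  colnames(comp_mat) <- uniq$component
  rownames(comp_mat) <- rownames(conc)
  list(matrix = comp_mat, map = sides[, c("ratio", "side", "component")])
}

#' Ratio-vs-obesity association with the p-gain
#'
#' End-to-end association stage: computes the standardized log2 ratio
#' matrix, fits each ratio and — with the identical model — each of its
#' component lipids (side aggregates, log2-standardized) against the
#' outcome adjusting for covariates, applies Benjamini-Hochberg adjustment
#' within the ratio and component families, and reports the p-gain per
#' ratio. By default the p-gain uses the BH-adjusted p-values, matching the
#' convention of reporting adjusted p-values throughout; set
#' `pgain_on = "raw"` to use unadjusted ones.
#'
#' @param dataset A `lipidomics` object (biological samples are used).
#' @param cohort Covariate tibble.
#' @param outcome Outcome column name (WC, BMI or WHR).
#' @param definitions Ratio definitions; default packaged table resolved
#'   against the dataset.
#' @param covariates Adjustment covariates.
#' @param n_tests Number of ratios for the p-gain threshold; defaults to
#'   the number of definitions.
#' @param pgain_on `"bh"` (default) or `"raw"`.
#' @return An `assoc_tbl` tibble with component results nested in a
#'   `components` list-column and columns `p_gain`, `p_gain_significant`.
#' @export
associate_ratios <- function(dataset, cohort, outcome = "WC",
                             definitions = NULL,
                             covariates = c("age", "sex"),
                             n_tests = NULL, pgain_on = c("bh", "raw")) {
  pgain_on <- match.arg(pgain_on)
  bio <- dataset$samples$sample_id[!dataset$samples$is_pqc &
                                     !dataset$samples$is_reference]
  bio <- intersect(bio, cohort$sample_id)
  if (is.null(definitions)) {
    definitions <- read_ratio_definitions(annotations = dataset$annotations)
  }
  if (is.null(n_tests)) n_tests <- nrow(definitions)

  ratios <- compute_ratio_matrix(dataset, definitions, samples = bio)
  ratio_fit <- fit_association(ratios, cohort, outcome, covariates)

  comp <- standardized_component_matrix(dataset, definitions, samples = bio)
  comp_fit <- fit_association(comp$matrix, cohort, outcome, covariates)
  comp_fit <- dplyr::rename(comp_fit, component = "target")

  comp_long <- dplyr::left_join(comp$map, comp_fit, by = "component")
  nested <- dplyr::group_split(dplyr::group_by(comp_long, .data$ratio))
  names(nested) <- vapply(nested, function(x) x$ratio[1], character(1))

  pick <- if (pgain_on == "bh") "p_bh" else "p"
  out <- ratio_fit
  out$components <- unname(nested[out$target])
  gains <- purrr::map2(out[[pick]], out$components, function(rp, comps) {
    p_gain(rp, comps[[pick]], n_tests)
  })
  out$p_gain <- vapply(gains, `[[`, numeric(1), "value")
  out$p_gain_significant <- vapply(gains, `[[`, logical(1), "significant")
  attr(out, "n_tests") <- n_tests
  attr(out, "pgain_on") <- pgain_on
  out
}

#' Sex-interaction association models
#'
#' Fits the fully sex-interacted model
#' `target ~ outcome * sex + age * sex` per target; the interaction p-value
#' is the outcome-by-sex coefficient's. Per-sex effects come from
#' sex-stratified fits adjusting for the remaining covariates (these
#' coincide exactly with the slopes implied by the fully interacted model).
#'
#' @inheritParams fit_association
#' @param covariates Covariates other than sex (each also interacted with
#'   sex in the joint model).
#' @return Tibble with per-target interaction_p, interaction_p_bh and
#'   nested per-sex records (beta, se, p, p_bh).
#' @export
sex_interaction <- function(targets, cohort, outcome = "WC",
                            covariates = "age") {
  y_mat <- target_matrix(targets)
  if (dplyr::n_distinct(cohort$sex[!is.na(cohort$sex)]) < 2) {
    stop("both sexes must be present for interaction models", call. = FALSE)
  }
  idx <- match(rownames(y_mat), cohort$sample_id)
  keep <- !is.na(idx)
  y_mat <- y_mat[keep, , drop = FALSE]
  cov_tab <- cohort[idx[keep], c(outcome, "sex", covariates)]

  inter <- purrr::map_dfr(seq_len(ncol(y_mat)), function(j) {
    dat <- dplyr::mutate(cov_tab, .y = y_mat[, j])
    dat <- dat[complete.cases(dat), ]
    rhs <- paste(c(outcome, "sex", covariates,
                   paste0(c(outcome, covariates), ":sex")), collapse = " + ")
    fit <- lm(stats::as.formula(paste(".y ~", rhs)), data = dat)
    sm <- summary(fit)$coefficients
    term <- paste0(outcome, ":sex")
    tibble::tibble(target = colnames(y_mat)[j],
                   interaction_p = sm[term, "Pr(>|t|)"],
                   interaction_beta = sm[term, "Estimate"])
  })
  inter$interaction_p_bh <- bh_adjust(inter$interaction_p)

  strat <- lapply(c(female = 0, male = 1), function(s) {
    rows <- which(cov_tab$sex == s)
    fit_association(y_mat[rows, , drop = FALSE],
                    dplyr::bind_cols(tibble::tibble(sample_id = rownames(y_mat)[rows]),
                                     cov_tab[rows, c(outcome, covariates)]),
                    outcome, covariates)
  })
  inter$female <- unname(split(strat$female, seq_len(nrow(strat$female))))
  inter$male <- unname(split(strat$male, seq_len(nrow(strat$male))))
  class(inter) <- c("interaction_tbl", class(inter))
  inter
}

#' Sex-interaction analysis of lipid ratios with per-sex p-gains
#'
#' @inheritParams associate_ratios
#' @return The [sex_interaction()] table augmented with per-sex p-gain
#'   columns computed from sex-stratified ratio and component fits.
#' @export
interaction_ratios <- function(dataset, cohort, outcome = "WC",
                               definitions = NULL, covariates = "age",
                               n_tests = NULL, pgain_on = c("bh", "raw")) {
  pgain_on <- match.arg(pgain_on)
  if (is.null(definitions)) {
    definitions <- read_ratio_definitions(annotations = dataset$annotations)
  }
  if (is.null(n_tests)) n_tests <- nrow(definitions)
  bio <- intersect(dataset$samples$sample_id[!dataset$samples$is_pqc &
                                               !dataset$samples$is_reference],
                   cohort$sample_id)
  ratios <- compute_ratio_matrix(dataset, definitions, samples = bio)
  inter <- sex_interaction(ratios, cohort, outcome, covariates)
  pick <- if (pgain_on == "bh") "p_bh" else "p"

  for (sx in c("female", "male")) {
    subcohort <- cohort[cohort$sex == (sx == "male"), ]
    sub <- associate_ratios(dataset, subcohort, outcome, definitions,
                            covariates, n_tests, pgain_on)
    ord <- match(inter$target, sub$target)
    inter[[paste0(sx, "_beta")]] <- sub$beta[ord]
    inter[[paste0(sx, "_p")]] <- sub[[pick]][ord]
    inter[[paste0(sx, "_p_gain")]] <- sub$p_gain[ord]
    inter[[paste0(sx, "_p_gain_significant")]] <- sub$p_gain_significant[ord]
  }
  inter
}

#' Cross-cohort concordance of ratio associations
#'
#' @param table_a,table_b `assoc_tbl` tibbles sharing target labels.
#' @param policy `"sign_and_significant"` (concordant means same beta sign
#'   and BH-significant in both cohorts at `alpha`) or `"sign"`.
#' @param alpha BH significance level used by the default policy.
#' @return A `concordance_report` list: counts, Pearson correlation of
#'   betas, discordant labels and the merged table.
#' @export
concordance <- function(table_a, table_b,
                        policy = c("sign_and_significant", "sign"),
                        alpha = 0.05) {
  policy <- match.arg(policy)
  shared <- dplyr::inner_join(
    dplyr::select(table_a, "target", beta_a = "beta", p_bh_a = "p_bh"),
    dplyr::select(table_b, "target", beta_b = "beta", p_bh_b = "p_bh"),
    by = "target"
  )
  if (!nrow(shared)) stop("no shared target labels", call. = FALSE)
  same_sign <- sign(shared$beta_a) == sign(shared$beta_b)
  shared$concordant <- if (policy == "sign_and_significant") {
    same_sign & shared$p_bh_a < alpha & shared$p_bh_b < alpha
  } else {
    same_sign
  }
  structure(
    list(n_shared = nrow(shared),
         n_concordant = sum(shared$concordant),
         beta_correlation = cor(shared$beta_a, shared$beta_b),
         discordant = shared$target[!shared$concordant],
         table = shared, policy = policy),
    class = "concordance_report"
  )
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("<concordance_report> ", x$n_concordant, "/", x$n_shared,
      " concordant (policy: ", x$policy, "); beta correlation r = ",
      round(x$beta_correlation, 3), "\n", sep = "")
  invisible(x)
}

#' Two-group Mann-Whitney comparison per gene
#'
#' Two-sided Mann-Whitney U tests per gene with exact enumeration when both
#' groups have at most eight untied observations, otherwise the normal
#' approximation with tie correction; BH adjustment across genes. Genes
#' constant across both groups get p = 1 by convention.
#'
#' @param expression Samples x genes numeric matrix.
#' @param groups Two-level factor or character vector per sample.
#' @return Tibble with gene, U (first group), p, p_bh and `direction`
#'   (sign of the group-2 minus group-1 median difference).
#' @export
group_difference <- function(expression, groups) {
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) == 2)
  g1 <- expression[groups == levels(groups)[1], , drop = FALSE]
  g2 <- expression[groups == levels(groups)[2], , drop = FALSE]
  if (nrow(g1) < 2 || nrow(g2) < 2) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  out <- purrr::map_dfr(seq_len(ncol(expression)), function(j) {
    x <- g1[, j]
    y <- g2[, j]
    if (length(unique(c(x, y))) == 1) {
      return(tibble::tibble(gene = colnames(expression)[j],
                            U = length(x) * length(y) / 2, p = 1,
                            direction = 0))
    }
    has_ties <- anyDuplicated(c(x, y)) > 0
    exact <- length(x) <= 8 && length(y) <= 8 && !has_ties
    wt <- suppressWarnings(
      wilcox.test(x, y, exact = exact, correct = FALSE)
    )
    tibble::tibble(gene = colnames(expression)[j],
                   U = unname(wt$statistic),
                   p = min(wt$p.value, 1),
                   direction = sign(median(y) - median(x)))
  })
  out$p_bh <- bh_adjust(out$p)
  out
}
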