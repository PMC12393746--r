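#' Reference-plasma correction factors
#'
#' For each species, the factor is the median concentration over the
#' dataset's reference-plasma aliquots divided by the consensus
#' concentration for that species. Applying the factors (division) aligns
#' the dataset with the consensus scale.
#'
#' @param dataset A `lipidomics` object with at least one sample flagged
#'   `is_reference`.
#' @param consensus Named numeric vector of consensus concentrations
#'   covering every species in the dataset.
#' @return A tibble of class `correction_factors` with columns `species`,
#'   `method`, `batch` (`NA` here) and `factor`.
#' @export
reference_correction_factors <- function(dataset, consensus) {
  ref <- dataset$concentrations[dataset$samples$sample_id[dataset$samples$is_reference],
                                , drop = FALSE]
  if (nrow(ref) == 0) stop("dataset has no reference samples", call. = FALSE)
  species <- colnames(dataset$concentrations)
  absent <- species[!species %in% names(consensus) |
                      is.na(consensus[species]) | consensus[species] == 0]
  if (length(absent)) {
    stop("consensus value missing or zero for: ",
         paste(head(absent, 5), collapse = ", "), call. = FALSE)
  }
  med <- apply(ref, 2, median, na.rm = TRUE)
  new_correction_factors(species, med / consensus[species], "reference")
}

new_correction_factors <- function(species, factor, method, batch = NA_character_) {
  if (any(!is.finite(factor) | factor <= 0)) {
    stop("correction factors must be positive and finite", call. = FALSE)
  }
  structure(
    tibble::tibble(species = species, method = method, batch = batch,
                   factor = unname(factor)),
    class = c("correction_factors", class(tibble::tibble()))
  )
}

#' Matched sub-cohort correction factors
#'
#' Builds matched sub-cohorts by greedy 1:1 nearest-neighbour matching
#' without replacement — exact on sex and disease flags, Euclidean distance
#' on standardized age, BMI and total cholesterol, ties broken by
#' lexicographic sample id — then takes per-species factors as the ratio of
#' matched-sample medians (cohort A over cohort B). Multiplying cohort B by
#' the factors aligns it with cohort A.
#'
#' @param dataset_a,dataset_b `lipidomics` objects for the two cohorts.
#' @param cohort_a,cohort_b Covariate tibbles with `sample_id`, `age`,
#'   `sex`, `BMI`, `total_cholesterol`, `disease`.
#' @param n_pairs Number of matched pairs to form.
#' @return A `correction_factors` tibble (`method = "matched_subcohort"`),
#'   with the matched pair table in attribute `pairs`.
#' @export
matched_subcohort_factors <- function(dataset_a, cohort_a, dataset_b, cohort_b,
                                      n_pairs = 1000L) {
  n_pairs <- min(n_pairs, nrow(cohort_a), nrow(cohort_b))
  vars <- c("age", "BMI", "total_cholesterol")
  pool <- dplyr::bind_rows(cohort_a[vars], cohort_b[vars])
  ctr <- colMeans(pool, na.rm = TRUE)
  scl <- vapply(pool, sd, numeric(1), na.rm = TRUE)
  std <- function(tab) scale(as.matrix(tab[vars]), center = ctr, scale = scl)
  za <- std(cohort_a)
  zb <- std(cohort_b)
  stratum <- function(tab) paste(tab$sex, tab$disease)
  sa <- stratum(cohort_a)
  sb <- stratum(cohort_b)
  if (!length(intersect(sa, sb))) {
    stop("no exact-match stratum shared between cohorts", call. = FALSE)
  }

  ord_b <- order(sb %in% sa, cohort_b$sample_id, decreasing = c(TRUE, FALSE),
                 method = "radix")
  used_a <- rep(FALSE, nrow(cohort_a))
  pair_a <- character(0)
  pair_b <- character(0)
  for (i in ord_b) {
    if (length(pair_b) >= n_pairs) break
    cand <- which(!used_a & sa == sb[i])
    if (!length(cand)) next
    d <- sqrt(rowSums((za[cand, , drop = FALSE] -
                         matrix(zb[i, ], length(cand), 3, byrow = TRUE))^2))
    best <- cand[order(d, cohort_a$sample_id[cand])[1]]
    used_a[best] <- TRUE
    pair_a <- c(pair_a, cohort_a$sample_id[best])
    pair_b <- c(pair_b, cohort_b$sample_id[i])
  }
  if (length(pair_b) < n_pairs / 2) {
    stop("matched fewer than half the requested pairs (",
         length(pair_b), " of ", n_pairs, ")", call. = FALSE)
  }

  med_a <- apply(dataset_a$concentrations[pair_a, , drop = FALSE], 2,
                 median, na.rm = TRUE)
  med_b <- apply(dataset_b$concentrations[pair_b, , drop = FALSE], 2,
                 median, na.rm = TRUE)
  out <- new_correction_factors(colnames(dataset_a$concentrations),
                                med_a / med_b, "matched_subcohort")
  attr(out, "pairs") <- tibble::tibble(sample_a = pair_a, sample_b = pair_b)
  out
}

#' Apply correction factors to a dataset
#'
#' Reference factors divide (aligning the dataset to the consensus);
#' matched sub-cohort factors multiply (aligning cohort B to cohort A);
#' PQC batch factors divide within their batch.
#'
#' @param dataset A `lipidomics` object.
#' @param factors A `correction_factors` tibble covering every species.
#' @return The corrected `lipidomics` object, with the method recorded in
#'   attribute `correction_history`.
#' @export
apply_correction <- function(dataset, factors) {
  conc <- dataset$concentrations
  missing <- setdiff(colnames(conc), factors$species)
  if (length(missing)) {
    stop("no correction factor for: ", paste(head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  method <- factors$method[1]
  if (method == "pqc_batch") {
    for (b in unique(factors$batch)) {
      rows <- dataset$samples$sample_id[dataset$samples$batch == b]
      f <- factors[factors$batch == b, ]
      fac <- setNames(f$factor, f$species)[colnames(conc)]
      fac[is.na(fac)] <- 1
      conc[rows, ] <- sweep(conc[rows, , drop = FALSE], 2, fac, `/`)
    }
  } else {
    fac <- setNames(factors$factor, factors$species)[colnames(conc)]
    op <- if (method == "matched_subcohort") `*` else `/`
    conc <- sweep(conc, 2, fac, op)
  }
  out <- dataset
  out$concentrations <- conc
  attr(out, "correction_history") <- c(attr(dataset, "correction_history"), method)
  out
}

#' Pooled-QC median centering
#'
#' Per (species, batch), computes the factor median(PQC in batch) /
#' median(all PQC) and divides every sample in the batch by it, so that
#' after correction the per-batch PQC medians coincide with the global PQC
#' median. Batches whose PQC median is missing for a species are left
#' uncorrected for that species, with a warning.
#'
#' @param dataset A `lipidomics` object in which every batch has at least
#'   one pooled-QC sample.
#' @return The corrected `lipidomics` object.
#' @export
pqc_median_center <- function(dataset) {
  smp <- dataset$samples
  pqc_ids <- smp$sample_id[smp$is_pqc]
  batches <- unique(smp$batch)
  no_pqc <- setdiff(batches, unique(smp$batch[smp$is_pqc]))
  if (length(no_pqc)) {
    stop("batch without PQC samples: ", paste(no_pqc, collapse = ", "),
         call. = FALSE)
  }
  pqc <- dataset$concentrations[pqc_ids, , drop = FALSE]
  global_med <- apply(pqc, 2, median, na.rm = TRUE)
  rows <- list()
  n_skipped <- 0L
  for (b in batches) {
    in_b <- pqc_ids[smp$batch[match(pqc_ids, smp$sample_id)] == b]
    med_b <- apply(pqc[in_b, , drop = FALSE], 2, median, na.rm = TRUE)
    fac <- med_b / global_med
    bad <- !is.finite(fac) | fac <= 0
    n_skipped <- n_skipped + sum(bad)
    fac[bad] <- 1
    rows[[b]] <- new_correction_factors(colnames(pqc), fac, "pqc_batch", b)
  }
  if (n_skipped > 0) {
    warning(n_skipped, " (species, batch) cell(s) left uncorrected: ",
            "missing or degenerate PQC median", call. = FALSE)
  }
  factors <- dplyr::bind_rows(rows)
  class(factors) <- c("correction_factors", class(tibble::tibble()))
  apply_correction(dataset, factors)
}

#' Read/write correction factor tables
#'
#' @param factors A `correction_factors` tibble.
#' @param path File path (TSV with columns species, method, batch, factor).
#' @export
write_correction_factors <- function(factors, path) {
  readr::write_tsv(factors, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_correction_factors
#' @export
read_correction_factors <- function(path) {
  out <- read_delim_auto(path)
  out$batch <- as.character(out$batch)
  new_correction_factors(out$species, out$factor, out$method[1], out$batch)
}
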