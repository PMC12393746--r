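#' Class-level abundance sums
#'
#' Sums the member species of each lipid class per sample, and appends the
#' composite ether classes (`Total PE Ether` = PE(O) + PE(P),
#' `Total PC Ether` = PC(O) + PC(P)) where their parts exist. A class value
#' is missing only when every member is missing; otherwise missing members
#' contribute zero to the sum.
#'
#' @param dataset A `lipidomics` object with species-level columns.
#' @return A class-level `lipidomics` object (one column per class).
#' @export
class_sums <- function(dataset) {
  ann <- dataset$annotations[match(colnames(dataset$concentrations),
                                   dataset$annotations$species_name), ]
  classes <- unique(ann$class_code)
  groups <- c(setNames(lapply(classes, function(cl) {
    which(ann$class_code == cl)
  }), classes))
  for (hg in c("PE", "PC")) {
    parts <- which(ann$class_code %in% paste0(hg, c("(O)", "(P)")))
    if (length(parts)) groups[[paste("Total", hg, "Ether")]] <- parts
  }
  conc <- dataset$concentrations
  out <- vapply(groups, function(ix) {
    sub <- conc[, ix, drop = FALSE]
    s <- rowSums(sub, na.rm = TRUE)
    s[rowSums(!is.na(sub)) == 0] <- NA_real_
    s
  }, numeric(nrow(conc)))
  rownames(out) <- rownames(conc)
  lipidomics_dataset(out, parse_lipid_name(names(groups)), dataset$samples)
}

#' Standardized log2 lipid-ratio phenotypes
#'
#' For each ratio definition, the raw ratio is the sum of numerator member
#' concentrations over the sum of denominator members per sample; the ratio
#' is missing when the denominator is nonpositive or either side is wholly
#' missing. Ratios are then log2-transformed and scaled per column to zero
#' mean and unit (n-1) standard deviation over non-missing entries, with
#' the transform parameters stored for exact back-transformation.
#'
#' @param dataset A `lipidomics` object (species- or class-level; selectors
#'   are resolved against its own annotation table).
#' @param definitions Ratio definition tibble from
#'   [read_ratio_definitions()], or `NULL` to re-resolve the packaged table
#'   against `dataset`'s annotations.
#' @param samples Optional subset of sample ids to standardize within.
#' @return A `ratio_matrix` object: list with `values` (samples x ratios
#'   matrix of standardized log2 ratios), `transform_params` (tibble of
#'   per-ratio mean and sd of the log2 ratio) and `definitions`.
#' @export
compute_ratio_matrix <- function(dataset, definitions = NULL, samples = NULL) {
  if (is.null(definitions)) {
    definitions <- read_ratio_definitions(annotations = dataset$annotations)
  }
  conc <- dataset$concentrations
  if (!is.null(samples)) conc <- conc[samples, , drop = FALSE]
  conc_pos <- conc
  conc_pos[!is.na(conc_pos) & conc_pos <= 0] <- NA_real_  # log undefined

  side_sum <- function(members) {
    sub <- conc_pos[, members, drop = FALSE]
    s <- rowSums(sub, na.rm = TRUE)
    s[rowSums(!is.na(sub)) == 0] <- NA_real_
    s
  }
  raw <- vapply(seq_len(nrow(definitions)), function(i) {
    num <- side_sum(definitions$numerator_species[[i]])
    den <- side_sum(definitions$denominator_species[[i]])
    out <- num / den
    out[!is.na(den) & den <= 0] <- NA_real_
    out
  }, numeric(nrow(conc_pos)))
  colnames(raw) <- definitions$label
  rownames(raw) <- rownames(conc_pos)

  lograt <- log2(raw)
  mu <- apply(lograt, 2, mean, na.rm = TRUE)
  sdev <- apply(lograt, 2, sd, na.rm = TRUE)
  all_missing <- colSums(!is.na(lograt)) == 0
  if (any(all_missing)) {
    stop("ratio column(s) entirely missing: ",
         paste(definitions$label[all_missing], collapse = ", "), call. = FALSE)
  }
  degenerate <- !all_missing & (is.na(sdev) | sdev == 0)
  if (any(degenerate)) {
    stop("cannot standardize constant ratio column(s): ",
         paste(definitions$label[degenerate], collapse = ", "), call. = FALSE)
  }
  values <- sweep(sweep(lograt, 2, mu), 2, sdev, `/`)

  structure(
    list(values = values,
         transform_params = tibble::tibble(label = definitions$label,
                                           mean = unname(mu), sd = unname(sdev)),
         definitions = definitions),
    class = "ratio_matrix"
  )
}

#' @export
print.ratio_matrix <- function(x, ...) {
  cat("<ratio_matrix> ", nrow(x$values), " samples x ", ncol(x$values),
      " standardized log2 ratios\n", sep = "")
  invisible(x)
}

#' Back-transform standardized ratios to raw ratio scale
#'
#' @param x A `ratio_matrix`.
#' @return Matrix of raw (concentration-scale) ratios.
#' @export
back_transform <- function(x) {
  p <- x$transform_params
  2^sweep(sweep(x$values, 2, p$sd, `*`), 2, p$mean, `+`)
}

#' Tidy a ratio matrix into long form
#'
#' @param x A `ratio_matrix`.
#' @param ... Unused.
#' @return Tibble with sample_id, label, value.
#' @method tidy ratio_matrix
#' @export
tidy.ratio_matrix <- function(x, ...) {
  tibble::tibble(
    sample_id = rep(rownames(x$values), times = ncol(x$values)),
    label = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values)
  )
}

#' Write a ratio matrix with its transform parameters
#'
#' @param x A `ratio_matrix`.
#' @param path Output TSV for the standardized values.
#' @param params_path Output TSV for per-ratio transform parameters.
#' @export
write_ratio_matrix <- function(x, path, params_path = NULL) {
  tab <- tibble::as_tibble(x$values, .name_repair = "minimal")
  tab <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(x$values)), tab)
  readr::write_tsv(tab, path, progress = FALSE)
  if (!is.null(params_path)) {
    readr::write_tsv(x$transform_params, params_path, progress = FALSE)
  }
  invisible(path)
}
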