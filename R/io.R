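read_delim_auto <- function(path, ...) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::read_delim(path, delim = delim, comment = "#", na = c("", "NA"),
                    show_col_types = FALSE, progress = FALSE, ...)
}

#' Read a lipid concentration table
#'
#' Reads a delimited text file (TSV, or CSV by extension) with a header row
#' of species names and sample ids in the first column, together with a
#' species annotation table. Negative cells violate the nonnegativity
#' invariant and are set to missing with a warning.
#'
#' @param path Path to the concentration table.
#' @param annotation_path Path to the annotation TSV
#'   (columns `species`, `class`, `linkage`, `sn1`, `sn2`, `omega`, `tags`),
#'   or `NULL` to derive annotations by parsing the species names.
#' @param sample_path Optional path to a sample metadata TSV with columns
#'   `sample_id`, `batch`, `is_pqc`, `is_reference`.
#' @return A [lipidomics_dataset()] object.
#' @export
read_lipidomics <- function(path, annotation_path = NULL, sample_path = NULL) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  # base parser: correctly rounded doubles, so write/read is bit-exact
  tab <- utils::read.delim(path, sep = delim, check.names = FALSE,
                           comment.char = "#", na.strings = c("", "NA"))
  ids <- as.character(tab[[1]])
  conc <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(conc) <- "double"
  rownames(conc) <- ids

  n_neg <- sum(conc < 0, na.rm = TRUE)
  if (n_neg > 0) {
    warning(n_neg, " negative concentration value(s) set to missing",
            call. = FALSE)
    conc[!is.na(conc) & conc < 0] <- NA_real_
  }

  annotations <- if (is.null(annotation_path)) {
    parse_lipid_name(colnames(conc))
  } else {
    read_lipid_annotations(annotation_path)
  }
  unmatched <- setdiff(colnames(conc), annotations$species_name)
  if (length(unmatched)) {
    stop("species in header but not in annotations: ",
         paste(unmatched, collapse = ", "), call. = FALSE)
  }

  samples <- if (is.null(sample_path)) NULL else {
    dplyr::mutate(read_delim_auto(sample_path),
                  sample_id = as.character(.data$sample_id),
                  is_pqc = as.logical(.data$is_pqc),
                  is_reference = as.logical(.data$is_reference))
  }
  lipidomics_dataset(conc, annotations, samples)
}

#' Write a lipidomics dataset to delimited text
#'
#' Concentrations are written with 17 significant digits so that a
#' write/read round trip is value-exact; missing values are empty cells.
#'
#' @param dataset A `lipidomics` object.
#' @param path Output path for the concentration table.
#' @param annotation_path,sample_path Optional output paths for the
#'   annotation and sample-metadata sidecars.
#' @return `path`, invisibly.
#' @export
write_lipidomics <- function(dataset, path, annotation_path = NULL,
                             sample_path = NULL) {
  conc <- dataset$concentrations
  body <- apply(conc, 2, function(col) {
    ifelse(is.na(col), "", sprintf("%.17g", col))
  })
  if (is.null(dim(body))) body <- matrix(body, nrow = nrow(conc))
  lines <- c(
    paste(c("sample_id", colnames(conc)), collapse = "\t"),
    vapply(seq_len(nrow(conc)), function(i) {
      paste(c(rownames(conc)[i], body[i, ]), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  if (!is.null(annotation_path)) {
    write_lipid_annotations(dataset$annotations, annotation_path)
  }
  if (!is.null(sample_path)) {
    readr::write_tsv(dataset$samples, sample_path, progress = FALSE)
  }
  invisible(path)
}

#' Read and write species annotation tables
#'
#' The annotation TSV has columns `species`, `class`, `linkage`, `sn1`,
#' `sn2`, `omega`, `tags` (semicolon-separated free-form tags).
#'
#' @param path File path.
#' @return For the reader, a tibble in the same layout as
#'   [parse_lipid_name()] output.
#' @export
read_lipid_annotations <- function(path) {
  tab <- read_delim_auto(path)
  parsed <- parse_lipid_name(tab$species)
  stored_class <- as.character(tab$class)
  if (!all(parsed$class_code == stored_class)) {
    bad <- tab$species[parsed$class_code != stored_class]
    stop("annotation class disagrees with parsed name for: ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  parsed
}

#' @rdname read_lipid_annotations
#' @param annotations Annotation tibble to write.
#' @export
write_lipid_annotations <- function(annotations, path) {
  out <- tibble::tibble(
    species = annotations$species_name,
    class = annotations$class_code,
    linkage = annotations$linkage,
    sn1 = annotations$sn1_chain,
    sn2 = annotations$sn2_chain,
    omega = annotations$omega_series,
    tags = vapply(annotations$feature_tags, paste, character(1),
                  collapse = ";")
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a ratio definition table
#'
#' Reads a TSV with columns `label`, `numerator`, `denominator`,
#' `annotation`, `provenance` and resolves the numerator/denominator
#' selectors to concrete species sets against an annotation table. Class
#' selectors (e.g. `"PE(P)"`) expand to all annotated members and
#' `"Total PE Ether"` to the union of PE(O) and PE(P); resolved sides must
#' be non-empty and disjoint.
#'
#' @param path Path to the definition TSV, or `NULL` for the packaged
#'   82-ratio table.
#' @param annotations Species annotation tibble to resolve against; default
#'   is the packaged synthetic lipidome annotation set.
#' @return A tibble with list-columns `numerator_species` and
#'   `denominator_species` appended.
#' @export
read_ratio_definitions <- function(path = NULL, annotations = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "lipid_ratios.tsv", package = "lipidratio",
                        mustWork = TRUE)
  }
  if (is.null(annotations)) annotations <- default_lipidome_annotations()
  defs <- read_delim_auto(path)
  required <- c("label", "numerator", "denominator", "annotation", "provenance")
  missing_cols <- setdiff(required, names(defs))
  if (length(missing_cols)) {
    stop("ratio table missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(defs$label)) {
    stop("duplicate ratio labels: ",
         paste(unique(defs$label[duplicated(defs$label)]), collapse = ", "),
         call. = FALSE)
  }
  defs$numerator_species <- resolve_selector(defs$numerator, annotations)
  defs$denominator_species <- resolve_selector(defs$denominator, annotations)
  overlap <- purrr::map2_lgl(defs$numerator_species, defs$denominator_species,
                             ~ length(intersect(.x, .y)) > 0)
  if (any(overlap)) {
    stop("numerator and denominator overlap for: ",
         paste(defs$label[overlap], collapse = ", "), call. = FALSE)
  }
  defs
}
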