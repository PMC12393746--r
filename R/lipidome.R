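#' Construct a lipidomics dataset
#'
#' Bundles a samples-by-species concentration matrix with species
#' annotations and per-sample technical metadata (batch, pooled-QC flag,
#' reference-plasma flag). Concentrations are relative abundances;
#' missing values are `NA`; all present values must be nonnegative.
#'
#' @param concentrations Numeric matrix, samples in rows (rownames are
#'   sample ids), species in columns (colnames are species names).
#' @param annotations Tibble of species annotations as returned by
#'   [parse_lipid_name()], one row per species column.
#' @param samples Tibble with columns `sample_id`, `batch`, `is_pqc`,
#'   `is_reference`. Defaults to a single-batch study with no QC samples.
#' @return An object of class `lipidomics`.
#' @export
lipidomics_dataset <- function(concentrations, annotations, samples = NULL) {
  stopifnot(is.matrix(concentrations), is.numeric(concentrations))
  if (is.null(rownames(concentrations)) || is.null(colnames(concentrations))) {
    stop("concentration matrix needs sample rownames and species colnames",
         call. = FALSE)
  }
  if (is.null(samples)) {
    samples <- tibble::tibble(
      sample_id = rownames(concentrations),
      batch = "batch1", is_pqc = FALSE, is_reference = FALSE
    )
  }
  validate_lipidomics(concentrations, annotations, samples)
  structure(
    list(concentrations = concentrations, annotations = annotations,
         samples = samples),
    class = "lipidomics"
  )
}

validate_lipidomics <- function(conc, annotations, samples) {
  ids <- rownames(conc)
  if (anyDuplicated(ids)) {
    stop("duplicate sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(conc))) {
    stop("duplicate species ids: ",
         paste(unique(colnames(conc)[duplicated(colnames(conc))]),
               collapse = ", "), call. = FALSE)
  }
  if (!identical(sort(ids), sort(samples$sample_id))) {
    stop("sample metadata does not match concentration matrix rows",
         call. = FALSE)
  }
  missing_ann <- setdiff(colnames(conc), annotations$species_name)
  if (length(missing_ann)) {
    stop("species missing from annotations: ",
         paste(head(missing_ann, 5), collapse = ", "), call. = FALSE)
  }
  if (any(conc < 0, na.rm = TRUE)) {
    stop("negative concentrations present", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.lipidomics <- function(x, ...) {
  cat("<lipidomics> ", nrow(x$concentrations), " samples x ",
      ncol(x$concentrations), " species (",
      dplyr::n_distinct(x$annotations$class_code[
        match(colnames(x$concentrations), x$annotations$species_name)]),
      " classes); ", sum(x$samples$is_pqc), " PQC, ",
      sum(x$samples$is_reference), " reference samples\n", sep = "")
  invisible(x)
}

#' Tidy a lipidomics dataset into long form
#'
#' @param x A `lipidomics` object.
#' @param ... Unused.
#' @return A tibble with one row per (sample, species) measurement.
#' @method tidy lipidomics
#' @export
tidy.lipidomics <- function(x, ...) {
  conc <- x$concentrations
  out <- tibble::tibble(
    sample_id = rep(rownames(conc), times = ncol(conc)),
    species_name = rep(colnames(conc), each = nrow(conc)),
    concentration = as.vector(conc)
  )
  out <- dplyr::left_join(
    out,
    dplyr::select(x$annotations, "species_name", "class_code", "linkage"),
    by = "species_name"
  )
  dplyr::left_join(out, x$samples, by = "sample_id")
}

#' Species class membership lookup
#'
#' Resolves a selector (a species name, a class code such as `"PE(P)"`, or a
#' composite such as `"Total PE Ether"`) to the concrete species it covers.
#'
#' @param selector Character vector of selectors; elements may also be
#'   semicolon-separated lists.
#' @param annotations Species annotation tibble.
#' @return A list of character vectors, one per selector.
#' @export
resolve_selector <- function(selector, annotations) {
  lapply(selector, function(sel) {
    items <- trimws(strsplit(sel, ";", fixed = TRUE)[[1]])
    out <- unlist(lapply(items, function(item) {
      if (item %in% annotations$species_name &&
          !item %in% setdiff(annotations$class_code, annotations$species_name)) {
        return(item)
      }
      if (grepl("^Total\\s+(\\S+)\\s+Ether$", item)) {
        hg <- sub("^Total\\s+(\\S+)\\s+Ether$", "\\1", item)
        hits <- annotations$species_name[
          annotations$class_code %in% paste0(hg, c("(O)", "(P)"))]
        if (!length(hits)) stop("selector '", item, "' resolves to no species",
                                call. = FALSE)
        return(hits)
      }
      hits <- annotations$species_name[annotations$class_code == item]
      if (!length(hits)) {
        stop("selector '", item, "' resolves to no species", call. = FALSE)
      }
      hits
    }))
    unique(out)
  })
}
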