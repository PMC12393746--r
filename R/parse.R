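#' Parse lipid shorthand nomenclature
#'
#' Turns shorthand species or class names such as `"PE(P-16:0/20:4)"`,
#' `"LPC(22:5) [sn2]"` or `"Total PE Ether"` into a structured annotation
#' row. The grammar is: a headgroup token, an optional `(O-`/`(P-` ether
#' marker, chains written `carbons:doublebonds` separated by `/` (known
#' sn-positions) or `_` (unknown), and optional bracketed tags
#' (`[sn1]`, `[sn2]`, `[n3]`, `[n6]`, ...). A `(P)` marker denotes a
#' vinyl-ether (alkenyl, plasmalogen) sn-1 linkage, `(O)` an alkyl ether,
#' otherwise the species is ester-linked (acyl).
#'
#' @param name Character vector of shorthand lipid names.
#' @return A tibble with one row per name and columns `species_name`,
#'   `class_code`, `headgroup`, `linkage` (`acyl`/`alkyl`/`alkenyl`),
#'   `sn1_chain`, `sn2_chain`, `chain_sep`, `omega_series`
#'   (`n-3`/`n-6`/`none`), `composite` (e.g. "Total PE Ether"),
#'   and a list-column `feature_tags`.
#' @examples
#' parse_lipid_name(c("PE(P-16:0/20:4)", "PC", "LPC(22:5) [sn2]"))
#' @export
parse_lipid_name <- function(name) {
  stopifnot(is.character(name), all(nzchar(name)))
  rows <- lapply(name, parse_one_lipid)
  dplyr::bind_rows(rows)
}

parse_one_lipid <- function(name) {
  raw <- name
  x <- trimws(name)

  # bracketed feature tags, e.g. "[sn2]", "[n3]"
  tags <- character(0)
  while (grepl("\\[[^][]*\\]\\s*$", x)) {
    tag <- sub("^.*\\[([^][]*)\\]\\s*$", "\\1", x)
    tags <- c(tag, tags)
    x <- trimws(sub("\\s*\\[[^][]*\\]\\s*$", "", x))
  }
  if (grepl("[][]", x)) {
    stop("malformed lipid name '", raw, "': unbalanced square bracket", call. = FALSE)
  }

  composite <- grepl("^Total\\s+\\S+\\s+Ether$", x)
  if (composite) {
    headgroup <- sub("^Total\\s+(\\S+)\\s+Ether$", "\\1", x)
    return(annotation_row(raw, class_code = x, headgroup = headgroup,
                          linkage = "acyl", composite = TRUE, tags = tags))
  }

  n_open <- lengths(regmatches(x, gregexpr("\\(", x)))
  n_close <- lengths(regmatches(x, gregexpr("\\)", x)))
  if (n_open != n_close) {
    stop("malformed lipid name '", raw, "': unbalanced parentheses", call. = FALSE)
  }

  if (!grepl("\\(", x)) {
    if (!grepl("^[A-Za-z][A-Za-z0-9]*$", x)) {
      stop("malformed lipid name '", raw, "': unrecognized token '", x, "'",
           call. = FALSE)
    }
    return(annotation_row(raw, class_code = x, headgroup = x,
                          linkage = "acyl", tags = tags))
  }

  headgroup <- sub("^([A-Za-z][A-Za-z0-9]*)\\(.*$", "\\1", x)
  inner <- sub("^[A-Za-z][A-Za-z0-9]*\\((.*)\\)$", "\\1", x)
  if (identical(inner, x)) {
    stop("malformed lipid name '", raw, "': cannot isolate parenthesized part",
         call. = FALSE)
  }

  marker <- NA_character_
  if (inner %in% c("O", "P")) {
    marker <- inner
    inner <- ""
  } else if (grepl("^[OP]-", inner)) {
    marker <- substr(inner, 1, 1)
    inner <- substring(inner, 3)
  }

  linkage <- switch(ifelse(is.na(marker), "none", marker),
                    P = "alkenyl", O = "alkyl", none = "acyl")
  class_code <- if (is.na(marker)) headgroup else paste0(headgroup, "(", marker, ")")

  sn1 <- NA_character_
  sn2 <- NA_character_
  sep <- NA_character_
  if (nzchar(inner)) {
    sep <- if (grepl("_", inner)) "_" else "/"
    chains <- strsplit(inner, "[/_]")[[1]]
    if (length(chains) > 3) {
      stop("malformed lipid name '", raw, "': too many chains in '", inner, "'",
           call. = FALSE)
    }
    for (ch in chains) {
      if (!grepl("^[0-9]+:[0-9]+$", ch)) {
        stop("malformed lipid name '", raw, "': non-numeric chain token '",
             ch, "'", call. = FALSE)
      }
    }
    if (length(chains) == 1) {
      # single chain: ether marker or [sn1] tag puts it at sn-1; [sn2] at sn-2
      if (any(grepl("^sn-?2$", tags)) && is.na(marker)) sn2 <- chains[[1]]
      else sn1 <- chains[[1]]
      sep <- NA_character_
    } else {
      sn1 <- chains[[1]]
      sn2 <- chains[[2]]
    }
  }

  omega <- "none"
  if (any(grepl("^n-?3$", tags))) omega <- "n-3"
  if (any(grepl("^n-?6$", tags))) omega <- "n-6"

  annotation_row(raw, class_code = class_code, headgroup = headgroup,
                 linkage = linkage, sn1 = sn1, sn2 = sn2, sep = sep,
                 omega = omega, tags = tags)
}

annotation_row <- function(raw, class_code, headgroup, linkage,
                           sn1 = NA_character_, sn2 = NA_character_,
                           sep = NA_character_, omega = "none",
                           composite = FALSE, tags = character(0)) {
  tibble::tibble(
    species_name = raw,
    class_code = class_code,
    headgroup = headgroup,
    linkage = linkage,
    sn1_chain = sn1,
    sn2_chain = sn2,
    chain_sep = sep,
    omega_series = omega,
    composite = composite,
    feature_tags = list(tags)
  )
}

#' Render an annotation back to shorthand
#'
#' Inverse of [parse_lipid_name()]: `parse -> render -> parse` is a fixed
#' point for every name the packaged grammar covers.
#'
#' @param annotation A tibble as returned by [parse_lipid_name()].
#' @return Character vector of shorthand names.
#' @export
render_lipid_name <- function(annotation) {
  purrr::pmap_chr(annotation, function(class_code, headgroup, linkage,
                                       sn1_chain, sn2_chain, chain_sep,
                                       composite, feature_tags, ...) {
    if (isTRUE(composite)) {
      base <- class_code
    } else {
      marker <- if (linkage == "alkenyl") "P" else if (linkage == "alkyl") "O" else NA
      chains <- c(sn1_chain, sn2_chain)
      chains <- chains[!is.na(chains)]
      if (length(chains) == 0) {
        base <- if (is.na(marker)) headgroup else paste0(headgroup, "(", marker, ")")
      } else {
        body <- paste(chains, collapse = if (is.na(chain_sep)) "/" else chain_sep)
        inner <- if (is.na(marker)) body else paste0(marker, "-", body)
        base <- paste0(headgroup, "(", inner, ")")
      }
    }
    if (length(feature_tags)) {
      base <- paste0(base, paste0(" [", feature_tags, "]", collapse = ""))
    }
    base
  })
}
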