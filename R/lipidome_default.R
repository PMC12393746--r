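# Canonical synthetic plasma lipidome: 735 species across 39 classes,
# matching the panel size of a targeted plasma lipidomics assay. Species
# names follow the packaged shorthand grammar; the triacylglycerol class
# absorbs the residual count so the totals are exact by construction.

# sn-2 acyls of the ether phospholipid grid; 22:5 occurs as separately
# measured n-3 and n-6 positional isomers, so it carries an omega tag
species_ether <- function(headgroup, marker, sn1s) {
  sn2 <- c("18:1", "18:2", "18:3", "20:3", "20:4", "20:5", "22:4",
           "22:5", "22:5", "22:6")
  tag <- c(NA, NA, NA, NA, NA, NA, NA, "n3", "n6", NA)
  unlist(lapply(sn1s, function(s1) {
    nm <- sprintf("%s(%s-%s/%s)", headgroup, marker, s1, sn2)
    ifelse(is.na(tag), nm, paste0(nm, " [", tag, "]"))
  }))
}

species_ether_single <- function(headgroup, marker, chains) {
  sprintf("%s(%s-%s)", headgroup, marker, chains)
}

species_diacyl <- function(headgroup, sn1s, sn2s) {
  as.vector(outer(sn1s, sn2s, function(a, b) {
    sprintf("%s(%s_%s)", headgroup, a, b)
  }))
}

species_single <- function(headgroup, chains, tag = NULL) {
  base <- sprintf("%s(%s)", headgroup, chains)
  if (is.null(tag)) base else paste0(base, " [", tag, "]")
}

#' Default synthetic lipidome annotations
#'
#' Builds the annotation table for the packaged synthetic plasma lipidome:
#' 735 lipid species across 39 classes, including the ether-lipid classes
#' (alkyl `(O)` and alkenyl/plasmalogen `(P)` phosphatidylethanolamine and
#' phosphatidylcholine, their lyso forms, and alkyl-triacylglycerol), the
#' major phospholipid, sphingolipid, glycerolipid and sterol classes, and
#' sn-resolved lyso-phospholipids. All species names referenced by the
#' packaged ratio table are present.
#'
#' @return A tibble as returned by [parse_lipid_name()], 735 rows.
#' @export
default_lipidome_annotations <- function() {
  acyl10 <- c("16:0", "18:1", "18:2", "18:3", "20:3", "20:4", "20:5",
              "22:4", "22:5", "22:6")
  lyso_all <- c("14:0", "15:0", "16:1", "17:0", "18:3", "20:3", "20:5",
                "22:1", "24:0")
  lyso_sn1 <- c("16:0", "18:0", "18:1")
  lyso_sn2 <- c("16:0", "18:0", "18:1", "18:2", "20:4", "22:4", "22:5", "22:6")
  sterol_acyls <- c("14:0", "15:0", "16:0", "16:1", "17:0", "18:0", "18:1",
                    "18:2", "18:3", "20:0", "20:3", "20:4", "20:5", "22:0",
                    "22:4", "22:5", "22:6", "24:0", "24:1", "24:6")
  sm_comps <- c("32:1", "32:2", "33:1", "34:0", "34:1", "34:2", "35:1",
                "35:2", "36:1", "36:2", "36:3", "37:1", "38:1", "38:2",
                "38:3", "39:1", "40:1", "40:2", "40:3", "41:1", "41:2",
                "42:1", "42:2", "42:3", "43:1", "43:2", "44:1", "44:2",
                "45:1", "46:1")
  cer_sn2 <- c("16:0", "18:0", "20:0", "22:0", "22:1", "23:0", "24:0",
               "24:1", "25:0", "26:0", "26:1", "18:1")

  names_by_class <- list(
    # glycerophospholipids
    species_diacyl("PC", c("14:0", "15:0", "16:0", "16:1", "17:0", "18:0",
                           "18:1"), acyl10),                          # 70
    species_diacyl("PE", c("16:0", "17:0", "18:0", "18:1"), acyl10),  # 40
    species_diacyl("PS", lyso_sn1, acyl10),                           # 30
    species_diacyl("PI", lyso_sn1, acyl10),                           # 30
    species_diacyl("PG", lyso_sn1, c("16:0", "18:1", "18:2", "18:3",
                                     "20:3", "20:4", "20:5", "22:6")), # 24
    species_diacyl("PA", lyso_sn1, c("18:1", "18:2", "20:4", "22:6")), # 12
    # ether lipids
    species_ether("PE", "P", c("16:0", "16:1", "18:0", "18:1")),      # 40
    species_ether("PE", "O", c("16:0", "16:1", "18:0", "18:1")),      # 40
    species_ether("PC", "P", c("16:0", "17:0", "18:0", "18:1")),      # 40
    species_ether("PC", "O", c("16:0", "17:0", "18:0", "18:1")),      # 40
    # lyso-phospholipids (sn-resolved where the assay separates isomers)
    c(species_single("LPC", lyso_all),
      species_single("LPC", lyso_sn1, "sn1"),
      species_single("LPC", lyso_sn2, "sn2")),                        # 20
    c(species_single("LPE", lyso_all[1:7]),
      species_single("LPE", lyso_sn1, "sn1"),
      species_single("LPE", lyso_sn2, "sn2")),                        # 18
    species_ether_single("LPC", "O", c("16:0", "16:1", "18:0", "18:1", "20:0",
                                       "22:0", "22:1", "24:1", "24:2", "26:0")),
    species_ether_single("LPC", "P", c("16:0", "16:1", "18:0", "18:1", "20:0",
                                       "20:1", "22:0", "22:1", "24:1", "24:2")),
    species_ether_single("LPE", "P", c("16:0", "16:1", "18:0", "18:1", "20:0",
                                       "20:1", "22:1", "24:2")),
    species_single("LPI", c("16:0", "18:0", "18:1", "18:2", "20:3", "20:4",
                            "20:5", "22:6")),                          # 8
    species_single("LPS", c("16:0", "18:0", "18:1", "18:2", "20:4", "22:6")),
    species_single("LPG", c("16:0", "18:0", "18:1", "18:2", "20:4", "22:6")),
    # sphingolipids
    species_single("SM", sm_comps),                                    # 30
    species_single("dhSM", c("32:0", "34:0", "36:0", "38:0", "40:0", "42:0",
                             "44:0", "46:0")),                         # 8
    species_diacyl("Cer", "18:1", cer_sn2),                            # 12
    species_diacyl("dhCer", "18:0", cer_sn2[1:8]),                     # 8
    species_diacyl("CerP", "18:1", c("16:0", "18:0", "20:0", "24:0", "24:1")),
    species_diacyl("HexCer", "18:1", cer_sn2[1:10]),                   # 10
    species_diacyl("Hex2Cer", "18:1", c("16:0", "18:0", "20:0", "22:0",
                                        "24:0", "24:1")),              # 6
    species_diacyl("Hex3Cer", "18:1", c("16:0", "18:0", "20:0", "22:0",
                                        "24:0", "24:1")),              # 6
    species_diacyl("GM1", "18:1", c("16:0", "18:0", "20:0", "24:0", "24:1")),
    species_diacyl("GM2", "18:1", c("16:0", "18:0", "20:0", "24:0", "24:1")),
    species_diacyl("GM3", "18:1", c("16:0", "18:0", "20:0", "22:0", "23:0",
                                    "24:0", "24:1", "26:1")),          # 8
    species_diacyl("GD3", "18:1", c("16:0", "18:0", "20:0", "24:0", "24:1")),
    # glycerolipids and sterols
    species_diacyl("DG", c("16:0", "16:1", "18:0", "18:1", "18:2"),
                   c("18:1", "18:2", "20:4")),                         # 15
    species_single("MG", c("16:0", "18:0", "18:1", "18:2", "20:4")),   # 5
    species_ether_single("TG", "O", c("48:0", "48:1", "48:2", "50:0", "50:1",
                                      "50:2", "50:3", "52:1", "52:2", "52:3",
                                      "52:4", "52:5", "54:2", "54:3", "54:4",
                                      "54:5", "56:3", "56:4", "56:5", "56:6")),
    species_single("CE", c(sterol_acyls, "18:4", "20:1")),             # 22
    "COH",                                                             # 1
    species_single("DE", c("18:1", "18:2", "20:4", "22:6")),           # 4
    species_single("FFA", sterol_acyls),                               # 20
    species_single("AC", c("12:0", "14:0", "16:0", "16:1", "18:0", "18:1",
                           "18:2", "20:0", "20:4", "26:0"))            # 10
  )

  curated <- unlist(names_by_class)
  n_tg <- 735L - length(curated)
  if (n_tg < 20L) stop("internal: curated lipidome leaves too few TG slots")
  tg_comps <- as.vector(t(outer(seq(44, 60, by = 2), 0:8, function(cc, db) {
    sprintf("%d:%d", cc, db)
  })))
  tg_nl <- c("NL-16:0", "NL-18:1", "NL-18:2")
  tg_candidates <- as.vector(t(outer(tg_comps, tg_nl, function(comp, nl) {
    sprintf("TG(%s) [%s]", comp, nl)
  })))
  all_names <- c(curated, tg_candidates[seq_len(n_tg)])

  ann <- parse_lipid_name(all_names)
  stopifnot(nrow(ann) == 735L,
            dplyr::n_distinct(ann$class_code) == 39L,
            !anyDuplicated(ann$species_name))
  ann
}
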