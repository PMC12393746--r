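#' Pipeline configuration
#'
#' Declarative configuration for [run_pipeline()]: a synthetic study block
#' (or input paths), stage toggles, outcomes, and the output directory.
#'
#' @param simulate A [synthetic_config()] describing the study to generate,
#'   or `NULL` to read inputs from `paths`.
#' @param paths Named list of input paths when `simulate` is `NULL`:
#'   `lipidomics_a`, `samples_a`, `cohort_a`, `lipidomics_b`, `samples_b`,
#'   `cohort_b`, `consensus`, `vcf`.
#' @param stages Stages to run, in pipeline order.
#' @param outcomes Obesity outcomes for the association stage.
#' @param gwas_ratio Ratio label for the GWAS stage.
#' @param gwas_chromosomes Chromosomes to test (`NULL` for all).
#' @param n_pairs Matched pairs for cohort alignment.
#' @param n_pcs Number of genomic PCs.
#' @param seed Master seed, recorded in every output header.
#' @param outdir Output directory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = synthetic_config(), paths = NULL,
                            stages = c("simulate", "harmonize", "ratios",
                                       "assoc", "lsea", "gwas"),
                            outcomes = "WC", gwas_ratio = "PC(O)/PC(P)",
                            gwas_chromosomes = NULL, n_pairs = 1000L,
                            n_pcs = 10L, seed = 1L, outdir = tempfile("lipidratio_")) {
  if (is.null(simulate)) {
    needed <- c("lipidomics_a", "cohort_a")
    missing_paths <- needed[!needed %in% names(paths)]
    if (length(missing_paths)) {
      stop("simulate is off and input paths are missing: ",
           paste(missing_paths, collapse = ", "), call. = FALSE)
    }
    gone <- unlist(paths)[!file.exists(unlist(paths))]
    if (length(gone)) {
      stop("input path(s) do not exist: ", paste(gone, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(list(simulate = simulate, paths = paths, stages = stages,
                 outcomes = outcomes, gwas_ratio = gwas_ratio,
                 gwas_chromosomes = gwas_chromosomes, n_pairs = n_pairs,
                 n_pcs = n_pcs, seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

write_stage_tsv <- function(tab, path, config, params = "") {
  header <- sprintf("# lipidratio %s; seed=%d%s",
                    as.character(utils::packageVersion("lipidratio")),
                    config$seed,
                    if (nzchar(params)) paste0("; ", params) else "")
  writeLines(header, path)
  readr::write_tsv(tab, path, append = TRUE, col_names = TRUE, progress = FALSE)
  path
}

flatten_assoc <- function(assoc) {
  flat <- dplyr::select(assoc, -dplyr::any_of("components"))
  sides <- purrr::map_dfr(assoc$components, function(comp) {
    num <- comp[comp$side == "numerator", ]
    den <- comp[comp$side == "denominator", ]
    tibble::tibble(num_beta = num$beta, num_p = num$p, num_p_bh = num$p_bh,
                   den_beta = den$beta, den_p = den$p, den_p_bh = den$p_bh)
  })
  dplyr::bind_cols(flat, sides)
}

#' Run the analysis pipeline end to end
#'
#' Stage order mirrors the analysis workflow: simulate (or load) the
#' two-cohort study, harmonize (PQC median centering, then reference-plasma
#' correction for cohort A and matched sub-cohort alignment of cohort B),
#' compute ratio phenotypes, run ratio-obesity associations with p-gains,
#' lipid-set enrichment, and the mixed-model GWAS. Every output TSV carries
#' a commented header with the package version and seed; identical config
#' and seed reproduce byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return A manifest tibble (stage, file, rows, md5), invisibly the full
#'   result list in attribute `results`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  results <- list()
  emit <- function(stage, name, tab, params = "") {
    path <- file.path(config$outdir, name)
    write_stage_tsv(tab, path, config, params)
    manifest[[length(manifest) + 1]] <<- tibble::tibble(
      stage = stage, file = name, rows = nrow(tab),
      md5 = unname(tools::md5sum(path)))
  }
  stage_on <- function(s) s %in% config$stages

  run_gwas <- stage_on("gwas")
  if (stage_on("simulate")) {
    # genotypes are simulated whenever configured so that toggling the GWAS
    # stage never perturbs upstream draws
    study <- simulate_study(config$simulate, config$seed,
                            genotypes = !is.null(config$simulate$genetics))
  } else {
    study <- load_study_inputs(config$paths)
  }
  results$study <- study
  if (stage_on("simulate")) {
    emit("simulate", "lipidomics_a.tsv",
         tibble::as_tibble(study$cohort_a$lipidomics$concentrations,
                           rownames = "sample_id"))
    emit("simulate", "cohort_a.tsv", study$cohort_a$cohort)
    emit("simulate", "cohort_b.tsv", study$cohort_b$cohort)
    if (!is.null(study$genotypes)) {
      vcf_path <- file.path(config$outdir, "genotypes.vcf")
      write_vcf(study$genotypes, vcf_path)
      manifest[[length(manifest) + 1]] <- tibble::tibble(
        stage = "simulate", file = "genotypes.vcf",
        rows = nrow(study$genotypes$variants),
        md5 = unname(tools::md5sum(vcf_path)))
    }
  }

  ds_a <- study$cohort_a$lipidomics
  ds_b <- study$cohort_b$lipidomics
  if (stage_on("harmonize")) {
    ds_a <- pqc_median_center(ds_a)
    ds_b <- pqc_median_center(ds_b)
    ref_fac <- reference_correction_factors(ds_a, study$consensus)
    ds_a <- apply_correction(ds_a, ref_fac)
    match_fac <- matched_subcohort_factors(ds_a, study$cohort_a$cohort,
                                           ds_b, study$cohort_b$cohort,
                                           config$n_pairs)
    ds_b <- apply_correction(ds_b, match_fac)
    emit("harmonize", "correction_factors.tsv",
         dplyr::bind_rows(ref_fac, match_fac))
  }
  results$dataset_a <- ds_a
  results$dataset_b <- ds_b

  defs <- read_ratio_definitions(annotations = ds_a$annotations)
  if (stage_on("ratios")) {
    bio_a <- ds_a$samples$sample_id[!ds_a$samples$is_pqc &
                                      !ds_a$samples$is_reference]
    ratios_a <- compute_ratio_matrix(ds_a, defs, samples = bio_a)
    results$ratios_a <- ratios_a
    emit("ratios", "ratio_matrix_a.tsv",
         tibble::as_tibble(ratios_a$values, rownames = "sample_id"))
    emit("ratios", "ratio_params_a.tsv", ratios_a$transform_params)
  }

  if (stage_on("assoc")) {
    results$assoc <- lapply(setNames(config$outcomes, config$outcomes),
                            function(oc) {
      assoc <- associate_ratios(ds_a, study$cohort_a$cohort, oc, defs)
      emit("assoc", sprintf("associations_%s.tsv", oc), flatten_assoc(assoc),
           params = paste0("outcome=", oc))
      assoc
    })
  }

  if (stage_on("lsea")) {
    enr <- lsea(ds_a, study$cohort_a$cohort, config$outcomes[1])
    results$lsea <- enr
    emit("lsea", "enrichment.tsv", enr)
  }

  if (run_gwas && !is.null(study$genotypes)) {
    geno <- study$genotypes
    ids_b <- intersect(study$cohort_b$cohort$sample_id, rownames(geno$dosage))
    ratios_b <- compute_ratio_matrix(ds_b, defs, samples = ids_b)
    lbl <- config$gwas_ratio
    if (!lbl %in% colnames(ratios_b$values)) {
      stop("gwas_ratio '", lbl, "' is not a defined ratio", call. = FALSE)
    }
    pruned <- ld_prune(geno)
    pcs <- genotype_pcs(geno, config$n_pcs, samples = ids_b,
                        variants = pruned)
    def <- defs[defs$label == lbl, ]
    comp <- standardized_component_matrix(ds_b, def, samples = ids_b)
    phen <- function(v) prepare_phenotype(v, study$cohort_b$cohort, pcs)
    y_ratio <- phen(setNames(ratios_b$values[, lbl], rownames(ratios_b$values)))
    y_num <- phen(setNames(comp$matrix[, comp$map$component[
      comp$map$side == "numerator"]], rownames(comp$matrix)))
    y_den <- phen(setNames(comp$matrix[, comp$map$component[
      comp$map$side == "denominator"]], rownames(comp$matrix)))

    gr <- lmm_gwas(y_ratio, geno, chromosomes = config$gwas_chromosomes)
    ga <- lmm_gwas(y_num, geno, chromosomes = config$gwas_chromosomes)
    gb <- lmm_gwas(y_den, geno, chromosomes = config$gwas_chromosomes)
    pg <- snp_p_gain(gr, ga, gb)
    results$gwas <- list(ratio = gr, numerator = ga, denominator = gb,
                         p_gain = pg)
    emit("gwas", "gwas_ratio.tsv", gr, params = paste0("ratio=", lbl))
    emit("gwas", "gwas_p_gain.tsv", pg, params = paste0("ratio=", lbl))
  }

  manifest <- dplyr::bind_rows(manifest)
  emitted <- manifest  # manifest itself is not listed inside itself
  readr::write_tsv(emitted, file.path(config$outdir, "manifest.tsv"),
                   progress = FALSE)
  attr(manifest, "results") <- results
  manifest
}

load_study_inputs <- function(paths) {
  ds_a <- read_lipidomics(paths$lipidomics_a, sample_path = paths$samples_a)
  cohort_a <- read_delim_auto(paths$cohort_a)
  out <- list(cohort_a = list(lipidomics = ds_a, cohort = cohort_a))
  if (!is.null(paths$lipidomics_b)) {
    out$cohort_b <- list(
      lipidomics = read_lipidomics(paths$lipidomics_b,
                                   sample_path = paths$samples_b),
      cohort = read_delim_auto(paths$cohort_b))
  } else {
    out$cohort_b <- out$cohort_a
  }
  if (!is.null(paths$consensus)) {
    cons <- read_delim_auto(paths$consensus)
    out$consensus <- setNames(cons[[2]], cons[[1]])
  }
  if (!is.null(paths$vcf)) out$genotypes <- read_vcf(paths$vcf)
  out
}
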