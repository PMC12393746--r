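# Shared in-code fixtures for the suite: all data are generated here, none
# are stored on disk.

tiny_lipidome <- function(n = 6, seed = 1, species = c("PC(16:0_18:1)",
                                                       "PC(16:0_20:4)",
                                                       "PE(P-16:0/20:4)",
                                                       "PE(P-18:0/20:4)")) {
  set.seed(seed)
  conc <- matrix(2^rnorm(n * length(species), 3, 1), n, length(species),
                 dimnames = list(sprintf("s%02d", seq_len(n)), species))
  lipidomics_dataset(conc, parse_lipid_name(species))
}

# two-batch dataset with PQC and reference samples, constructed by hand so
# every harmonization quantity has a closed form
harmonization_fixture <- function() {
  species <- c("PC(16:0_18:1)", "PE(P-16:0/20:4)")
  ids <- c("b1", "b2", "PQC1", "PQC2", "PQC3", "PQC4", "REF1", "REF2", "REF3")
  conc <- rbind(
    b1 = c(4, 10), b2 = c(6, 14),
    PQC1 = c(2, 8), PQC2 = c(2, 8),     # batch 1 PQC
    PQC3 = c(4, 8), PQC4 = c(4, 8),     # batch 2 PQC: doubled for species 1
    REF1 = c(4, 2), REF2 = c(4, 2), REF3 = c(4, 2)
  )
  colnames(conc) <- species
  samples <- tibble::tibble(
    sample_id = ids,
    batch = c("batch1", "batch2", "batch1", "batch1", "batch2", "batch2",
              "batch1", "batch1", "batch1"),
    is_pqc = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    is_reference = c(rep(FALSE, 6), TRUE, TRUE, TRUE)
  )
  lipidomics_dataset(conc, parse_lipid_name(species), samples)
}

# full 735-species lipidome at a small sample size
small_study_config <- function(n_samples = c(150, 120), ...) {
  synthetic_config(n_samples = n_samples, n_batches = 2, n_reference = 6,
                   n_pqc_per_batch = 3, genetics = NULL, ...)
}

# compact generic lipidome (CL01..CL39 classes)
generic_config <- function(...) {
  synthetic_config(n_samples = c(150, 120), n_species = 78, n_classes = 39,
                   n_batches = 2, n_reference = 6, n_pqc_per_batch = 3,
                   genetics = NULL, ...)
}

# generic-lipidome config with a causal locus on the CL01/CL02 ratio
causal_config <- function(n = 600, m = 600, n_chrom = 3, effect = 0.3,
                          n_species = 60, n_classes = 20) {
  synthetic_config(
    n_samples = c(30, n), n_species = n_species, n_classes = n_classes,
    effect_table = tibble::tibble(class = character(), beta_wc = numeric(),
                                  beta_sex = numeric(), beta_wc_sex = numeric()),
    n_batches = 1, n_reference = 3, n_pqc_per_batch = 2,
    cohort_scale = c(1, 1),
    genetics = list(n_snps = m, n_chromosomes = n_chrom,
                    maf_range = c(0.05, 0.5),
                    causal = list(numerator_class = "CL01",
                                  denominator_class = "CL02",
                                  effect = effect, maf = 0.3, chrom = 1L,
                                  ld_block = 12L, ld_flip = 0.1),
                    h2_polygenic = 0.2)
  )
}

causal_ratio_definitions <- function(annotations) {
  tibble::tibble(
    label = "CL01/CL02",
    numerator = "CL01", denominator = "CL02",
    annotation = "causal", provenance = "synthetic",
    numerator_species = resolve_selector("CL01", annotations),
    denominator_species = resolve_selector("CL02", annotations)
  )
}

# printed association p-values used as worked p-gain inputs
printed_pgain_rows <- function() {
  tibble::tibble(
    label = c("PE(O)/PE", "PE(P)/PE", "PC(P)/PC",
              "PE(P-16:0/22:6)/PE(P-18:0/22:6)",
              "PE(P-16:0/18:2)/PE(P-16:0/20:4)",
              "Total PE Ether/PE"),
    component_1 = c(4.31e-22, 3.05e-3, 3.48e-78, 9.68e-1, 8.99e-7, 1.05e-3),
    component_2 = c(3.36e-35, 3.36e-35, 1.38e-9, 1.59e-31, 4.35e-15, 3.36e-35),
    ratio_p = c(4.30e-68, 4.41e-39, 1.09e-133, 4.8e-105, 7.31e-52, 7.39e-13),
    published = c(7.80e32, 7.60e3, 3.20e55, 3.32e73, 5.95e36, 1.00)
  )
}
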