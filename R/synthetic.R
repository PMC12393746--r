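# Seed substream derivation: one master seed, each named stage hashed to its
# own substream so adding a stage never perturbs earlier draws.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Configuration for the synthetic two-cohort study
#'
#' Defaults emulate the statistical structure of a large two-cohort plasma
#' lipidomics study: 735 species in 39 classes, within-class latent-factor
#' correlation, obesity-marker and sex effects on the ether-lipid classes,
#' batch structure with pooled-QC samples, reference plasma aliquots, and a
#' genotype panel carrying a causal locus with opposing effects on the
#' numerator and denominator classes of one ratio.
#'
#' @param n_samples Integer vector of per-cohort biological sample sizes.
#' @param n_species,n_classes Lipidome dimensions. The packaged 735/39
#'   lipidome is used when these match its dimensions; otherwise a generic
#'   lipidome of evenly sized classes is generated.
#' @param class_factor_loading Within-class latent factor loading in [0,1).
#' @param effect_table Tibble with columns `class`, `beta_wc` (log2
#'   abundance change per cm waist circumference), `beta_sex` (log2 shift in
#'   males), `beta_wc_sex` (male-minus-female slope difference).
#' @param n_batches,batch_sd Batch count and SD of per-(species,batch)
#'   log2 offsets.
#' @param n_reference,n_pqc_per_batch Reference-plasma aliquots per cohort
#'   and pooled-QC samples per batch.
#' @param cohort_scale Per-cohort global measurement scale factors
#'   (misalignment the harmonization stage must remove).
#' @param genetics List: `n_snps`, `n_chromosomes`, `maf_range`,
#'   `causal` (list with `numerator_class`, `denominator_class`, `effect`
#'   per-allele log2 shift, `maf`, `chrom`, `ld_block`, `ld_flip`),
#'   `h2_polygenic` for the causal ratio.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_samples = c(10399L, 4492L),
                             n_species = 735L,
                             n_classes = 39L,
                             class_factor_loading = 0.6,
                             effect_table = default_effect_table(),
                             n_batches = 4L,
                             batch_sd = 0.1,
                             n_reference = 12L,
                             n_pqc_per_batch = 5L,
                             cohort_scale = c(1, 1.25),
                             genetics = list(
                               n_snps = 5000L,
                               n_chromosomes = 5L,
                               maf_range = c(0.05, 0.5),
                               causal = list(
                                 numerator_class = "PC(O)",
                                 denominator_class = "PC(P)",
                                 effect = 0.15,
                                 maf = 0.3,
                                 chrom = 1L,
                                 ld_block = 12L,
                                 ld_flip = 0.1
                               ),
                               h2_polygenic = 0.2
                             )) {
  cfg <- list(n_samples = as.integer(n_samples), n_species = as.integer(n_species),
              n_classes = as.integer(n_classes),
              class_factor_loading = class_factor_loading,
              effect_table = effect_table, n_batches = as.integer(n_batches),
              batch_sd = batch_sd, n_reference = as.integer(n_reference),
              n_pqc_per_batch = as.integer(n_pqc_per_batch),
              cohort_scale = cohort_scale, genetics = genetics)
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  if (cfg$n_species < cfg$n_classes || cfg$n_classes < 1) {
    stop("need n_species >= n_classes >= 1", call. = FALSE)
  }
  if (cfg$class_factor_loading < 0 || cfg$class_factor_loading >= 1) {
    stop("class_factor_loading must be in [0, 1)", call. = FALSE)
  }
  if (any(cfg$cohort_scale <= 0)) stop("cohort_scale must be positive", call. = FALSE)
  g <- cfg$genetics
  if (!is.null(g)) {
    if (any(g$maf_range <= 0) || any(g$maf_range > 0.5)) {
      stop("MAF range must lie in (0, 0.5]", call. = FALSE)
    }
    if (g$h2_polygenic < 0 || g$h2_polygenic >= 1) {
      stop("h2_polygenic must be in [0, 1)", call. = FALSE)
    }
    if (g$n_snps < g$causal$ld_block) {
      stop("n_snps smaller than the LD block", call. = FALSE)
    }
  }
  invisible(cfg)
}

#' @rdname synthetic_config
#' @export
default_effect_table <- function() {
  tibble::tibble(
    class = c("PE(O)", "PE(P)", "PC(O)", "PC(P)", "LPC", "LPE",
              "LPC(P)", "LPE(P)", "PE", "PC", "TG", "TG(O)"),
    beta_wc = c(-0.01, -0.01, -0.01, -0.01, -0.008, -0.008,
                -0.01, -0.005, 0.01, 0.005, 0.02, 0.013),
    beta_sex = c(-0.1, -0.1, -0.1, -0.1, 0.05, 0.05,
                 -0.05, -0.05, 0.1, 0.05, 0.2, 0.15),
    beta_wc_sex = c(0, 0, 0, 0, 0.006, 0.006, 0, 0, 0, 0, 0, 0)
  )
}

config_annotations <- function(cfg) {
  if (cfg$n_species == 735L && cfg$n_classes == 39L) {
    return(default_lipidome_annotations())
  }
  per <- diff(round(seq(0, cfg$n_species, length.out = cfg$n_classes + 1)))
  cls <- sprintf("CL%02d", seq_len(cfg$n_classes))
  names <- unlist(lapply(seq_len(cfg$n_classes), function(k) {
    sprintf("%s(%d:0)", cls[k], 10 + seq_len(per[k]))
  }))
  parse_lipid_name(names)
}

species_params <- function(cfg, param_seed) {
  ann <- config_annotations(cfg)
  set.seed(derive_seed(param_seed, "species-params"))
  base <- runif(nrow(ann), -3, 6)
  eff <- dplyr::left_join(tibble::tibble(class = ann$class_code),
                          cfg$effect_table, by = "class")
  list(annotations = ann,
       base = base,
       beta_wc = ifelse(is.na(eff$beta_wc), 0, eff$beta_wc),
       beta_sex = ifelse(is.na(eff$beta_sex), 0, eff$beta_sex),
       beta_wc_sex = ifelse(is.na(eff$beta_wc_sex), 0, eff$beta_wc_sex))
}

#' Simulate one cohort of the synthetic study
#'
#' Generates covariates (age truncated normal, Bernoulli sex,
#' sex-dependent waist circumference with BMI and waist-hip ratio as noisy
#' deterministic functions of WC so the three markers correlate above 0.9),
#' then log2 species abundances from a within-class latent factor model
#' plus covariate effects, batch offsets, optional genetic effects and a
#' cohort-wide measurement scale. Pooled-QC samples carry batch offsets but
#' no biology; reference aliquots are identical in expectation across
#' cohorts up to the cohort scale factor.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed for this cohort's draws.
#' @param cohort_id Short label used in sample ids.
#' @param cohort_scale Measurement scale factor for this cohort.
#' @param genotypes Optional `genotype_data` for these samples; applies the
#'   configured causal and polygenic effects.
#' @param param_seed Seed for the species-level parameters (bases, effect
#'   sizes). Two cohorts of one study share it.
#' @return A list with elements `lipidomics` (a [lipidomics_dataset()]),
#'   `cohort` (covariate tibble) and `consensus` (expected reference-plasma
#'   concentrations, the analogue of a consensus reference-material table).
#' @export
simulate_cohort <- function(config, seed, cohort_id = "A", cohort_scale = 1,
                            genotypes = NULL, param_seed = seed) {
  validate_synthetic_config(config)
  pars <- species_params(config, param_seed)
  ann <- pars$annotations
  n <- config$n_samples[[1]]
  n_sp <- nrow(ann)

  set.seed(derive_seed(seed, paste0("covariates-", cohort_id)))
  age <- rnorm(n, 50, 12)
  while (any(age < 25)) age[age < 25] <- rnorm(sum(age < 25), 50, 12)
  sex <- rbinom(n, 1, 0.5)                       # 0 = female, 1 = male
  wc <- ifelse(sex == 1, rnorm(n, 98, 11), rnorm(n, 89, 13))
  bmi <- 2 + 0.27 * wc + rnorm(n, 0, 0.8)
  whr <- 0.40 + 0.0048 * wc + rnorm(n, 0, 0.01)
  chol <- rnorm(n, 5.5, 1.0)
  disease <- rbinom(n, 1, stats::plogis(-2.9 + 0.04 * (wc - 95)))
  ids <- sprintf("%s%05d", cohort_id, seq_len(n))
  cohort <- tibble::tibble(sample_id = ids, age = age, sex = sex, WC = wc,
                           BMI = bmi, WHR = whr, total_cholesterol = chol,
                           disease = disease)

  set.seed(derive_seed(seed, paste0("batch-", cohort_id)))
  batch_labels <- paste0("batch", 1 + (seq_len(n) - 1) %% config$n_batches)
  batch_offsets <- matrix(rnorm(n_sp * config$n_batches, 0, config$batch_sd),
                          nrow = config$n_batches,
                          dimnames = list(paste0("batch", seq_len(config$n_batches)),
                                          ann$species_name))

  loading <- config$class_factor_loading
  idio_sd <- sqrt(1 - loading^2)
  class_idx <- match(ann$class_code, unique(ann$class_code))
  n_cl <- max(class_idx)

  set.seed(derive_seed(seed, paste0("concentrations-", cohort_id)))
  factors <- matrix(rnorm(n * n_cl), n, n_cl)
  log2_conc <- factors[, class_idx, drop = FALSE] * loading +
    matrix(rnorm(n * n_sp, 0, idio_sd), n, n_sp)
  log2_conc <- sweep(log2_conc, 2, pars$base, `+`)
  wc_c <- wc - mean(wc)
  log2_conc <- log2_conc +
    outer(wc_c, pars$beta_wc) +
    outer(sex, pars$beta_sex) +
    outer(wc_c * sex, pars$beta_wc_sex) +
    batch_offsets[batch_labels, , drop = FALSE]

  if (!is.null(genotypes)) {
    log2_conc <- log2_conc + genetic_shift(config, genotypes, ids, ann, seed)
  }

  # technical samples: pooled QC per batch, reference plasma aliquots
  set.seed(derive_seed(seed, paste0("technical-", cohort_id)))
  batches <- paste0("batch", seq_len(config$n_batches))
  pqc_ids <- as.vector(t(outer(batches, seq_len(config$n_pqc_per_batch),
                               function(b, i) sprintf("PQC_%s_%s_%d", cohort_id, b, i))))
  pqc_batch <- rep(batches, each = config$n_pqc_per_batch)
  pqc_log2 <- matrix(rep(pars$base, each = length(pqc_ids)),
                     nrow = length(pqc_ids)) +
    batch_offsets[pqc_batch, , drop = FALSE] +
    matrix(rnorm(length(pqc_ids) * n_sp, 0, 0.05), length(pqc_ids), n_sp)

  ref_ids <- sprintf("REF_%s_%d", cohort_id, seq_len(config$n_reference))
  ref_log2 <- matrix(rep(pars$base, each = config$n_reference),
                     nrow = config$n_reference) +
    matrix(rnorm(config$n_reference * n_sp, 0, 0.05), config$n_reference, n_sp)

  conc <- 2^rbind(log2_conc, pqc_log2, ref_log2) * cohort_scale
  rownames(conc) <- c(ids, pqc_ids, ref_ids)
  colnames(conc) <- ann$species_name

  samples <- tibble::tibble(
    sample_id = rownames(conc),
    batch = c(batch_labels, pqc_batch, rep(batches[1], config$n_reference)),
    is_pqc = c(rep(FALSE, n), rep(TRUE, length(pqc_ids)),
               rep(FALSE, config$n_reference)),
    is_reference = c(rep(FALSE, n + length(pqc_ids)),
                     rep(TRUE, config$n_reference))
  )

  list(
    lipidomics = lipidomics_dataset(conc, ann, samples),
    cohort = cohort,
    consensus = setNames(2^pars$base, ann$species_name)
  )
}

genetic_shift <- function(config, genotypes, ids, ann, seed) {
  g <- config$genetics
  dos <- genotypes$dosage[ids, , drop = FALSE]
  shift <- matrix(0, length(ids), nrow(ann))
  causal_id <- genotypes$causal_id
  a <- g$causal$effect
  num <- ann$class_code == g$causal$numerator_class
  den <- ann$class_code == g$causal$denominator_class
  dc <- dos[, causal_id]
  shift[, num] <- shift[, num] + a * dc
  shift[, den] <- shift[, den] - a * dc
  if (g$h2_polygenic > 0) {
    set.seed(derive_seed(seed, "polygenic"))
    p <- colMeans(dos) / 2
    # background drawn from the other chromosomes only, so the causal
    # locus carries exactly its configured effect
    keep <- p > 0 & p < 1 &
      genotypes$variants$chrom != as.character(g$causal$chrom)
    w <- rnorm(sum(keep), 0, 1 / sqrt(sum(keep))) /
      sqrt(2 * p[keep] * (1 - p[keep]))
    u <- as.vector(dos[, keep, drop = FALSE] %*% w) - sum(2 * p[keep] * w)
    # scale so the causal log2-ratio carries roughly the configured h2
    tau <- sqrt(g$h2_polygenic / (1 - g$h2_polygenic)) / stats::sd(u)
    u <- u * tau
    shift[, num] <- shift[, num] + u / 2
    shift[, den] <- shift[, den] - u / 2
  }
  shift
}

#' Simulate a genotype panel
#'
#' Dosages are Binomial(2, MAF) per variant, independent across variants
#' except for a linkage-disequilibrium block around the causal SNP, whose
#' members copy the causal haplotypes with a small flip probability so
#' pairwise r-squared inside the block stays high. Variants occupy
#' contiguous position blocks per chromosome.
#'
#' @param config A [synthetic_config()] with a `genetics` block.
#' @param seed Integer seed.
#' @param sample_ids Character vector of sample ids (rows of the panel).
#' @return A `genotype_data` list: `dosage` (samples x variants matrix),
#'   `variants` (tibble with chrom, pos, id, ref, alt, call_rate, MAC, MAF,
#'   hwe_p, imputation_r2, palindromic), and `causal_id`.
#' @export
simulate_genotypes <- function(config, seed, sample_ids) {
  g <- config$genetics
  n <- length(sample_ids)
  m <- g$n_snps
  set.seed(derive_seed(seed, "genotypes"))

  maf <- runif(m, g$maf_range[1], g$maf_range[2])
  chrom <- rep(seq_len(g$n_chromosomes), length.out = m)
  chrom <- sort(chrom)
  pos <- unlist(lapply(split(seq_len(m), chrom), function(ix) {
    seq(1e5, by = 5e3, length.out = length(ix))
  }), use.names = FALSE)

  chr_ix <- which(chrom == g$causal$chrom)
  causal_pos <- chr_ix[ceiling(length(chr_ix) / 2)]
  block <- causal_pos + seq(0, g$causal$ld_block - 1)
  block <- block[block %in% chr_ix]
  maf[block] <- g$causal$maf

  # independent variants drawn directly as Binomial(2, maf) dosages; the
  # LD block is built at the haplotype level by copying the causal
  # haplotypes with a small flip probability
  dosage <- matrix(rbinom(n * m, 2, rep(maf, each = n)), n, m)
  h1c <- rbinom(n, 1, g$causal$maf)
  h2c <- rbinom(n, 1, g$causal$maf)
  dosage[, causal_pos] <- h1c + h2c
  for (j in setdiff(block, causal_pos)) {
    keep1 <- runif(n) > g$causal$ld_flip
    keep2 <- runif(n) > g$causal$ld_flip
    b1 <- ifelse(keep1, h1c, rbinom(n, 1, g$causal$maf))
    b2 <- ifelse(keep2, h2c, rbinom(n, 1, g$causal$maf))
    dosage[, j] <- b1 + b2
  }
  storage.mode(dosage) <- "double"

  alleles <- cbind(ref = sample(c("A", "C", "G", "T"), m, replace = TRUE),
                   alt = NA_character_)
  nonpal <- list(A = c("C", "G"), C = c("A", "T"), G = c("A", "T"),
                 T = c("C", "G"))
  alleles[, "alt"] <- vapply(alleles[, "ref"], function(r) {
    sample(nonpal[[r]], 1)
  }, character(1))

  ids <- sprintf("snp%05d", seq_len(m))
  rownames(dosage) <- sample_ids
  colnames(dosage) <- ids

  af <- colMeans(dosage) / 2
  obs_maf <- pmin(af, 1 - af)
  variants <- tibble::tibble(
    chrom = as.character(chrom), pos = pos, id = ids,
    ref = alleles[, "ref"], alt = alleles[, "alt"],
    call_rate = 1, MAC = round(2 * n * obs_maf), MAF = obs_maf,
    hwe_p = NA_real_, imputation_r2 = 1,
    palindromic = paste0(alleles[, "ref"], alleles[, "alt"]) %in%
      c("AT", "TA", "CG", "GC")
  )
  structure(list(dosage = dosage, variants = variants,
                 causal_id = ids[causal_pos]),
            class = "genotype_data")
}

#' Simulate two-group expression data
#'
#' Log2 expression is Normal(gene mean, 1) with a per-gene shift applied to
#' the second group, emulating strain-mean microarray comparisons between
#' two diet groups.
#'
#' @param n_genes Number of genes.
#' @param n_per_group Integer vector of two group sizes.
#' @param shift Numeric per-gene shift (recycled) added to group 2.
#' @param seed Integer seed.
#' @return List with `expression` (samples x genes matrix) and `groups`.
#' @export
simulate_expression <- function(n_genes = 200, n_per_group = c(152, 222),
                                shift = 0, seed = 1) {
  if (any(n_per_group < 2)) stop("each group needs at least 2 samples", call. = FALSE)
  set.seed(derive_seed(seed, "expression"))
  shift <- rep_len(shift, n_genes)
  mu <- runif(n_genes, 4, 12)
  n <- sum(n_per_group)
  groups <- rep(c("group1", "group2"), n_per_group)
  expr <- matrix(rnorm(n * n_genes, 0, 1), n, n_genes)
  expr <- sweep(expr, 2, mu, `+`)
  expr[groups == "group2", ] <- sweep(expr[groups == "group2", , drop = FALSE],
                                      2, shift, `+`)
  rownames(expr) <- sprintf("s%04d", seq_len(n))
  colnames(expr) <- sprintf("gene%04d", seq_len(n_genes))
  list(expression = expr, groups = groups)
}

#' Simulate the full two-cohort study
#'
#' Cohort A carries reference-plasma aliquots; cohort B carries the
#' genotype panel and a different global measurement scale, so the
#' harmonization, association and GWAS stages are all exercised.
#'
#' @param config A [synthetic_config()].
#' @param seed Master seed; each stage derives its own substream.
#' @param genotypes Whether to simulate the genotype panel for cohort B.
#' @return List with `cohort_a`, `cohort_b` (each as [simulate_cohort()]),
#'   `genotypes` and `consensus`.
#' @export
simulate_study <- function(config, seed, genotypes = TRUE) {
  a <- simulate_cohort(config, derive_seed(seed, "cohort-a"), "A",
                       cohort_scale = config$cohort_scale[1], param_seed = seed)
  n_b <- if (length(config$n_samples) > 1) config$n_samples[2] else config$n_samples[1]
  cfg_b <- config
  cfg_b$n_samples <- n_b
  ids_b <- sprintf("B%05d", seq_len(n_b))
  geno <- if (genotypes && !is.null(config$genetics)) {
    simulate_genotypes(config, derive_seed(seed, "genotypes"), ids_b)
  }
  b <- simulate_cohort(cfg_b, derive_seed(seed, "cohort-b"), "B",
                       cohort_scale = config$cohort_scale[2],
                       genotypes = geno, param_seed = seed)
  list(cohort_a = a, cohort_b = b, genotypes = geno, consensus = a$consensus)
}
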