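test_that("Hardy-Weinberg chi-squared matches hand computation", {
  # (50, 0, 50): expected (25, 50, 25) -> chi2 = 25 + 50 + 25 = 100
  expect_equal(hwe_test(50, 0, 50), pchisq(100, 1, lower.tail = FALSE))
  expect_lt(hwe_test(50, 0, 50), 5e-4)
  expect_equal(hwe_test(25, 50, 25), 1)
  expect_equal(hwe_test(0, 0, 100), 1)  # monomorphic convention
})

test_that("sample QC flags missingness and heterozygosity outliers", {
  cfg <- causal_config(n = 500, m = 60, n_chrom = 2)
  geno <- simulate_genotypes(cfg, seed = 12, sprintf("s%04d", 1:500))
  clean <- sample_qc(geno)
  expect_equal(nrow(clean$report), 0)

  dirty <- geno
  dirty$dosage["s0001", 1:6] <- NA          # 10% missing
  dirty$dosage["s0002", ] <- 1              # all heterozygous
  res <- sample_qc(dirty)
  expect_setequal(res$report$sample_id, c("s0001", "s0002"))
  expect_equal(res$report$reason[res$report$sample_id == "s0001"],
               "missingness")
  expect_equal(res$report$reason[res$report$sample_id == "s0002"],
               "heterozygosity")
  expect_false(any(c("s0001", "s0002") %in% rownames(res$genotypes$dosage)))
})

test_that("variant QC applies each filter once on a constructed toy panel", {
  n <- 400
  set.seed(5)
  good <- rbinom(n, 2, 0.3)
  panel <- cbind(
    clean = good,
    low_call = replace(good, 1:40, NA),               # call rate 0.9
    rare = c(rep(1, 3), rep(0, n - 3)),               # MAC 3
    hwe_bad = rep(c(0, 2), n / 2),                    # no hets at p = 0.5
    pal_common = rbinom(n, 2, 0.45),                  # A/T at MAF ~0.45
    low_r2 = rbinom(n, 2, 0.3)                        # imputation r2 0.1
  )
  rownames(panel) <- sprintf("s%03d", 1:n)
  variants <- tibble::tibble(
    chrom = "1", pos = 1:6 * 1000, id = colnames(panel),
    ref = c("A", "A", "A", "A", "A", "A"),
    alt = c("G", "G", "G", "G", "T", "G"),
    call_rate = NA, MAC = NA, MAF = NA, hwe_p = NA,
    imputation_r2 = c(1, 1, 1, 1, 1, 0.1),
    palindromic = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE)
  )
  geno <- structure(list(dosage = panel, variants = variants,
                         causal_id = NULL), class = "genotype_data")
  res <- variant_qc(geno)
  expect_equal(res$genotypes$variants$id, "clean")
  counts <- setNames(res$report$n_failed, res$report$filter)
  expect_equal(unname(counts[c("call_rate", "hwe", "palindromic",
                               "imputation_r2")]), c(1L, 1L, 1L, 1L))
  expect_equal(unname(counts["mac"]), 1L)       # the MAC-3 variant
  expect_equal(unname(counts["post_mac"]), 1L)  # same variant fails both MAC stages

  # palindromic variant at moderate MAF is kept
  variants2 <- variants
  pal_mod <- rbinom(n, 2, 0.3)
  panel2 <- cbind(panel[, "clean", drop = FALSE], pal_mod = pal_mod)
  variants2 <- variants[1:2, ]
  variants2$id <- colnames(panel2)
  variants2$palindromic <- c(FALSE, TRUE)
  variants2$imputation_r2 <- c(1, 1)
  geno2 <- structure(list(dosage = panel2, variants = variants2,
                          causal_id = NULL), class = "genotype_data")
  res2 <- variant_qc(geno2)
  expect_true("pal_mod" %in% res2$genotypes$variants$id)

  # all filters disabled -> identity
  res3 <- variant_qc(geno, params = list())
  expect_equal(ncol(res3$genotypes$dosage), 6L)
})

test_that("GRM structure: duplicates, null off-diagonals, LOCO recombination", {
  cfg <- causal_config(n = 300, m = 400, n_chrom = 2)
  geno <- simulate_genotypes(cfg, seed = 9, sprintf("s%04d", 1:300))
  # duplicated sample: its cross entry equals the shared diagonal
  dup <- geno
  dup$dosage <- rbind(dup$dosage, twin = dup$dosage[1, ])
  K <- compute_grm(dup)$K
  expect_equal(K[1, nrow(K)], K[1, 1], tolerance = 1e-12)

  K0 <- compute_grm(geno)
  offdiag <- K0$K[upper.tri(K0$K)]
  # empirical-frequency centering constrains each column of Z to sum to 0,
  # so unrelated samples have mean off-diagonal -mean(diag)/(n-1), not 0
  n0 <- nrow(K0$K)
  expected_off <- -mean(diag(K0$K)) / (n0 - 1)
  expect_lt(abs(mean(offdiag) - expected_off),
            3 * sd(offdiag) / sqrt(length(offdiag)))

  # all-chromosome GRM is the variant-weighted recombination of LOCO parts
  loco1 <- compute_grm(geno, exclude_chrom = "1")  # built from chr 2
  loco2 <- compute_grm(geno, exclude_chrom = "2")  # built from chr 1
  recombined <- (loco1$K * loco1$m_variants + loco2$K * loco2$m_variants) /
    (loco1$m_variants + loco2$m_variants)
  expect_equal(K0$K, recombined, tolerance = 1e-10)
})

test_that("genomic PCs separate subpopulations and reconstruct the GRM", {
  set.seed(20)
  n <- 120
  m <- 300
  p1 <- runif(m, 0.1, 0.5)
  p2 <- pmin(0.95, p1 + 0.4)  # divergent frequencies
  dos <- rbind(
    matrix(rbinom(n / 2 * m, 2, rep(p1, each = n / 2)), n / 2, m),
    matrix(rbinom(n / 2 * m, 2, rep(p2, each = n / 2)), n / 2, m)
  )
  rownames(dos) <- sprintf("s%03d", 1:n)
  colnames(dos) <- sprintf("v%03d", 1:m)
  geno <- structure(list(
    dosage = dos,
    variants = tibble::tibble(chrom = "1", pos = 1:m, id = colnames(dos),
                              ref = "A", alt = "G", call_rate = 1, MAC = 1,
                              MAF = 0.2, hwe_p = NA, imputation_r2 = 1,
                              palindromic = FALSE),
    causal_id = NULL), class = "genotype_data")
  grm <- compute_grm(geno)
  pcs <- genomic_pcs(grm, k = 2)
  grp <- rep(c(1, 2), each = n / 2)
  # silhouette of the PC1 split
  sil <- vapply(seq_len(n), function(i) {
    a <- mean(abs(pcs[i, 1] - pcs[setdiff(which(grp == grp[i]), i), 1]))
    b <- mean(abs(pcs[i, 1] - pcs[grp != grp[i], 1]))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)

  # full-rank reconstruction
  pcs_full <- genomic_pcs(grm, k = n)
  expect_equal(pcs_full %*% t(pcs_full), grm$K, tolerance = 1e-8,
               ignore_attr = TRUE)

  # identity GRM: sign convention enforced, unit eigenvalues
  eye <- diag(50)
  rownames(eye) <- sprintf("i%02d", 1:50)
  pid <- genomic_pcs(eye, k = 3)
  expect_true(all(apply(pid, 2, function(col) col[which.max(abs(col))] > 0)))
  expect_error(genomic_pcs(eye, k = 51), "exceeds")
})

test_that("rank inverse-normal transform uses Blom offsets", {
  got <- rint(c(3, 1, 2))
  expect_equal(got, qnorm((c(3, 1, 2) - 3 / 8) / 3.25), tolerance = 1e-12)
  expect_equal(got[3], 0)
  expect_equal(got[1], 0.8694, tolerance = 1e-4)

  set.seed(2)
  x <- rnorm(101)
  expect_equal(rint(x), rint(exp(x)))        # monotone invariance
  expect_equal(mean(rint(x)), 0, tolerance = 1e-12)
  expect_error(rint(rep(1, 5)), "constant")
})

test_that("phenotype preparation is affine invariant and normalizing", {
  set.seed(33)
  n <- 1000
  cohort <- tibble::tibble(sample_id = sprintf("s%04d", 1:n),
                           age = rnorm(n, 50, 10), sex = rbinom(n, 1, 0.5))
  pcs <- matrix(rnorm(n * 3), n, 3,
                dimnames = list(cohort$sample_id, paste0("PC", 1:3)))
  y <- setNames(rnorm(n), cohort$sample_id)
  out <- prepare_phenotype(y, cohort, pcs)
  expect_gt(stats::shapiro.test(out[1:999])$p.value, 0.01)

  shifted <- dplyr::mutate(cohort, age = age + 7)
  expect_equal(prepare_phenotype(y, shifted, pcs), out, tolerance = 1e-10)

  # orthogonal phenotype: residuals equal the input, so output is rint(y)
  X <- cbind(1, cohort$age, cohort$sex, cohort$age^2, cohort$age * cohort$sex,
             cohort$age^2 * cohort$sex, pcs)
  y_orth <- setNames(qr.resid(qr(X), y), cohort$sample_id)
  expect_equal(prepare_phenotype(y_orth, cohort, pcs), rint(y_orth),
               tolerance = 1e-10)

  bad_pcs <- cbind(pcs, PC4 = pcs[, 1])
  expect_error(prepare_phenotype(y, cohort, bad_pcs), "rank deficient")
})

test_that("identity GRM reduces the mixed model to OLS", {
  cfg <- causal_config(n = 300, m = 80, n_chrom = 2, effect = 0)
  geno <- simulate_genotypes(cfg, seed = 40, sprintf("s%04d", 1:300))
  set.seed(41)
  y <- setNames(rnorm(300), rownames(geno$dosage))
  eye <- structure(list(K = diag(300), excluded_chromosome = NULL,
                        m_variants = 1), class = "grm")
  got <- lmm_gwas(y, geno, chromosomes = "1", grms = list(`1` = eye))
  for (j in sample(which(geno$variants$chrom == "1"), 5)) {
    ols <- summary(lm(y ~ geno$dosage[, j]))$coefficients
    row <- got[got$id == geno$variants$id[j], ]
    expect_equal(row$beta, ols[2, 1], tolerance = 1e-8)
    expect_equal(row$se, ols[2, 2], tolerance = 1e-8)
    expect_equal(row$p, ols[2, 4], tolerance = 1e-8)
  }
})

test_that("mixed-model betas match a dense GLS oracle at n = 20", {
  set.seed(50)
  n <- 20
  ids <- sprintf("s%02d", 1:n)
  dos <- matrix(rbinom(n * 6, 2, 0.4), n, 6,
                dimnames = list(ids, sprintf("v%d", 1:6)))
  geno <- structure(list(
    dosage = dos,
    variants = tibble::tibble(chrom = "1", pos = 1:6, id = colnames(dos),
                              ref = "A", alt = "G", call_rate = 1, MAC = 5,
                              MAF = 0.4, hwe_p = NA, imputation_r2 = 1,
                              palindromic = FALSE),
    causal_id = NULL), class = "genotype_data")
  Z <- matrix(rnorm(n * 15), n, 15)
  K <- tcrossprod(Z) / 15
  grm <- structure(list(K = K, excluded_chromosome = "1", m_variants = 15),
                   class = "grm")
  y <- setNames(rnorm(n), ids)
  got <- lmm_gwas(y, geno, chromosomes = "1", grms = list(`1` = grm))
  fit <- fit_lmm_reml(y, K)
  V <- K + fit$delta * diag(n)
  Vi <- solve(V)
  for (j in 1:6) {
    X <- cbind(1, dos[, j])
    beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
    expect_equal(got$beta[j], beta[2, 1], tolerance = 1e-10)
  }
})

test_that("REML recovers a simulated heritability of 0.5", {
  set.seed(60)
  n <- 500
  Z <- matrix(rbinom(n * 800, 2, 0.3), n, 800)
  Z <- scale(Z)
  K <- tcrossprod(Z) / ncol(Z)
  e <- eigen(K, symmetric = TRUE)
  h2 <- 0.5
  est <- vapply(1:50, function(i) {
    u <- e$vectors %*% (sqrt(pmax(e$values, 0) * h2) * rnorm(n))
    y <- u[, 1] + rnorm(n, 0, sqrt(1 - h2))
    fit_lmm_reml(y, K)$h2
  }, numeric(1))
  expect_lt(abs(mean(est) - h2), 3 * sd(est) / sqrt(length(est)))
})

test_that("null GWAS is calibrated: uniform p and lambda near 1", {
  cfg <- synthetic_config(
    n_samples = c(10, 1000), n_species = 20, n_classes = 5,
    genetics = list(n_snps = 5000, n_chromosomes = 5,
                    maf_range = c(0.05, 0.5),
                    causal = list(numerator_class = "CL01",
                                  denominator_class = "CL02",
                                  effect = 0, maf = 0.3, chrom = 1L,
                                  ld_block = 12L, ld_flip = 0.1),
                    h2_polygenic = 0))
  geno <- simulate_genotypes(cfg, seed = 71, sprintf("s%04d", 1:1000))
  set.seed(72)
  y <- setNames(rnorm(1000), rownames(geno$dosage))
  res <- lmm_gwas(y, geno)
  frac <- mean(res$p < 0.05)
  mc_se <- sqrt(0.05 * 0.95 / nrow(res))
  expect_lt(abs(frac - 0.05), 3 * mc_se)
  lam <- glance(res)$lambda_gc
  expect_gt(lam, 0.95)
  expect_lt(lam, 1.05)
})

test_that("LOCO exclusion strengthens the causal test statistic", {
  cfg <- causal_config(n = 800, m = 600, n_chrom = 3)
  st <- simulate_study(cfg, seed = 81)
  geno <- st$genotypes
  ids <- st$cohort_b$cohort$sample_id
  defs <- causal_ratio_definitions(st$cohort_b$lipidomics$annotations)
  rm <- compute_ratio_matrix(st$cohort_b$lipidomics, defs, samples = ids)
  y <- setNames(rm$values[, 1], rownames(rm$values))

  loco <- lmm_gwas(y, geno, chromosomes = "1")
  full <- lmm_gwas(y, geno, chromosomes = "1", loco = FALSE)
  cid <- geno$causal_id
  t_loco <- abs(loco$beta[loco$id == cid] / loco$se[loco$id == cid])
  t_full <- abs(full$beta[full$id == cid] / full$se[full$id == cid])
  expect_gte(t_loco, t_full)

  # monotonicity in the effect size
  p_at <- vapply(c(0.05, 0.15, 0.3), function(a) {
    st_a <- simulate_study(causal_config(n = 800, m = 600, n_chrom = 3,
                                         effect = a), seed = 82)
    rm_a <- compute_ratio_matrix(
      st_a$cohort_b$lipidomics,
      causal_ratio_definitions(st_a$cohort_b$lipidomics$annotations),
      samples = st_a$cohort_b$cohort$sample_id)
    ya <- setNames(rm_a$values[, 1], rownames(rm_a$values))
    g <- lmm_gwas(ya, st_a$genotypes, chromosomes = "1")
    g$p[g$id == st_a$genotypes$causal_id]
  }, numeric(1))
  expect_true(all(diff(p_at) < 0))
})

test_that("SNP p-gain matches a scalar loop oracle", {
  cfg <- causal_config(n = 400, m = 120, n_chrom = 2)
  st <- simulate_study(cfg, seed = 91)
  geno <- st$genotypes
  ids <- st$cohort_b$cohort$sample_id
  ann <- st$cohort_b$lipidomics$annotations
  defs <- causal_ratio_definitions(ann)
  rm <- compute_ratio_matrix(st$cohort_b$lipidomics, defs, samples = ids)
  comp <- lipidratio:::standardized_component_matrix(
    st$cohort_b$lipidomics, defs, samples = ids)
  y_r <- setNames(rm$values[, 1], ids)
  y_a <- setNames(comp$matrix[, 1], ids)
  y_b <- setNames(comp$matrix[, 2], ids)
  gr <- lmm_gwas(y_r, geno, chromosomes = "1")
  ga <- lmm_gwas(y_a, geno, chromosomes = "1")
  gb <- lmm_gwas(y_b, geno, chromosomes = "1")
  pg <- snp_p_gain(gr, ga, gb, n_significant_snps = 12)
  for (i in sample(nrow(pg), 10)) {
    expect_equal(pg$p_gain[i], min(ga$p[i], gb$p[i]) / gr$p[i])
  }
  expect_identical(pg$p_gain_significant, pg$p_gain > 120)

  # component p equal to ratio p gives gain 1
  pg_self <- snp_p_gain(gr, gr, gr, n_significant_snps = 1)
  expect_true(all(pg_self$p_gain == 1))

  expect_error(snp_p_gain(gr, ga[-1, ], gb), "differ")
})

test_that("GRM TSV round trip preserves the matrix and metadata", {
  cfg <- causal_config(n = 25, m = 40, n_chrom = 2)
  geno <- simulate_genotypes(cfg, seed = 96, sprintf("s%03d", 1:25))
  grm <- compute_grm(geno, exclude_chrom = "2")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_grm(grm, path)
  back <- read_grm(path)
  expect_equal(back$K, grm$K, tolerance = 1e-12)
  expect_equal(back$excluded_chromosome, "2")
  expect_equal(back$m_variants, grm$m_variants)
})

test_that("low-rank and GRM-based PC routes agree", {
  cfg <- causal_config(n = 80, m = 50, n_chrom = 2)
  geno <- simulate_genotypes(cfg, seed = 97, sprintf("s%03d", 1:80))
  a <- genotype_pcs(geno, k = 4)
  b <- genomic_pcs(compute_grm(geno), k = 4)
  expect_equal(a, b, tolerance = 1e-8)
})

test_that("VCF round trip preserves dosages and metadata", {
  cfg <- causal_config(n = 40, m = 30, n_chrom = 2)
  geno <- simulate_genotypes(cfg, seed = 95, sprintf("s%03d", 1:40))
  geno$dosage[3, 5] <- NA
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(geno, path)
  back <- read_vcf(path)
  expect_equal(back$dosage, geno$dosage, tolerance = 1e-5)
  expect_equal(back$variants$chrom, geno$variants$chrom)
  expect_equal(back$variants$pos, geno$variants$pos)
  expect_equal(back$variants$ref, geno$variants$ref)
})
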