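# symmetric eigendecomposition, eigenvalues descending
sym_eigen <- function(K) {
  if (nrow(K) < 256) {
    e <- eigen(K, symmetric = TRUE)
    return(list(values = e$values, vectors = e$vectors))
  }
  e <- eig_sym_dc(K)
  ord <- rev(seq_along(e$values))
  list(values = e$values[ord], vectors = e$vectors[, ord, drop = FALSE])
}

hard_calls <- function(dosage) {
  hc <- round(dosage)
  hc[hc < 0] <- 0
  hc[hc > 2] <- 2
  hc
}

#' Per-sample genotype quality control
#'
#' Removes samples with call missingness above 3% or a heterozygosity rate
#' (from hard calls) more than five standard deviations from the
#' sample-wise mean.
#'
#' @param genotypes A `genotype_data` object.
#' @param max_missing Maximum tolerated per-sample missingness.
#' @param het_sd Heterozygosity outlier threshold in standard deviations.
#' @return List with `genotypes` (filtered) and `report` (tibble of removed
#'   samples and reasons).
#' @export
sample_qc <- function(genotypes, max_missing = 0.03, het_sd = 5) {
  dos <- genotypes$dosage
  miss <- rowMeans(is.na(dos))
  hc <- hard_calls(dos)
  het <- rowMeans(hc == 1, na.rm = TRUE)
  het_z <- (het - mean(het)) / sd(het)
  het_out <- if (sd(het) == 0) rep(FALSE, nrow(dos)) else abs(het_z) > het_sd

  report <- dplyr::bind_rows(
    tibble::tibble(sample_id = rownames(dos)[miss > max_missing],
                   reason = "missingness"),
    tibble::tibble(sample_id = rownames(dos)[het_out],
                   reason = "heterozygosity")
  )
  keep <- setdiff(rownames(dos), report$sample_id)
  if (length(keep) < 10) stop("fewer than 10 samples remain after QC", call. = FALSE)
  out <- genotypes
  out$dosage <- dos[keep, , drop = FALSE]
  list(genotypes = out, report = report)
}

#' Hardy-Weinberg equilibrium test
#'
#' One-degree-of-freedom Pearson chi-squared test of observed genotype
#' counts against expectations at the observed allele frequency.
#' Monomorphic variants return p = 1 by convention.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (vectorized).
#' @return P-values.
#' @examples
#' hwe_test(50, 0, 50)   # total disequilibrium
#' hwe_test(25, 50, 25)  # exact HWE proportions
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  stopifnot(all(n >= 1))
  p <- (2 * n_AA + n_Aa) / (2 * n)
  exp_counts <- cbind(n * p^2, n * 2 * p * (1 - p), n * (1 - p)^2)
  obs <- cbind(n_AA, n_Aa, n_aa)
  chisq <- rowSums((obs - exp_counts)^2 / exp_counts)
  out <- pchisq(chisq, df = 1, lower.tail = FALSE)
  out[p == 0 | p == 1] <- 1
  out
}

#' Per-variant genotype quality control
#'
#' Applies the two-stage variant filters of a standard GWAS pipeline.
#' Pre-imputation stage: call rate at least 95%, minor allele count at
#' least 10, Hardy-Weinberg p at least 5e-4, palindromic (A/T, C/G)
#' variants with MAF above 0.4 removed. Post-imputation stage: minor allele
#' count at least 5 and imputation quality at least 0.3. Any filter can be
#' disabled by setting its parameter to `NULL`. Hardy-Weinberg is computed
#' on hard calls; fractional dosages trigger a warning.
#'
#' @param genotypes A `genotype_data` object.
#' @param params List of thresholds: `call_rate`, `mac`, `hwe_p`,
#'   `palindromic_maf`, `post_mac`, `imputation_r2`.
#' @return List with `genotypes` (surviving variants) and `report` (tibble
#'   of per-filter failure counts).
#' @export
variant_qc <- function(genotypes,
                       params = list(call_rate = 0.95, mac = 10, hwe_p = 5e-4,
                                     palindromic_maf = 0.4, post_mac = 5,
                                     imputation_r2 = 0.3)) {
  dos <- genotypes$dosage
  v <- genotypes$variants
  n <- nrow(dos)
  call_rate <- colMeans(!is.na(dos))
  af <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  hc <- hard_calls(dos)
  if (max(abs(dos - hc), na.rm = TRUE) > 1e-8) {
    warning("fractional dosages rounded to hard calls for the HWE test",
            call. = FALSE)
  }
  mac <- round(2 * colSums(!is.na(dos)) * maf)
  hwe <- hwe_test(colSums(hc == 0, na.rm = TRUE),
                  colSums(hc == 1, na.rm = TRUE),
                  colSums(hc == 2, na.rm = TRUE))
  r2 <- v$imputation_r2
  if (is.null(r2)) r2 <- rep(NA_real_, ncol(dos))

  fails <- list(
    call_rate = if (!is.null(params$call_rate)) call_rate < params$call_rate,
    mac = if (!is.null(params$mac)) mac < params$mac,
    hwe = if (!is.null(params$hwe_p)) hwe < params$hwe_p,
    palindromic = if (!is.null(params$palindromic_maf))
      v$palindromic & maf > params$palindromic_maf,
    post_mac = if (!is.null(params$post_mac)) mac < params$post_mac,
    imputation_r2 = if (!is.null(params$imputation_r2))
      !is.na(r2) & r2 < params$imputation_r2
  )
  fails <- fails[!vapply(fails, is.null, logical(1))]
  report <- tibble::tibble(filter = names(fails),
                           n_failed = vapply(fails, sum, integer(1)))
  drop <- if (length(fails)) Reduce(`|`, fails) else rep(FALSE, ncol(dos))
  if (all(drop)) stop("no variants survive QC", call. = FALSE)

  out <- genotypes
  out$dosage <- dos[, !drop, drop = FALSE]
  out$variants <- v[!drop, ]
  out$variants$call_rate <- call_rate[!drop]
  out$variants$MAF <- maf[!drop]
  out$variants$MAC <- mac[!drop]
  out$variants$hwe_p <- hwe[!drop]
  list(genotypes = out, report = report)
}

#' Genetic relationship matrix
#'
#' Standardized GRM: K = Z Z' / m with per-variant columns
#' (dosage - 2p) / sqrt(2 p (1 - p)), missing dosages mean-imputed.
#' Optionally excludes one chromosome (leave-one-chromosome-out
#' construction, which avoids proximal contamination when testing variants
#' on that chromosome).
#'
#' @param genotypes A `genotype_data` object.
#' @param exclude_chrom Chromosome label to leave out, or `NULL`.
#' @param samples Optional sample subset (ids).
#' @param variants Optional variant id subset (e.g. from [ld_prune()]).
#' @return A `grm` object: list with `K`, `excluded_chromosome`,
#'   `m_variants`.
#' @export
compute_grm <- function(genotypes, exclude_chrom = NULL, samples = NULL,
                        variants = NULL) {
  dos <- genotypes$dosage
  if (!is.null(samples)) dos <- dos[samples, , drop = FALSE]
  keep_var <- rep(TRUE, ncol(dos))
  if (!is.null(variants)) {
    keep_var <- keep_var & genotypes$variants$id %in% variants
  }
  if (!is.null(exclude_chrom)) {
    keep_var <- keep_var &
      !(genotypes$variants$chrom %in% as.character(exclude_chrom))
  }
  dos <- dos[, keep_var, drop = FALSE]
  if (ncol(dos) == 0) stop("no variants left for the GRM", call. = FALSE)

  p <- colMeans(dos, na.rm = TRUE) / 2
  mono <- p <= 0 | p >= 1
  if (any(mono)) {
    warning(sum(mono), " monomorphic variant(s) skipped in GRM", call. = FALSE)
    dos <- dos[, !mono, drop = FALSE]
    p <- p[!mono]
  }
  Z <- sweep(dos, 2, 2 * p)
  Z[is.na(Z)] <- 0  # mean imputation after centering
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), `/`)
  K <- tcrossprod(Z) / ncol(Z)
  structure(list(K = K, excluded_chromosome = exclude_chrom,
                 m_variants = ncol(Z)),
            class = "grm")
}

#' Read and write a GRM as square TSV
#'
#' Sample ids travel in the header row and first column.
#'
#' @param grm A `grm` object.
#' @param path File path.
#' @return For the reader, a `grm` object (excluded chromosome and variant
#'   count restored from the commented header).
#' @export
write_grm <- function(grm, path) {
  header <- sprintf("# excluded_chromosome=%s m_variants=%d",
                    grm$excluded_chromosome %||% "none", grm$m_variants)
  tab <- tibble::as_tibble(grm$K, .name_repair = "minimal")
  names(tab) <- rownames(grm$K) %||% paste0("s", seq_len(nrow(grm$K)))
  tab <- dplyr::bind_cols(tibble::tibble(sample_id = names(tab)), tab)
  writeLines(header, path)
  readr::write_tsv(tab, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_grm
#' @export
read_grm <- function(path) {
  header <- readLines(path, n = 1)
  excl <- sub(".*excluded_chromosome=(\\S+).*", "\\1", header)
  m <- as.integer(sub(".*m_variants=(\\d+).*", "\\1", header))
  tab <- read_delim_auto(path)
  K <- as.matrix(tab[, -1])
  rownames(K) <- tab[[1]]
  structure(list(K = K, excluded_chromosome = if (excl == "none") NULL else excl,
                 m_variants = m),
            class = "grm")
}

#' Attach the eigendecomposition to a GRM for reuse
#'
#' The decomposition is the expensive step of the mixed model; attaching
#' it once lets several phenotypes share it.
#'
#' @param grm A `grm` object.
#' @return The same object with an `eigen` element.
#' @export
grm_eigen <- function(grm) {
  if (is.null(grm$eigen)) grm$eigen <- sym_eigen(grm$K)
  grm
}

#' Greedy linkage-disequilibrium pruning
#'
#' Walks each chromosome in position order and keeps a variant only when
#' its squared correlation with every recently kept variant (a sliding
#' window) stays below the threshold. Principal components are computed on
#' the pruned panel so that a single high-LD block cannot masquerade as an
#' axis of population structure.
#'
#' @param genotypes A `genotype_data` object.
#' @param r2_threshold Maximum tolerated pairwise r-squared.
#' @param window Number of recently kept variants compared against.
#' @return Character vector of retained variant ids.
#' @export
ld_prune <- function(genotypes, r2_threshold = 0.2, window = 25L) {
  v <- genotypes$variants
  dos <- genotypes$dosage
  n <- nrow(dos)
  keep <- logical(nrow(v))
  for (chr in unique(v$chrom)) {
    ix <- which(v$chrom == chr)
    ix <- ix[order(v$pos[ix])]
    # standardize once so each comparison is a single crossproduct
    Z <- dos[, ix, drop = FALSE]
    Z <- sweep(Z, 2, colMeans(Z, na.rm = TRUE))
    Z[is.na(Z)] <- 0
    ss <- sqrt(colSums(Z^2))
    ss[ss == 0] <- Inf  # monomorphic: correlates with nothing, always kept
    Z <- sweep(Z, 2, ss, `/`)
    buf <- matrix(0, n, window)  # ring buffer of recently kept columns
    n_buf <- 0L
    pos <- 0L
    for (k in seq_along(ix)) {
      zk <- Z[, k]
      ok <- n_buf == 0L ||
        all((crossprod(buf[, seq_len(n_buf), drop = FALSE], zk))^2 <
              r2_threshold)
      if (ok) {
        keep[ix[k]] <- TRUE
        pos <- pos %% window + 1L
        buf[, pos] <- zk
        n_buf <- min(n_buf + 1L, window)
      }
    }
  }
  v$id[keep]
}

#' Genomic principal components
#'
#' Top-k eigenvectors of the GRM scaled by the square root of their
#' eigenvalues, with a deterministic sign convention (the largest-magnitude
#' loading of each component is positive).
#'
#' @param grm A `grm` object or symmetric matrix.
#' @param k Number of components.
#' @return n x k matrix of PC scores (rownames preserved).
#' @export
genomic_pcs <- function(grm, k = 10) {
  K <- if (inherits(grm, "grm")) grm$K else grm
  if (k > nrow(K)) stop("k exceeds the number of samples", call. = FALSE)
  e <- sym_eigen(K)
  vals <- pmax(e$values[seq_len(k)], 0)
  scores <- sweep(e$vectors[, seq_len(k), drop = FALSE], 2, sqrt(vals), `*`)
  for (j in seq_len(k)) {
    i_max <- which.max(abs(scores[, j]))
    if (scores[i_max, j] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- rownames(K)
  colnames(scores) <- paste0("PC", seq_len(k))
  scores
}

#' Genomic PCs directly from a genotype panel
#'
#' Computes the same scores as [genomic_pcs()] on the corresponding GRM,
#' but through the variants-by-variants crossproduct, which is much
#' cheaper when the (typically LD-pruned) panel is smaller than the
#' cohort.
#'
#' @param genotypes A `genotype_data` object.
#' @param k Number of components.
#' @param samples,variants Optional subsets (ids).
#' @return n x k PC score matrix with the [genomic_pcs()] sign convention.
#' @export
genotype_pcs <- function(genotypes, k = 10, samples = NULL, variants = NULL) {
  dos <- genotypes$dosage
  if (!is.null(samples)) dos <- dos[samples, , drop = FALSE]
  if (!is.null(variants)) dos <- dos[, variants, drop = FALSE]
  p <- colMeans(dos, na.rm = TRUE) / 2
  keep <- p > 0 & p < 1
  Z <- sweep(dos[, keep, drop = FALSE], 2, 2 * p[keep])
  Z[is.na(Z)] <- 0
  Z <- sweep(Z, 2, sqrt(2 * p[keep] * (1 - p[keep])), `/`)
  m <- ncol(Z)
  if (m >= nrow(Z)) {
    return(genomic_pcs(tcrossprod(Z) / m, k))
  }
  e <- sym_eigen(crossprod(Z) / m)
  scores <- Z %*% e$vectors[, seq_len(k), drop = FALSE] / sqrt(m)
  for (j in seq_len(k)) {
    i_max <- which.max(abs(scores[, j]))
    if (scores[i_max, j] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- rownames(dos)
  colnames(scores) <- paste0("PC", seq_len(k))
  scores
}

#' Rank-based inverse normal transformation
#'
#' Blom-offset transform: qnorm((rank - 3/8) / (n + 1/4)), average ranks
#' for ties.
#'
#' @param values Numeric vector (at least two distinct values).
#' @return Transformed vector (names preserved).
#' @export
rint <- function(values) {
  ok <- !is.na(values)
  if (length(unique(values[ok])) < 2) {
    stop("rank inverse-normal transform undefined for constant input",
         call. = FALSE)
  }
  out <- values
  r <- rank(values[ok], ties.method = "average")
  out[ok] <- qnorm((r - 3 / 8) / (sum(ok) + 1 / 4))
  out
}

#' Prepare a ratio phenotype for mixed-model association
#'
#' Regresses the standardized ratio on age, sex, age squared, age-by-sex,
#' age-squared-by-sex and the leading genomic principal components, then
#' applies the rank-based inverse normal transform to the residuals.
#'
#' @param values Named numeric vector (sample ids) of the ratio phenotype.
#' @param cohort Covariate tibble with `sample_id`, `age`, `sex`.
#' @param pcs Matrix of genomic PC scores with sample id rownames.
#' @return Named numeric phenotype vector over the complete cases.
#' @export
prepare_phenotype <- function(values, cohort, pcs) {
  ids <- intersect(names(values), intersect(cohort$sample_id, rownames(pcs)))
  y <- values[ids]
  cv <- cohort[match(ids, cohort$sample_id), ]
  X <- cbind(1, cv$age, cv$sex, cv$age^2, cv$age * cv$sex, cv$age^2 * cv$sex,
             pcs[ids, , drop = FALSE])
  cc <- complete.cases(y, X)
  y <- y[cc]
  X <- X[cc, , drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("phenotype design matrix is rank deficient",
                               call. = FALSE)
  res <- qr.resid(qrX, y)
  setNames(rint(res), names(y))
}

#' REML variance components for a kinship random effect
#'
#' Single-random-effect linear mixed model y = Xb + g + e with
#' cov(g) = sigma_g^2 K, fitted by restricted maximum likelihood after a
#' one-time eigendecomposition of K; the variance ratio
#' delta = sigma_e^2 / sigma_g^2 is optimized by golden-section search on
#' log(delta) over the interval -10 to 10.
#'
#' @param y Named numeric phenotype.
#' @param K Kinship matrix (a `grm` or plain symmetric matrix) with
#'   matching sample order.
#' @param X Fixed-effect design matrix; default intercept only.
#' @return An `lmm_fit` object: sigma_g2, sigma_e2, delta, h2, loglik, and
#'   the eigendecomposition for reuse.
#' @export
fit_lmm_reml <- function(y, K, X = NULL) {
  eig <- NULL
  if (inherits(K, "grm")) {
    eig <- K$eigen
    K <- K$K
  }
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  e <- if (is.null(eig)) sym_eigen(K) else eig
  d <- pmax(e$values, 0)
  U <- e$vectors
  ys <- crossprod(U, y)[, 1]
  Xs <- crossprod(U, X)

  reml_ll <- function(log_delta) {
    delta <- exp(log_delta)
    w <- 1 / (d + delta)
    XtWX <- crossprod(Xs, Xs * w)
    XtWy <- crossprod(Xs, ys * w)
    beta <- solve(XtWX, XtWy)
    r <- ys - Xs %*% beta
    rss <- sum(w * r^2)
    q <- ncol(X)
    0.5 * ((n - q) * log((n - q) / (2 * pi)) - (n - q) -
             (n - q) * log(rss) - sum(log(d + delta)) -
             determinant(XtWX, logarithm = TRUE)$modulus[1] +
             determinant(crossprod(X), logarithm = TRUE)$modulus[1])
  }

  opt <- optimize(reml_ll, interval = c(-10, 10), maximum = TRUE, tol = 1e-6)
  # guard: compare against the boundary points (near-zero or huge delta)
  cand <- c(opt$maximum, -10, 10)
  lls <- vapply(cand, reml_ll, numeric(1))
  log_delta <- cand[which.max(lls)]
  delta <- exp(log_delta)

  w <- 1 / (d + delta)
  XtWX <- crossprod(Xs, Xs * w)
  beta <- solve(XtWX, crossprod(Xs, ys * w))
  r <- ys - Xs %*% beta
  sigma_g2 <- sum(w * r^2) / (n - ncol(X))
  structure(
    list(sigma_g2 = sigma_g2, sigma_e2 = delta * sigma_g2, delta = delta,
         h2 = 1 / (1 + delta), loglik = max(lls), beta = beta[, 1],
         eigenvalues = d, eigenvectors = U, n = n),
    class = "lmm_fit"
  )
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("<lmm_fit> sigma_g2 = ", signif(x$sigma_g2, 4), ", sigma_e2 = ",
      signif(x$sigma_e2, 4), ", h2 = ", signif(x$h2, 4), "\n", sep = "")
  invisible(x)
}

#' Linear mixed-model genome-wide association
#'
#' EMMAX-style association: per chromosome, variance components are
#' estimated once by REML on the null (intercept-only) model using that
#' chromosome's leave-one-chromosome-out GRM, and every variant on the
#' chromosome is then tested by a generalized least squares Wald test
#' under the fixed variance ratio. With an identity GRM the results
#' coincide with ordinary least squares.
#'
#' @param phenotype Named numeric vector (sample ids), typically from
#'   [prepare_phenotype()], or a samples x phenotypes matrix with rownames
#'   (variance components are re-estimated per phenotype but the
#'   eigendecomposition and genotype rotation are shared).
#' @param genotypes A `genotype_data` object.
#' @param chromosomes Chromosomes to test; default all.
#' @param loco Use leave-one-chromosome-out GRMs (default). When `FALSE`, a
#'   single all-chromosome GRM is reused.
#' @param grms Optional pre-computed named list of `grm` objects keyed by
#'   excluded chromosome (or `"all"` when `loco = FALSE`); attach
#'   [grm_eigen()] to reuse decompositions across calls.
#' @return A `gwas_tbl` tibble: id, chrom, pos, eaf, beta, se, p, n,
#'   significant (p below 5e-8), with per-chromosome h2 estimates in
#'   attribute `variance_components`. Matrix input adds a `phenotype`
#'   column.
#' @export
lmm_gwas <- function(phenotype, genotypes, chromosomes = NULL, loco = TRUE,
                     grms = NULL) {
  y_mat <- if (is.matrix(phenotype)) phenotype else
    matrix(phenotype, ncol = 1, dimnames = list(names(phenotype), "phenotype"))
  ids <- intersect(rownames(y_mat), rownames(genotypes$dosage))
  if (!length(ids)) stop("phenotype and genotype samples do not overlap",
                         call. = FALSE)
  y_mat <- y_mat[ids, , drop = FALSE]
  n <- length(ids)
  v <- genotypes$variants
  if (is.null(chromosomes)) chromosomes <- unique(v$chrom)

  vc <- list()
  res <- list()
  grm_all <- NULL
  for (chr in as.character(chromosomes)) {
    grm <- if (!is.null(grms)) {
      grms[[if (loco) chr else "all"]]
    } else if (loco) {
      compute_grm(genotypes, exclude_chrom = chr, samples = ids)
    } else {
      if (is.null(grm_all)) grm_all <- grm_eigen(compute_grm(genotypes,
                                                             samples = ids))
      grm_all
    }
    grm <- grm_eigen(grm)
    U <- grm$eigen$vectors

    vix <- which(v$chrom == chr)
    G <- genotypes$dosage[ids, vix, drop = FALSE]
    af <- colMeans(G, na.rm = TRUE) / 2
    if (anyNA(G)) {
      for (j in seq_len(ncol(G))) G[is.na(G[, j]), j] <- 2 * af[j]
    }
    Gs <- crossprod(U, G)
    ones <- crossprod(U, rep(1, n))[, 1]

    for (ph in colnames(y_mat)) {
      y <- setNames(y_mat[, ph], ids)
      fit <- fit_lmm_reml(y, grm)
      vc[[paste(chr, ph)]] <- tibble::tibble(
        phenotype = ph, chrom = chr, sigma_g2 = fit$sigma_g2,
        sigma_e2 = fit$sigma_e2, h2 = fit$h2)

      w <- 1 / (fit$eigenvalues + fit$delta)
      ys <- crossprod(U, y)[, 1]
      a11 <- sum(w * ones^2)
      b1 <- sum(w * ones * ys)
      yy <- sum(w * ys^2)
      a12 <- colSums(Gs * (w * ones))
      a22 <- colSums(Gs^2 * w)
      b2 <- colSums(Gs * (w * ys))
      det <- a11 * a22 - a12^2
      beta <- (a11 * b2 - a12 * b1) / det
      alpha <- (a22 * b1 - a12 * b2) / det
      rss <- yy - alpha * b1 - beta * b2
      sigma2 <- rss / (n - 2)
      se <- sqrt(sigma2 * a11 / det)
      tval <- beta / se
      res[[paste(chr, ph)]] <- tibble::tibble(
        phenotype = ph, id = v$id[vix], chrom = chr, pos = v$pos[vix],
        eaf = unname(af), beta = unname(beta), se = unname(se),
        p = unname(2 * pt(-abs(tval), n - 2)), n = n
      )
    }
  }
  out <- dplyr::bind_rows(res)
  if (!is.matrix(phenotype)) out$phenotype <- NULL
  out$significant <- out$p < 5e-8
  attr(out, "variance_components") <- dplyr::bind_rows(vc)
  class(out) <- c("gwas_tbl", class(out))
  out
}

#' SNP-level p-gain for a ratio GWAS
#'
#' Per variant, the smaller of the two component-lipid GWAS p-values
#' divided by the ratio GWAS p-value. The significance threshold is ten
#' times the number of genome-wide-significant SNPs for the ratio.
#'
#' @param gwas_ratio,gwas_component_a,gwas_component_b `gwas_tbl` tibbles
#'   over the same variants.
#' @param n_significant_snps Number of significant SNPs for the ratio;
#'   default counted from `gwas_ratio` (minimum 1).
#' @return Tibble: id, chrom, pos, p_ratio, p_components, p_gain,
#'   p_gain_significant.
#' @export
snp_p_gain <- function(gwas_ratio, gwas_component_a, gwas_component_b,
                       n_significant_snps = NULL) {
  if (!identical(gwas_ratio$id, gwas_component_a$id) ||
      !identical(gwas_ratio$id, gwas_component_b$id)) {
    stop("variant sets differ between the ratio and component GWAS",
         call. = FALSE)
  }
  if (is.null(n_significant_snps)) {
    n_significant_snps <- max(1L, sum(gwas_ratio$significant))
  }
  p_comp <- pmin(gwas_component_a$p, gwas_component_b$p)
  gain <- p_comp / gwas_ratio$p
  tibble::tibble(
    id = gwas_ratio$id, chrom = gwas_ratio$chrom, pos = gwas_ratio$pos,
    p_ratio = gwas_ratio$p, p_components = p_comp, p_gain = gain,
    p_gain_significant = gain > p_gain_threshold(n_significant_snps)
  )
}

#' Read genotypes from VCF
#'
#' Uses dosage (`DS`) genotypes when present, otherwise allele counts from
#' `GT`. Imputation quality is taken from the `R2` INFO field when present.
#'
#' @param path Path to a VCF 4.x file.
#' @return A `genotype_data` object.
#' @export
read_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(vcf),
                                         stringsAsFactors = FALSE))
  ds <- tryCatch(vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE),
                 error = function(e) NULL)
  if (is.null(ds) || all(is.na(ds))) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    ds <- apply(gt, 2, function(col) {
      vapply(strsplit(col, "[/|]"), function(al) {
        if (any(is.na(al)) || any(al == ".")) NA_real_ else sum(al == "1")
      }, numeric(1))
    })
  }
  dosage <- t(ds)  # vcfR is variants x samples
  colnames(dosage) <- fix$ID
  r2 <- suppressWarnings(
    as.numeric(sub(".*R2=([0-9.eE+-]+).*", "\\1",
                   vcfR::getINFO(vcf)))
  )
  af <- colMeans(dosage, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  variants <- tibble::tibble(
    chrom = fix$CHROM, pos = as.numeric(fix$POS), id = fix$ID,
    ref = fix$REF, alt = fix$ALT,
    call_rate = colMeans(!is.na(dosage)),
    MAC = round(2 * colSums(!is.na(dosage)) * maf), MAF = maf,
    hwe_p = NA_real_, imputation_r2 = r2,
    palindromic = paste0(fix$REF, fix$ALT) %in% c("AT", "TA", "CG", "GC")
  )
  structure(list(dosage = dosage, variants = variants, causal_id = NULL),
            class = "genotype_data")
}

#' Write genotypes as minimal VCF 4.2
#'
#' Emits GT (hard calls) and DS (dosage) fields.
#'
#' @param genotypes A `genotype_data` object.
#' @param path Output path.
#' @export
write_vcf <- function(genotypes, path) {
  v <- genotypes$variants
  dos <- genotypes$dosage
  hc <- hard_calls(dos)
  gt_map <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(dos)), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(v)), function(i) {
    cells <- ifelse(is.na(dos[, i]), "./.:.",
                    paste0(gt_map[hc[, i] + 1], ":",
                           formatC(dos[, i], format = "g", digits = 6)))
    paste(c(v$chrom[i], format(v$pos[i], scientific = FALSE), v$id[i],
            v$ref[i], v$alt[i], ".", "PASS",
            paste0("R2=", formatC(v$imputation_r2[i], format = "g", digits = 4)),
            "GT:DS", cells), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
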