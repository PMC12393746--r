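test_that("OLS fits agree with a pseudoinverse oracle", {
  set.seed(101)
  for (rep in 1:5) {
    n <- 50
    covs <- tibble::tibble(sample_id = sprintf("s%02d", 1:n),
                           WC = rnorm(n, 95, 12), age = rnorm(n, 50, 10),
                           sex = rbinom(n, 1, 0.5))
    y <- matrix(rnorm(n * 3), n, 3,
                dimnames = list(covs$sample_id, paste0("t", 1:3)))
    fit <- fit_association(y, covs, "WC")
    X <- cbind(1, covs$WC, covs$age, covs$sex)
    beta_oracle <- solve(t(X) %*% X) %*% t(X) %*% y
    expect_equal(fit$beta, unname(beta_oracle[2, ]), tolerance = 1e-8)
    # residual t identity
    expect_equal(fit$t, fit$beta / fit$se, tolerance = 1e-10)
  }
})

test_that("null associations produce uniform p-values", {
  set.seed(77)
  n <- 5000
  covs <- tibble::tibble(sample_id = sprintf("s%04d", 1:n),
                         WC = rnorm(n, 95, 12), age = rnorm(n, 50, 10),
                         sex = rbinom(n, 1, 0.5))
  y <- matrix(rnorm(n * 200), n, 200,
              dimnames = list(covs$sample_id, paste0("t", 1:200)))
  fit <- fit_association(y, covs, "WC")
  expect_gt(suppressWarnings(ks.test(fit$p, "punif"))$p.value, 0.01)
})

test_that("beta is invariant to affine rescaling of covariates", {
  set.seed(55)
  n <- 200
  covs <- tibble::tibble(sample_id = sprintf("s%03d", 1:n),
                         WC = rnorm(n, 95, 12), age = rnorm(n, 50, 10),
                         sex = rbinom(n, 1, 0.5))
  y <- matrix(rnorm(n), n, 1, dimnames = list(covs$sample_id, "t"))
  fit1 <- fit_association(y, covs, "WC")
  covs2 <- dplyr::mutate(covs, age = 3 * age - 40)
  fit2 <- fit_association(y, covs2, "WC")
  expect_equal(fit1$beta, fit2$beta, tolerance = 1e-10)
})

test_that("p-gain arithmetic and threshold match their definitions", {
  pg <- p_gain(4.30e-68, c(4.31e-22, 3.36e-35), n_tests = 82)
  expect_equal(pg$value, 3.36e-35 / 4.30e-68)
  expect_true(pg$significant)

  expect_equal(p_gain(1e-5, c(1e-5, 0.2), 82)$value, 1)
  expect_false(p_gain(1e-5, c(1e-5, 0.2), 82)$significant)
  expect_equal(p_gain_threshold(82), 820)
  expect_error(p_gain(0, c(0.1), 10), "0")
  expect_error(p_gain(0.5, c(1.2), 10), "0, 1")
})

test_that("BH adjustment matches the step-up hand computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  set.seed(1)
  p <- runif(40)
  perm <- sample(40)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
})

test_that("stored p-gains are reproducible from stored p-values", {
  sim <- simulate_cohort(small_study_config(), seed = 18)
  assoc <- associate_ratios(sim$lipidomics, sim$cohort, "WC")
  recomputed <- purrr::map2_dbl(assoc$p_bh, assoc$components, function(rp, comp) {
    min(comp$p_bh) / rp
  })
  expect_identical(assoc$p_gain, recomputed)
  expect_identical(assoc$p_gain_significant, assoc$p_gain > 820)
})

test_that("stratified fits coincide with the fully interacted model", {
  set.seed(42)
  n <- 600
  covs <- tibble::tibble(sample_id = sprintf("s%04d", 1:n),
                         WC = rnorm(n, 95, 12), age = rnorm(n, 50, 10),
                         sex = rbinom(n, 1, 0.5))
  slope <- ifelse(covs$sex == 1, -0.02, 0.02)
  y <- matrix(slope * covs$WC + 0.01 * covs$age + rnorm(n), n, 1,
              dimnames = list(covs$sample_id, "t"))
  res <- sex_interaction(y, covs, "WC")
  female <- res$female[[1]]
  male <- res$male[[1]]
  # implied male slope = female slope + interaction coefficient
  expect_equal(male$beta, female$beta + res$interaction_beta,
               tolerance = 1e-8)
  expect_error(sex_interaction(y, dplyr::mutate(covs, sex = 1), "WC"),
               "both sexes")
})

test_that("opposite per-sex slopes are detected with correct signs", {
  set.seed(4242)
  n <- 5000
  covs <- tibble::tibble(sample_id = sprintf("s%05d", 1:(2 * n)),
                         WC = rnorm(2 * n, 95, 12), age = rnorm(2 * n, 50, 10),
                         sex = rep(c(0, 1), each = n))
  slope <- ifelse(covs$sex == 1, -0.01, 0.01)
  y <- matrix(slope * covs$WC + rnorm(2 * n), 2 * n, 1,
              dimnames = list(covs$sample_id, "t"))
  res <- sex_interaction(y, covs, "WC")
  expect_lt(res$interaction_p_bh[1], 0.05)
  expect_gt(res$female[[1]]$beta, 0)
  expect_lt(res$male[[1]]$beta, 0)
})

test_that("interaction test keeps nominal type-I error under the null", {
  set.seed(7)
  n <- 200
  reps <- 1000
  rejections <- 0
  for (i in seq_len(reps)) {
    wc <- rnorm(n, 95, 12)
    sex <- rbinom(n, 1, 0.5)
    age <- rnorm(n, 50, 10)
    y <- 0.01 * wc + rnorm(n)  # same slope in both sexes
    fit <- lm(y ~ wc * sex + age * sex)
    p <- summary(fit)$coefficients["wc:sex", 4]
    rejections <- rejections + (p < 0.05)
  }
  mc_se <- sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(rejections / reps - 0.05), 3 * mc_se)
})

test_that("concordance counts and correlations match a recount oracle", {
  sim <- simulate_cohort(small_study_config(), seed = 25)
  assoc <- associate_ratios(sim$lipidomics, sim$cohort, "WC")
  self <- concordance(assoc, assoc, policy = "sign")
  expect_equal(self$n_concordant, self$n_shared)
  expect_equal(self$beta_correlation, 1)

  flipped <- assoc
  flipped$beta[3] <- -flipped$beta[3]
  one_off <- concordance(assoc, flipped, policy = "sign")
  expect_equal(one_off$n_concordant, one_off$n_shared - 1)
  expect_equal(one_off$discordant, assoc$target[3])

  set.seed(12)
  noisy <- assoc
  noisy$beta <- noisy$beta + rnorm(nrow(noisy), 0, sd(noisy$beta))
  rep <- concordance(assoc, noisy, policy = "sign")
  brute <- sum(sign(assoc$beta) == sign(noisy$beta))
  expect_equal(rep$n_concordant, brute)
  expect_true(rep$beta_correlation > 0 && rep$beta_correlation < 1)

  expect_error(concordance(assoc, dplyr::mutate(assoc, target = paste0(target, "_x"))),
               "shared")
})

test_that("Mann-Whitney results match exact enumeration and rank properties", {
  expr <- cbind(g1 = c(1, 2, 3, 4, 5, 6))
  rownames(expr) <- sprintf("s%d", 1:6)
  res <- group_difference(expr, rep(c("a", "b"), each = 3))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)   # 2 * 1/20 orderings

  same <- cbind(g1 = rep(2, 8))
  expect_equal(group_difference(same, rep(c("a", "b"), each = 4))$p, 1)

  set.seed(3)
  x <- matrix(rnorm(40), 20, 2, dimnames = list(sprintf("s%d", 1:20), c("a", "b")))
  grp <- rep(c("a", "b"), each = 10)
  p1 <- group_difference(x, grp)$p
  p2 <- group_difference(exp(x), grp)$p  # monotone transform
  expect_equal(p1, p2)
})
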