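test_that("reference factors follow median/consensus arithmetic", {
  ds <- harmonization_fixture()
  species <- colnames(ds$concentrations)

  # reference medians (4, 2); consensus equal -> all factors 1
  fac <- reference_correction_factors(ds, setNames(c(4, 2), species))
  expect_equal(fac$factor, c(1, 1))

  # reference median 4 over consensus 2 -> factor 2
  fac2 <- reference_correction_factors(ds, setNames(c(2, 2), species))
  expect_equal(fac2$factor[1], 2)

  expect_error(reference_correction_factors(ds, setNames(2, species[1])),
               species[2], fixed = TRUE)
  no_ref <- tiny_lipidome()
  expect_error(reference_correction_factors(no_ref, setNames(c(1, 1, 1, 1),
                                                             colnames(no_ref$concentrations))),
               "no reference")
})

test_that("applying reference factors aligns medians and is idempotent", {
  ds <- harmonization_fixture()
  species <- colnames(ds$concentrations)
  consensus <- setNames(c(2, 8), species)
  fac <- reference_correction_factors(ds, consensus)
  corrected <- apply_correction(ds, fac)
  ref_ids <- ds$samples$sample_id[ds$samples$is_reference]
  expect_equal(
    unname(apply(corrected$concentrations[ref_ids, ], 2, median)),
    unname(consensus)
  )
  refac <- reference_correction_factors(corrected, consensus)
  expect_equal(refac$factor, c(1, 1))

  # scale equivariance: c * matrix, re-derive, same corrected matrix
  scaled <- ds
  scaled$concentrations <- ds$concentrations * 7
  fac_s <- reference_correction_factors(scaled, consensus)
  corrected_s <- apply_correction(scaled, fac_s)
  expect_equal(corrected_s$concentrations, corrected$concentrations)

  expect_error(apply_correction(ds, fac[1, ]), "no correction factor")
})

test_that("matched sub-cohorts give unit factors for identical cohorts", {
  cfg <- small_study_config(cohort_scale = c(1, 1))
  sim <- simulate_cohort(cfg, seed = 31)
  fac <- matched_subcohort_factors(sim$lipidomics, sim$cohort,
                                   sim$lipidomics, sim$cohort, n_pairs = 80)
  expect_true(all(fac$factor == 1))

  doubled <- sim$lipidomics
  sp <- colnames(doubled$concentrations)[5]
  doubled$concentrations[, sp] <- doubled$concentrations[, sp] * 2
  fac2 <- matched_subcohort_factors(sim$lipidomics, sim$cohort,
                                    doubled, sim$cohort, n_pairs = 80)
  expect_equal(fac2$factor[fac2$species == sp], 0.5)
  expect_true(all(fac2$factor[fac2$species != sp] == 1))

  males <- sim$cohort[sim$cohort$sex == 1, ]
  females <- sim$cohort[sim$cohort$sex == 0, ]
  females$disease <- 1 - males$disease[1]  # force disjoint strata too
  expect_error(
    matched_subcohort_factors(sim$lipidomics,
                              dplyr::mutate(males, disease = 0),
                              sim$lipidomics,
                              dplyr::mutate(females, sex = 0, disease = 1)),
    "stratum"
  )
})

test_that("PQC centering equalizes batch medians and is idempotent", {
  ds <- harmonization_fixture()
  centered <- pqc_median_center(ds)
  pqc_ids <- ds$samples$sample_id[ds$samples$is_pqc]
  batches <- ds$samples$batch[match(pqc_ids, ds$samples$sample_id)]
  for (sp in colnames(ds$concentrations)) {
    meds <- tapply(centered$concentrations[pqc_ids, sp], batches, median)
    expect_equal(unname(diff(range(meds))), 0)
  }
  # species 1 had batch-2 PQC median double batch 1: batch-2 samples halved
  # relative to their batch factor (4/3 vs global median 3)
  expect_equal(centered$concentrations["b2", 1],
               ds$concentrations["b2", 1] / (4 / 3))

  again <- pqc_median_center(centered)
  expect_equal(again$concentrations, centered$concentrations)

  single <- tiny_lipidome()
  single$samples$is_pqc[1] <- TRUE
  expect_equal(pqc_median_center(single)$concentrations,
               single$concentrations)

  missing_pqc <- harmonization_fixture()
  missing_pqc$concentrations["PQC3", 1] <- NA_real_
  missing_pqc$concentrations["PQC4", 1] <- NA_real_
  expect_warning(out <- pqc_median_center(missing_pqc), "uncorrected")
  # uncorrected species left untouched in that batch
  expect_equal(out$concentrations["b2", 1], missing_pqc$concentrations["b2", 1])

  no_pqc <- harmonization_fixture()
  no_pqc$samples$is_pqc[no_pqc$samples$batch == "batch2"] <- FALSE
  expect_error(pqc_median_center(no_pqc), "batch2")
})

test_that("reference correction removes a configured cohort scale offset", {
  cfg <- small_study_config(cohort_scale = c(1.4, 1))
  st <- simulate_study(cfg, seed = 13, genotypes = FALSE)
  corrected <- apply_correction(
    st$cohort_a$lipidomics,
    reference_correction_factors(st$cohort_a$lipidomics, st$consensus)
  )
  ref_ids <- corrected$samples$sample_id[corrected$samples$is_reference]
  med <- apply(corrected$concentrations[ref_ids, ], 2, median)
  expect_equal(unname(med), unname(st$consensus), tolerance = 1e-12)
})
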