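# Synthetic cohort and slice generator: determinism, calibration to the
# configured marginals/correlations, and image fidelity.

test_that("identical configuration yields identical cohorts and slices", {
  cfg <- small_config(n_subjects = 12, seed = 77)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  attr(c1, "generator_config") <- NULL
  attr(c2, "generator_config") <- NULL
  expect_identical(c1, c2)
  s1 <- generate_pdff_slice(c1[3, ], cfg)
  s2 <- generate_pdff_slice(c1[3, ], cfg)
  expect_identical(s1$map$intensities, s2$map$intensities)
  expect_identical(s1$masks$labels, s2$masks$labels)
  # a different seed changes the draw
  c3 <- generate_cohort(small_config(n_subjects = 12, seed = 78))
  expect_false(identical(c1$bmi, c3$bmi))
})

test_that("configuration contract violations are rejected", {
  expect_error(generator_config(n_subjects = 1),
               class = "musclemap_config_error")
  expect_error(generator_config(obese_fraction = 0),
               class = "musclemap_config_error")
  expect_error(generator_config(obese_fraction = 1.2),
               class = "musclemap_config_error")
  expect_error(generator_config(septum_fat_fraction_range = c(15, 30)),
               class = "musclemap_config_error")
  expect_error(generator_config(pixel_spacing = -1),
               class = "musclemap_config_error")
  bad_marg <- default_marginals()
  bad_marg$sd[1] <- 0
  expect_error(generator_config(stratum_marginals = bad_marg),
               class = "musclemap_config_error")
  # asymmetric correlation input
  R <- default_correlations("non_obese")
  Rbad <- R
  Rbad[1, 2] <- 0.5
  expect_error(
    generator_config(correlation_targets = list(non_obese = Rbad, obese = R)),
    "symmetric"
  )
})

test_that("a slightly indefinite user correlation matrix is PSD-projected", {
  R <- default_correlations("non_obese", calibrated = FALSE)
  cfg <- generator_config(correlation_targets = list(non_obese = R, obese = R))
  ev <- eigen(cfg$correlation_targets$non_obese, symmetric = TRUE,
              only.values = TRUE)$values
  expect_gte(min(ev), 0)
  expect_equal(diag(cfg$correlation_targets$non_obese), rep(1, 14),
               ignore_attr = TRUE)
})

test_that("derived subject fields are mutually consistent", {
  cohort <- generate_cohort(generator_config(n_subjects = 400, seed = 5))
  expect_equal(nrow(cohort), 400)
  expect_equal(cohort$bmi, cohort$weight / cohort$height^2, tolerance = 1e-12)
  expect_identical(cohort$obese, cohort$bmi >= 30)
  expect_true(all(cohort$target_ratio > 0 & cohort$target_ratio < 1))
  expect_true(all(cohort$target_pdff_muscle >= 0 &
                    cohort$target_pdff_muscle <= 100))
  expect_true(all(cohort$target_csa_total > 0))
  expect_true(all(cohort$resistance > 0))
  # Janssen round trip at full cohort scale
  back <- smi_bia(janssen_smm(cohort$resistance, cohort$height * 100,
                              cohort$age, cohort$sex), cohort$height)
  expect_lt(max(abs(back / cohort$smi_bia - 1)), 1e-9)
})

test_that("independent correlations produce near-zero sample correlation", {
  R0 <- default_correlations("obese")
  R <- diag(nrow(R0))
  dimnames(R) <- dimnames(R0)
  cfg <- generator_config(n_subjects = 10000, seed = 9,
                          correlation_targets = list(non_obese = R, obese = R))
  cohort <- generate_cohort(cfg)
  sub <- cohort[!cohort$obese & cohort$sex == "male", ]
  expect_lt(abs(cor(sub$age, sub$smi_bia)), 0.03)
  expect_lt(abs(cor(sub$lean_body_mass_index, sub$vat)), 0.03)
})

test_that("marginals and targeted correlations are calibrated", {
  # seed-averaged (10 seeds x n = 10000) to separate calibration error from
  # sampling noise in the smallest stratum-sex cell; weight is derived
  # (bmi * height^2) rather than drawn, so it is not part of the check
  seeds <- 101:110
  pairs <- musclemap:::calibration_pairs()
  cfg0 <- generator_config(n_subjects = 10000, seed = seeds[1])
  marg <- cfg0$stratum_marginals
  col_of <- function(v) switch(v, ammi_total = "target_ammi_total",
                               ammi_fatfree = "target_ammi_fatfree",
                               pdff_muscle = "target_pdff_muscle", v)
  marg_mean <- matrix(0, nrow(marg), length(seeds))
  marg_sd <- matrix(0, nrow(marg), length(seeds))
  corr_acc <- NULL
  for (k in seq_along(seeds)) {
    cfg <- generator_config(n_subjects = 10000, seed = seeds[k])
    cohort <- generate_cohort(cfg)
    for (i in seq_len(nrow(marg))) {
      sel <- cohort$obese == marg$obese[i]
      if (marg$sex[i] != "both") sel <- sel & cohort$sex == marg$sex[i]
      x <- cohort[[col_of(marg$variable[i])]][sel]
      marg_mean[i, k] <- mean(x)
      marg_sd[i, k] <- sd(x)
    }
    cohort$ammi_total <- cohort$target_ammi_total
    cohort$ammi_fatfree <- cohort$target_ammi_fatfree
    cohort$pdff_muscle <- cohort$target_pdff_muscle
    rows <- NULL
    for (ob in c(FALSE, TRUE)) {
      R <- cfg$correlation_targets[[if (ob) "obese" else "non_obese"]]
      for (sx in c("male", "female")) {
        sub <- cohort[cohort$obese == ob & cohort$sex == sx, ]
        for (p in pairs) {
          rows <- rbind(rows, data.frame(
            pair = paste(p, collapse = "~"), obese = ob, sex = sx,
            target = R[p[1], p[2]], r = cor(sub[[p[1]]], sub[[p[2]]])
          ))
        }
      }
    }
    corr_acc <- if (is.null(corr_acc)) rows else {
      corr_acc$r <- corr_acc$r + rows$r
      corr_acc
    }
  }
  mean_err <- abs(rowMeans(marg_mean) / marg$mean - 1)
  sd_err <- abs(rowMeans(marg_sd) / marg$sd - 1)
  expect_lt(max(mean_err), 0.01)
  expect_lt(max(sd_err), 0.03)
  corr_acc$r <- corr_acc$r / length(seeds)
  expect_lt(max(abs(corr_acc$r - corr_acc$target)), 0.03)
})

test_that("masks are disjoint, inside the grid, 4-connected, with exact area", {
  cfg <- small_config(n_subjects = 6, seed = 33)
  cohort <- generate_cohort(cfg)
  for (i in seq_len(nrow(cohort))) {
    sl <- generate_pdff_slice(cohort[i, ], cfg)
    lab <- sl$masks$labels
    # label encoding makes masks disjoint; every compartment present
    expect_setequal(sort(unique(as.vector(lab[lab > 0]))), 1:8)
    for (k in 1:8) {
      expect_true(musclemap:::is_four_connected(lab == k))
    }
    V <- sum(lab > 0)
    expect_lte(abs(V * cfg$pixel_spacing^2 - cohort$target_csa_total[i]),
               cfg$pixel_spacing^2)
  }
})

test_that("quantification recovers the generator targets", {
  cfg <- generator_config(n_subjects = 25, seed = 44)
  cohort <- generate_cohort(cfg)
  mq <- simulate_and_quantify(cohort, cfg)
  V <- mq$n_voxels
  # CSA within one voxel area
  expect_true(all(abs(mq$csa_total - cohort$target_csa_total) <=
                    cfg$pixel_spacing^2))
  # ratio within 1/V when no feasibility projection occurred
  ok <- !mq$feasibility_projected
  expect_true(any(ok))
  expect_true(all(abs(mq$ratio / 100 - cohort$target_ratio)[ok] <= 1 / V[ok]))
  expect_true(all(abs(mq$pdff_muscle - cohort$target_pdff_muscle)[ok] <= 0.5))
  # projected subjects still match their recorded effective PDFF
  expect_true(all(abs(mq$pdff_muscle - mq$pdff_effective) <= 0.5))
})

test_that("a subject at the printed cohort means is recovered", {
  cfg <- generator_config(seed = 55)
  subject <- tibble::tibble(
    subject_id = "MEAN", target_csa_total = 8759.2,
    target_ratio = 0.577, target_pdff_muscle = 11.5, slice_seed = 4242
  )
  sl <- generate_pdff_slice(subject, cfg)
  expect_false(sl$qc$feasibility_projected)
  m <- quantify_subject(sl$map, sl$masks, height = 1.715, id = "MEAN")
  expect_lt(abs(m$csa_total - 8759.2), cfg$pixel_spacing^2)
  expect_lt(abs(m$ratio - 57.7), 2)
  expect_lt(abs(m$pdff_muscle - 11.5), 0.5)
})

test_that("degenerate fat-free subject yields ratio 100%", {
  cfg <- small_config(seed = 66)
  subject <- tibble::tibble(
    subject_id = "FF", target_csa_total = 6000,
    target_ratio = 1.0, target_pdff_muscle = 5, slice_seed = 99
  )
  sl <- generate_pdff_slice(subject, cfg)
  vals <- sl$map$intensities[sl$masks$labels > 0]
  expect_true(all(vals <= 200))
  m <- quantify_subject(sl$map, sl$masks, height = 1.7)
  expect_equal(m$ratio, 100)
})

test_that("jointly infeasible targets trigger the feasibility projection", {
  cfg <- small_config(seed = 67)
  # PDFF below the septum-driven floor: (1 - ratio) * 20 > pdff
  low <- tibble::tibble(subject_id = "LOW", target_csa_total = 6000,
                        target_ratio = 0.3, target_pdff_muscle = 2,
                        slice_seed = 7)
  sl <- generate_pdff_slice(low, cfg)
  expect_true(sl$qc$feasibility_projected)
  expect_gt(sl$qc$pdff_effective, 2)
  # PDFF above what fat-free voxels can carry
  high <- tibble::tibble(subject_id = "HIGH", target_csa_total = 6000,
                         target_ratio = 0.9, target_pdff_muscle = 60,
                         slice_seed = 8)
  sl2 <- generate_pdff_slice(high, cfg)
  expect_true(sl2$qc$feasibility_projected)
  expect_lt(sl2$qc$pdff_effective, 60)
})

test_that("YAML configuration round trip and error handling", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_subjects: 10", "seed: 3", "grid_size: 96",
               "pixel_spacing: 3.0"), path)
  cfg <- read_generator_config(path)
  expect_s3_class(cfg, "generator_config")
  expect_equal(cfg$n_subjects, 10L)
  expect_equal(cfg$pixel_spacing, 3)
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_subjects: 10", "  seed: : 3"), bad)
  expect_error(read_generator_config(bad), class = "musclemap_config_error")
  unknown <- withr::local_tempfile(fileext = ".yaml")
  writeLines("not_a_field: 1", unknown)
  expect_error(read_generator_config(unknown),
               class = "musclemap_config_error")
  expect_error(read_generator_config("does/not/exist.yaml"),
               class = "musclemap_config_error")
})
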