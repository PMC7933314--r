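small_spec <- function(...) {
  phantom_spec(dim = c(40, 40, 56), spacing_mm = c(3, 3, 3),
               liver_center_mm = c(60, 60, 50),
               liver_semiaxes_mm = c(42, 38, 32),
               tumors = list(list(center_mm = c(70, 60, 55),
                                  radius_mm = 14, tnr = 2.6)),
               lung_center_mm = c(60, 60, 135),
               lung_semiaxes_mm = c(42, 38, 18),
               ...)
}

test_that("phantom generation is deterministic given the seed", {
  a <- generate_phantom(small_spec(noise = "poisson", seed = 11))
  b <- generate_phantom(small_spec(noise = "poisson", seed = 11))
  expect_identical(a$map$values, b$map$values)
  expect_identical(a$planar$anterior, b$planar$anterior)
  c <- generate_phantom(small_spec(noise = "poisson", seed = 12))
  expect_false(identical(a$map$values, c$map$values))
})

test_that("voxelized geometry matches analytic volumes", {
  sp <- phantom_spec(dim = c(24, 24, 40), spacing_mm = c(1, 1, 1),
                     liver_center_mm = c(12, 12, 12),
                     liver_semiaxes_mm = c(10, 10, 9),
                     tumors = list(list(center_mm = c(12, 12, 12),
                                        radius_mm = 6.2, tnr = 2)),
                     lung_center_mm = c(12, 12, 33),
                     lung_semiaxes_mm = c(8, 8, 4),
                     shunt_fraction = 0, psf_sigma_mm = 0, seed = 1)
  ph <- generate_phantom(sp)
  expect_equal(ph$truth$tumor_ml_analytic, 4 / 3 * pi * 6.2^3 / 1000,
               tolerance = 1e-12)
  expect_lt(abs(ph$truth$tumor_ml_voxel - ph$truth$tumor_ml_analytic) /
              ph$truth$tumor_ml_analytic, 0.05)
  expect_lt(abs(ph$truth$target_ml_voxel - ph$truth$target_ml_analytic) /
              ph$truth$target_ml_analytic, 0.05)
})

test_that("degenerate specs are handled: no tumors, tumor outside liver", {
  sp <- small_spec(seed = 2)
  sp$tumors <- list()
  ph <- generate_phantom(sp)
  expect_true(is.na(ph$truth$tnr))
  expect_equal(ph$truth$hps, 0.069)

  bad <- small_spec(seed = 2)
  bad$tumors <- list(list(center_mm = c(10, 10, 130), radius_mm = 10,
                          tnr = 2))
  expect_error(generate_phantom(bad), "outside the liver")

  expect_error(phantom_spec(), "seed")
  expect_error(phantom_spec(shunt_fraction = 0.7, seed = 1), "shunt")
})

test_that("noise-free phantoms are recovered by the measurement chain", {
  ph <- generate_phantom(small_spec(psf_sigma_mm = 0, seed = 3))
  # a liver-side search VOI (everything below the lung), as a physician's
  # drawn VOI would be; the 1% isocontour then recovers the target exactly
  # on a noise-free piecewise-constant map
  d <- dim(ph$map$values)
  zc <- (seq_len(d[3]) - 0.5) * ph$map$spacing_mm[3]
  voi <- array(rep(zc < 100, each = d[1] * d[2]), d)
  seg <- isocontour_volume(ph$map, voi, 1)
  expect_equal(seg$mtv_ml, ph$truth$target_ml_voxel, tolerance = 1e-9)
  # TNR recovered from the generating masks
  tnr <- tumor_to_normal_ratio(ph$map, ph$masks$tumors, ph$masks$normal)
  expect_lt(abs(tnr - ph$truth$tnr) / ph$truth$tnr, 0.02)
  # shunt recovered exactly
  expect_lt(abs(lung_shunt_fraction(ph$planar)$hps - ph$truth$hps), 1e-6)
})

test_that("blur conserves counts away from the grid edges", {
  sp <- small_spec(psf_sigma_mm = 4, seed = 4)
  ph <- generate_phantom(sp)
  expect_lt(abs(sum(ph$map$values) - sp$total_counts) / sp$total_counts,
            1e-6)
})

test_that("simulated cohorts honor their generating parameters", {
  spec <- cohort_sim_spec(seed = 21)
  g <- generate_cohort(spec)
  expect_s3_class(g$cohort, "cohort_table")
  expect_equal(nrow(g$cohort), 24)
  expect_equal(sum(is.na(g$cohort$tgv_cbct_ml)), 5)
  expect_equal(sum(g$cohort$changed_administration), 4)
  expect_equal(sum(g$cohort$lobar_or_total), 7)
  expect_true(all(g$truth$tnr >= 1))
  expect_true(all(g$truth$hps >= 0 & g$truth$hps <= 0.2))
  # tumor volume never exceeds any observed target volume
  expect_true(all(g$truth$tumor_ml <
                  pmin(g$cohort$tgv_cect_ml, g$cohort$tgv_maa_ml,
                       g$cohort$tgv_pet_ml, na.rm = TRUE)))
  # round-trips through the cohort reader
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(g$cohort, f)
  expect_equal(load_cohort(f)$tgv_pet_ml, g$cohort$tgv_pet_ml,
               tolerance = 1e-6)
})

test_that("zero noise and unit bias give perfect concordance", {
  spec <- cohort_sim_spec(modality_bias = c(cect = 1, cbct = 1, maa = 1),
                          modality_noise_sd = c(cect = 0, cbct = 0, maa = 0),
                          changed_extra_sd = 0, seed = 31)
  g <- generate_cohort(spec)
  for (col in c("tgv_cect_ml", "tgv_maa_ml")) {
    expect_equal(lin_ccc(g$cohort[[col]], g$cohort$tgv_pet_ml)$ccc, 1)
  }
})

test_that("excluding changed administrations raises MAA concordance", {
  diffs <- vapply(1:30, function(s) {
    g <- generate_cohort(cohort_sim_spec(seed = 200 + s))
    all_ccc <- lin_ccc(g$cohort$tgv_maa_ml, g$cohort$tgv_pet_ml)$ccc
    keep <- !g$cohort$changed_administration
    sub_ccc <- lin_ccc(g$cohort$tgv_maa_ml[keep],
                       g$cohort$tgv_pet_ml[keep])$ccc
    sub_ccc - all_ccc
  }, 0)
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.7)
})

test_that("phantom and cohort specs load from YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("dim: [24, 24, 40]", "spacing_mm: [2, 2, 2]",
               "liver_center_mm: [24, 24, 24]",
               "liver_semiaxes_mm: [16, 14, 12]",
               "tumors:",
               "- center_mm: [28, 24, 26]", "  radius_mm: 6", "  tnr: 3",
               "lung_center_mm: [24, 24, 68]",
               "lung_semiaxes_mm: [14, 12, 6]",
               "shunt_fraction: 0.1", "psf_sigma_mm: 0",
               "total_counts: 1e5", "seed: 5"), f)
  sp <- phantom_spec_from_yaml(f)
  expect_s3_class(sp, "phantom_spec")
  expect_equal(sp$tumors[[1]]$tnr, 3)
  ph <- generate_phantom(sp)
  expect_lt(abs(lung_shunt_fraction(ph$planar)$hps - 0.1), 1e-6)

  f2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_patients: 10", "seed: 9",
               "modality_bias: {cect: 0.6, cbct: 0.7, maa: 0.9}",
               "modality_noise_sd: {cect: 0.3, cbct: 0.3, maa: 0.1}"), f2)
  sp2 <- cohort_sim_spec_from_yaml(f2)
  expect_equal(nrow(generate_cohort(sp2)$cohort), 10)
})
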