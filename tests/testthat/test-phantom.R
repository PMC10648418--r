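test_that("atrophy shrinks the hippocampal structures by the cubed factor", {
  pp <- phantom_params(base_side = 64, noise_sd = 0,
                       atrophy_factor = c(NC = 1, sMCI = 0.9, pMCI = 0.8,
                                          AD = 0.7))
  vAD <- generate_brain_phantom(pp, "AD")
  vNC <- generate_brain_phantom(pp, "NC")
  ratio <- hippocampal_voxel_count(vAD) / hippocampal_voxel_count(vNC)
  expect_equal(ratio, 0.7^3, tolerance = 0.05)

  expect_error(generate_brain_phantom(pp, "MCI"), "label")
  expect_error(phantom_params(atrophy_factor = c(NC = 0.7, sMCI = 0.8,
                                                 pMCI = 0.9, AD = 1)),
               "nonincreasing")
})

test_that("phantom generation is deterministic given the RNG state", {
  pp <- phantom_params(base_side = 32, noise_sd = 0.05, seed = 9)
  set.seed(9); v1 <- generate_brain_phantom(pp, "pMCI")
  set.seed(9); v2 <- generate_brain_phantom(pp, "pMCI")
  expect_identical(v1$voxels, v2$voxels)
  expect_true(all(v1$voxels >= 0 & v1$voxels <= 1))
})

test_that("mean hippocampal volume decreases along the disease axis", {
  pp <- phantom_params(base_side = 48, noise_sd = 0)
  set.seed(10)
  jit <- rnorm(50, sd = 0.02)
  means <- vapply(c("NC", "sMCI", "pMCI", "AD"), function(cl) {
    mean(vapply(jit, function(j)
      hippocampal_voxel_count(generate_brain_phantom(pp, cl,
                                                     subject_jitter = j)),
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("cube resampling preserves shape contracts", {
  pp <- phantom_params(base_side = 48, noise_sd = 0.05, seed = 2)
  set.seed(2)
  v <- generate_brain_phantom(pp, "NC")

  # idempotence at the native side
  same <- resample_to_cube(v, 48)
  expect_equal(same$voxels, v$voxels, tolerance = 1e-10)

  # anisotropic input is reshaped onto the requested cube
  aniso <- volume_sample(array(runif(20 * 24 * 24), c(20, 24, 24)), "NC",
                         "s1")
  out <- resample_to_cube(aniso, 32)
  expect_equal(dim(out$voxels), c(32L, 32L, 32L))
  expect_gte(min(out$voxels), min(aniso$voxels) - 1e-12)
  expect_lte(max(out$voxels), max(aniso$voxels) + 1e-12)

  const <- volume_sample(array(0.7, c(10, 12, 12)), "NC", "s1")
  expect_equal(max(abs(resample_to_cube(const, 21)$voxels - 0.7)), 0,
               tolerance = 1e-12)

  small <- resample_to_cube(v, 32)
  expect_equal(dim(small$voxels), c(32L, 32L, 32L))
  expect_error(resample_to_cube(volume_sample(array(1, c(1, 5, 5)), "NC",
                                              "s"), 8),
               "degenerate")
})

test_that("volumes round-trip through NIfTI with spacing intact", {
  pp <- phantom_params(base_side = 24, noise_sd = 0.05, seed = 3)
  set.seed(3)
  v <- generate_brain_phantom(pp, "sMCI", subject_id = "sMCI_s01",
                              voxel_spacing = c(1.2, 1, 1))
  path <- tempfile(fileext = ".nii.gz")
  write_volume(v, path)
  back <- read_volume(path)
  expect_equal(back$voxels, v$voxels, tolerance = 1e-12)
  expect_equal(back$voxel_spacing, c(1.2, 1, 1), tolerance = 1e-6)
  expect_error(read_volume(tempfile(fileext = ".nii")), "no such file")

  # manifest carries label and subject id
  dir <- tempfile(); dir.create(dir)
  co <- generate_cohort(pp, c(AD = 1, NC = 1), images_per_subject = 1,
                        seed = 4)
  mpath <- write_cohort(co, dir)
  expect_true(file.exists(mpath))
  v2 <- read_volume(file.path(dir, paste0(co$manifest$image[1], ".nii.gz")),
                    manifest = mpath)
  expect_equal(v2$label, co$manifest$label[1])
  expect_equal(v2$subject_id, co$manifest$subject_id[1])
  expect_error(read_volume(path, manifest = mpath), "not listed")

  back_cohort <- read_cohort(mpath)
  expect_equal(length(back_cohort$samples), 2)
  expect_equal(back_cohort$manifest$label, co$manifest$label)
})

test_that("cohorts have the requested structure and are reproducible", {
  pp <- phantom_params(base_side = 16, noise_sd = 0.02, seed = 5)
  co <- generate_cohort(pp, c(AD = 8, NC = 10), images_per_subject = 3,
                        seed = 5)
  expect_equal(length(co$samples), 54)
  expect_equal(length(unique(co$manifest$subject_id)), 18)
  # every subject appears with exactly one class
  tab <- unique(co$manifest[c("subject_id", "label")])
  expect_equal(nrow(tab), 18)

  co2 <- generate_cohort(pp, c(AD = 8, NC = 10), images_per_subject = 3,
                         seed = 5)
  expect_identical(co$manifest, co2$manifest)
  expect_identical(co$samples[[7]]$voxels, co2$samples[[7]]$voxels)
})

test_that("images of one subject correlate more than images across subjects", {
  pp <- phantom_params(base_side = 32, noise_sd = 0.02,
                       subject_jitter_sd = 0.05, seed = 6)
  co <- generate_cohort(pp, c(NC = 20), images_per_subject = 2, seed = 6)
  vecs <- vapply(co$samples, function(s) as.vector(s$voxels),
                 numeric(32^3))
  cors <- stats::cor(vecs)
  subj <- co$manifest$subject_id
  same <- outer(subj, subj, "==")
  diag(same) <- NA
  within <- mean(cors[same & !is.na(same)])
  between <- mean(cors[!same & !is.na(same)])
  expect_gt(within, between)
})
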