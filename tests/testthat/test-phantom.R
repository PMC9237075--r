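test_that("phantom geometry invariant rejects heads that touch the border", {
  expect_error(generate_case(phantom_spec(grid_shape = c(32, 32, 32),
                                          brain_semiaxes_mm = c(14, 14, 14))),
               "margin|fit|exceed")
  # the small spec used throughout the tests is valid
  expect_s3_class(generate_case(small_phantom_spec()), "phantom_case")
})

test_that("phantom cases are deterministic and masks are binary", {
  spec <- small_phantom_spec(condition = "pre_op", seed = 9)
  a <- generate_case(spec)
  b <- generate_case(spec)
  expect_identical(a$volumes$T1$values, b$volumes$T1$values)
  expect_identical(a$brain_mask$values, b$brain_mask$values)
  expect_true(all(a$brain_mask$values %in% c(0, 1)))
  expect_gt(sum(a$brain_mask$values), 0)
})

test_that("noiseless phantoms take exactly the tabulated intensities", {
  spec <- small_phantom_spec(noise_sd = 0, condition = "pre_op", seed = 4)
  case <- generate_case(spec)
  ct <- default_contrast_table()
  for (m in c("FLAIR", "T1", "T1ce", "T2"))
    expect_true(all(case$volumes[[m]]$values %in% ct[, m]))
  # tumor voxels belong to the mask, and are bright on T1ce
  tum <- case$volumes$T1ce$values == ct["tumor", "T1ce"] &
    case$volumes$T1$values == ct["tumor", "T1"]
  expect_gt(sum(tum), 0)
  expect_true(all(case$brain_mask$values[tum] == 1))
})

test_that("post-op cavities are excluded from the brain mask", {
  spec_h <- small_phantom_spec(noise_sd = 0, condition = "healthy", seed = 5)
  spec_p <- small_phantom_spec(noise_sd = 0, condition = "post_op", seed = 5)
  h <- generate_case(spec_h)
  p <- generate_case(spec_p)
  expect_lt(sum(p$brain_mask$values), sum(h$brain_mask$values))
  # cavity voxels carry background intensity
  cav <- h$brain_mask$values == 1 & p$brain_mask$values == 0
  expect_gt(sum(cav), 0)
  expect_true(all(p$volumes$T1$values[cav] == 0))
})

test_that("ellipsoid mask volume approximates the analytic volume", {
  spec <- phantom_spec(grid_shape = c(64, 64, 64),
                       brain_semiaxes_mm = c(20, 25, 18), noise_sd = 0)
  case <- generate_case(spec)
  analytic <- 4 / 3 * pi * 20 * 25 * 18
  expect_lt(abs(sum(case$brain_mask$values) - analytic) / analytic, 0.02)
})

test_that("condition apportionment follows largest remainders", {
  mix <- c(healthy = 0.5, pre_op = 0.3, post_op = 0.2)
  expect_identical(enstrip:::apportion_conditions(24L, mix),
                   c(healthy = 12L, pre_op = 7L, post_op = 5L))
  expect_identical(sum(enstrip:::apportion_conditions(7L, mix)), 7L)
  expect_identical(enstrip:::apportion_conditions(10L, mix),
                   c(healthy = 5L, pre_op = 3L, post_op = 2L))
})

test_that("generate_cohort writes volumes, masks and a readable manifest", {
  out <- file.path(tempdir(), "enstrip-cohort-test")
  man <- generate_cohort(3, small_phantom_spec(), seed = 31, out_dir = out)
  expect_identical(nrow(man), 3L)
  expect_true(all(file.exists(man$flair, man$t1, man$t1ce, man$t2, man$mask)))
  man2 <- read_manifest(file.path(out, "manifest.csv"))
  expect_identical(man2$case_id, man$case_id)
  m <- load_volume(man$mask[1])
  expect_true(all(m$values %in% c(0, 1)))
  # per-case geometry jitter: cases differ
  v1 <- load_volume(man$mask[1])$values
  v2 <- load_volume(man$mask[2])$values
  expect_false(identical(v1, v2))
  # cohort generation is reproducible for the same seed
  out2 <- file.path(tempdir(), "enstrip-cohort-test2")
  man3 <- generate_cohort(3, small_phantom_spec(), seed = 31, out_dir = out2)
  expect_identical(load_volume(man3$flair[2])$values,
                   load_volume(man$flair[2])$values)
  unlink(c(out, out2), recursive = TRUE)
})
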