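test_that("z-score normalization uses nonzero voxels and keeps zeros", {
  vals <- array(0, dim = c(6, 6, 6))
  vals[2:5, 2:5, 2:5] <- rnorm(64, mean = 50, sd = 7)
  v <- normalize_intensity(volume_grid(vals))
  nz <- vals != 0
  expect_equal(mean(v$values[nz]), 0, tolerance = 1e-10)
  expect_equal(stats::sd(v$values[nz]), 1, tolerance = 1e-10)
  expect_true(all(v$values[!nz] == 0))
  expect_error(normalize_intensity(volume_grid(array(5, dim = c(4, 4, 4)))))
})

test_that("stack_modalities enforces the fixed FLAIR,T1,T1ce,T2 order", {
  mk <- function(x) volume_grid(array(x, dim = c(4, 4, 4)))
  vols <- list(T2 = mk(4), FLAIR = mk(1), T1ce = mk(3), T1 = mk(2))
  st <- stack_modalities(vols, combo = "f1c2")
  expect_identical(names(st$channels), c("FLAIR", "T1", "T1ce", "T2"))
  X <- enstrip:::stack_matrix(st)
  expect_equal(unname(X[1, ]), c(1, 2, 3, 4))
  st2 <- stack_modalities(vols[c("T2", "FLAIR")], combo = "f2")
  expect_identical(names(st2$channels), c("FLAIR", "T2"))
  expect_error(stack_modalities(vols[c("T1")], combo = "f1"))
})

test_that("apply_mask multiplies every channel by a binary mask", {
  mk <- function(x) volume_grid(array(x, dim = c(4, 4, 4)))
  st <- stack_modalities(list(FLAIR = mk(2), T1 = mk(3)), combo = "f1")
  m <- array(0, dim = c(4, 4, 4)); m[2:3, 2:3, 2:3] <- 1
  mask <- volume_grid(m)
  out <- apply_mask(st, mask)
  expect_equal(out$channels$FLAIR$values, 2 * m)
  expect_equal(out$channels$T1$values, 3 * m)
  bad <- volume_grid(array(0.5, dim = c(4, 4, 4)))
  expect_error(apply_mask(st, bad), "binary")
})

test_that("preprocess_case runs the full pipeline on a phantom", {
  case <- generate_case(small_phantom_spec(seed = 8))
  st <- preprocess_case(case$volumes, combo = "f1c2",
                        target_shape = c(32, 32, 32),
                        target_spacing_mm = c(1, 1, 1))
  expect_s3_class(st, "modality_stack")
  expect_identical(dim(st), c(32L, 32L, 32L))
  for (ch in st$channels) {
    nz <- ch$values != 0
    expect_equal(mean(ch$values[nz]), 0, tolerance = 1e-8)
    expect_equal(stats::sd(ch$values[nz]), 1, tolerance = 1e-8)
  }
  # restricting to a sub-combination keeps only those channels
  st2 <- preprocess_case(case$volumes[c("T1", "T2")], combo = "12",
                         target_shape = NULL)
  expect_identical(names(st2$channels), c("T1", "T2"))
})

test_that("noise reduction and bias correction hooks default to identity", {
  v <- volume_grid(array(rnorm(64), dim = c(4, 4, 4)))
  expect_identical(reduce_noise(v)$values, v$values)
  expect_identical(correct_bias_field(v)$values, v$values)
  expect_error(reduce_noise(v, method = "nonlocal-means"))
})
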