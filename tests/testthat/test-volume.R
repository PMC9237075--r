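test_that("volume round-trips through NIfTI with a non-trivial affine", {
  aff <- rbind(c(0, -1.2, 0, 10.5),
               c(-2, 0, 0, 7),
               c(0, 0, 3.1, -4.25),
               c(0, 0, 0, 1))
  vals <- array(rnorm(5 * 4 * 3), dim = c(5, 4, 3))
  v <- volume_grid(vals, affine = aff)
  p <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, p)
  v2 <- load_volume(p)
  expect_equal(v2$values, vals)
  # NIfTI stores the affine in float32
  expect_lt(max(abs(v2$affine - aff)), 1e-4)
  expect_equal(v2$spacing, c(2, 1.2, 3.1), tolerance = 1e-5)
})

test_that("load_volume rejects non-3D images", {
  p <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, dim = c(4, 4, 4, 2))), p)
  expect_error(load_volume(p), "3")
  expect_error(load_volume("no/such/file.nii.gz"))
})

test_that("voxel_to_world applies the 0-based affine convention", {
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- c(10, 20, 30)
  # voxel (1,1,1) in 1-based R indexing is voxel 0 -> the translation
  got <- enstrip:::voxel_to_world(aff, rbind(c(1, 1, 1), c(2, 3, 4)))
  expect_equal(unname(got), rbind(c(10, 20, 30), c(12, 24, 36)))
})

test_that("reorientation to RAS preserves world coordinates", {
  # axes stored as (A, -S, -R): a permuted, partly flipped volume
  aff <- rbind(c(0, 0, -1.5, 20),
               c(2, 0, 0, -15),
               c(0, -1, 0, 12),
               c(0, 0, 0, 1))
  vals <- array(seq_len(6 * 5 * 4), dim = c(6, 5, 4))
  v <- volume_grid(vals, affine = aff)
  r <- reorient_to_atlas(v)
  # RAS: positive dominant diagonal
  expect_true(all(diag(r$affine[1:3, 1:3]) > 0))
  expect_true(all(abs(r$affine[1:3, 1:3][upper.tri(diag(3)) |
                                           lower.tri(diag(3))]) < 1e-8))
  # the multiset of world positions of all voxels is unchanged, and the
  # voxel value at a given world position is preserved
  key <- function(vol) {
    idx <- as.matrix(expand.grid(i = seq_len(dim(vol$values)[1]),
                                 j = seq_len(dim(vol$values)[2]),
                                 k = seq_len(dim(vol$values)[3])))
    w <- unname(enstrip:::voxel_to_world(vol$affine, idx))
    ord <- order(w[, 1], w[, 2], w[, 3])
    list(w = round(w[ord, ], 6), v = vol$values[idx][ord])
  }
  k1 <- key(v); k2 <- key(r)
  expect_equal(k1$w, k2$w)
  expect_equal(k1$v, k2$v)
})

test_that("resampling onto the same grid is the identity", {
  v <- volume_grid(array(rnorm(4 * 4 * 4), dim = c(4, 4, 4)))
  r <- resample_to_atlas_grid(v, target_shape = c(4, 4, 4),
                              target_spacing_mm = c(1, 1, 1))
  expect_equal(r$values, v$values)
})

test_that("resampling preserves constants and keeps masks binary", {
  v <- volume_grid(array(3.5, dim = c(8, 8, 8)), affine = diag(c(2, 2, 2, 1)))
  r <- resample_to_atlas_grid(v, target_shape = c(12, 12, 12),
                              target_spacing_mm = c(1, 1, 1))
  inside <- r$values != 0  # voxels mapped inside the source support
  expect_true(any(inside))
  expect_true(all(abs(r$values[inside] - 3.5) < 1e-10))

  m <- volume_grid(array(as.double(random_mask(c(8, 8, 8))), dim = c(8, 8, 8)),
                   affine = diag(c(2, 2, 2, 1)))
  rm_ <- resample_to_atlas_grid(m, target_shape = c(10, 10, 10),
                                target_spacing_mm = c(1.5, 1.5, 1.5),
                                interpolation = "nearest")
  expect_true(all(rm_$values %in% c(0, 1)))
})

test_that("trilinear sampling is exact on linear fields", {
  d <- c(5, 6, 7)
  arr <- array(0, dim = d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3])
    arr[i, j, k] <- 2 * i - 3 * j + 0.5 * k
  cx <- runif(20, 1, d[1]); cy <- runif(20, 1, d[2]); cz <- runif(20, 1, d[3])
  got <- enstrip:::sample_trilinear(arr, cx, cy, cz)
  expect_equal(got, 2 * cx - 3 * cy + 0.5 * cz, tolerance = 1e-12)
  # outside the grid -> fill value
  expect_equal(enstrip:::sample_trilinear(arr, -1, 1, 1), 0)
})
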