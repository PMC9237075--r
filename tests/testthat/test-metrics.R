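test_that("rate metrics reproduce a hand-worked confusion table", {
  # TP=3, FP=1, FN=1, TN=95
  pred <- array(0, dim = c(10, 10, 1)); gt <- pred
  pred[1:4, 1, 1] <- 1          # voxels 1-4 predicted
  gt[2:5, 1, 1] <- 1            # voxels 2-5 true
  p <- volume_grid(pred); g <- volume_grid(gt)
  cc <- confusion_counts(p, g)
  expect_identical(c(cc$TP, cc$FP, cc$FN, cc$TN), c(3L, 1L, 1L, 95L))
  r <- rate_metrics(cc)
  expect_equal(r$dice, 0.75)
  expect_equal(r$precision, 0.75)
  expect_equal(r$recall, 0.75)
  expect_equal(r$fpr, 1 / 96)
  expect_equal(r$fnr, 0.25)
})

test_that("degenerate masks follow the documented conventions", {
  z <- volume_grid(array(0, dim = c(4, 4, 4)))
  o <- volume_grid(array(1, dim = c(4, 4, 4)))
  r0 <- rate_metrics(confusion_counts(z, z))
  expect_equal(unlist(r0[c("dice", "precision", "recall")]),
               c(dice = 1, precision = 1, recall = 1))
  expect_equal(unlist(r0[c("fpr", "fnr")]), c(fpr = 0, fnr = 0))
  expect_equal(rate_metrics(confusion_counts(o, z))$dice, 0)
  expect_error(hd95(z, o), "nonempty")
  expect_true(is.na(evaluate_case(z, o)$hd95_mm))
})

test_that("metrics refuse misaligned grids", {
  a <- volume_grid(array(1, dim = c(4, 4, 4)))
  b <- volume_grid(array(1, dim = c(4, 4, 4)), affine = diag(c(2, 2, 2, 1)))
  expect_error(confusion_counts(a, b), "alignment|grid")
  expect_error(hd95(a, b), "alignment|grid")
})

test_that("hd95 is zero for identical masks and exact on a known pair", {
  m <- array(0, dim = c(12, 12, 12)); m[4:8, 4:8, 4:8] <- 1
  v <- volume_grid(m, affine = diag(c(1, 2, 0.5, 1)))
  expect_equal(hd95(v, v), 0)

  # two 1-voxel masks: distance is simply the inter-centre distance
  a <- array(0, dim = c(8, 8, 8)); a[2, 2, 2] <- 1
  b <- array(0, dim = c(8, 8, 8)); b[5, 2, 6] <- 1
  sp <- c(1, 1, 2)
  expect_equal(hd95(volume_grid(a, affine = diag(c(sp, 1))),
                    volume_grid(b, affine = diag(c(sp, 1)))),
               sqrt(3^2 + (4 * 2)^2))
})

test_that("hd95 matches the brute-force oracle under anisotropic spacing", {
  set.seed(77)
  for (rep in 1:5) {
    d <- sample(4:10, 3, replace = TRUE)
    sp <- round(runif(3, 0.5, 3), 2)
    pm <- random_mask(d); gm <- random_mask(d)
    aff <- diag(c(sp, 1))
    got <- hd95(volume_grid(array(as.double(pm), dim = d), affine = aff),
                volume_grid(array(as.double(gm), dim = d), affine = aff))
    expect_equal(got, ref_hd95(pm, gm, sp), tolerance = 1e-9)
  }
})

test_that("cohort summaries aggregate mean and sd per metric", {
  reports <- tibble::tibble(dice = c(0.9, 1.0), precision = c(1, 1),
                            recall = c(0.9, 1.0), fpr = c(0, 0),
                            fnr = c(0.1, 0), hd95_mm = c(2, 4))
  s <- summarize_cohort(reports)
  expect_identical(s$stat, c("mean", "sd"))
  expect_equal(s$dice, c(0.95, stats::sd(c(0.9, 1.0))))
  expect_equal(s$dice[2], 0.0707107, tolerance = 1e-6)
  expect_equal(s$hd95_mm, c(3, sqrt(2)))
  expect_identical(s$n_cases, c(2L, 2L))
  # grouped
  sg <- summarize_cohort(reports, c("a", "b"))
  expect_true(all(c("all", "a", "b") %in% sg$group))
  expect_equal(sg$dice[sg$group == "a" & sg$stat == "sd"], 0)
  expect_error(summarize_cohort(reports[, 1:3]), "metric")
})
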