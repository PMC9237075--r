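test_that("poly_lr reproduces frozen schedule values", {
  expect_identical(poly_lr(0, 300), 0.001)
  expect_equal(poly_lr(150, 300), 0.001 * 0.5^0.9)
  expect_equal(poly_lr(150, 300), 5.358867e-04, tolerance = 1e-6)
  expect_identical(poly_lr(300, 300), 0)
  expect_error(poly_lr(-1, 300), "0|range")
  expect_error(poly_lr(301, 300), "N|range")
})

test_that("soft Dice loss matches hand-worked values and bounds", {
  # 16 true voxels, prediction covers them plus 16 false positives:
  # numerator 2*16 = 32, denominator 32 + 16 + 1e-5
  y <- c(rep(1, 16), rep(0, 16))
  p <- rep(1, 32)
  expect_equal(soft_dice_loss(p, y, 1e-5), 1 - 32 / (48 + 1e-5),
               tolerance = 1e-12)
  expect_equal(soft_dice_loss(p, y), 0.3333335, tolerance = 1e-6)
  # perfect and disjoint predictions
  expect_lt(soft_dice_loss(y, y), 1e-4)
  expect_equal(soft_dice_loss(1 - y, y), 1)
  # improving overlap lowers the loss
  p2 <- c(rep(1, 16), rep(0.2, 16))
  expect_lt(soft_dice_loss(p2, y), soft_dice_loss(p, y))
  expect_error(soft_dice_loss(c(1, 0), c(1, 0, 0)), "shape")
})

test_that("soft Dice gradient matches finite differences", {
  set.seed(13)
  p <- runif(40); y <- as.double(runif(40) > 0.5)
  g <- enstrip:::soft_dice_grad(p, y, 1e-5)
  eps <- 1e-6
  for (i in c(1, 7, 40)) {
    pp <- p; pp[i] <- p[i] + eps; lp <- soft_dice_loss(pp, y, 1e-5)
    pm <- p; pm[i] <- p[i] - eps; lm <- soft_dice_loss(pm, y, 1e-5)
    expect_equal(g[i], (lp - lm) / (2 * eps), tolerance = 1e-5)
  }
})

test_that("Adam first step matches the published update rule", {
  params <- list(w = c(2, -1))
  grads <- list(w = c(0.5, -0.25))
  st <- enstrip:::adam_init(params)
  up <- enstrip:::adam_step(params, grads, st, lr = 0.01)
  # independent computation of the bias-corrected first step
  g <- grads$w
  m_hat <- (0.1 * g) / (1 - 0.9)
  v_hat <- (0.001 * g^2) / (1 - 0.999)
  expect_equal(up$params$w, params$w - 0.01 * m_hat / (sqrt(v_hat) + 1e-8),
               tolerance = 1e-12)
})

test_that("rotation keeps volumes in place and nearest keeps masks binary", {
  m <- array(0, dim = c(9, 9, 9)); m[4:6, 4:6, 4:6] <- 1
  r0 <- enstrip:::rotate_volume(m, axis = 3, angle_deg = 0)
  expect_equal(r0, m, tolerance = 1e-12)
  r <- enstrip:::rotate_volume(m, axis = 3, angle_deg = 90,
                               interp = "nearest")
  expect_true(all(r %in% c(0, 1)))
  expect_equal(sum(r), sum(m))   # 90-degree rotation permutes voxels
})

test_that("augmentation is seed-deterministic and preserves binarity", {
  case <- generate_case(small_phantom_spec(seed = 17, condition = "pre_op"))
  stack <- stack_modalities(case$volumes, "f1c2")
  cfg <- train_config(epochs = 2, crop_shape = c(16, 16, 16))
  a1 <- enstrip:::augment(stack, case$brain_mask, cfg, draw_seed = 99)
  a2 <- enstrip:::augment(stack, case$brain_mask, cfg, draw_seed = 99)
  a3 <- enstrip:::augment(stack, case$brain_mask, cfg, draw_seed = 100)
  expect_identical(a1$stack$channels$T1$values, a2$stack$channels$T1$values)
  expect_identical(a1$mask$values, a2$mask$values)
  expect_false(identical(a1$stack$channels$T1$values,
                         a3$stack$channels$T1$values))
  expect_identical(dim(a1$mask$values), c(16L, 16L, 16L))
  expect_true(all(a1$mask$values %in% c(0, 1)))
})

test_that("train_config validates and defaults to the paper settings", {
  tc <- train_config()
  expect_identical(tc$epochs, 300L)
  expect_equal(tc$initial_lr, 0.001)
  expect_equal(tc$lr_power, 0.9)
  expect_identical(tc$batch_size, 1L)
  expect_identical(tc$validate_every, 5L)
  expect_true(all(c("crop", "rotation_deg", "intensity_shift", "flip") %in%
                    names(tc$augmentation)))
  expect_error(train_config(epochs = 0))
  expect_error(train_config(initial_lr = -1))
})

test_that("a tiny training run produces a usable, serialisable fit", {
  fit <- tiny_fit()
  expect_s3_class(fit, "ennet_fit")
  h <- tidy(fit)
  expect_identical(nrow(h), 2L)
  expect_identical(names(h), c("epoch", "lr", "train_loss", "train_dice",
                               "val_loss", "val_dice"))
  expect_true(is.na(h$val_dice[1]) && !is.na(h$val_dice[2]))
  expect_equal(h$lr, c(poly_lr(0, 2), poly_lr(1, 2)))

  g <- glance(fit)
  expect_identical(nrow(g), 1L)
  expect_identical(g$combo, "f1c2")
  expect_gt(g$n_parameters, 0)

  pl <- autoplot(fit)
  expect_s3_class(pl, "ggplot")

  # checkpoint round trip preserves predictions
  case <- generate_case(small_phantom_spec(seed = 33))
  prob1 <- predict(fit, stack_modalities(case$volumes, fit$combo))
  p <- tempfile(fileext = ".rds")
  save_checkpoint(fit, p)
  fit2 <- load_checkpoint(p)
  prob2 <- predict(fit2, stack_modalities(case$volumes, fit2$combo))
  expect_identical(prob1$probability, prob2$probability)
  unlink(p)

  # strip_case returns a mask and masked channels on the input grid
  res <- strip_case(fit, case$volumes)
  expect_true(all(res$mask$values %in% c(0, 1)))
  expect_identical(dim(res$mask$values), dim(case$volumes$T1$values))
  out <- res$stripped$channels$T1$values
  expect_true(all(out[res$mask$values == 0] == 0))
})

test_that("training refuses manifests with missing files", {
  man <- tibble::tibble(case_id = "x", condition = "healthy",
                        flair = "gone.nii.gz", t1 = "gone.nii.gz",
                        t1ce = "gone.nii.gz", t2 = "gone.nii.gz",
                        mask = "gone.nii.gz")
  ns <- network_spec(in_channels = 4, depth = 2, base_width = 4,
                     groupnorm_groups = 4)
  expect_error(train_model(man, man, "f1c2", ns,
                           train_config(epochs = 1,
                                        crop_shape = c(8, 8, 8))),
               "manifest|missing")
})
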