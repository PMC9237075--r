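test_that("network_spec validates its configuration", {
  expect_s3_class(network_spec(), "network_spec")
  expect_error(network_spec(in_channels = 0))
  expect_error(network_spec(depth = 1))
  expect_error(network_spec(base_width = 6, groupnorm_groups = 4),
               "divis|group")
})

test_that("input dimensions must be divisible by the pooling factor", {
  ns <- network_spec(in_channels = 1, depth = 3, base_width = 8)
  net <- build_ennet(ns, seed = 1)
  X <- matrix(rnorm(6^3), 6^3, 1)
  expect_error(enstrip:::ennet_forward(net, X, c(6, 6, 6)), "divisible|multiple")
})

test_that("builds are seed-deterministic", {
  ns <- network_spec(in_channels = 2, depth = 2, base_width = 4,
                     groupnorm_groups = 2)
  a <- build_ennet(ns, seed = 5)
  b <- build_ennet(ns, seed = 5)
  c <- build_ennet(ns, seed = 6)
  expect_identical(a$params, b$params)
  expect_false(identical(a$params, c$params))
  expect_gt(count_parameters(a), 0)
})

test_that("forward pass yields probabilities and an ensemble decoder sum", {
  ns <- network_spec(in_channels = 2, depth = 2, base_width = 4,
                     groupnorm_groups = 2)
  net <- build_ennet(ns, seed = 2)
  dims <- c(4L, 4L, 4L)
  X <- matrix(rnorm(prod(dims) * 2), prod(dims), 2)
  f <- enstrip:::ennet_forward(net, X, dims, keep = TRUE)
  expect_true(all(f$p > 0 & f$p < 1))
  expect_length(f$p, prod(dims))
  # decoder levels combine main and auxiliary branches by elementwise sum
  br <- f$branches[[1]]
  expect_equal(br$combined, br$main + br$aux)
  # disabling the auxiliary decoder changes the output
  ns0 <- ns; ns0$use_aux <- FALSE
  net0 <- build_ennet(ns0, seed = 2)
  net0$params <- net$params[names(net0$params)]
  f0 <- enstrip:::ennet_forward(net0, X, dims, keep = FALSE)
  expect_false(isTRUE(all.equal(f$p, f0$p)))
})

test_that("analytic gradients match finite differences", {
  set.seed(42)
  ns <- network_spec(in_channels = 2, depth = 2, base_width = 4,
                     groupnorm_groups = 2)
  net <- build_ennet(ns, seed = 7)
  dims <- c(4L, 4L, 4L); V <- prod(dims)
  X <- matrix(rnorm(V * 2), V, 2)
  y <- as.double(runif(V) > 0.6)
  lossfn <- function(net) {
    f <- enstrip:::ennet_forward(net, X, dims, keep = FALSE)
    soft_dice_loss(f$p, y, 1e-5)
  }
  f <- enstrip:::ennet_forward(net, X, dims, keep = TRUE)
  dp <- enstrip:::soft_dice_grad(f$p, y, 1e-5)
  gr <- enstrip:::ennet_backward(net, f, dp)
  eps <- 1e-5
  for (nm in names(net$params)) {
    p <- net$params[[nm]]
    for (i in sample(length(p), min(2, length(p)))) {
      n2 <- net
      n2$params[[nm]][i] <- p[i] + eps; lp <- lossfn(n2)
      n2$params[[nm]][i] <- p[i] - eps; lm <- lossfn(n2)
      num <- (lp - lm) / (2 * eps)
      rel <- abs(num - gr[[nm]][i]) / max(1e-6, abs(num), abs(gr[[nm]][i]))
      expect_lt(rel, 1e-3, label = paste("relative gradient error of", nm))
    }
  }
})

test_that("conv and upsample kernels are exact adjoints", {
  set.seed(11)
  nx <- 5L; ny <- 4L; nz <- 3L; V <- nx * ny * nz
  C <- 3L; Cout <- 2L
  W <- matrix(rnorm(27 * C * Cout), 27 * C, Cout)
  x <- matrix(rnorm(V * C), V, C)
  u <- matrix(rnorm(V * Cout), V, Cout)
  y <- enstrip:::cpp_conv3_fwd(x, nx, ny, nz, W, rep(0, Cout))
  bw <- enstrip:::cpp_conv3_bwd(x, u, nx, ny, nz, W)
  # <Ax, u> == <x, A^T u> for the linear (zero-bias) conv operator
  expect_equal(sum(y * u), sum(x * bw$dx), tolerance = 1e-10)

  xs <- matrix(rnorm(V * C), V, C)
  ys <- enstrip:::cpp_upsample_fwd(xs, nx, ny, nz)
  us <- matrix(rnorm(8 * V * C), 8 * V, C)
  xt <- enstrip:::cpp_upsample_bwd(us, nx, ny, nz)
  expect_equal(sum(ys * us), sum(xs * xt), tolerance = 1e-10)
})

test_that("max pooling picks block maxima and routes gradients to them", {
  x <- matrix(0, 8, 1)
  x[, 1] <- c(1, 5, 2, 3, 9, 0, -1, 4)   # single 2x2x2 block
  r <- enstrip:::cpp_maxpool_fwd(x, 2, 2, 2)
  expect_equal(r$y[1, 1], 9)
  dy <- matrix(7, 1, 1)
  dx <- enstrip:::cpp_maxpool_bwd(dy, r$argmax, 8L)
  expect_equal(which(dx[, 1] != 0), 5L)
  expect_equal(dx[5, 1], 7)
})

test_that("binarize thresholds probabilities and validates the threshold", {
  p <- array(c(0.2, 0.5, 0.8, 0.49), dim = c(4, 1, 1))
  m <- binarize(p, 0.5)
  expect_equal(as.vector(m$values), c(0, 1, 1, 0))
  expect_error(binarize(p, 0))
  expect_error(binarize(p, 1))
  # monotone: raising the threshold never adds voxels
  q <- array(runif(64), dim = c(4, 4, 4))
  m1 <- binarize(q, 0.3)$values; m2 <- binarize(q, 0.7)$values
  expect_true(all(m2 <= m1))
})
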