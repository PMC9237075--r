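# Independent reference implementations ("oracles") used to validate the
# package's vectorised / C++ metric code. Deliberately written as plain,
# slow voxel loops so they share no code path with the implementation.

# confusion counts by an explicit loop over every voxel
ref_confusion <- function(pred, gt) {
  p <- pred > 0.5
  g <- gt > 0.5
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(p)) {
    if (p[i] && g[i]) tp <- tp + 1L
    else if (p[i] && !g[i]) fp <- fp + 1L
    else if (!p[i] && g[i]) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(TP = tp, FP = fp, FN = fn, TN = tn)
}

# 6-connectivity boundary: a mask voxel with any of its six face neighbours
# outside the mask (grid edges count as outside)
ref_boundary <- function(m) {
  d <- dim(m)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  ix <- 2:(d[1] + 1); iy <- 2:(d[2] + 1); iz <- 2:(d[3] + 1)
  interior <- pad[ix - 1, iy, iz] & pad[ix + 1, iy, iz] &
    pad[ix, iy - 1, iz] & pad[ix, iy + 1, iz] &
    pad[ix, iy, iz - 1] & pad[ix, iy, iz + 1]
  m & !interior
}

# symmetric 95th-percentile Hausdorff distance by brute-force pairwise
# distances between boundary voxel centres (mm)
ref_hd95 <- function(pm, gm, spacing) {
  bp <- which(ref_boundary(pm), arr.ind = TRUE)
  bg <- which(ref_boundary(gm), arr.ind = TRUE)
  cp <- sweep(bp - 1, 2, spacing, "*")
  cg <- sweep(bg - 1, 2, spacing, "*")
  dmin <- function(a, b) {
    apply(a, 1, function(pt) {
      sqrt(min((b[, 1] - pt[1])^2 + (b[, 2] - pt[2])^2 + (b[, 3] - pt[3])^2))
    })
  }
  d_pg <- stats::quantile(dmin(cp, cg), 0.95, names = FALSE)
  d_gp <- stats::quantile(dmin(cg, cp), 0.95, names = FALSE)
  max(d_pg, d_gp)
}

# random nonempty binary mask of the given dims
random_mask <- function(dims, p = runif(1, 0.2, 0.8)) {
  m <- array(runif(prod(dims)) < p, dim = dims)
  if (!any(m)) m[ceiling(dims[1] / 2), ceiling(dims[2] / 2),
                 ceiling(dims[3] / 2)] <- TRUE
  m
}

# small phantom spec that fits a 32^3 grid (fast unit-test cohorts)
small_phantom_spec <- function(...) {
  phantom_spec(grid_shape = c(32, 32, 32),
               brain_semiaxes_mm = c(7.5, 8.5, 6.5),
               lesion_radius_mm = 2.5, ...)
}

# tiny trained model for API-level tests: 2 cases, 2 epochs, depth 2
tiny_fit_cache <- new.env(parent = emptyenv())
tiny_fit <- function() {
  if (!is.null(tiny_fit_cache$fit)) return(tiny_fit_cache$fit)
  td <- file.path(tempdir(), "enstrip-tiny")
  tr <- generate_cohort(2, small_phantom_spec(), seed = 21,
                        out_dir = file.path(td, "train"))
  va <- generate_cohort(1, small_phantom_spec(), seed = 22,
                        out_dir = file.path(td, "val"))
  ns <- network_spec(in_channels = 4, depth = 2, base_width = 4,
                     groupnorm_groups = 4)
  tc <- train_config(epochs = 2, crop_shape = c(16, 16, 16),
                     validate_every = 2, seed = 3)
  fit <- train_model(tr, va, "f1c2", ns, tc)
  tiny_fit_cache$fit <- fit
  tiny_fit_cache$train_dir <- file.path(td, "train")
  tiny_fit_cache$val_dir <- file.path(td, "val")
  fit
}
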