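# Synthetic multiparametric head phantoms.
#
# A phantom is a set of nested ellipsoids on a regular grid: a brain
# ellipsoid wrapped in a thin CSF rim, a skull shell and a scalp shell, in
# background. Optional spherical lesions model a contrast-enhancing tumor
# (pre-operative) or a resection cavity (post-operative). Each tissue class
# maps to a per-modality mean intensity; Gaussian noise and a smooth
# multiplicative bias field are added on top. The ground-truth brain mask is
# the set of voxels generated as brain tissue: tumor voxels count as brain,
# cavity voxels do not.

TISSUE_CLASSES <- c("background", "scalp", "skull", "csf_rim", "brain",
                    "tumor", "cavity")

#' Default tissue-contrast table
#'
#' Mean intensity of each tissue class in each modality (arbitrary units).
#' The values are chosen so that no single modality separates brain from all
#' non-brain classes on intensity alone: scalp matches brain on FLAIR, T1 and
#' T1ce (it only separates on T2), and the CSF rim matches brain on T2 (it
#' separates on FLAIR/T1/T1ce, where fluid is suppressed or dark). Combining
#' modalities therefore carries genuine extra information, so a
#' multi-sequence advantage is measurable in principle. Tumor is brightest
#' on T1ce (contrast enhancement) and cavity matches background.
#'
#' @return a 7 x 4 numeric matrix (tissue class x modality).
#' @export
default_contrast_table <- function() {
  m <- rbind(
    background = c(0, 0, 0, 0),
    scalp      = c(62, 72, 72, 20),
    skull      = c(15, 25, 25, 12),
    csf_rim    = c(12, 35, 35, 46),
    brain      = c(60, 70, 70, 45),
    tumor      = c(75, 55, 90, 65),
    cavity     = c(0, 0, 0, 0))
  colnames(m) <- MODALITIES
  m
}

#' Phantom specification
#'
#' @param grid_shape integer length-3 voxel counts.
#' @param voxel_spacing_mm numeric length-3 voxel spacing in mm.
#' @param brain_semiaxes_mm brain ellipsoid semiaxes in mm.
#' @param csf_rim_mm,skull_thickness_mm,scalp_thickness_mm shell thicknesses
#'   in mm.
#' @param condition one of `"healthy"`, `"pre_op"`, `"post_op"`.
#' @param lesion_radius_mm radius of the tumor (pre_op) or resection cavity
#'   (post_op) sphere, in mm; ignored for healthy cases.
#' @param noise_sd additive Gaussian noise, as a fraction of the
#'   tissue-contrast range of `contrast_table`.
#' @param bias_field_amplitude amplitude of the smooth multiplicative bias
#'   field (0 disables it).
#' @param contrast_table tissue class x modality intensity matrix; see
#'   [default_contrast_table()].
#' @param seed integer RNG seed for this case.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64),
                         voxel_spacing_mm = c(1, 1, 1),
                         brain_semiaxes_mm = c(20, 25, 18),
                         csf_rim_mm = 1.0,
                         skull_thickness_mm = 1.5,
                         scalp_thickness_mm = 1.5,
                         condition = c("healthy", "pre_op", "post_op"),
                         lesion_radius_mm = 6,
                         noise_sd = 0.05,
                         bias_field_amplitude = 0,
                         contrast_table = default_contrast_table(),
                         seed = 1L) {
  condition <- match.arg(condition)
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 8),
            length(voxel_spacing_mm) == 3, all(voxel_spacing_mm > 0),
            length(brain_semiaxes_mm) == 3, all(brain_semiaxes_mm > 0),
            csf_rim_mm > 0, skull_thickness_mm > 0, scalp_thickness_mm > 0,
            noise_sd >= 0, bias_field_amplitude >= 0, lesion_radius_mm > 0)
  if (!all(TISSUE_CLASSES %in% rownames(contrast_table)) ||
      !all(MODALITIES %in% colnames(contrast_table)))
    stop("contrast_table must cover all tissue classes and all four modalities",
         call. = FALSE)
  spec <- structure(list(
    grid_shape = grid_shape, voxel_spacing_mm = as.numeric(voxel_spacing_mm),
    brain_semiaxes_mm = as.numeric(brain_semiaxes_mm),
    csf_rim_mm = csf_rim_mm, skull_thickness_mm = skull_thickness_mm,
    scalp_thickness_mm = scalp_thickness_mm, condition = condition,
    lesion_radius_mm = lesion_radius_mm, noise_sd = noise_sd,
    bias_field_amplitude = bias_field_amplitude,
    contrast_table = contrast_table[TISSUE_CLASSES, MODALITIES],
    seed = as.integer(seed)), class = "phantom_spec")
  check_phantom_geometry(spec)
  spec
}

# The head (brain + all shells) must keep a >= 2-voxel background margin to
# every grid face.
check_phantom_geometry <- function(spec) {
  outer <- spec$brain_semiaxes_mm + spec$csf_rim_mm +
    spec$skull_thickness_mm + spec$scalp_thickness_mm
  half_extent <- (spec$grid_shape - 1) / 2 * spec$voxel_spacing_mm
  margin_ok <- outer <= half_extent - 2 * spec$voxel_spacing_mm
  if (!all(margin_ok))
    stop("phantom geometry error: head (semiaxes + shells = ",
         paste(sprintf("%.1f", outer), collapse = " x "),
         " mm) does not fit grid ",
         paste(spec$grid_shape, collapse = "x"),
         " with a 2-voxel background margin", call. = FALSE)
  invisible(spec)
}

# Normalised ellipsoidal radius of every voxel for semiaxes `a` (mm), as a
# 3D array; `xs`, `ys`, `zs` are world coordinates centred on the head.
ellipsoid_rho <- function(xs, ys, zs, a) {
  rx2 <- (xs / a[1])^2
  ry2 <- (ys / a[2])^2
  rz2 <- (zs / a[3])^2
  sqrt(outer(outer(rx2, ry2, "+"), rz2, "+"))
}

#' Generate one phantom case
#'
#' Deterministic for a fixed `spec$seed`. Returns four modality volumes and
#' the ground-truth brain mask on a shared grid.
#'
#' @param spec a [phantom_spec].
#' @param case_id identifier stored with the case.
#' @return an object of class `phantom_case`: named list of `volumes`
#'   (FLAIR, T1, T1ce, T2 [volume_grid]s), `brain_mask`, `condition`,
#'   `case_id`.
#' @export
generate_case <- function(spec, case_id = "case_001") {
  stopifnot(inherits(spec, "phantom_spec"))
  check_phantom_geometry(spec)
  set.seed(spec$seed)
  n <- spec$grid_shape; sp <- spec$voxel_spacing_mm
  ctr <- (n - 1) / 2 * sp
  xs <- (seq_len(n[1]) - 1) * sp[1] - ctr[1]
  ys <- (seq_len(n[2]) - 1) * sp[2] - ctr[2]
  zs <- (seq_len(n[3]) - 1) * sp[3] - ctr[3]

  a <- spec$brain_semiaxes_mm
  rho_brain <- ellipsoid_rho(xs, ys, zs, a)
  rho_rim   <- ellipsoid_rho(xs, ys, zs, a + spec$csf_rim_mm)
  rho_skull <- ellipsoid_rho(xs, ys, zs, a + spec$csf_rim_mm +
                               spec$skull_thickness_mm)
  rho_scalp <- ellipsoid_rho(xs, ys, zs, a + spec$csf_rim_mm +
                               spec$skull_thickness_mm +
                               spec$scalp_thickness_mm)

  cls <- array("background", dim = n)
  cls[rho_scalp <= 1] <- "scalp"
  cls[rho_skull <= 1] <- "skull"
  cls[rho_rim   <= 1] <- "csf_rim"
  cls[rho_brain <= 1] <- "brain"

  # lesion: a sphere fully inside the brain ellipsoid, direction random
  if (spec$condition != "healthy") {
    r <- spec$lesion_radius_mm
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    scale <- 0.45
    repeat {
      cen <- u * scale * a
      if (sqrt(sum((cen / a)^2)) + r / min(a) <= 0.95 || scale < 1e-3) break
      scale <- scale * 0.8
    }
    dist2 <- outer(outer((xs - cen[1])^2, (ys - cen[2])^2, "+"),
                   (zs - cen[3])^2, "+")
    inside <- dist2 <= r^2 & cls == "brain"
    cls[inside] <- if (spec$condition == "pre_op") "tumor" else "cavity"
  }

  mask <- array(as.double(cls == "brain" | cls == "tumor"), dim = n)

  # bias field: low-order polynomial in centred normalised coordinates,
  # rescaled so max |q| = 1, applied multiplicatively as 1 + amplitude * q
  bias <- NULL
  if (spec$bias_field_amplitude > 0) {
    cf <- rnorm(9, sd = 1)
    nx <- xs / max(abs(xs)); ny <- ys / max(abs(ys)); nz <- zs / max(abs(zs))
    X <- outer(outer(nx, rep(1, n[2])), rep(1, n[3]))
    Y <- outer(outer(rep(1, n[1]), ny), rep(1, n[3]))
    Z <- outer(outer(rep(1, n[1]), rep(1, n[2])), nz)
    q <- cf[1] * X + cf[2] * Y + cf[3] * Z + cf[4] * X * Y + cf[5] * X * Z +
      cf[6] * Y * Z + cf[7] * X^2 + cf[8] * Y^2 + cf[9] * Z^2
    q <- q / max(abs(q))
    bias <- 1 + spec$bias_field_amplitude * q
  }

  ct <- spec$contrast_table
  rng <- diff(range(ct))
  affine <- diag(c(sp, 1))
  class_idx <- match(cls, TISSUE_CLASSES)
  vols <- list()
  for (mod in MODALITIES) {
    v <- array(ct[class_idx, mod], dim = n)
    if (!is.null(bias)) v <- v * bias
    if (spec$noise_sd > 0)
      v <- v + array(rnorm(prod(n), sd = spec$noise_sd * rng), dim = n)
    vols[[mod]] <- volume_grid(v, affine = affine)
  }

  structure(list(volumes = vols,
                 brain_mask = volume_grid(mask, affine = affine),
                 condition = spec$condition, case_id = case_id, spec = spec),
            class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> %s (%s), %s voxels, brain volume %d voxels\n",
              x$case_id, x$condition,
              paste(dim(x$brain_mask$values), collapse = "x"),
              sum(x$brain_mask$values > 0)))
  invisible(x)
}

# Deterministic apportionment of n cases to conditions: floor shares first,
# remainders to the largest fractional parts (ties by condition order).
apportion_conditions <- function(n, mix) {
  stopifnot(abs(sum(mix) - 1) < 1e-8, all(mix >= 0))
  raw <- n * mix
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(cnt), names(mix))
}

#' Generate a phantom cohort on disk
#'
#' Writes `n` phantom cases as NIfTI volumes plus masks, with per-case
#' geometry randomised around the template (semiaxes scaled by +/-10%,
#' lesion radius by +/-20%) and per-case seeds derived deterministically
#' from `seed`. A manifest CSV (`case_id,condition,flair,t1,t1ce,t2,mask`)
#' is written alongside.
#'
#' @param n number of cases (>= 1).
#' @param spec_template a [phantom_spec] providing grid, contrasts, noise and
#'   shell geometry.
#' @param condition_mix named proportions over
#'   `c("healthy","pre_op","post_op")`, summing to 1.
#' @param seed master integer seed.
#' @param out_dir output directory (created if missing).
#' @param prefix case-id prefix.
#' @return the manifest as a tibble (also written to
#'   `file.path(out_dir, "manifest.csv")`).
#' @export
generate_cohort <- function(n, spec_template,
                            condition_mix = c(healthy = 0.5, pre_op = 0.3,
                                              post_op = 0.2),
                            seed = 1L, out_dir, prefix = "case") {
  stopifnot(n >= 1, inherits(spec_template, "phantom_spec"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir))
      stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  mix <- condition_mix[c("healthy", "pre_op", "post_op")]
  mix[is.na(mix)] <- 0
  names(mix) <- c("healthy", "pre_op", "post_op")
  cnt <- apportion_conditions(n, mix)
  conditions <- rep(names(cnt), cnt)

  set.seed(as.integer(seed))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ax_scale <- runif(3, 0.9, 1.1)
    les_scale <- runif(1, 0.8, 1.2)
    case_seed <- as.integer((as.double(seed) * 7919 + i * 104729) %% 2147483647)
    spec_i <- spec_template
    spec_i$brain_semiaxes_mm <- spec_template$brain_semiaxes_mm * ax_scale
    spec_i$lesion_radius_mm <- spec_template$lesion_radius_mm * les_scale
    spec_i$condition <- conditions[i]
    spec_i$seed <- case_seed
    check_phantom_geometry(spec_i)
    case_id <- sprintf("%s_%03d", prefix, i)
    case <- generate_case(spec_i, case_id = case_id)
    paths <- c(
      flair = file.path(out_dir, paste0(case_id, "_flair.nii.gz")),
      t1    = file.path(out_dir, paste0(case_id, "_t1.nii.gz")),
      t1ce  = file.path(out_dir, paste0(case_id, "_t1ce.nii.gz")),
      t2    = file.path(out_dir, paste0(case_id, "_t2.nii.gz")),
      mask  = file.path(out_dir, paste0(case_id, "_mask.nii.gz")))
    write_volume(case$volumes$FLAIR, paths["flair"])
    write_volume(case$volumes$T1,    paths["t1"])
    write_volume(case$volumes$T1ce,  paths["t1ce"])
    write_volume(case$volumes$T2,    paths["t2"])
    write_volume(case$brain_mask,    paths["mask"])
    rows[[i]] <- tibble::tibble(case_id = case_id, condition = conditions[i],
                                flair = paths[["flair"]], t1 = paths[["t1"]],
                                t1ce = paths[["t1ce"]], t2 = paths[["t2"]],
                                mask = paths[["mask"]])
  }
  manifest <- dplyr::bind_rows(rows)
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}

#' Read a cohort manifest
#'
#' @param path manifest CSV written by [generate_cohort()].
#' @return a tibble with columns `case_id,condition,flair,t1,t1ce,t2,mask`.
#' @export
read_manifest <- function(path) {
  m <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("case_id", "condition", "flair", "t1", "t1ce", "t2", "mask")
  missing <- setdiff(need, names(m))
  if (length(missing))
    stop("manifest is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  m
}
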