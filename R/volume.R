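#' @useDynLib enstrip, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif quantile sd
#' @importFrom utils head tail
NULL

#' Single 3D scalar volume with grid metadata
#'
#' A `volume_grid` holds one 3D image together with its voxel spacing and a
#' 4x4 affine mapping 0-based voxel indices to world (RAS) millimetre
#' coordinates, mirroring the NIfTI sform convention.
#'
#' @param values numeric 3D array of voxel values.
#' @param spacing numeric length-3 voxel spacing in mm (default 1 mm
#'   isotropic). Ignored when `affine` is supplied.
#' @param affine optional 4x4 voxel-to-world matrix; defaults to a diagonal
#'   RAS affine built from `spacing` with the origin at voxel (0,0,0).
#' @return an object of class `volume_grid`.
#' @export
volume_grid <- function(values, spacing = c(1, 1, 1), affine = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array, got ", length(dim(values)), " dims",
         call. = FALSE)
  storage.mode(values) <- "double"
  if (is.null(affine)) {
    spacing <- as.numeric(spacing)
    if (length(spacing) != 3L || any(spacing <= 0))
      stop("`spacing` must be three positive numbers", call. = FALSE)
    affine <- diag(c(spacing, 1))
  } else {
    affine <- unclass(affine)
    if (!is.matrix(affine) || !all(dim(affine) == c(4, 4)))
      stop("`affine` must be a 4x4 matrix", call. = FALSE)
    spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
    if (any(spacing <= 0)) stop("degenerate affine: zero-length axis",
                                call. = FALSE)
  }
  structure(list(values = values, spacing = spacing,
                 affine = affine[1:4, 1:4, drop = FALSE]),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume_grid> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$values)

is_volume_grid <- function(x) inherits(x, "volume_grid")

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    max(abs(a$affine - b$affine)) < tol
}

#' Read a 3D NIfTI volume
#'
#' Decodes voxel data, spacing and the voxel-to-world affine from a NIfTI-1
#' file (`.nii` or `.nii.gz`). Integer and floating-point voxel types are
#' accepted; the payload is promoted to double.
#'
#' @param path path to a NIfTI file.
#' @return a [volume_grid].
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not a readable NIfTI file: ", path,
                                           " (", conditionMessage(e), ")",
                                           call. = FALSE))
  a <- as.array(img)
  attributes(a) <- list(dim = dim(a))
  storage.mode(a) <- "double"
  nd <- length(dim(a))
  if (nd != 3L)
    stop("expected a 3D volume, got a ", nd, "D payload in ", path,
         call. = FALSE)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  volume_grid(a, affine = aff)
}

#' Write a volume to NIfTI
#'
#' @param vol a [volume_grid].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_volume_grid(vol))
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# World coordinates (rows) of 1-based voxel indices given a 0-based affine.
voxel_to_world <- function(affine, ijk1) {
  ijk0 <- cbind(ijk1 - 1, 1)
  t(affine %*% t(ijk0))[, 1:3, drop = FALSE]
}

# Trilinear sampling at continuous 1-based voxel coordinates; coordinates
# outside the grid return `outside`. Fully vectorised.
sample_trilinear <- function(arr, cx, cy, cz, outside = 0) {
  d <- dim(arr)
  ok <- cx >= 1 & cx <= d[1] & cy >= 1 & cy <= d[2] & cz >= 1 & cz <= d[3]
  fx <- pmin(floor(cx), d[1] - 1L); fx <- pmax(fx, 1L)
  fy <- pmin(floor(cy), d[2] - 1L); fy <- pmax(fy, 1L)
  fz <- pmin(floor(cz), d[3] - 1L); fz <- pmax(fz, 1L)
  if (d[1] == 1L) fx <- rep(1L, length(cx))
  if (d[2] == 1L) fy <- rep(1L, length(cy))
  if (d[3] == 1L) fz <- rep(1L, length(cz))
  wx <- pmin(pmax(cx - fx, 0), 1)
  wy <- pmin(pmax(cy - fy, 0), 1)
  wz <- pmin(pmax(cz - fz, 0), 1)
  sx <- if (d[1] > 1L) 1L else 0L
  sy <- if (d[2] > 1L) 1L else 0L
  sz <- if (d[3] > 1L) 1L else 0L
  lin <- function(ix, iy, iz) arr[cbind(ix, iy, iz)]
  v000 <- lin(fx,      fy,      fz)
  v100 <- lin(fx + sx, fy,      fz)
  v010 <- lin(fx,      fy + sy, fz)
  v110 <- lin(fx + sx, fy + sy, fz)
  v001 <- lin(fx,      fy,      fz + sz)
  v101 <- lin(fx + sx, fy,      fz + sz)
  v011 <- lin(fx,      fy + sy, fz + sz)
  v111 <- lin(fx + sx, fy + sy, fz + sz)
  out <- (1 - wz) * ((1 - wy) * ((1 - wx) * v000 + wx * v100) +
                       wy * ((1 - wx) * v010 + wx * v110)) +
         wz * ((1 - wy) * ((1 - wx) * v001 + wx * v101) +
                 wy * ((1 - wx) * v011 + wx * v111))
  out[!ok] <- outside
  out
}

# Nearest-neighbour sampling at continuous 1-based voxel coordinates.
sample_nearest <- function(arr, cx, cy, cz, outside = 0) {
  d <- dim(arr)
  ix <- round(cx); iy <- round(cy); iz <- round(cz)
  ok <- ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2] & iz >= 1 & iz <= d[3]
  ix <- pmin(pmax(ix, 1L), d[1])
  iy <- pmin(pmax(iy, 1L), d[2])
  iz <- pmin(pmax(iz, 1L), d[3])
  out <- arr[cbind(ix, iy, iz)]
  out[!ok] <- outside
  out
}
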