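# Preprocessing pipeline: per-modality NIfTI volumes -> reoriented,
# atlas-grid, intensity-normalised, channel-ordered input stack, and the
# final mask multiplication that produces the skull-stripped images.

#' Multi-modality stack
#'
#' Channel-stacked co-registered volumes restricted to a modality
#' combination. Channels always follow the fixed global order FLAIR, T1,
#' T1ce, T2.
#'
#' @param channels named list of [volume_grid]s (names among the four
#'   modalities), all on one shared grid.
#' @param combo a [modality_combo] (or code string) selecting the members.
#' @return an object of class `modality_stack`.
#' @export
modality_stack <- function(channels, combo) {
  combo <- modality_combo(combo)
  missing <- setdiff(combo$members, names(channels))
  if (length(missing))
    stop("missing modality: ", paste(missing, collapse = ", "), call. = FALSE)
  chans <- channels[combo$members]
  ref <- chans[[1]]
  for (nm in names(chans)) {
    if (!is_volume_grid(chans[[nm]]))
      stop("channel ", nm, " is not a volume_grid", call. = FALSE)
    if (!same_grid(ref, chans[[nm]]))
      stop("alignment error: channel ", nm,
           " is not on the shared grid", call. = FALSE)
  }
  structure(list(channels = chans, combo = combo), class = "modality_stack")
}

#' @export
print.modality_stack <- function(x, ...) {
  d <- dim(x$channels[[1]]$values)
  cat(sprintf("<modality_stack> %s: %d channel(s), %d x %d x %d voxels\n",
              x$combo$code, length(x$channels), d[1], d[2], d[3]))
  invisible(x)
}

#' @export
dim.modality_stack <- function(x) dim(x$channels[[1]]$values)

# Voxels-by-channels matrix view used by the network.
stack_matrix <- function(stack) {
  vapply(stack$channels, function(v) as.vector(v$values),
         numeric(length(stack$channels[[1]]$values)))
}

#' Reorient a volume to the canonical atlas orientation
#'
#' Permutes and flips the voxel axes so each array axis runs along its
#' dominant world axis with positive direction (RAS), preserving the world
#' coordinate of every voxel. Oblique acquisitions beyond `tol` are snapped
#' to the nearest axis-aligned orientation with a warning.
#'
#' @param vol a [volume_grid].
#' @param tol maximum tolerated off-axis direction cosine before warning.
#' @return the reoriented [volume_grid].
#' @export
reorient_to_atlas <- function(vol, tol = 1e-4) {
  stopifnot(is_volume_grid(vol))
  R <- vol$affine[1:3, 1:3]
  if (abs(det(R)) < 1e-12) stop("affine is rank deficient", call. = FALSE)
  D <- sweep(R, 2, sqrt(colSums(R^2)), "/")
  dom <- apply(abs(D), 2, which.max)          # world axis of each voxel axis
  if (anyDuplicated(dom))
    stop("affine axes are too oblique to assign unique world axes",
         call. = FALSE)
  offmat <- abs(D)
  offmat[cbind(dom, 1:3)] <- 0
  off <- max(offmat)
  if (off > tol)
    warning(sprintf(paste0("oblique affine (max off-axis cosine %.3g); ",
                           "snapping to nearest axis-aligned orientation"),
                    off))
  signs <- sign(D[cbind(dom, 1:3)])
  perm <- integer(3)                           # old axis feeding each new axis
  perm[dom] <- 1:3
  flip <- signs[perm] < 0

  vals <- aperm(vol$values, perm)
  d <- dim(vals)
  idx <- lapply(1:3, function(a) if (flip[a]) rev(seq_len(d[a])) else
    seq_len(d[a]))
  vals <- vals[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]

  # new affine: column a is the (sign-corrected) old column perm[a]; the
  # origin shifts by the full extent of every flipped axis
  Anew <- diag(4)
  Anew[1:3, 4] <- vol$affine[1:3, 4]
  for (a in 1:3) {
    col <- vol$affine[1:3, perm[a]]
    if (flip[a]) {
      Anew[1:3, 4] <- Anew[1:3, 4] + col * (d[a] - 1)
      col <- -col
    }
    Anew[1:3, a] <- col
  }
  # snap residual obliqueness so downstream grids are exactly axis-aligned
  for (a in 1:3) {
    len <- sqrt(sum(Anew[1:3, a]^2))
    v <- numeric(3); v[a] <- len
    Anew[1:3, a] <- v
  }
  volume_grid(vals, affine = Anew)
}

#' Resample a volume onto the atlas grid
#'
#' Rigid grid resampling (no registration): the output grid is axis-aligned
#' with the requested spacing, centred on the same world point as the input
#' grid. Trilinear interpolation for images, nearest-neighbour for masks.
#'
#' @param vol a [volume_grid] in canonical orientation.
#' @param target_shape integer length-3 output voxel counts (default the
#'   SRI24 atlas grid, 240 x 240 x 155).
#' @param target_spacing_mm output spacing (default 1 mm isotropic).
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @return a [volume_grid] on the target grid.
#' @export
resample_to_atlas_grid <- function(vol, target_shape = c(240, 240, 155),
                                   target_spacing_mm = c(1, 1, 1),
                                   interpolation = c("trilinear", "nearest")) {
  stopifnot(is_volume_grid(vol), all(target_spacing_mm > 0))
  interpolation <- match.arg(interpolation)
  target_shape <- as.integer(target_shape)
  src_dim <- dim(vol$values)

  centre <- vol$affine %*% c((src_dim - 1) / 2, 1)
  Anew <- diag(c(target_spacing_mm, 1))
  Anew[1:3, 4] <- centre[1:3] - target_spacing_mm * (target_shape - 1) / 2

  if (identical(target_shape, src_dim) &&
      max(abs(Anew - vol$affine)) < 1e-9)
    return(vol)

  ti <- seq_len(target_shape[1]) - 1
  tj <- seq_len(target_shape[2]) - 1
  tk <- seq_len(target_shape[3]) - 1
  wx <- Anew[1, 1] * ti + Anew[1, 4]
  wy <- Anew[2, 2] * tj + Anew[2, 4]
  wz <- Anew[3, 3] * tk + Anew[3, 4]
  inv <- solve(vol$affine)
  # source continuous 1-based voxel coords (affines are axis-aligned here)
  big1 <- function(v) rep(v, times = target_shape[2] * target_shape[3])
  big2 <- function(v) rep(rep(v, each = target_shape[1]),
                          times = target_shape[3])
  big3 <- function(v) rep(v, each = target_shape[1] * target_shape[2])
  cx <- inv[1, 1] * big1(wx) + inv[1, 4] + 1
  cy <- inv[2, 2] * big2(wy) + inv[2, 4] + 1
  cz <- inv[3, 3] * big3(wz) + inv[3, 4] + 1
  vals <- if (interpolation == "trilinear")
    sample_trilinear(vol$values, cx, cy, cz)
  else sample_nearest(vol$values, cx, cy, cz)
  volume_grid(array(vals, dim = target_shape), affine = Anew)
}

#' Z-score intensity normalisation over nonzero voxels
#'
#' Rescales the nonzero voxels to zero mean and unit (sample) standard
#' deviation; zero voxels stay exactly zero, so background introduced by
#' masking or padding is preserved.
#'
#' @param vol a [volume_grid] with at least one nonzero voxel.
#' @return the normalised [volume_grid].
#' @export
normalize_intensity <- function(vol) {
  stopifnot(is_volume_grid(vol))
  nz <- vol$values != 0
  if (!any(nz))
    stop("degenerate input: all-zero volume cannot be normalised",
         call. = FALSE)
  mu <- mean(vol$values[nz])
  s <- stats::sd(vol$values[nz])
  if (!is.finite(s) || s == 0)
    stop("degenerate input: zero variance over nonzero voxels",
         call. = FALSE)
  v <- vol$values
  v[nz] <- (v[nz] - mu) / s
  volume_grid(v, affine = vol$affine)
}

#' Stack modalities into a network input
#'
#' @param volumes named list of [volume_grid]s (names among FLAIR, T1, T1ce,
#'   T2) on one shared grid.
#' @param combo a [modality_combo] or code string; defaults to all four.
#' @return a [modality_stack] with channels in the fixed global order.
#' @export
stack_modalities <- function(volumes, combo = "f1c2") {
  modality_stack(volumes, combo)
}

#' Apply a binary brain mask to a stack
#'
#' Voxelwise multiplication of every channel by the mask: the final brain
#' extraction step.
#'
#' @param stack a [modality_stack].
#' @param mask a binary [volume_grid] on the stack's grid.
#' @return the masked [modality_stack].
#' @export
apply_mask <- function(stack, mask) {
  stopifnot(inherits(stack, "modality_stack"), is_volume_grid(mask))
  if (!same_grid(stack$channels[[1]], mask))
    stop("alignment error: mask is not on the stack's grid", call. = FALSE)
  if (!all(mask$values %in% c(0, 1)))
    stop("mask must be binary", call. = FALSE)
  chans <- lapply(stack$channels, function(v)
    volume_grid(v$values * mask$values, affine = v$affine))
  modality_stack(chans, stack$combo)
}

#' Optional preprocessing hooks
#'
#' Noise reduction and bias-field correction are optional steps of the
#' pipeline. No algorithm is bundled; each hook applies a user-supplied
#' function to the voxel array (grid metadata preserved) and defaults to the
#' identity.
#'
#' @param vol a [volume_grid].
#' @param method `NULL` (no-op) or a function `array -> array`.
#' @return a [volume_grid].
#' @export
reduce_noise <- function(vol, method = NULL) {
  apply_hook(vol, method, "noise-reduction")
}

#' @rdname reduce_noise
#' @export
correct_bias_field <- function(vol, method = NULL) {
  apply_hook(vol, method, "bias-correction")
}

apply_hook <- function(vol, method, what) {
  stopifnot(is_volume_grid(vol))
  if (is.null(method)) return(vol)
  if (!is.function(method))
    stop(what, " hook must be NULL or a function", call. = FALSE)
  v <- method(vol$values)
  if (!is.array(v) || !identical(dim(v), dim(vol$values)))
    stop(what, " hook must preserve the array shape", call. = FALSE)
  volume_grid(v, affine = vol$affine)
}

#' Full preprocessing of one case
#'
#' Reorients, resamples onto the target grid, normalises and stacks the
#' requested modalities: the standard path from NIfTI files (or loaded
#' volumes) to a network input.
#'
#' @param volumes named list of [volume_grid]s or of NIfTI file paths.
#' @param combo modality combination (code or [modality_combo]).
#' @param target_shape,target_spacing_mm output grid (pass `NULL` shape to
#'   keep the native grid).
#' @param normalize apply [normalize_intensity()] per channel.
#' @param noise_method,bias_method optional hooks, see [reduce_noise()].
#' @return a [modality_stack].
#' @export
preprocess_case <- function(volumes, combo = "f1c2",
                            target_shape = NULL,
                            target_spacing_mm = c(1, 1, 1),
                            normalize = TRUE,
                            noise_method = NULL, bias_method = NULL) {
  combo <- modality_combo(combo)
  vols <- lapply(volumes, function(v)
    if (is.character(v)) load_volume(v) else v)
  vols <- vols[combo$members]
  if (any(vapply(vols, is.null, logical(1))))
    stop("missing modality for combo ", combo$code, call. = FALSE)
  vols <- lapply(vols, reorient_to_atlas)
  vols <- lapply(vols, reduce_noise, method = noise_method)
  vols <- lapply(vols, correct_bias_field, method = bias_method)
  if (!is.null(target_shape))
    vols <- lapply(vols, resample_to_atlas_grid, target_shape = target_shape,
                   target_spacing_mm = target_spacing_mm)
  if (normalize) vols <- lapply(vols, normalize_intensity)
  modality_stack(vols, combo)
}
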