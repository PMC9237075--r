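# Training: soft Dice loss, polynomial learning-rate decay, on-the-fly 3D
# augmentation, an Adam loop with periodic validation and best-checkpoint
# selection, and the 15-way modality-combination study.

#' Training configuration
#'
#' @param epochs total training epochs.
#' @param initial_lr initial learning rate for the polynomial decay.
#' @param lr_power exponent of the decay (see [poly_lr()]).
#' @param batch_size cases per gradient step (the reference protocol uses 1;
#'   values > 1 accumulate gradients over consecutive cases).
#' @param crop_shape random-crop size (training only); must be divisible by
#'   the network's downsampling factor. The full-resolution protocol uses
#'   160 x 192 x 128; phantom-scale runs use much smaller crops.
#' @param epsilon soft-Dice stabiliser.
#' @param validate_every validation cadence in epochs.
#' @param threshold binarisation threshold for validation/test Dice.
#' @param augmentation list of switches/ranges: `crop`, `flip` (logicals),
#'   `rotation_deg` (range, degrees), `intensity_shift` (range, intensity
#'   units on normalised images). Set an entry to `FALSE`/`NULL` to disable.
#' @param seed master integer seed for weight init, shuffling and
#'   augmentation draws.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 300L, initial_lr = 0.001, lr_power = 0.9,
                         batch_size = 1L, crop_shape = c(160L, 192L, 128L),
                         epsilon = 1e-5, validate_every = 5L,
                         threshold = 0.5,
                         augmentation = list(crop = TRUE,
                                             rotation_deg = c(0, 10),
                                             intensity_shift = c(-0.1, 0.1),
                                             flip = TRUE),
                         seed = 1L) {
  stopifnot(epochs >= 1, initial_lr > 0, epsilon > 0, batch_size >= 1,
            validate_every >= 1)
  structure(list(epochs = as.integer(epochs), initial_lr = initial_lr,
                 lr_power = lr_power, batch_size = as.integer(batch_size),
                 crop_shape = if (is.null(crop_shape)) NULL else
                   as.integer(crop_shape),
                 epsilon = epsilon,
                 validate_every = as.integer(validate_every),
                 threshold = threshold, augmentation = augmentation,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Soft Dice loss
#'
#' `1 - 2*sum(p*y) / (sum(p^2) + sum(y^2) + epsilon)`: the differentiable
#' Dice relaxation used as the training objective. For binary `p` equal to a
#' nonempty `y` it approaches 0; for a total miss it equals 1.
#'
#' @param p predicted probabilities in `[0,1]`.
#' @param y binary target, same shape.
#' @param epsilon small positive stabiliser.
#' @return scalar loss in `[0, 1]`.
#' @export
soft_dice_loss <- function(p, y, epsilon = 1e-5) {
  if (length(p) != length(y))
    stop("prediction and target shapes differ", call. = FALSE)
  stopifnot(epsilon > 0)
  1 - 2 * sum(p * y) / (sum(p^2) + sum(y^2) + epsilon)
}

# dL/dp of the soft Dice loss.
soft_dice_grad <- function(p, y, epsilon = 1e-5) {
  num <- 2 * sum(p * y)
  den <- sum(p^2) + sum(y^2) + epsilon
  -2 * y / den + 2 * num * p / den^2
}

#' Polynomial learning-rate decay
#'
#' `r_i = r0 * (1 - i/N)^power`: the rate starts at `r0` (epoch 0), decreases
#' strictly, and reaches 0 at epoch `N`.
#'
#' @param i epoch counter, `0 <= i <= N`.
#' @param N total epochs.
#' @param r0 initial rate.
#' @param power decay exponent (default 0.9).
#' @return the learning rate at epoch `i`.
#' @export
poly_lr <- function(i, N, r0 = 0.001, power = 0.9) {
  if (any(i < 0) || any(i > N))
    stop("epoch counter out of range [0, N]", call. = FALSE)
  r0 * (1 - i / N)^power
}

# ---- augmentation --------------------------------------------------------

# Rotate a 3D array about one axis by `angle` degrees around the volume
# centre; trilinear or nearest sampling, zero outside.
rotate_volume <- function(arr, axis, angle_deg, interp = "trilinear") {
  d <- dim(arr)
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2; cz <- (d[3] + 1) / 2
  gi <- rep(seq_len(d[1]), times = d[2] * d[3]) - cx
  gj <- rep(rep(seq_len(d[2]), each = d[1]), times = d[3]) - cy
  gk <- rep(seq_len(d[3]), each = d[1] * d[2]) - cz
  if (axis == 3L) {        # rotate in (x, y)
    sx <- ct * gi + st * gj; sy <- -st * gi + ct * gj; sz <- gk
  } else if (axis == 2L) { # rotate in (x, z)
    sx <- ct * gi + st * gk; sy <- gj; sz <- -st * gi + ct * gk
  } else {                 # rotate in (y, z)
    sx <- gi; sy <- ct * gj + st * gk; sz <- -st * gj + ct * gk
  }
  f <- if (interp == "trilinear") sample_trilinear else sample_nearest
  array(f(arr, sx + cx, sy + cy, sz + cz), dim = d)
}

#' Random augmentation of a stack and its mask
#'
#' One random crop (identical across channels and mask), a random rotation
#' about one random axis with angle drawn from `rotation_deg` (trilinear for
#' images, nearest for the mask), a random intensity shift per channel drawn
#' from `intensity_shift` (images only), and an independent flip of each axis
#' with probability 1/2 (identical for channels and mask). Deterministic for
#' a fixed `draw_seed`.
#'
#' @param stack a [modality_stack].
#' @param mask the matching binary [volume_grid].
#' @param config a [train_config] (its `crop_shape` and `augmentation`
#'   entries are used).
#' @param draw_seed integer seed for this draw.
#' @return list with elements `stack` and `mask`.
#' @export
augment <- function(stack, mask, config, draw_seed = 1L) {
  stopifnot(inherits(stack, "modality_stack"), is_volume_grid(mask),
            inherits(config, "train_config"))
  set.seed(as.integer(draw_seed))
  aug <- config$augmentation
  chans <- lapply(stack$channels, function(v) v$values)
  mk <- mask$values
  d <- dim(mk)

  use_crop <- isTRUE(aug$crop) && !is.null(config$crop_shape)
  if (use_crop) {
    cs <- config$crop_shape
    if (any(cs > d))
      stop("geometry error: crop ", paste(cs, collapse = "x"),
           " exceeds volume ", paste(d, collapse = "x"), call. = FALSE)
    o <- vapply(1:3, function(a)
      if (cs[a] == d[a]) 1L else sample.int(d[a] - cs[a] + 1L, 1L),
      integer(1))
    sub <- function(v) v[o[1]:(o[1] + cs[1] - 1), o[2]:(o[2] + cs[2] - 1),
                         o[3]:(o[3] + cs[3] - 1), drop = FALSE]
    chans <- lapply(chans, sub)
    mk <- sub(mk)
    d <- cs
  }

  rot <- aug$rotation_deg
  if (!is.null(rot) && !isFALSE(rot)) {
    axis <- sample(1:3, 1)
    ang <- runif(1, rot[1], rot[2])
    if (ang != 0) {
      chans <- lapply(chans, rotate_volume, axis = axis, angle_deg = ang,
                      interp = "trilinear")
      mk <- rotate_volume(mk, axis, ang, interp = "nearest")
    }
  }

  shift <- aug$intensity_shift
  if (!is.null(shift) && !isFALSE(shift)) {
    chans <- lapply(chans, function(v) v + runif(1, shift[1], shift[2]))
  }

  if (isTRUE(aug$flip)) {
    for (a in 1:3) {
      if (runif(1) < 0.5) {
        idx <- rev(seq_len(d[a]))
        flip1 <- function(v) switch(a, v[idx, , , drop = FALSE],
                                    v[, idx, , drop = FALSE],
                                    v[, , idx, drop = FALSE])
        chans <- lapply(chans, flip1)
        mk <- flip1(mk)
      }
    }
  }

  affine <- diag(c(mask$spacing, 1))
  out_ch <- lapply(chans, volume_grid, affine = affine)
  list(stack = modality_stack(out_ch, stack$combo),
       mask = volume_grid(mk, affine = affine))
}

# ---- Adam ---------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# ---- case loading --------------------------------------------------------

manifest_col <- c(FLAIR = "flair", T1 = "t1", T1ce = "t1ce", T2 = "t2")

# Load, normalise and stack the requested modalities for every manifest row.
load_cases <- function(manifest, combo) {
  combo <- modality_combo(combo)
  need <- c(unname(manifest_col[combo$members]), "mask")
  files <- unlist(manifest[need], use.names = FALSE)
  missing <- files[!file.exists(files)]
  if (length(missing))
    stop("manifest error: missing files: ",
         paste(utils::head(missing, 3), collapse = ", "),
         if (length(missing) > 3) " ...", call. = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    vols <- lapply(stats::setNames(manifest_col[combo$members],
                                   combo$members),
                   function(col) load_volume(row[[col]]))
    stack <- preprocess_case(vols, combo = combo, target_shape = NULL,
                             normalize = TRUE)
    mask <- load_volume(row$mask)
    list(case_id = row$case_id, condition = row$condition, stack = stack,
         mask = mask)
  })
}

hard_dice <- function(pred, truth) {
  s <- sum(pred) + sum(truth)
  if (s == 0) return(1)
  2 * sum(pred * truth) / s
}

# ---- training loop -------------------------------------------------------

#' Train an EnNet model
#'
#' Runs the full protocol: per-epoch polynomial learning-rate decay, Adam,
#' on-the-fly augmentation, periodic validation (soft-Dice loss and
#' thresholded Dice) and retention of the weights with the best validation
#' Dice. Fully seeded: identical seeds, data and config reproduce the run.
#'
#' @param train_manifest,val_manifest cohort manifests (tibbles from
#'   [generate_cohort()]/[read_manifest()], or paths to manifest CSVs).
#' @param combo modality combination to train on.
#' @param net_spec a [network_spec]; its `in_channels` must match the combo
#'   size.
#' @param config a [train_config].
#' @param verbose print per-epoch progress.
#' @return an object of class `ennet_fit`: fields `net` (best-validation
#'   weights), `history` (tibble: epoch, lr, train_loss, train_dice,
#'   val_loss, val_dice), `best_epoch`, `best_val_dice`, `combo`, `config`.
#' @export
train_model <- function(train_manifest, val_manifest, combo, net_spec,
                        config = train_config(), verbose = FALSE) {
  if (is.character(train_manifest)) train_manifest <- read_manifest(train_manifest)
  if (is.character(val_manifest)) val_manifest <- read_manifest(val_manifest)
  combo <- modality_combo(combo)
  stopifnot(inherits(net_spec, "network_spec"), inherits(config, "train_config"))
  if (net_spec$in_channels != length(combo$members))
    stop("net_spec$in_channels (", net_spec$in_channels,
         ") must equal the combo size (", length(combo$members), ")",
         call. = FALSE)
  if (!is.null(config$crop_shape))
    check_divisible(config$crop_shape, net_spec$depth)

  train_cases <- load_cases(train_manifest, combo)
  val_cases <- load_cases(val_manifest, combo)

  set.seed(config$seed)
  net <- build_ennet(net_spec, seed = sample.int(2147483647L, 1))
  state <- adam_init(net$params)

  N <- config$epochs
  hist <- vector("list", N)
  best <- list(dice = -Inf, params = net$params, epoch = NA_integer_)
  n_train <- length(train_cases)

  for (epoch in seq_len(N)) {
    lr <- poly_lr(epoch - 1L, N, config$initial_lr, config$lr_power)
    ord <- sample.int(n_train)
    losses <- dices <- numeric(n_train)
    accum <- NULL
    n_acc <- 0L
    for (k in seq_along(ord)) {
      cs <- train_cases[[ord[k]]]
      draw_seed <- sample.int(2147483647L, 1)
      ag <- augment(cs$stack, cs$mask, config, draw_seed)
      X <- stack_matrix(ag$stack)
      y <- as.vector(ag$mask$values)
      fwd <- ennet_forward(net, X, dim(ag$stack), keep = TRUE)
      losses[k] <- soft_dice_loss(fwd$p, y, config$epsilon)
      dices[k] <- hard_dice(as.double(fwd$p >= config$threshold), y)
      dp <- soft_dice_grad(fwd$p, y, config$epsilon)
      grads <- ennet_backward(net, fwd, dp)
      if (is.null(accum)) accum <- grads
      else for (nm in names(grads)) accum[[nm]] <- accum[[nm]] + grads[[nm]]
      n_acc <- n_acc + 1L
      if (n_acc == config$batch_size || k == length(ord)) {
        if (n_acc > 1L)
          for (nm in names(accum)) accum[[nm]] <- accum[[nm]] / n_acc
        upd <- adam_step(net$params, accum, state, lr)
        net$params <- upd$params
        state <- upd$state
        accum <- NULL
        n_acc <- 0L
      }
    }

    val_loss <- val_dice <- NA_real_
    if (epoch %% config$validate_every == 0L) {
      vl <- vd <- numeric(length(val_cases))
      for (j in seq_along(val_cases)) {
        vc <- val_cases[[j]]
        X <- stack_matrix(vc$stack)
        fwd <- ennet_forward(net, X, dim(vc$stack), keep = FALSE)
        yv <- as.vector(vc$mask$values)
        vl[j] <- soft_dice_loss(fwd$p, yv, config$epsilon)
        vd[j] <- hard_dice(as.double(fwd$p >= config$threshold), yv)
      }
      val_loss <- mean(vl)
      val_dice <- mean(vd)
      if (val_dice > best$dice) {
        best <- list(dice = val_dice, params = net$params, epoch = epoch)
      }
    }
    hist[[epoch]] <- tibble::tibble(epoch = epoch, lr = lr,
                                    train_loss = mean(losses),
                                    train_dice = mean(dices),
                                    val_loss = val_loss, val_dice = val_dice)
    if (verbose)
      message(sprintf("epoch %3d  lr %.2e  loss %.4f  dice %.4f%s", epoch, lr,
                      mean(losses), mean(dices),
                      if (!is.na(val_dice))
                        sprintf("  val dice %.4f", val_dice) else ""))
  }

  if (!is.finite(best$dice)) {             # no validation epoch hit
    best <- list(dice = NA_real_, params = net$params, epoch = N)
  }
  best_net <- net
  best_net$params <- best$params
  structure(list(net = best_net, final_net = net,
                 history = dplyr::bind_rows(hist),
                 best_epoch = best$epoch, best_val_dice = best$dice,
                 combo = combo, net_spec = net_spec, config = config),
            class = "ennet_fit")
}

#' @export
print.ennet_fit <- function(x, ...) {
  cat(sprintf(paste0("<ennet_fit> combo %s, %d epochs; best validation dice",
                     " %.4f at epoch %s\n"),
              x$combo$code, nrow(x$history),
              if (is.na(x$best_val_dice)) NA else x$best_val_dice,
              x$best_epoch))
  invisible(x)
}

#' Predict a brain-probability map from a fitted model
#'
#' @param object an [train_model()] fit.
#' @param stack a [modality_stack] matching the fit's combo.
#' @param ... unused.
#' @return a `segmentation_output`.
#' @export
predict.ennet_fit <- function(object, stack, ...) {
  forward_probability(object$net, stack)
}

#' Skull-strip one case with a fitted model
#'
#' Predicts the brain mask and multiplies it into the (unnormalised) input
#' volumes: the complete inference path.
#'
#' @param fit an `ennet_fit`.
#' @param volumes named list of [volume_grid]s (or NIfTI paths) covering the
#'   fit's modalities.
#' @param threshold binarisation threshold.
#' @return list with `mask` (binary [volume_grid]), `stripped`
#'   (masked [modality_stack] of the raw volumes) and `probability`.
#' @export
strip_case <- function(fit, volumes, threshold = 0.5) {
  stopifnot(inherits(fit, "ennet_fit"))
  vols <- lapply(volumes, function(v) if (is.character(v)) load_volume(v)
                 else v)
  stack <- preprocess_case(vols, combo = fit$combo, target_shape = NULL,
                           normalize = TRUE)
  prob <- predict(fit, stack)
  mask <- binarize(prob, threshold)
  raw <- modality_stack(vols[fit$combo$members], fit$combo)
  list(mask = mask, stripped = apply_mask(raw, mask), probability = prob)
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores the architecture spec, weights, combo, training
#' config and history.
#'
#' @param fit an `ennet_fit`.
#' @param path checkpoint file path.
#' @return `path` (save) or the restored `ennet_fit` (load).
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "ennet_fit"))
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  fit <- readRDS(path)
  if (!inherits(fit, "ennet_fit"))
    stop("not an ennet checkpoint: ", path, call. = FALSE)
  fit
}

#' Evaluate a fitted model on a test cohort
#'
#' @param fit an `ennet_fit`.
#' @param test_manifest manifest tibble or CSV path.
#' @param threshold binarisation threshold.
#' @return tibble: one [evaluate_case()] row per case, with `case_id` and
#'   `condition`.
#' @export
evaluate_fit <- function(fit, test_manifest, threshold = 0.5) {
  if (is.character(test_manifest)) test_manifest <- read_manifest(test_manifest)
  cases <- load_cases(test_manifest, fit$combo)
  rows <- lapply(cases, function(cs) {
    prob <- predict(fit, cs$stack)
    pred <- binarize(prob, threshold)
    dplyr::bind_cols(tibble::tibble(case_id = cs$case_id,
                                    condition = cs$condition),
                     evaluate_case(pred, cs$mask))
  })
  dplyr::bind_rows(rows)
}

#' Modality-combination ablation study
#'
#' Trains one model per combination with identical seeds and configuration
#' (apart from the input channel count), evaluates each on the test cohort,
#' and tabulates per-combination cohort means and standard deviations of all
#' six metrics.
#'
#' @param train_manifest,val_manifest,test_manifest cohort manifests.
#' @param net_spec a [network_spec] (its `in_channels` is overridden per
#'   combination).
#' @param config a [train_config].
#' @param combos combination codes to run (default: all 15).
#' @param out_csv optional path for the results CSV (sorted by combo code).
#' @param verbose print progress.
#' @return tibble sorted by combo code: `combo`, `n_channels`, then
#'   `<metric>_mean` / `<metric>_sd` for dice, precision, recall, fpr, fnr,
#'   hd95_mm.
#' @export
run_combination_study <- function(train_manifest, val_manifest, test_manifest,
                                  net_spec, config = train_config(),
                                  combos = all_modality_combos(),
                                  out_csv = NULL, verbose = FALSE) {
  combos <- sort(vapply(combos, function(cc) modality_combo(cc)$code,
                        character(1)))
  rows <- lapply(combos, function(code) {
    cb <- modality_combo(code)
    spec_c <- net_spec
    spec_c$in_channels <- length(cb$members)
    if (verbose) message("training combo ", code, " (", spec_c$in_channels,
                         " channel(s))")
    fit <- train_model(train_manifest, val_manifest, cb, spec_c, config)
    ev <- evaluate_fit(fit, test_manifest, config$threshold)
    met <- c("dice", "precision", "recall", "fpr", "fnr", "hd95_mm")
    out <- tibble::tibble(combo = code, n_channels = spec_c$in_channels)
    for (m in met) {
      out[[paste0(m, "_mean")]] <- mean(ev[[m]])
      out[[paste0(m, "_sd")]] <- stats::sd(ev[[m]])
    }
    out
  })
  res <- dplyr::arrange(dplyr::bind_rows(rows), combo)
  if (!is.null(out_csv)) readr::write_csv(res, out_csv)
  res
}
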