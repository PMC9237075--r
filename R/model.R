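# EnNet: a residual-block 3D encoder-decoder with an auxiliary
# transposed-convolution decoder whose feature maps are summed elementwise
# with the main decoder's at every resolution level ("ensemble" decoding),
# ending in a 1x1x1 convolution and a sigmoid brain-probability map.

#' Network architecture specification
#'
#' @param in_channels number of input modalities (1-4).
#' @param depth number of resolution levels (>= 2); each level below the
#'   first halves the grid by 2x2x2 max pooling.
#' @param base_width channels at the first level; widths double per level.
#'   Must be divisible by `groupnorm_groups`.
#' @param groupnorm_groups groups for group normalization.
#' @param leaky_slope negative slope of the leaky ReLU activations.
#' @param use_aux enable the auxiliary transposed-convolution decoder branch;
#'   with `FALSE` the model reduces to a plain residual UNet (ablation
#'   switch).
#' @return an object of class `network_spec`.
#' @export
network_spec <- function(in_channels = 4L, depth = 4L, base_width = 16L,
                         groupnorm_groups = 8L, leaky_slope = 0.01,
                         use_aux = TRUE) {
  in_channels <- as.integer(in_channels)
  depth <- as.integer(depth)
  base_width <- as.integer(base_width)
  groupnorm_groups <- as.integer(groupnorm_groups)
  if (!in_channels %in% 1:4)
    stop("in_channels must be 1-4", call. = FALSE)
  if (depth < 2) stop("depth must be >= 2", call. = FALSE)
  if (base_width %% groupnorm_groups != 0)
    stop("configuration error: base_width (", base_width,
         ") must be divisible by groupnorm_groups (", groupnorm_groups, ")",
         call. = FALSE)
  structure(list(in_channels = in_channels, depth = depth,
                 base_width = base_width,
                 groupnorm_groups = groupnorm_groups,
                 leaky_slope = leaky_slope, use_aux = isTRUE(use_aux)),
            class = "network_spec")
}

level_width <- function(spec, l) spec$base_width * 2L^(l - 1L)

# ---- parameter initialisation -------------------------------------------

he_mat <- function(nin, nout, fan) matrix(rnorm(nin * nout, sd = sqrt(2 / fan)),
                                          nin, nout)

init_conv3 <- function(P, nm, cin, cout) {
  P[[paste0(nm, ".W")]] <- he_mat(cin * 27L, cout, cin * 27L)
  P[[paste0(nm, ".b")]] <- numeric(cout)
  P
}

init_gn <- function(P, nm, c) {
  P[[paste0(nm, ".gamma")]] <- rep(1, c)
  P[[paste0(nm, ".beta")]] <- numeric(c)
  P
}

init_ennet_params <- function(spec, seed = 1L) {
  set.seed(as.integer(seed))
  P <- list()
  D <- spec$depth
  G <- spec$groupnorm_groups
  for (l in seq_len(D)) {
    w <- level_width(spec, l)
    cin <- if (l == 1L) spec$in_channels else level_width(spec, l - 1L)
    P <- init_conv3(P, sprintf("enc%d.in.conv", l), cin, w)
    P <- init_gn(P, sprintf("enc%d.in.gn", l), w)
    P <- init_conv3(P, sprintf("enc%d.res.conv1", l), w, w)
    P <- init_gn(P, sprintf("enc%d.res.gn1", l), w)
    P <- init_conv3(P, sprintf("enc%d.res.conv2", l), w, w)
    P <- init_gn(P, sprintf("enc%d.res.gn2", l), w)
  }
  for (l in seq_len(D - 1L)) {
    w <- level_width(spec, l)
    wup <- level_width(spec, l + 1L)
    P <- init_conv3(P, sprintf("dec%d.up.conv", l), wup, w)
    P <- init_gn(P, sprintf("dec%d.up.gn", l), w)
    P <- init_conv3(P, sprintf("dec%d.res.conv1", l), w, w)
    P <- init_gn(P, sprintf("dec%d.res.gn1", l), w)
    P <- init_conv3(P, sprintf("dec%d.res.conv2", l), w, w)
    P <- init_gn(P, sprintf("dec%d.res.gn2", l), w)
    if (spec$use_aux) {
      P[[sprintf("aux%d.tc.W", l)]] <-
        array(rnorm(wup * w * 8L, sd = sqrt(2 / (8 * wup))), dim = c(wup, w, 8L))
      P[[sprintf("aux%d.tc.b", l)]] <- numeric(w)
    }
  }
  w1 <- level_width(spec, 1L)
  P[["head.W"]] <- matrix(rnorm(w1, sd = sqrt(1 / w1)), w1, 1L)
  P[["head.b"]] <- 0
  P
}

#' Build an EnNet model
#'
#' Instantiates the network with seeded random weights: a per-level
#' residual-block encoder with 2x2x2 max pooling, a main decoder
#' (trilinear upsampling + convolution, additive encoder skips, residual
#' blocks) and, unless disabled, an auxiliary transposed-convolution decoder
#' whose feature maps are added to the main decoder's at every level.
#'
#' @param spec a [network_spec].
#' @param seed integer seed for weight initialisation.
#' @return an object of class `ennet`.
#' @export
build_ennet <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  structure(list(spec = spec, params = init_ennet_params(spec, seed),
                 init_seed = as.integer(seed)),
            class = "ennet")
}

#' @export
print.ennet <- function(x, ...) {
  s <- x$spec
  cat(sprintf(paste0("<ennet> depth %d, base width %d, %d input channel(s),",
                     " aux decoder %s; %s parameters\n"),
              s$depth, s$base_width, s$in_channels,
              if (s$use_aux) "on" else "off",
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Number of trainable parameters
#'
#' @param net an [build_ennet()] model.
#' @return integer parameter count.
#' @export
count_parameters <- function(net) {
  sum(vapply(net$params, length, numeric(1)))
}

# ---- composite layer units ----------------------------------------------

conv_unit_fwd <- function(x, dims, P, nm, G, slope, keep) {
  cv <- conv3_fwd(x, dims, P[[paste0(nm, ".conv.W")]],
                  P[[paste0(nm, ".conv.b")]], keep)
  gn <- gn_fwd(cv$y, P[[paste0(nm, ".gn.gamma")]],
               P[[paste0(nm, ".gn.beta")]], G, keep)
  rl <- lrelu_fwd(gn$y, slope)
  list(y = rl$y, cache = if (keep) list(cv = cv$cache, gn = gn$cache,
                                        neg = rl$neg) else NULL)
}

conv_unit_bwd <- function(dy, cache, P, nm, G, slope, gr) {
  dy <- lrelu_bwd(dy, cache$neg, slope)
  g <- gn_bwd(dy, cache$gn, P[[paste0(nm, ".gn.gamma")]])
  acc_grad(gr, paste0(nm, ".gn.gamma"), g$dgamma)
  acc_grad(gr, paste0(nm, ".gn.beta"), g$dbeta)
  cb <- conv3_bwd(g$dx, cache$cv, P[[paste0(nm, ".conv.W")]])
  acc_grad(gr, paste0(nm, ".conv.W"), cb$dW)
  acc_grad(gr, paste0(nm, ".conv.b"), cb$db)
  cb$dx
}

resblock_fwd <- function(x, dims, P, nm, G, slope, keep) {
  c1 <- conv3_fwd(x, dims, P[[paste0(nm, ".conv1.W")]],
                  P[[paste0(nm, ".conv1.b")]], keep)
  g1 <- gn_fwd(c1$y, P[[paste0(nm, ".gn1.gamma")]],
               P[[paste0(nm, ".gn1.beta")]], G, keep)
  r1 <- lrelu_fwd(g1$y, slope)
  c2 <- conv3_fwd(r1$y, dims, P[[paste0(nm, ".conv2.W")]],
                  P[[paste0(nm, ".conv2.b")]], keep)
  g2 <- gn_fwd(c2$y, P[[paste0(nm, ".gn2.gamma")]],
               P[[paste0(nm, ".gn2.beta")]], G, keep)
  r2 <- lrelu_fwd(g2$y + x, slope)
  list(y = r2$y, cache = if (keep) list(c1 = c1$cache, g1 = g1$cache,
                                        neg1 = r1$neg, c2 = c2$cache,
                                        g2 = g2$cache, neg2 = r2$neg)
       else NULL)
}

resblock_bwd <- function(dy, cache, P, nm, G, slope, gr) {
  ds <- lrelu_bwd(dy, cache$neg2, slope)
  g2 <- gn_bwd(ds, cache$g2, P[[paste0(nm, ".gn2.gamma")]])
  acc_grad(gr, paste0(nm, ".gn2.gamma"), g2$dgamma)
  acc_grad(gr, paste0(nm, ".gn2.beta"), g2$dbeta)
  c2 <- conv3_bwd(g2$dx, cache$c2, P[[paste0(nm, ".conv2.W")]])
  acc_grad(gr, paste0(nm, ".conv2.W"), c2$dW)
  acc_grad(gr, paste0(nm, ".conv2.b"), c2$db)
  dr1 <- lrelu_bwd(c2$dx, cache$neg1, slope)
  g1 <- gn_bwd(dr1, cache$g1, P[[paste0(nm, ".gn1.gamma")]])
  acc_grad(gr, paste0(nm, ".gn1.gamma"), g1$dgamma)
  acc_grad(gr, paste0(nm, ".gn1.beta"), g1$dbeta)
  c1 <- conv3_bwd(g1$dx, cache$c1, P[[paste0(nm, ".conv1.W")]])
  acc_grad(gr, paste0(nm, ".conv1.W"), c1$dW)
  acc_grad(gr, paste0(nm, ".conv1.b"), c1$db)
  c1$dx + ds
}

acc_grad <- function(gr, nm, val) {
  if (is.null(gr[[nm]])) gr[[nm]] <- val else gr[[nm]] <- gr[[nm]] + val
  invisible(NULL)
}

# ---- full forward / backward --------------------------------------------

check_divisible <- function(dims, depth) {
  need <- 2L^(depth - 1L)
  if (any(dims %% need != 0))
    stop("shape error: spatial dims (", paste(dims, collapse = "x"),
         ") must be multiples of ", need, " for depth ", depth, call. = FALSE)
  invisible(need)
}

# X: V x C matrix; returns probability vector plus (optionally) full caches
# and the per-level decoder branch tensors (for instrumentation).
ennet_forward <- function(net, X, dims, keep = FALSE) {
  spec <- net$spec
  P <- net$params
  G <- spec$groupnorm_groups
  sl <- spec$leaky_slope
  D <- spec$depth
  if (ncol(X) != spec$in_channels)
    stop("input has ", ncol(X), " channels, spec expects ",
         spec$in_channels, call. = FALSE)
  check_divisible(dims, D)

  enc <- vector("list", D)
  cache <- list(enc = vector("list", D), dec = vector("list", D - 1L),
                dims = vector("list", D))
  x <- X
  dcur <- dims
  for (l in seq_len(D)) {
    centry <- list()
    if (l > 1L) {
      mp <- cpp_maxpool_fwd(x, dcur[1], dcur[2], dcur[3])
      if (keep) centry$pool <- list(argmax = mp$argmax, V = nrow(x))
      x <- mp$y
      dcur <- dcur %/% 2L
    }
    cache$dims[[l]] <- dcur
    cu <- conv_unit_fwd(x, dcur, P, sprintf("enc%d.in", l), G, sl, keep)
    rb <- resblock_fwd(cu$y, dcur, P, sprintf("enc%d.res", l), G, sl, keep)
    if (keep) { centry$in_unit <- cu$cache; centry$res <- rb$cache }
    enc[[l]] <- rb$y
    cache$enc[[l]] <- centry
    x <- rb$y
  }

  branches <- if (keep) vector("list", D - 1L) else NULL
  for (l in rev(seq_len(D - 1L))) {
    dlow <- cache$dims[[l + 1L]]
    up <- cpp_upsample_fwd(x, dlow[1], dlow[2], dlow[3])
    dhi <- cache$dims[[l]]
    cu <- conv_unit_fwd(up, dhi, P, sprintf("dec%d.up", l), G, sl, keep)
    s <- cu$y + enc[[l]]
    rb <- resblock_fwd(s, dhi, P, sprintf("dec%d.res", l), G, sl, keep)
    m <- rb$y
    dentry <- list(up_unit = cu$cache, res = rb$cache, dlow = dlow,
                   xlow = if (keep && spec$use_aux) x else NULL)
    if (spec$use_aux) {
      tc <- tconv_fwd(x, dlow, P[[sprintf("aux%d.tc.W", l)]],
                      P[[sprintf("aux%d.tc.b", l)]], keep)
      if (keep) dentry$tc <- tc$cache
      xnew <- m + tc$y
      if (keep) branches[[l]] <- list(main = m, aux = tc$y, combined = xnew)
    } else {
      xnew <- m
      if (keep) branches[[l]] <- list(main = m, aux = NULL, combined = xnew)
    }
    if (keep) cache$dec[[l]] <- dentry
    x <- xnew
  }

  logits <- conv1_fwd(x, P[["head.W"]], P[["head.b"]])
  p <- sigmoid(logits)
  list(p = as.vector(p), logits = logits,
       x_final = if (keep) x else NULL,
       cache = if (keep) cache else NULL,
       branches = branches)
}

# dp: dL/d(probability), length V. Returns named list of gradients.
ennet_backward <- function(net, fwd, dp) {
  spec <- net$spec
  P <- net$params
  G <- spec$groupnorm_groups
  sl <- spec$leaky_slope
  D <- spec$depth
  cache <- fwd$cache
  gr <- new.env(parent = emptyenv())

  p <- fwd$p
  dlogits <- matrix(dp * p * (1 - p), ncol = 1)
  hb <- conv1_bwd(dlogits, fwd$x_final, P[["head.W"]])
  acc_grad(gr, "head.W", hb$dW)
  acc_grad(gr, "head.b", hb$db)
  dx <- hb$dx

  denc <- vector("list", D)   # gradients flowing into each encoder output
  for (l in seq_len(D - 1L)) {
    dentry <- cache$dec[[l]]
    dm <- dx
    if (spec$use_aux) {
      tb <- tconv_bwd(dx, dentry$tc, P[[sprintf("aux%d.tc.W", l)]])
      acc_grad(gr, sprintf("aux%d.tc.W", l), tb$dW)
      acc_grad(gr, sprintf("aux%d.tc.b", l), tb$db)
      dxlow_aux <- tb$dx
    } else dxlow_aux <- 0
    ds <- resblock_bwd(dm, dentry$res, P, sprintf("dec%d.res", l), G, sl, gr)
    denc[[l]] <- ds                     # skip-connection branch
    dup <- conv_unit_bwd(ds, dentry$up_unit, P, sprintf("dec%d.up", l), G,
                         sl, gr)
    dlow <- cpp_upsample_bwd(dup, dentry$dlow[1], dentry$dlow[2],
                             dentry$dlow[3])
    dx <- dlow + dxlow_aux
  }
  denc[[D]] <- dx

  for (l in rev(seq_len(D))) {
    dy <- denc[[l]]
    centry <- cache$enc[[l]]
    dy <- resblock_bwd(dy, centry$res, P, sprintf("enc%d.res", l), G, sl, gr)
    dy <- conv_unit_bwd(dy, centry$in_unit, P, sprintf("enc%d.in", l), G,
                        sl, gr)
    if (l > 1L) {
      dy <- cpp_maxpool_bwd(dy, centry$pool$argmax, centry$pool$V)
      # add to the gradient waiting at the level above (encoder output l-1
      # also feeds the decoder skip, already stored in denc[[l-1]])
      denc[[l - 1L]] <- denc[[l - 1L]] + dy
    }
  }
  as.list(gr)
}

#' Brain-probability forward pass
#'
#' Runs the network on a modality stack in evaluation mode (deterministic for
#' fixed weights) and returns the voxelwise brain probability.
#'
#' @param net an `ennet` model.
#' @param stack a [modality_stack] whose channel count equals the network's
#'   `in_channels` and whose spatial dims are divisible by
#'   `2^(depth - 1)`.
#' @return an object of class `segmentation_output` with fields
#'   `probability` (3D array in `[0,1]`), `affine` and `spacing`.
#' @export
forward_probability <- function(net, stack) {
  stopifnot(inherits(net, "ennet"), inherits(stack, "modality_stack"))
  X <- stack_matrix(stack)
  dims <- dim(stack)
  fwd <- ennet_forward(net, X, dims, keep = FALSE)
  ref <- stack$channels[[1]]
  structure(list(probability = array(fwd$p, dim = dims),
                 affine = ref$affine, spacing = ref$spacing),
            class = "segmentation_output")
}

#' @export
print.segmentation_output <- function(x, ...) {
  d <- dim(x$probability)
  cat(sprintf("<segmentation_output> %d x %d x %d, mean probability %.3f\n",
              d[1], d[2], d[3], mean(x$probability)))
  invisible(x)
}

#' Binarise a probability map into a brain mask
#'
#' @param prob a [forward_probability()] output (or a plain 3D array /
#'   [volume_grid] of probabilities).
#' @param threshold scalar in (0, 1); voxels with probability >= threshold
#'   become brain.
#' @return a binary [volume_grid].
#' @export
binarize <- function(prob, threshold = 0.5) {
  if (!(threshold > 0 && threshold < 1))
    stop("threshold must be in (0, 1)", call. = FALSE)
  if (inherits(prob, "segmentation_output")) {
    vals <- prob$probability; affine <- prob$affine
  } else if (is_volume_grid(prob)) {
    vals <- prob$values; affine <- prob$affine
  } else {
    vals <- prob; affine <- NULL
  }
  m <- array(as.double(vals >= threshold), dim = dim(vals))
  if (is.null(affine)) volume_grid(m) else volume_grid(m, affine = affine)
}
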