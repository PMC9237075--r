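# Layer primitives for the 3D segmentation network, with hand-written
# forward/backward passes. Feature tensors are V x C matrices (V voxels in
# column-major spatial order, C channels); spatial dims travel alongside.
# Convolutions are 3x3x3, padding 1, stride 1, realised as 27 offset-blocked
# GEMMs in C++ (see src/ennet_ops.cpp); the weight matrix is (27*C_in) x
# C_out with row index o*C_in + c for offset o and input channel c.

GN_EPS <- 1e-5

# ---- 3x3x3 convolution --------------------------------------------------

conv3_fwd <- function(x, dims, W, b, keep = TRUE) {
  y <- cpp_conv3_fwd(x, dims[1], dims[2], dims[3], W, b)
  list(y = y, cache = if (keep) list(x = x, dims = dims) else NULL)
}

conv3_bwd <- function(dy, cache, W) {
  cpp_conv3_bwd(cache$x, dy, cache$dims[1], cache$dims[2], cache$dims[3], W)
}

# ---- 1x1x1 convolution (head) ------------------------------------------

conv1_fwd <- function(x, W, b) {
  y <- x %*% W
  sweep(y, 2, b, "+")
}

conv1_bwd <- function(dy, x, W) {
  list(dx = dy %*% t(W), dW = crossprod(x, dy), db = colSums(dy))
}

# ---- 2x2x2 stride-2 transposed convolution ------------------------------

# W: array (C_in, C_out, 8); offset o = dx + 2*dy + 4*dz + 1, d* in {0,1}.
tconv_offsets <- function(dims) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  ox <- 2L * nx; oy <- 2L * ny
  ix <- rep(seq_len(nx) - 1L, times = ny * nz)
  iy <- rep(rep(seq_len(ny) - 1L, each = nx), times = nz)
  iz <- rep(seq_len(nz) - 1L, each = nx * ny)
  lapply(0:7, function(o) {
    dx <- o %% 2L; dy <- (o %/% 2L) %% 2L; dz <- o %/% 4L
    (2L * ix + dx) + ox * ((2L * iy + dy) + oy * (2L * iz + dz)) + 1L
  })
}

tconv_fwd <- function(x, dims, W, b, keep = TRUE) {
  cout <- dim(W)[2]
  idx <- tconv_offsets(dims)
  y <- matrix(0, 8L * nrow(x), cout)
  for (o in 1:8) y[idx[[o]], ] <- x %*% W[, , o]
  y <- sweep(y, 2, b, "+")
  list(y = y, cache = if (keep) list(x = x, idx = idx) else NULL)
}

tconv_bwd <- function(dy, cache, W) {
  cin <- dim(W)[1]
  dW <- array(0, dim = dim(W))
  dx <- matrix(0, nrow(cache$x), cin)
  for (o in 1:8) {
    dyo <- dy[cache$idx[[o]], , drop = FALSE]
    dW[, , o] <- crossprod(cache$x, dyo)
    dx <- dx + dyo %*% t(W[, , o])
  }
  list(dx = dx, dW = dW, db = colSums(dy))
}

# ---- group normalization ------------------------------------------------

gn_groups_index <- function(C, G) {
  split(seq_len(C), rep(seq_len(G), each = C / G))
}

gn_fwd <- function(x, gamma, beta, G, keep = TRUE) {
  r <- cpp_gn_fwd(x, gamma, beta, G, GN_EPS)
  list(y = r$y, cache = if (keep) list(xhat = r$xhat,
                                       inv_sd = r$inv_sd, G = G) else NULL)
}

gn_bwd <- function(dy, cache, gamma) {
  cpp_gn_bwd(dy, cache$xhat, cache$inv_sd, gamma, cache$G)
}

# ---- leaky ReLU ---------------------------------------------------------

# The forward output doubles as the backward mask (slope > 0 preserves sign).
lrelu_fwd <- function(x, slope) {
  y <- cpp_lrelu_fwd(x, slope)
  list(y = y, neg = y)
}

lrelu_bwd <- function(dy, neg, slope) {
  cpp_lrelu_bwd(dy, neg, slope)
}

sigmoid <- function(x) 1 / (1 + exp(-x))
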