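# Reference patch encoder: a small 3D convolutional network operating on one
# bag of K patches at a time. Layers are hand-rolled on BLAS matrix products
# (im2col convolution) with manual backpropagation; at desk scale (20^3
# patches, a few channels) each bag step is a handful of matrix products.

#' Configure the reference 3D CNN patch encoder
#'
#' Strided valid convolutions with ReLU, optional non-overlapping max
#' pooling per block, then a dense projection to the embedding width M with
#' ReLU. The default architecture uses a non-overlapping (kernel = stride)
#' first block — a patchify convolution whose im2col is a pure reshape —
#' followed by a small overlapping block, sized automatically from the patch
#' side. Spatial sizes are computed and validated at configuration time.
#'
#' @param patch_side input patch side length in voxels.
#' @param channels output channels per conv block (default `c(8, 8)`).
#' @param kernels convolution kernel side per block; default
#'   `c(k1, 2)` where `k1` is the largest of 4, 3, 2 dividing `patch_side`.
#' @param strides stride per block; default `c(k1, 1)`.
#' @param pools non-overlapping pool side per block (1 = none); default
#'   pools only the last block by 2 when its output side is even.
#' @param m embedding width M (default 32).
#' @param bias use bias terms (default `TRUE`; `FALSE` gives a linear-in-zero
#'   encoder for which the all-zero patch embeds to the zero vector).
#' @return A list of class `encoder_config` with a `shapes` field recording
#'   the spatial side after every block and the flattened feature count.
#' @export
encoder_config <- function(patch_side, channels = c(8, 8), kernels = NULL,
                           strides = NULL, pools = NULL, m = 32, bias = TRUE) {
  nb <- length(channels)
  side <- as.integer(patch_side)
  if (is.null(kernels)) {
    k1 <- if (side %% 4L == 0L) 4L else if (side %% 3L == 0L) 3L else
      if (side %% 2L == 0L) 2L else
        stop("no default kernel for this patch side; pass 'kernels'", call. = FALSE)
    kernels <- c(k1, rep(2L, nb - 1L))
  }
  if (is.null(strides)) strides <- c(kernels[1], rep(1L, nb - 1L))
  if (length(kernels) != nb || length(strides) != nb) {
    stop("one kernel and stride per conv block required", call. = FALSE)
  }
  if (is.null(pools)) {
    pools <- rep(1L, nb)
    last <- side
    for (b in seq_len(nb)) last <- (last - kernels[b]) %/% strides[b] + 1L
    if (last %% 2L == 0L && last > 2L) pools[nb] <- 2L
  }
  if (length(pools) != nb) stop("one pool size per conv block required", call. = FALSE)
  shapes <- integer(0)
  for (b in seq_len(nb)) {
    if (side < kernels[b]) {
      stop(sprintf("block %d: input side %d smaller than kernel %d",
                   b, side, kernels[b]), call. = FALSE)
    }
    side <- (side - kernels[b]) %/% strides[b] + 1L
    if (side %% pools[b] != 0L) {
      stop(sprintf("block %d: conv output side %d not divisible by pool %d",
                   b, side, pools[b]), call. = FALSE)
    }
    side <- side %/% pools[b]
    shapes <- c(shapes, side)
  }
  structure(list(patch_side = as.integer(patch_side), channels = channels,
                 kernels = as.integer(kernels), strides = as.integer(strides),
                 pools = as.integer(pools), m = as.integer(m),
                 bias = isTRUE(bias), shapes = shapes,
                 flat = side^3 * channels[nb]),
            class = "encoder_config")
}

# ---- parameter initialization -------------------------------------------------

init_encoder <- function(cfg) {
  cin <- c(1L, cfg$channels[-length(cfg$channels)])
  blocks <- lapply(seq_along(cfg$channels), function(b) {
    fan_in <- cfg$kernels[b]^3 * cin[b]
    list(W = matrix(stats::rnorm(fan_in * cfg$channels[b], 0, sqrt(2 / fan_in)),
                    fan_in, cfg$channels[b]),
         b = if (cfg$bias) numeric(cfg$channels[b]) else NULL)
  })
  dense <- list(W = matrix(stats::rnorm(cfg$flat * cfg$m, 0, sqrt(2 / cfg$flat)),
                           cfg$flat, cfg$m),
                b = if (cfg$bias) numeric(cfg$m) else NULL)
  list(blocks = blocks, dense = dense)
}

# ---- conv / pool primitives ---------------------------------------------------
#
# Activations flow through the encoder in layout (s, s, s, K, C): spatial
# axes first, then the K patches of the bag, then channels. Convolutions are
# im2col matrix products; patch extraction/scatter uses flat 2-D indexing
# with precomputed linear spatial offsets, which is far cheaper than 5-D
# array subscripting.

# linear spatial indices of the o^3 output grid shifted by (di, dj, dk)
conv_offsets <- function(s, idx, kernel) {
  out <- vector("list", kernel^3)
  n <- 1L
  for (dk in seq_len(kernel)) for (dj in seq_len(kernel)) for (di in seq_len(kernel)) {
    out[[n]] <- as.vector(outer(outer(idx + di, (idx + dj - 1L) * s, "+"),
                                (idx + dk - 1L) * s * s, "+"))
    n <- n + 1L
  }
  out
}

# x: array (s, s, s, K, Cin). Returns im2col matrix (o^3*K) x (kernel^3*Cin),
# rows ordered (i, j, k, patch); column blocks ordered offset-fastest,
# channel-slowest. Non-overlapping windows (kernel == stride) reduce to a
# pure reshape; the general case is one C-level gather plus one aperm.
im2col3d <- function(x, kernel, stride) {
  d <- dim(x); s <- d[1]; K <- d[4]; cin <- d[5]
  if (kernel == stride && s %% kernel == 0L) {
    o <- s %/% kernel
    x7 <- x
    dim(x7) <- c(kernel, o, kernel, o, kernel, o, K, cin)
    E <- aperm(x7, c(2, 4, 6, 7, 1, 3, 5, 8))
    dim(E) <- c(o^3 * K, kernel^3 * cin)
    return(list(Xc = E, o = o, stacked = NULL))
  }
  o <- (s - kernel) %/% stride + 1L
  idx <- seq.int(0L, by = stride, length.out = o)
  stacked <- unlist(conv_offsets(s, idx, kernel), use.names = FALSE)
  x3 <- x; dim(x3) <- c(s^3, K * cin)
  E <- x3[stacked, , drop = FALSE]             # (o^3 * kernel^3) x (K*cin)
  dim(E) <- c(o^3, kernel^3, K, cin)
  E <- aperm(E, c(1, 3, 2, 4))
  dim(E) <- c(o^3 * K, kernel^3 * cin)
  list(Xc = E, o = o, stacked = stacked)
}

conv3d_forward <- function(x, W, b, kernel, stride, ic = NULL, xdim = NULL) {
  xdim <- xdim %||% dim(x)
  K <- xdim[4]
  ic <- ic %||% im2col3d(x, kernel, stride)
  Y <- ic$Xc %*% W
  if (!is.null(b)) Y <- sweep(Y, 2, b, "+")
  y <- array(Y, c(ic$o, ic$o, ic$o, K, ncol(W)))
  list(y = y, cache = list(Xc = ic$Xc, o = ic$o, stacked = ic$stacked,
                           xdim = xdim, kernel = kernel))
}

conv3d_backward <- function(dy, W, cache, want_dx = TRUE) {
  o <- cache$o; K <- cache$xdim[4]; cin <- cache$xdim[5]; s <- cache$xdim[1]
  kernel <- cache$kernel
  dYm <- dy; dim(dYm) <- c(o^3 * K, ncol(W))
  dW <- crossprod(cache$Xc, dYm)
  db <- colSums(dYm)
  if (!want_dx) return(list(dx = NULL, dW = dW, db = db))
  dXc <- tcrossprod(dYm, W)                     # (o^3*K) x (kernel^3*cin)
  if (is.null(cache$stacked)) {                 # non-overlapping: pure reshape
    dim(dXc) <- c(o, o, o, K, kernel, kernel, kernel, cin)
    dx <- aperm(dXc, c(5, 1, 6, 2, 7, 3, 4, 8))
    dim(dx) <- cache$xdim
    return(list(dx = dx, dW = dW, db = db))
  }
  dim(dXc) <- c(o^3, K, kernel^3, cin)
  dXc <- aperm(dXc, c(1, 3, 2, 4))
  dim(dXc) <- c(o^3 * kernel^3, K * cin)
  agg <- rowsum(dXc, group = cache$stacked, reorder = FALSE)  # overlap reduce
  dx3 <- matrix(0, s^3, K * cin)
  dx3[as.integer(rownames(agg)), ] <- agg
  dim(dx3) <- cache$xdim
  list(dx = dx3, dW = dW, db = db)
}

maxpool_forward <- function(x, p) {
  if (p == 1L) return(list(y = x, cache = NULL))
  d <- dim(x); s <- d[1]; o <- s %/% p
  y <- array(-Inf, c(o, o, o, d[4], d[5]))
  for (dk in seq_len(p)) for (dj in seq_len(p)) for (di in seq_len(p)) {
    blk <- x[seq(di, s, p), seq(dj, s, p), seq(dk, s, p), , , drop = FALSE]
    y <- array(pmax(y, blk), dim(y))
  }
  list(y = y, cache = list(x = x, y = y, p = p))
}

maxpool_backward <- function(dy, cache) {
  if (is.null(cache)) return(dy)
  x <- cache$x; y <- cache$y; p <- cache$p
  d <- dim(x); s <- d[1]
  cnt <- array(0, dim(y))
  for (dk in seq_len(p)) for (dj in seq_len(p)) for (di in seq_len(p)) {
    blk <- x[seq(di, s, p), seq(dj, s, p), seq(dk, s, p), , , drop = FALSE]
    cnt <- cnt + (blk == y)
  }
  dx <- array(0, d)
  g <- dy / cnt                              # ties share the gradient equally
  for (dk in seq_len(p)) for (dj in seq_len(p)) for (di in seq_len(p)) {
    blk <- x[seq(di, s, p), seq(dj, s, p), seq(dk, s, p), , , drop = FALSE]
    dx[seq(di, s, p), seq(dj, s, p), seq(dk, s, p), , ] <- (blk == y) * g
  }
  dx
}

# ---- encoder forward / backward ----------------------------------------------

# Precompute the input-layer im2col of a bag (constant across training
# steps when the bag itself is fixed).
precompute_input_cols <- function(patches, cfg) {
  d <- dim(patches)
  x <- patches
  dim(x) <- c(d[1], d[1], d[1], d[4], 1L)
  ic <- im2col3d(x, cfg$kernels[1], cfg$strides[1])
  ic$xdim <- dim(x)
  ic
}

# patches: array (p, p, p, K). Returns H (K x M) and a cache for backward.
# `ic1`: optional precomputed input-layer im2col from precompute_input_cols().
encoder_forward <- function(patches, enc_params, cfg, ic1 = NULL) {
  d <- if (is.null(patches)) ic1$xdim[c(1, 2, 3, 4)] else dim(patches)
  if (d[1] != cfg$patch_side) {
    stop(sprintf("patch side %d does not match encoder input side %d",
                 d[1], cfg$patch_side), call. = FALSE)
  }
  K <- d[4]
  if (is.null(ic1)) {
    x <- patches
    dim(x) <- c(d[1], d[1], d[1], K, 1L)
  } else x <- NULL
  caches <- vector("list", length(cfg$channels))
  for (b in seq_along(cfg$channels)) {
    cv <- if (b == 1L && !is.null(ic1)) {
      conv3d_forward(NULL, enc_params$blocks[[1]]$W, enc_params$blocks[[1]]$b,
                     cfg$kernels[1], cfg$strides[1], ic = ic1, xdim = ic1$xdim)
    } else {
      conv3d_forward(x, enc_params$blocks[[b]]$W, enc_params$blocks[[b]]$b,
                     cfg$kernels[b], cfg$strides[b])
    }
    a <- pmax(cv$y, 0)
    dim(a) <- dim(cv$y)
    pl <- maxpool_forward(a, cfg$pools[b])
    caches[[b]] <- list(conv = cv$cache, relu_in = cv$y, pool = pl$cache)
    x <- pl$y
  }
  flat <- matrix(aperm(x, c(4, 1, 2, 3, 5)), K, cfg$flat)   # K x flat
  H <- flat %*% enc_params$dense$W
  if (!is.null(enc_params$dense$b)) H <- sweep(H, 2, enc_params$dense$b, "+")
  Hr <- pmax(H, 0)
  list(H = Hr, cache = list(caches = caches, flat = flat, dense_in = H,
                            last_dim = dim(x), K = K))
}

# dH: K x M. Returns gradients mirroring enc_params.
encoder_backward <- function(dH, enc_params, cfg, cache) {
  dH <- dH * (cache$dense_in > 0)
  dW_dense <- crossprod(cache$flat, dH)
  db_dense <- colSums(dH)
  dflat <- tcrossprod(dH, enc_params$dense$W)              # K x flat
  ld <- cache$last_dim
  dx <- aperm(array(dflat, c(cache$K, ld[1], ld[2], ld[3], ld[5])),
              c(2, 3, 4, 1, 5))
  gblocks <- vector("list", length(cfg$channels))
  for (b in rev(seq_along(cfg$channels))) {
    cc <- cache$caches[[b]]
    dx <- maxpool_backward(dx, cc$pool)
    dx <- dx * (cc$relu_in > 0)
    bw <- conv3d_backward(dx, enc_params$blocks[[b]]$W, cc$conv,
                          want_dx = b > 1L)    # block 1 input needs no gradient
    gblocks[[b]] <- list(W = bw$dW,
                         b = if (!is.null(enc_params$blocks[[b]]$b)) bw$db else NULL)
    dx <- bw$dx
  }
  list(blocks = gblocks, dense = list(W = dW_dense,
                                      b = if (!is.null(enc_params$dense$b)) db_dense else NULL))
}

#' Embed the patches of a bag
#'
#' Runs the reference encoder in evaluation mode (deterministic; no dropout)
#' and returns one embedding row per patch.
#'
#' @param bag a `patch_bag` (or an array `side^3 x K`).
#' @param model a fitted [mil_fit] model, or a list with `params$enc` and
#'   `encoder` (config) as produced by the internals.
#' @return A numeric matrix K x M.
#' @export
encode_patches <- function(bag, model) {
  patches <- if (inherits(bag, "patch_bag")) bag$patches else bag
  encoder_forward(patches, model$params$enc, model$encoder)$H
}
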