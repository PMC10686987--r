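# Gated attention-based MIL pooling: the scoring, normalization, pooling and
# classification primitives, plus their manual backward passes used by the
# training loop.

#' Initialize attention and classification-head parameters
#'
#' Attention weights follow the original attention-MIL choice of a hidden
#' width L = 128 with a single attention branch. Initialization is uniform
#' in +/- 1/sqrt(fan_in), the standard dense-layer default.
#'
#' @param m embedding width M.
#' @param l attention hidden width L (default 128).
#' @param gated use the gated (tanh x sigmoid) scorer (default `TRUE`).
#' @return A list with `V`, `U` (L x M), `w` (L), `gated`.
#' @export
attention_params <- function(m, l = 128, gated = TRUE) {
  if (m <= 0 || l <= 0) stop("L and M must be positive", call. = FALSE)
  r <- 1 / sqrt(m)
  list(V = matrix(stats::runif(l * m, -r, r), l, m),
       U = matrix(stats::runif(l * m, -r, r), l, m),
       w = stats::runif(l, -1 / sqrt(l), 1 / sqrt(l)),
       gated = isTRUE(gated))
}

# forward with cache: embeddings H (K x M)
attention_forward <- function(H, pars) {
  if (!is.matrix(H)) H <- matrix(H, nrow = 1)
  if (ncol(H) != ncol(pars$V)) {
    stop(sprintf("embedding width %d does not match attention M = %d",
                 ncol(H), ncol(pars$V)), call. = FALSE)
  }
  T_ <- tanh(H %*% t(pars$V))                  # K x L
  if (pars$gated) {
    G <- 1 / (1 + exp(-(H %*% t(pars$U))))     # K x L
    S <- (T_ * G) %*% pars$w                   # K
  } else {
    G <- NULL
    S <- T_ %*% pars$w
  }
  s <- as.numeric(S)
  e <- exp(s - max(s))                          # shift-invariant softmax
  a <- e / sum(e)
  list(a = a, T = T_, G = G, s = s, H = H)
}

# backward: da (K) -> gradients for H, V, U, w
attention_backward <- function(da, pars, cache) {
  a <- cache$a; T_ <- cache$T; G <- cache$G; H <- cache$H
  ds <- a * (da - sum(a * da))                  # softmax backward
  if (pars$gated) {
    dTG <- outer(ds, pars$w)                    # K x L
    dT <- dTG * G
    dG <- dTG * T_
    dpreV <- dT * (1 - T_^2)
    dpreU <- dG * G * (1 - G)
    dH <- dpreV %*% pars$V + dpreU %*% pars$U
    dV <- crossprod(dpreV, H)
    dU <- crossprod(dpreU, H)
    dw <- as.numeric(crossprod(T_ * G, ds))
  } else {
    dT <- outer(ds, pars$w)
    dpreV <- dT * (1 - T_^2)
    dH <- dpreV %*% pars$V
    dV <- crossprod(dpreV, H)
    dU <- NULL
    dw <- as.numeric(crossprod(T_, ds))
  }
  list(dH = dH, dV = dV, dU = dU, dw = dw)
}

#' Attention weights over a bag of embeddings
#'
#' Ungated scorer: `a_k = softmax_k( w' tanh(V h_k') )`. Gated scorer:
#' `a_k = softmax_k( w' (tanh(V h_k') * sigmoid(U h_k')) )` with elementwise
#' product. Weights are strictly positive, sum to 1, and are invariant to
#' adding a constant to all pre-softmax scores.
#'
#' @param embeddings numeric matrix K x M (one row per patch), or a length-M
#'   vector for K = 1.
#' @param params a list with `V`, `U` (L x M), `w` (length L), `gated`
#'   (see [attention_params]).
#' @return Numeric length-K weight vector.
#' @export
attention_weights <- function(embeddings, params) {
  attention_forward(embeddings, params)$a
}

#' Attention-weighted MIL pooling
#'
#' `z = sum_k a_k h_k`: the bag representation is the attention-weighted sum
#' of patch embeddings — permutation invariant and contained in the convex
#' hull of the embeddings.
#'
#' @param embeddings numeric matrix K x M.
#' @param weights length-K weights summing to 1.
#' @return Numeric length-M pooled feature vector.
#' @export
attention_pool <- function(embeddings, weights) {
  if (!is.matrix(embeddings)) embeddings <- matrix(embeddings, nrow = 1)
  if (length(weights) != nrow(embeddings)) {
    stop("one weight per embedding row required", call. = FALSE)
  }
  as.numeric(crossprod(embeddings, weights))
}

#' Classify a pooled bag vector
#'
#' Single affine layer plus logistic link: `Y_pred = sigmoid(w'z + b)`,
#' probability of the positive (female) class. The predicted label is 1 when
#' `Y_pred >= 0.5`.
#'
#' @param z length-M pooled feature vector.
#' @param head list with `w` (length M) and `b` (scalar).
#' @return Named list `y_prob`, `y_hat`.
#' @export
classify_bag <- function(z, head) {
  if (length(z) != length(head$w)) stop("head width mismatch", call. = FALSE)
  p <- 1 / (1 + exp(-(sum(z * head$w) + head$b)))
  list(y_prob = p, y_hat = as.integer(p >= 0.5))
}

#' Bag-level negative log-likelihood loss
#'
#' `loss = -(Y log p + (1 - Y) log(1 - p))` with the prediction clipped to
#' `[eps, 1 - eps]`. Non-negative, and zero (up to the clip) only for a
#' certain, correct prediction.
#'
#' @param y_true label in `{0, 1}`.
#' @param y_pred predicted probability of the positive class.
#' @param eps clipping constant (default 1e-7).
#' @return Scalar loss.
#' @export
bag_loss <- function(y_true, y_pred, eps = 1e-7) {
  if (!y_true %in% c(0, 1)) stop("'y_true' must be 0 or 1", call. = FALSE)
  p <- pmin(pmax(y_pred, eps), 1 - eps)
  -(y_true * log(p) + (1 - y_true) * log(1 - p))
}
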