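# shared fixtures built in code

small_params <- function(...) skull_params(side = 30, ...)

# a deterministic binary ball mask, used as an augmentation fixture
ball_volume <- function(side = 40, radius = side * 0.3) {
  g <- seq_len(side) - (side + 1) / 2
  r2 <- outer(outer(g^2, g^2, "+"), g^2, "+")
  out <- (r2 <= radius^2) * 1.0
  dim(out) <- c(side, side, side)
  out
}

# tiny random labelled bags for attention property tests
random_bag <- function(k = 5, patch_side = 6, seed = 1) {
  withr::with_seed(seed, {
    patches <- array((stats::runif(patch_side^3 * k) < 0.4) * 1.0,
                     c(patch_side, patch_side, patch_side, k))
    skullmil:::new_patch_bag(patches,
                             origins = matrix(1L, k, 3),
                             label = stats::rbinom(1, 1, 0.5))
  })
}

# random attention parameter set of given widths
random_attention <- function(m, l, gated = TRUE, seed = 1) {
  withr::with_seed(seed, attention_params(m, l, gated))
}

# independent loop-based oracle for the printed attention formulas
attention_oracle <- function(H, pars) {
  K <- nrow(H)
  scores <- numeric(K)
  for (k in seq_len(K)) {
    hk <- H[k, ]
    t_k <- tanh(as.numeric(pars$V %*% hk))
    if (isTRUE(pars$gated)) {
      g_k <- 1 / (1 + exp(-as.numeric(pars$U %*% hk)))
      scores[k] <- sum(pars$w * (t_k * g_k))
    } else {
      scores[k] <- sum(pars$w * t_k)
    }
  }
  exp(scores) / sum(exp(scores))
}
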