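# grid patching, encoder, attention pooling, loss, training loop

test_that("grid patching yields 27 patches at study and desk scale and round-trips", {
  v60 <- array((runif(60^3) < 0.2) * 1.0, c(60, 60, 60))
  b <- grid_patches(v60, 20)
  expect_equal(b$k, 27L)
  expect_identical(assemble_patches(b), v60)
  # single-patch degenerate bag
  v <- array(rnorm(8^3), c(8, 8, 8))
  b1 <- grid_patches(v, 8)
  expect_equal(b1$k, 1L)
  expect_equal(b1$patches[, , , 1], v)
  expect_error(grid_patches(v60, 25), "divisible")
})

test_that("the encoder is deterministic, shape-correct, and zero-preserving without bias", {
  for (ps in c(8, 12)) {
    for (m in c(8, 16)) {
      cfg <- encoder_config(ps, channels = c(4, 6), m = m)
      enc <- withr::with_seed(1, skullmil:::init_encoder(cfg))
      patches <- withr::with_seed(2, array(runif(ps^3 * 3), c(ps, ps, ps, 3)))
      H <- skullmil:::encoder_forward(patches, enc, cfg)$H
      expect_equal(dim(H), c(3L, m))
      expect_true(all(is.finite(H)))
    }
  }
  cfg <- encoder_config(10, channels = 4, m = 8)
  enc <- withr::with_seed(1, skullmil:::init_encoder(cfg))
  p2 <- withr::with_seed(3, array(runif(10^3 * 2), c(10, 10, 10, 2)))
  p2[, , , 2] <- p2[, , , 1]  # identical patches -> identical embeddings
  H <- skullmil:::encoder_forward(p2, enc, cfg)$H
  expect_equal(H[1, ], H[2, ])
  # all-zero patch through a bias-free encoder embeds to zero
  cfg0 <- encoder_config(10, channels = 4, m = 8, bias = FALSE)
  enc0 <- withr::with_seed(1, skullmil:::init_encoder(cfg0))
  Hz <- skullmil:::encoder_forward(array(0, c(10, 10, 10, 1)), enc0, cfg0)$H
  expect_true(all(Hz == 0))
})

test_that("convolution matches a brute-force sliding-window oracle", {
  set.seed(31)
  for (cse in list(list(s = 6, k = 3, st = 3), list(s = 5, k = 3, st = 2))) {
    s <- cse$s; K <- 2L; cin <- 2L; cout <- 3L
    x <- array(rnorm(s^3 * K * cin), c(s, s, s, K, cin))
    W <- matrix(rnorm(cse$k^3 * cin * cout), cse$k^3 * cin, cout)
    b <- rnorm(cout)
    got <- skullmil:::conv3d_forward(x, W, b, cse$k, cse$st)$y
    o <- (s - cse$k) %/% cse$st + 1
    want <- array(0, c(o, o, o, K, cout))
    for (co in 1:cout) for (k in 1:K) for (i in 1:o) for (j in 1:o) for (l in 1:o) {
      acc <- b[co]; col <- 1
      for (ci in 1:cin) for (dk in 1:cse$k) for (dj in 1:cse$k) for (di in 1:cse$k) {
        acc <- acc + x[(i - 1) * cse$st + di, (j - 1) * cse$st + dj,
                       (l - 1) * cse$st + dk, k, ci] * W[col, co]
        col <- col + 1
      }
      want[i, j, l, k, co] <- acc
    }
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("attention weights match the scalar oracle of the printed formulas", {
  pars <- list(V = matrix(1, 1, 1), U = matrix(1, 1, 1), w = 1, gated = FALSE)
  h <- matrix(c(1, 2), 2, 1)
  expect_equal(attention_weights(h, pars), c(0.450, 0.550), tolerance = 1e-3)
  pars$gated <- TRUE
  expect_equal(attention_weights(h, pars), c(0.427, 0.573), tolerance = 1e-3)
})

test_that("attention weights match an independent loop oracle for small L, M, K", {
  for (gated in c(TRUE, FALSE)) {
    for (trial in 1:10) {
      l <- sample(1:3, 1); m <- sample(1:3, 1); k <- sample(1:4, 1)
      pars <- random_attention(m, l, gated, seed = trial + gated * 100)
      H <- withr::with_seed(trial + 50, matrix(rnorm(k * m), k, m))
      expect_equal(attention_weights(H, pars), attention_oracle(H, pars),
                   tolerance = 1e-10)
    }
  }
})

test_that("attention weights are a positive, normalized, shift-invariant softmax", {
  pars <- random_attention(6, 10, gated = TRUE, seed = 2)
  for (trial in 1:20) {
    H <- withr::with_seed(trial, matrix(rnorm(7 * 6), 7, 6))
    a <- attention_weights(H, pars)
    expect_equal(sum(a), 1, tolerance = 1e-6)
    expect_true(all(a > 0))
  }
  # singleton bag and identical embeddings
  expect_equal(attention_weights(matrix(rnorm(6), 1, 6), pars), 1)
  H2 <- matrix(rep(rnorm(6), each = 2), 2, 6)
  expect_equal(attention_weights(H2, pars), c(0.5, 0.5))
})

test_that("gated weights converge to ungated weights as the gate saturates", {
  pars <- random_attention(4, 8, gated = TRUE, seed = 5)
  H <- withr::with_seed(9, matrix(abs(rnorm(5 * 4)) + 0.5, 5, 4))  # positive h
  ungated <- attention_weights(H, list(V = pars$V, w = pars$w, gated = FALSE))
  sat <- pars; sat$U <- pars$U * 0 + 1000  # gate pre-activation -> +Inf
  expect_equal(attention_weights(H, sat), ungated, tolerance = 1e-6)
})

test_that("attention pooling is the weighted sum with its invariants", {
  H <- rbind(c(1, 0), c(0, 1))
  expect_equal(attention_pool(H, c(0.25, 0.75)), c(0.25, 0.75))
  expect_equal(attention_pool(H, c(0.5, 0.5)), colMeans(H))
  expect_equal(attention_pool(matrix(c(3, 4), 1, 2), 1), c(3, 4))
  # permutation invariance of the (embedding, weight) pairs
  H3 <- matrix(rnorm(12), 4, 3); w3 <- c(0.1, 0.2, 0.3, 0.4)
  perm <- c(3, 1, 4, 2)
  expect_equal(attention_pool(H3, w3), attention_pool(H3[perm, ], w3[perm]))
  expect_error(attention_pool(H3, c(0.5, 0.5)), "weight")
})

test_that("the classification head is a logistic affine map", {
  expect_equal(classify_bag(c(0, 0), list(w = c(0, 0), b = 0))$y_prob, 0.5)
  expect_equal(classify_bag(1, list(w = 2, b = -2))$y_prob, 0.5)
  z <- c(0.3, -1.2, 0.8); head <- list(w = c(0.5, 1, -2), b = 0.25)
  expect_equal(classify_bag(z, head)$y_prob,
               1 / (1 + exp(-(sum(z * head$w) + head$b))))
  expect_equal(classify_bag(c(10, 10), list(w = c(5, 5), b = 0))$y_hat, 1L)
})

test_that("bag loss is the negated log likelihood with clipping", {
  expect_equal(bag_loss(1, 0.5), log(2), tolerance = 1e-12)
  expect_equal(bag_loss(0, 0.5), log(2), tolerance = 1e-12)
  expect_lt(bag_loss(1, 1 - 1e-9), 1e-6)
  expect_gte(bag_loss(0, 1), 0)          # clipped, finite
  expect_true(is.finite(bag_loss(1, 0)))
  expect_error(bag_loss(0.5, 0.5), "y_true")
})

test_that("early stopping halts after patience epochs without a new minimum", {
  expect_equal(early_stopping_epoch(rep(1, 10), 4), 5L)      # constant: patience + 1
  expect_true(is.na(early_stopping_epoch(seq(1, 0.1, length.out = 10), 4)))
  v <- c(1, 0.5, 0.6, 0.6, 0.6, 0.6, 0.6)
  expect_equal(early_stopping_epoch(v, 5), 7L)
  expect_true(is.na(early_stopping_epoch(c(1, 0.9, 0.8), 5)))
})

test_that("training is seeded-deterministic and the best model is kept", {
  bags <- lapply(1:8, function(i)
    make_signal_bag(3, 1 + (i %% 3), 0.9, seed = i, patch_side = 8,
                    label = i %% 2))
  cfg <- mil_config(max_epochs = 6, early_stop_patience = 5, seed = 4)
  enc <- encoder_config(8, channels = 4, m = 8)
  m1 <- mil_fit(bags[1:6], bags[7:8], config = cfg, encoder = enc)
  m2 <- mil_fit(bags[1:6], bags[7:8], config = cfg, encoder = enc)
  expect_identical(m1$history, m2$history)
  expect_equal(m1$best_epoch, which.min(m1$history$val_loss))
  expect_lte(nrow(m1$history), 6)
})

test_that("prediction is deterministic, permutation invariant, and matches the
           step-by-step composition oracle", {
  bag <- random_bag(k = 4, patch_side = 8, seed = 3)
  cfg <- mil_config(max_epochs = 2, early_stop_patience = 1, seed = 1)
  enc <- encoder_config(8, channels = 4, m = 8)
  bags <- lapply(1:6, function(i) random_bag(4, 8, seed = i))
  model <- mil_fit(bags[1:4], bags[5:6], config = cfg, encoder = enc)
  p1 <- predict(model, bag)
  p2 <- predict(model, bag)
  expect_identical(p1$y_prob, p2$y_prob)
  # patch permutation leaves the bag probability unchanged, weights permute
  perm <- c(4, 2, 1, 3)
  bag_p <- skullmil:::new_patch_bag(bag$patches[, , , perm],
                                    origins = bag$origins[perm, ],
                                    label = bag$label)
  pp <- predict(model, bag_p)
  expect_equal(pp$y_prob, p1$y_prob, tolerance = 1e-6)
  expect_equal(attr(pp, "attention")[, 1], attr(p1, "attention")[perm, 1],
               tolerance = 1e-10)
  # composition oracle: encode -> weights -> pool -> classify
  H <- encode_patches(bag, model)
  a <- attention_weights(H, model$params$att)
  z <- attention_pool(H, a)
  expect_equal(classify_bag(z, model$params$head)$y_prob, p1$y_prob,
               tolerance = 1e-12)
  expect_equal(a, attr(p1, "attention")[, 1], tolerance = 1e-12)
})

test_that("training learns single-signal bags and attention finds the signal patch", {
  r <- run_signal_experiment(n_bags = 80, k_patches = 5, patch_side = 10,
                             signal_strength = 0.9, seed = 11,
                             config = mil_config(max_epochs = 250,
                                                 early_stop_patience = 50,
                                                 seed = 11))
  expect_gte(r$accuracy, 0.85)
  expect_gte(r$localization_rate, 0.8)
})
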