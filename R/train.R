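#' Training configuration for the MIL model
#'
#' Defaults are the study's optimization settings: AdamW with learning rate
#' 1e-4 and weight decay 5e-4, dropout 0.3, at most 1000 epochs, one bag per
#' optimization step, and early stopping with patience 50 on the validation
#' loss.
#'
#' @param learning_rate AdamW step size (default 1e-4).
#' @param weight_decay decoupled weight decay (default 5e-4).
#' @param dropout_rate dropout on patch embeddings and the pooled vector
#'   during training (default 0.3).
#' @param max_epochs epoch cap (default 1000).
#' @param batch_size bags per optimization step; only 1 is supported.
#' @param early_stop_patience epochs without a new validation-loss minimum
#'   before stopping (default 50).
#' @param attention_width attention hidden width L (default 128).
#' @param gated use gated attention (default `TRUE`).
#' @param seed global seed governing initialization, shuffling, dropout and
#'   augmentation.
#' @return A list of class `mil_config`.
#' @export
mil_config <- function(learning_rate = 1e-4, weight_decay = 5e-4,
                       dropout_rate = 0.3, max_epochs = 1000, batch_size = 1,
                       early_stop_patience = 50, attention_width = 128,
                       gated = TRUE, seed = 1L) {
  if (learning_rate <= 0 || weight_decay < 0 || max_epochs <= 0 ||
      early_stop_patience <= 0) {
    stop("learning rate, epochs and patience must be positive", call. = FALSE)
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("'dropout_rate' must lie in [0, 1)", call. = FALSE)
  }
  if (batch_size != 1) stop("only batch_size = 1 (one bag per step) is supported",
                            call. = FALSE)
  if (early_stop_patience >= max_epochs) {
    stop("patience must be smaller than max_epochs", call. = FALSE)
  }
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 dropout_rate = dropout_rate, max_epochs = as.integer(max_epochs),
                 batch_size = 1L,
                 early_stop_patience = as.integer(early_stop_patience),
                 attention_width = as.integer(attention_width),
                 gated = isTRUE(gated), seed = as.integer(seed)),
            class = "mil_config")
}

#' Epoch at which early stopping halts training
#'
#' Training stops after the first epoch `t` such that the running minimum of
#' the validation loss (strict improvement) was last updated at epoch
#' `t - patience`. A constant validation-loss sequence therefore stops at
#' epoch `patience + 1`.
#'
#' @param val_losses numeric vector of per-epoch validation losses.
#' @param patience patience in epochs.
#' @return The stopping epoch, or `NA` if the sequence never triggers the
#'   rule.
#' @export
early_stopping_epoch <- function(val_losses, patience) {
  best <- Inf; best_t <- 0L
  for (t in seq_along(val_losses)) {
    if (val_losses[t] < best) {
      best <- val_losses[t]; best_t <- t
    } else if (t - best_t >= patience) {
      return(t)
    }
  }
  NA_integer_
}

# ---- full-model forward/backward on one bag ----------------------------------

model_forward <- function(patches, params, cfg_enc, training = FALSE,
                          dropout_rate = 0, ic1 = NULL) {
  ef <- encoder_forward(patches, params$enc, cfg_enc, ic1 = ic1)
  H <- ef$H
  mask_H <- NULL; mask_z <- NULL
  if (training && dropout_rate > 0) {
    mask_H <- matrix((stats::runif(length(H)) >= dropout_rate) /
                       (1 - dropout_rate), nrow(H), ncol(H))
    H <- H * mask_H
  }
  af <- attention_forward(H, params$att)
  a <- af$a
  z <- attention_pool(H, a)
  zd <- z
  if (training && dropout_rate > 0) {
    mask_z <- (stats::runif(length(z)) >= dropout_rate) / (1 - dropout_rate)
    zd <- z * mask_z
  }
  cls <- classify_bag(zd, params$head)
  list(y_prob = cls$y_prob, y_hat = cls$y_hat, a = a, z = z,
       cache = list(ef = ef, af = af, H = H, zd = zd,
                    mask_H = mask_H, mask_z = mask_z))
}

model_backward <- function(y_true, fwd, params, cfg_enc) {
  cc <- fwd$cache
  p <- fwd$y_prob
  dlogit <- p - y_true                       # d loss / d (w'z + b)
  dw_head <- dlogit * cc$zd
  db_head <- dlogit
  dzd <- dlogit * params$head$w
  dz <- if (is.null(cc$mask_z)) dzd else dzd * cc$mask_z
  # z = sum_k a_k H_k
  H <- cc$H; a <- fwd$a
  dH <- outer(a, dz)
  da <- as.numeric(H %*% dz)
  ab <- attention_backward(da, params$att, c(cc$af, list(a = a)))
  dH <- dH + ab$dH
  if (!is.null(cc$mask_H)) dH <- dH * cc$mask_H
  genc <- encoder_backward(dH, params$enc, cfg_enc, cc$ef$cache)
  list(enc = genc,
       att = list(V = ab$dV, U = ab$dU, w = ab$dw, gated = NULL),
       head = list(w = dw_head, b = db_head))
}

# ---- AdamW on a nested parameter list ----------------------------------------

adamw_state <- function(params) {
  walk <- function(x) {
    if (is.numeric(x)) list(m = x * 0, v = x * 0)
    else if (is.list(x)) lapply(x, walk)
    else NULL
  }
  walk(params)
}

adamw_step <- function(params, grads, state, lr, wd, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, s) {
    if (is.numeric(p)) {
      if (is.null(g)) return(list(p = p, s = s))
      s$m <- beta1 * s$m + (1 - beta1) * g
      s$v <- beta2 * s$v + (1 - beta2) * g^2
      mhat <- s$m / (1 - beta1^t)
      vhat <- s$v / (1 - beta2^t)
      p <- p - lr * (mhat / (sqrt(vhat) + eps) + wd * p)  # decoupled decay
      list(p = p, s = s)
    } else if (is.list(p)) {
      out_p <- p; out_s <- s
      for (nm in seq_along(p)) {
        r <- walk(p[[nm]], if (is.list(g)) g[[nm]] else NULL, s[[nm]])
        if (!is.null(r)) { out_p[[nm]] <- r$p; out_s[[nm]] <- r$s }
      }
      list(p = out_p, s = out_s)
    } else NULL
  }
  walk(params, grads, state)
}

# ---- fitting ------------------------------------------------------------------

#' Fit the gated attention MIL sex classifier
#'
#' Trains the patch encoder, attention scorer and classification head end to
#' end on labelled bags with AdamW (one bag per step), computing the
#' validation loss after every epoch and stopping when it has not reached a
#' new minimum for `early_stop_patience` consecutive epochs. The returned
#' model carries the parameters of the epoch with minimal validation loss.
#'
#' @param train_bags list of `patch_bag`s with `label` set (female = 1).
#' @param val_bags list of labelled validation bags.
#' @param config a [mil_config].
#' @param encoder an [encoder_config]; defaults to the reference encoder for
#'   the training bags' patch side.
#' @param augment optional [augmentation_config]; when supplied, each
#'   training volume is re-augmented on the fly every epoch before tiling.
#'   Requires `train_volumes`.
#' @param train_volumes optional list of source volumes (arrays or
#'   [volume_image]s) aligned with `train_bags`, used only when `augment` is
#'   given.
#' @param verbose print a line per 25 epochs (default `FALSE`).
#' @return An object of class `mil_model`: `params`, `config`, `encoder`,
#'   `history` (data.frame `epoch`, `train_loss`, `val_loss`), `best_epoch`,
#'   `stopped_epoch`.
#' @export
mil_fit <- function(train_bags, val_bags, config = mil_config(),
                    encoder = NULL, augment = NULL, train_volumes = NULL,
                    verbose = FALSE) {
  if (length(train_bags) == 0L || length(val_bags) == 0L) {
    stop("training and validation sets must be non-empty", call. = FALSE)
  }
  labels <- vapply(train_bags, function(b) b$label %||% NA_integer_, numeric(1))
  if (any(is.na(labels))) stop("every training bag needs a label", call. = FALSE)
  if (!is.null(augment) && is.null(train_volumes)) {
    stop("'augment' requires 'train_volumes'", call. = FALSE)
  }
  ps <- train_bags[[1]]$patch_side
  encoder <- encoder %||% encoder_config(ps)
  set.seed(config$seed)
  params <- list(enc = init_encoder(encoder),
                 att = attention_params(encoder$m, config$attention_width,
                                        config$gated),
                 head = list(w = stats::runif(encoder$m, -1 / sqrt(encoder$m),
                                              1 / sqrt(encoder$m)),
                             b = 0))
  state <- adamw_state(params)
  n <- length(train_bags)
  # when bags are fixed across epochs, the input-layer im2col is bag-constant
  static_bags <- is.null(augment)
  ic_train <- if (static_bags) {
    lapply(train_bags, function(b) precompute_input_cols(b$patches, encoder))
  } else NULL
  ic_val <- lapply(val_bags, function(b) precompute_input_cols(b$patches, encoder))
  hist_train <- hist_val <- numeric(0)
  best_params <- params; best_epoch <- 0L; step_t <- 0
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    tl <- 0
    for (i in ord) {
      bag <- train_bags[[i]]
      if (!is.null(augment)) {
        v <- augment_volume(train_volumes[[i]], augment)
        bag <- grid_patches(v, ps, label = bag$label)
      }
      fwd <- model_forward(if (static_bags) NULL else bag$patches, params,
                           encoder, training = TRUE,
                           dropout_rate = config$dropout_rate,
                           ic1 = if (static_bags) ic_train[[i]] else NULL)
      loss <- bag_loss(bag$label, fwd$y_prob)
      if (!is.finite(loss)) {
        stop(sprintf("training diverged (non-finite loss at epoch %d)", epoch),
             call. = FALSE)
      }
      tl <- tl + loss
      grads <- model_backward(bag$label, fwd, params, encoder)
      step_t <- step_t + 1
      upd <- adamw_step(params, grads, state, config$learning_rate,
                        config$weight_decay, step_t)
      params <- upd$p; state <- upd$s
    }
    vl <- mean(vapply(seq_along(val_bags), function(j) {
      bag_loss(val_bags[[j]]$label,
               model_forward(NULL, params, encoder, ic1 = ic_val[[j]])$y_prob)
    }, numeric(1)))
    hist_train <- c(hist_train, tl / n)
    hist_val <- c(hist_val, vl)
    if (best_epoch == 0L || vl < hist_val[best_epoch]) {
      best_params <- params; best_epoch <- epoch
    }
    if (verbose && epoch %% 25 == 0) {
      message(sprintf("epoch %d  train %.4f  val %.4f", epoch,
                      tl / n, vl))
    }
    st <- early_stopping_epoch(hist_val, config$early_stop_patience)
    if (!is.na(st) && st == epoch) break
  }
  structure(list(params = best_params, config = config, encoder = encoder,
                 history = data.frame(epoch = seq_along(hist_val),
                                      train_loss = hist_train,
                                      val_loss = hist_val),
                 best_epoch = best_epoch,
                 stopped_epoch = length(hist_val)),
            class = "mil_model")
}

#' @export
print.mil_model <- function(x, ...) {
  cat("Gated attention MIL sex classifier\n")
  cat(sprintf("  encoder: %d conv block(s), patch %d^3, M = %d, L = %d (%s attention)\n",
              length(x$encoder$channels), x$encoder$patch_side, x$encoder$m,
              x$config$attention_width,
              if (x$config$gated) "gated" else "ungated"))
  cat(sprintf("  trained %d epoch(s); best validation loss %.4f at epoch %d\n",
              x$stopped_epoch, min(x$history$val_loss), x$best_epoch))
  invisible(x)
}

#' @export
summary.mil_model <- function(object, ...) {
  npar <- sum(rapply(object$params, length, how = "unlist"))
  out <- list(n_parameters = npar, best_epoch = object$best_epoch,
              stopped_epoch = object$stopped_epoch,
              best_val_loss = min(object$history$val_loss),
              config = object$config)
  class(out) <- "summary.mil_model"
  out
}

#' @export
print.summary.mil_model <- function(x, ...) {
  cat(sprintf("MIL model: %d trainable parameters\n", x$n_parameters))
  cat(sprintf("  stopped at epoch %d (best epoch %d, val loss %.4f)\n",
              x$stopped_epoch, x$best_epoch, x$best_val_loss))
  cat(sprintf("  AdamW lr %.2g, weight decay %.2g, dropout %.2g, patience %d\n",
              x$config$learning_rate, x$config$weight_decay,
              x$config$dropout_rate, x$config$early_stop_patience))
  invisible(x)
}

#' @export
coef.mil_model <- function(object, ...) object$params

#' Predict bags with a fitted MIL model
#'
#' Evaluation mode (dropout off), so predictions are deterministic. Each bag
#' yields a predicted female probability, a hard label at the 0.5 threshold,
#' and the per-patch attention weights for interpretation.
#'
#' @param object a fitted `mil_model`.
#' @param newdata a `patch_bag` or list of bags.
#' @param ... unused.
#' @return A data.frame with one row per bag (`y_prob`, `y_hat`, plus the
#'   true `label` when present) carrying the attention weights as the
#'   `"attention"` attribute (K x n matrix, one column per bag).
#' @export
predict.mil_model <- function(object, newdata, ...) {
  bags <- if (inherits(newdata, "patch_bag")) list(newdata) else newdata
  res <- lapply(bags, function(b) {
    model_forward(b$patches, object$params, object$encoder)
  })
  out <- data.frame(
    y_prob = vapply(res, `[[`, numeric(1), "y_prob"),
    y_hat = vapply(res, `[[`, integer(1), "y_hat"))
  labs <- vapply(bags, function(b) b$label %||% NA_real_, numeric(1))
  if (!all(is.na(labs))) out$label <- labs
  attr(out, "attention") <- vapply(res, `[[`, numeric(bags[[1]]$k), "a")
  out
}

#' @export
plot.mil_model <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("steelblue", "darkorange"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::abline(v = x$best_epoch, lty = 3, col = "grey40")
  graphics::legend("topright", c("training", "validation"), lty = 1,
                   col = c("steelblue", "darkorange"), bty = "n")
  invisible(x)
}
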