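# Training of the sequence classifiers: stacked (Phased-)LSTM layers, a
# softmax output head, loss (MSE on the softmax output by default, as the
# reference setup uses; cross-entropy available), gradients by full
# backpropagation through time, Adam or plain SGD updates.

#' Sequence-classifier configuration
#'
#' @param cell `"phased_lstm"` or `"lstm"`.
#' @param input_size input feature count; `NULL` infers it from the training
#'   sequences.
#' @param hidden_size hidden units per layer (the reference architecture uses
#'   310; desk-scale runs use 8-16).
#' @param layers number of stacked recurrent layers.
#' @param loss `"mse"` (squared error between the softmax output and the
#'   one-hot label) or `"cross_entropy"`.
#' @param epochs training epochs.
#' @param lr learning rate.
#' @param batch_size mini-batch size.
#' @param optimizer `"adam"` or `"sgd"`.
#' @param r_on,leak time-gate open ratio and leak (Phased-LSTM only).
#' @param horizon upper end of the gate-period initialisation (hours).
#' @param train_gates should the gate periods/shifts be learned?
#' @param seed integer seed governing initialisation and batch order.
#' @return object of class `model_config`.
#' @export
model_config <- function(cell = c("phased_lstm", "lstm"), input_size = NULL,
                         hidden_size = 310, layers = 2,
                         loss = c("mse", "cross_entropy"), epochs = 100,
                         lr = 0.01, batch_size = 64,
                         optimizer = c("adam", "sgd"), r_on = 0.1,
                         leak = 0.001, horizon = 72, train_gates = TRUE,
                         seed = 1) {
  cell <- match.arg(cell); loss <- match.arg(loss)
  optimizer <- match.arg(optimizer)
  stopifnot(hidden_size >= 1, layers >= 1, epochs >= 0, batch_size >= 1)
  structure(list(cell = cell, input_size = input_size,
                 hidden_size = as.integer(hidden_size),
                 layers = as.integer(layers), n_classes = 2L, loss = loss,
                 epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size), optimizer = optimizer,
                 r_on = r_on, leak = leak, horizon = horizon,
                 train_gates = isTRUE(train_gates), seed = as.integer(seed)),
            class = "model_config")
}

init_model <- function(config) {
  H <- config$hidden_size
  layers <- vector("list", config$layers)
  for (l in seq_len(config$layers)) {
    in_l <- if (l == 1) config$input_size else H
    layers[[l]] <- list(
      params = lstm_params(in_l, H, seed = derive_seed(config$seed,
                                                       paste0("layer", l))),
      gate = if (config$cell == "phased_lstm") {
        phased_gate_params(H, horizon = config$horizon, r_on = config$r_on,
                           leak = config$leak,
                           seed = derive_seed(config$seed, paste0("gate", l)))
      })
  }
  with_seed(derive_seed(config$seed, "head"), {
    g <- sqrt(6 / (H + config$n_classes))
    structure(list(config = config, layers = layers,
                   W_out = matrix(stats::runif(H * config$n_classes, -g, g),
                                  H, config$n_classes),
                   b_out = rep(0, config$n_classes), scaler = NULL),
              class = "risk_model")
  })
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("%s classifier: %d x %d hidden, input %d, loss %s%s\n",
              x$config$cell, x$config$layers, x$config$hidden_size,
              x$config$input_size, x$config$loss,
              if (!is.null(x$trace)) sprintf(", trained %d epochs",
                                             length(x$trace$train_loss)) else ""))
  invisible(x)
}

slice_step <- function(X, t) matrix(X[, t, ], nrow = dim(X)[1])

# Batched multi-layer forward pass. Padded steps enter as k = 0 so the state
# is carried through unchanged; the final h therefore equals the h at each
# sequence's last valid event. Returns softmax probabilities and, if
# requested, the per-step caches BPTT needs.
forward_batch <- function(model, X, Tm, Mk, cache = FALSE,
                          force_open_gates = FALSE) {
  cfg <- model$config
  B <- dim(X)[1]; L <- dim(X)[2]; H <- cfg$hidden_size
  caches <- if (cache) vector("list", length(model$layers))
  Hseq <- NULL
  for (l in seq_along(model$layers)) {
    par <- model$layers[[l]]$params
    gate <- model$layers[[l]]$gate
    Hc <- matrix(0, B, H); Cc <- matrix(0, B, H)
    Hout <- vector("list", L)
    step_cache <- if (cache) vector("list", L)
    for (t in seq_len(L)) {
      Xt <- if (l == 1) slice_step(X, t) else Hseq[[t]]
      g <- lstm_gates(Xt, Hc, Cc, par)
      m <- Mk[, t]
      if (!is.null(gate) && !force_open_gates) {
        tvec <- Tm[, t]
        diff_t <- outer(tvec, gate$s, "-")
        phi <- (diff_t %% matrix(gate$tau, B, H, byrow = TRUE)) /
          matrix(gate$tau, B, H, byrow = TRUE)
        kraw <- matrix(time_gate_openness(phi, gate$r_on, gate$leak), B, H)
        k <- kraw * m
      } else {
        phi <- NULL; kraw <- NULL; diff_t <- NULL
        k <- matrix(m, B, H)
      }
      Hn <- k * g$h_star + (1 - k) * Hc
      Cn <- k * g$c_star + (1 - k) * Cc
      if (cache) {
        step_cache[[t]] <- list(Xt = Xt, Hprev = Hc, Cprev = Cc, g = g, k = k,
                                phi = phi, diff_t = diff_t, m = m)
      }
      Hc <- Hn; Cc <- Cn
      Hout[[t]] <- Hn
    }
    if (cache) caches[[l]] <- step_cache
    Hseq <- Hout
  }
  logits <- Hc %*% model$W_out + matrix(model$b_out, B, cfg$n_classes,
                                        byrow = TRUE)
  probs <- softmax_output(logits)
  list(probs = matrix(probs, B), h_final = Hc, caches = caches)
}

# loss and dL/dlogits for one batch; y in {0,1}, class 2 = death
loss_and_dlogits <- function(probs, y, loss) {
  B <- nrow(probs)
  Y <- cbind(1 - y, y)
  if (loss == "mse") {
    val <- mean(rowSums((probs - Y)^2))
    dP <- 2 * (probs - Y) / B
    dZ <- probs * (dP - rowSums(dP * probs))
  } else {
    p_true <- probs[cbind(seq_len(B), y + 1L)]
    val <- -mean(log(pmax(p_true, 1e-12)))
    dZ <- (probs - Y) / B
  }
  list(value = val, dlogits = dZ)
}

# Full BPTT for one batch. Returns loss value and gradients in a flat named
# list matching collect_params().
backward_batch <- function(model, X, Tm, Mk, y) {
  cfg <- model$config
  fw <- forward_batch(model, X, Tm, Mk, cache = TRUE)
  lo <- loss_and_dlogits(fw$probs, y, cfg$loss)
  B <- dim(X)[1]; L <- dim(X)[2]; H <- cfg$hidden_size
  grads <- list(W_out = crossprod(fw$h_final, lo$dlogits),
                b_out = colSums(lo$dlogits))
  inject <- vector("list", L)
  inject[[L]] <- lo$dlogits %*% t(model$W_out)
  zero <- matrix(0, B, H)
  for (l in rev(seq_along(model$layers))) {
    par <- model$layers[[l]]$params
    gate <- model$layers[[l]]$gate
    sc <- fw$caches[[l]]
    dWx <- matrix(0, nrow(par$W_x), 4 * H); dWh <- matrix(0, H, 4 * H)
    db <- rep(0, 4 * H)
    dwci <- rep(0, H); dwcf <- rep(0, H); dwco <- rep(0, H)
    dltau <- rep(0, H); ds <- rep(0, H)
    inject_below <- if (l > 1) vector("list", L)
    dH <- zero; dC <- zero
    for (t in rev(seq_len(L))) {
      st <- sc[[t]]
      if (!is.null(inject[[t]])) dH <- dH + inject[[t]]
      g <- st$g; k <- st$k
      dh_star <- dH * k
      dHprev <- dH * (1 - k)
      dCprev <- dC * (1 - k)
      dk <- dH * (g$h_star - st$Hprev) + dC * (g$c_star - st$Cprev)
      do <- dh_star * g$tc
      dc_star <- dC * k + dh_star * g$o * (1 - g$tc^2)
      df <- dc_star * st$Cprev
      di <- dc_star * g$g
      dgc <- dc_star * g$i
      dCprev <- dCprev + dc_star * g$f
      dz_i <- di * g$i * (1 - g$i)
      dz_f <- df * g$f * (1 - g$f)
      dz_g <- dgc * (1 - g$g^2)
      dz_o <- do * g$o * (1 - g$o)
      dCprev <- dCprev + t(t(dz_i) * par$w_ci) + t(t(dz_f) * par$w_cf) +
        t(t(dz_o) * par$w_co)
      dwci <- dwci + colSums(dz_i * st$Cprev)
      dwcf <- dwcf + colSums(dz_f * st$Cprev)
      dwco <- dwco + colSums(dz_o * st$Cprev)
      dZ <- cbind(dz_i, dz_f, dz_g, dz_o)
      dWx <- dWx + crossprod(st$Xt, dZ)
      dWh <- dWh + crossprod(st$Hprev, dZ)
      db <- db + colSums(dZ)
      dHprev <- dHprev + dZ %*% t(par$W_h)
      if (l > 1) inject_below[[t]] <- dZ %*% t(par$W_x)
      if (!is.null(gate) && cfg$train_gates && !is.null(st$phi)) {
        dkraw <- dk * st$m                       # k = kraw * mask
        dphi <- dkraw * time_gate_dk_dphi(st$phi, gate$r_on, gate$leak)
        tau_row <- matrix(gate$tau, B, H, byrow = TRUE)
        # phi = ((t - s) mod tau)/tau:
        #   d phi / d log(tau) = -(t - s)/tau ; d phi / d s = -1/tau
        dltau <- dltau + colSums(dphi * (-st$diff_t / tau_row))
        ds <- ds + colSums(dphi * (-1 / tau_row))
      }
      dH <- dHprev; dC <- dCprev
    }
    pre <- paste0("l", l, "_")
    grads[[paste0(pre, "W_x")]] <- dWx
    grads[[paste0(pre, "W_h")]] <- dWh
    grads[[paste0(pre, "b")]] <- db
    grads[[paste0(pre, "w_ci")]] <- dwci
    grads[[paste0(pre, "w_cf")]] <- dwcf
    grads[[paste0(pre, "w_co")]] <- dwco
    if (!is.null(gate) && cfg$train_gates) {
      grads[[paste0(pre, "log_tau")]] <- dltau
      grads[[paste0(pre, "s")]] <- ds
    }
    if (l > 1) inject <- inject_below
  }
  list(value = lo$value, grads = grads, probs = fw$probs)
}

# flat named parameter list <-> model
collect_params <- function(model) {
  out <- list(W_out = model$W_out, b_out = model$b_out)
  for (l in seq_along(model$layers)) {
    par <- model$layers[[l]]$params
    pre <- paste0("l", l, "_")
    out[[paste0(pre, "W_x")]] <- par$W_x
    out[[paste0(pre, "W_h")]] <- par$W_h
    out[[paste0(pre, "b")]] <- par$b
    out[[paste0(pre, "w_ci")]] <- par$w_ci
    out[[paste0(pre, "w_cf")]] <- par$w_cf
    out[[paste0(pre, "w_co")]] <- par$w_co
    gate <- model$layers[[l]]$gate
    if (!is.null(gate) && model$config$train_gates) {
      out[[paste0(pre, "log_tau")]] <- log(gate$tau)
      out[[paste0(pre, "s")]] <- gate$s
    }
  }
  out
}

apply_params <- function(model, flat) {
  model$W_out <- flat$W_out; model$b_out <- flat$b_out
  for (l in seq_along(model$layers)) {
    pre <- paste0("l", l, "_")
    for (nm in c("W_x", "W_h", "b", "w_ci", "w_cf", "w_co")) {
      model$layers[[l]]$params[[nm]] <- flat[[paste0(pre, nm)]]
    }
    if (!is.null(model$layers[[l]]$gate) && model$config$train_gates) {
      model$layers[[l]]$gate$tau <- exp(flat[[paste0(pre, "log_tau")]])
      model$layers[[l]]$gate$s <- flat[[paste0(pre, "s")]]
    }
  }
  model
}

adam_state <- function(flat) list(m = lapply(flat, function(p) p * 0),
                                  v = lapply(flat, function(p) p * 0),
                                  t = 0)

adam_update <- function(flat, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    flat[[nm]] <- flat[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(flat = flat, state = state)
}

fit_scaler <- function(X, Mk) {
  D <- dim(X)[3]
  mu <- numeric(D); sd_ <- numeric(D)
  valid <- Mk == 1
  for (d in seq_len(D)) {
    v <- X[, , d][valid]
    mu[d] <- mean(v)
    sd_[d] <- stats::sd(v)
    if (!is.finite(sd_[d]) || sd_[d] < 1e-8) sd_[d] <- 1
  }
  list(mu = mu, sd = sd_)
}

apply_scaler <- function(X, Mk, scaler) {
  for (d in seq_len(dim(X)[3])) {
    X[, , d] <- (X[, , d] - scaler$mu[d]) / scaler$sd[d] * Mk
  }
  X
}

#' Train a mortality-risk sequence classifier
#'
#' Mini-batch gradient training (BPTT through every valid step) of a stacked
#' LSTM or Phased-LSTM on fixed-length event-vector sequences. Features are
#' standardised with statistics of the training split (stored in the model
#' and reapplied at prediction time); event times stay in hours so the gate
#' periods keep physical units. Deterministic given `config$seed`.
#'
#' When a validation split is supplied, the returned model carries the
#' weights of the epoch with the lowest validation loss (standard
#' early-stopping-style model selection; disable with `keep_best = FALSE` to
#' keep the final-epoch weights).
#'
#' @param train_seqs an [assemble_event_vectors()] object (training split).
#' @param val_seqs optional validation split, evaluated once per epoch.
#' @param config a [model_config()].
#' @param keep_best return the best-validation-epoch weights (needs
#'   `val_seqs`).
#' @return a trained `risk_model` whose `trace` holds per-epoch training and
#'   validation loss plus the selected epoch.
#' @export
train_classifier <- function(train_seqs, val_seqs = NULL,
                             config = model_config(), keep_best = TRUE) {
  stopifnot(inherits(train_seqs, "event_sequences"),
            inherits(config, "model_config"))
  n <- dim(train_seqs$x)[1]
  if (n == 0) stopf("empty training set")
  if (is.null(config$input_size)) config$input_size <- dim(train_seqs$x)[3]
  if (config$input_size != dim(train_seqs$x)[3]) {
    stopf("input_size (%d) does not match sequence features (%d)",
          config$input_size, dim(train_seqs$x)[3])
  }
  model <- init_model(config)
  model$scaler <- fit_scaler(train_seqs$x, train_seqs$mask)
  model$feature_names <- train_seqs$feature_names
  Xtr <- apply_scaler(train_seqs$x, train_seqs$mask, model$scaler)
  ytr <- train_seqs$labels
  if (!is.null(val_seqs)) {
    Xv <- apply_scaler(val_seqs$x, val_seqs$mask, model$scaler)
  }
  flat <- collect_params(model)
  opt <- if (config$optimizer == "adam") adam_state(flat)
  train_loss <- numeric(config$epochs); val_loss <- numeric(config$epochs)
  best <- list(loss = Inf, flat = NULL, epoch = 0L)
  with_seed(derive_seed(config$seed, "train"), {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- 0
      for (bidx in batches) {
        bw <- backward_batch(model,
                             Xtr[bidx, , , drop = FALSE],
                             train_seqs$times[bidx, , drop = FALSE],
                             train_seqs$mask[bidx, , drop = FALSE],
                             ytr[bidx])
        if (!is.finite(bw$value)) {
          stopf("non-finite training loss at epoch %d (lr too high?)", ep)
        }
        if (config$lr > 0) {
          if (config$optimizer == "adam") {
            upd <- adam_update(flat, bw$grads, opt, config$lr)
            flat <- upd$flat; opt <- upd$state
          } else {
            for (nm in names(bw$grads)) {
              flat[[nm]] <- flat[[nm]] - config$lr * bw$grads[[nm]]
            }
          }
          model <- apply_params(model, flat)
        }
        ep_loss <- ep_loss + bw$value * length(bidx)
      }
      train_loss[ep] <- ep_loss / n
      if (!is.null(val_seqs)) {
        fv <- forward_batch(model, Xv, val_seqs$times, val_seqs$mask)
        val_loss[ep] <- loss_and_dlogits(fv$probs, val_seqs$labels,
                                         config$loss)$value
        if (keep_best && val_loss[ep] < best$loss) {
          best <- list(loss = val_loss[ep], flat = flat, epoch = ep)
        }
      }
    }
  })
  if (keep_best && !is.null(best$flat)) model <- apply_params(model, best$flat)
  model$trace <- list(train_loss = train_loss,
                      val_loss = if (!is.null(val_seqs)) val_loss,
                      selected_epoch = if (keep_best && !is.null(val_seqs))
                        best$epoch else config$epochs)
  model
}

#' Classify event sequences with a trained model
#'
#' Runs the forward pass per patient and returns the class probabilities
#' `[p(survival), p(death)]` and the predicted label (death iff
#' `p(death) > p(survival)`; ties go to survival).
#'
#' @param model a trained `risk_model` (or an untrained [init_model] result
#'   with a scaler attached).
#' @param sequences an [assemble_event_vectors()] object.
#' @param force_open_gates test hook: force every time gate fully open, which
#'   reduces a Phased-LSTM to the plain LSTM on the same weights.
#' @return data.frame of class `prediction_result` with columns `patient_id`,
#'   `p_survival`, `p_death`, `predicted`, `label` (if available).
#' @export
forward_sequence <- function(model, sequences, force_open_gates = FALSE) {
  stopifnot(inherits(model, "risk_model"),
            inherits(sequences, "event_sequences"))
  if (any(rowSums(sequences$mask) == 0)) {
    stopf("sequence(s) with empty validity mask (no valid events)")
  }
  X <- if (!is.null(model$scaler)) {
    apply_scaler(sequences$x, sequences$mask, model$scaler)
  } else sequences$x
  fw <- forward_batch(model, X, sequences$times, sequences$mask,
                      force_open_gates = force_open_gates)
  out <- data.frame(patient_id = sequences$patient_id,
                    p_survival = fw$probs[, 1], p_death = fw$probs[, 2],
                    predicted = as.integer(fw$probs[, 2] > fw$probs[, 1]))
  if (!is.null(sequences$labels)) out$label <- sequences$labels
  class(out) <- c("prediction_result", "data.frame")
  out
}
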