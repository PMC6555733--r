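# Recurrent estimator for fixed four-second windows: a stack of two LSTM
# layers (hidden size 64) over the 250-step block-averaged input, followed by
# a fully connected scalar head reading the final hidden state.  Training
# minimizes mean-squared error; reported evaluation uses mean absolute error.
# Implemented directly with batched matrix operations and backpropagation
# through time.

sigmoid <- function(x) 1 / (1 + exp(-x))

lstm_init <- function(input_size, hidden, n_layers) {
  params <- list()
  for (l in seq_len(n_layers)) {
    ins <- if (l == 1L) input_size else hidden
    k <- 1 / sqrt(hidden)
    params[[paste0("Wx", l)]] <- matrix(runif(ins * 4 * hidden, -k, k), ins, 4 * hidden)
    params[[paste0("Wh", l)]] <- matrix(runif(hidden * 4 * hidden, -k, k), hidden, 4 * hidden)
    b <- rep(0, 4 * hidden)
    b[(hidden + 1L):(2L * hidden)] <- 1   # forget-gate bias
    params[[paste0("b", l)]] <- b
  }
  params$W_out <- matrix(runif(hidden, -1 / sqrt(hidden), 1 / sqrt(hidden)), hidden, 1)
  params$b_out <- 0
  params
}

# xs: list over time of (m x C) matrices
lstm_forward <- function(params, xs, hidden, n_layers, keep_cache = FALSE) {
  T_len <- length(xs)
  m <- nrow(xs[[1L]])
  cache <- if (keep_cache) vector("list", n_layers)
  input_seq <- xs
  for (l in seq_len(n_layers)) {
    Wx <- params[[paste0("Wx", l)]]
    Wh <- params[[paste0("Wh", l)]]
    b <- params[[paste0("b", l)]]
    h <- matrix(0, m, hidden)
    cc <- matrix(0, m, hidden)
    hs <- vector("list", T_len)
    lc <- if (keep_cache) vector("list", T_len)
    idx_i <- 1:hidden; idx_f <- hidden + idx_i
    idx_g <- 2L * hidden + idx_i; idx_o <- 3L * hidden + idx_i
    for (t in seq_len(T_len)) {
      z <- sweep(input_seq[[t]] %*% Wx + h %*% Wh, 2L, b, "+")
      gi <- sigmoid(z[, idx_i, drop = FALSE])
      gf <- sigmoid(z[, idx_f, drop = FALSE])
      gg <- tanh(z[, idx_g, drop = FALSE])
      go <- sigmoid(z[, idx_o, drop = FALSE])
      c_prev <- cc
      cc <- gf * c_prev + gi * gg
      tc <- tanh(cc)
      h_prev <- h
      h <- go * tc
      hs[[t]] <- h
      if (keep_cache)
        lc[[t]] <- list(i = gi, f = gf, g = gg, o = go, c = cc,
                        c_prev = c_prev, h_prev = h_prev, tc = tc,
                        x = input_seq[[t]])
    }
    if (keep_cache) cache[[l]] <- lc
    input_seq <- hs
  }
  h_last <- input_seq[[T_len]]
  yhat <- as.numeric(h_last %*% params$W_out + params$b_out)
  list(yhat = yhat, h_last = h_last, cache = cache, top_seq = input_seq)
}

lstm_backward <- function(params, fwd, dy, hidden, n_layers, T_len, l2) {
  m <- length(dy)
  grads <- list()
  grads$W_out <- crossprod(fwd$h_last, matrix(dy, ncol = 1L)) + l2 * params$W_out
  grads$b_out <- sum(dy)
  # gradient flowing into each layer's output sequence
  dseq <- vector("list", T_len)
  for (t in seq_len(T_len)) dseq[[t]] <- matrix(0, m, hidden)
  dseq[[T_len]] <- matrix(dy, ncol = 1L) %*% t(params$W_out)

  for (l in rev(seq_len(n_layers))) {
    Wx <- params[[paste0("Wx", l)]]
    Wh <- params[[paste0("Wh", l)]]
    lc <- fwd$cache[[l]]
    dWx <- Wx * 0; dWh <- Wh * 0; db <- rep(0, 4L * hidden)
    dh_next <- matrix(0, m, hidden)
    dc_next <- matrix(0, m, hidden)
    dx_seq <- if (l > 1L) vector("list", T_len)
    for (t in rev(seq_len(T_len))) {
      s <- lc[[t]]
      dh <- dseq[[t]] + dh_next
      dc <- dc_next + dh * s$o * (1 - s$tc^2)
      do_ <- dh * s$tc
      di <- dc * s$g
      dg <- dc * s$i
      df <- dc * s$c_prev
      dc_next <- dc * s$f
      dz <- cbind(di * s$i * (1 - s$i),
                  df * s$f * (1 - s$f),
                  dg * (1 - s$g^2),
                  do_ * s$o * (1 - s$o))
      dWx <- dWx + crossprod(s$x, dz)
      dWh <- dWh + crossprod(s$h_prev, dz)
      db <- db + colSums(dz)
      dh_next <- dz %*% t(Wh)
      if (l > 1L) dx_seq[[t]] <- dz %*% t(Wx)
    }
    grads[[paste0("Wx", l)]] <- dWx + l2 * Wx
    grads[[paste0("Wh", l)]] <- dWh + l2 * Wh
    grads[[paste0("b", l)]] <- db
    if (l > 1L) dseq <- dx_seq
  }
  grads
}

windows_to_xs <- function(mats, scaler) {
  T_len <- nrow(mats[[1L]])
  m <- length(mats)
  scaled <- lapply(mats, apply_scaler, sc = scaler)
  lapply(seq_len(T_len), function(t) {
    do.call(rbind, lapply(scaled, function(M) M[t, ]))
  })
}

#' Recurrent (LSTM) energy-expenditure model for fixed windows
#'
#' @param data Window tibble from [assemble_windows()] (list-column `matrix`
#'   of time-by-channel matrices, label `y`).  All windows must share the
#'   same time length (250 steps in the standard 4 s / 2000 Hz / block-32
#'   configuration).
#' @param hidden LSTM hidden size per layer (default 64).
#' @param n_layers Number of stacked LSTM layers (default 2).
#' @param l2 L2 weight-decay coefficient.
#' @param epochs,batch_size,learning_rate,validation_frac,patience,seed,verbose
#'   Training controls as in [fit_ee_mlp()].  Training loss is mean-squared
#'   error; validation and reporting use mean absolute error.
#' @return An `ee_rnn` object.
#' @export
fit_ee_rnn <- function(data, hidden = 64, n_layers = 2, l2 = 0,
                       epochs = 30, batch_size = 16, learning_rate = 1e-3,
                       validation_frac = 0.1, patience = 8,
                       seed = 1, verbose = FALSE) {
  mats <- data$matrix
  y <- as.numeric(data$y)
  if (length(mats) < 2L) abort("Need at least 2 windows to fit")
  T_len <- nrow(mats[[1L]])
  bad <- vapply(mats, nrow, 1L) != T_len
  if (any(bad))
    abort(sprintf(
      "All windows must share the same time length (expected %d steps, e.g. 250 for 4 s at 2000 Hz / block 32)",
      T_len))
  C <- ncol(mats[[1L]])
  flat <- do.call(rbind, mats)
  sc_x <- fit_scaler(flat)
  y_center <- mean(y)
  y_scale <- max(stats::sd(y), 1e-12)
  ys <- (y - y_center) / y_scale
  n <- length(mats)
  xs_all <- windows_to_xs(mats, sc_x)

  result <- withr::with_seed(seed, {
    n_val <- if (validation_frac > 0) max(1L, floor(validation_frac * n)) else 0L
    idx <- sample.int(n)
    val_idx <- head(idx, n_val)
    tr_idx <- setdiff(idx, val_idx)
    if (length(tr_idx) < 2L) { tr_idx <- idx; val_idx <- integer(0) }

    params <- lstm_init(C, hidden, n_layers)
    state <- adam_state(params)
    best <- list(params = params, val = Inf)
    hist <- numeric(0)
    stall <- 0L
    slice_xs <- function(ii) lapply(xs_all, function(M) M[ii, , drop = FALSE])
    for (ep in seq_len(epochs)) {
      ord <- sample(tr_idx)
      for (start in seq(1L, length(ord), by = batch_size)) {
        bi <- ord[start:min(start + batch_size - 1L, length(ord))]
        fwd <- lstm_forward(params, slice_xs(bi), hidden, n_layers,
                            keep_cache = TRUE)
        err <- fwd$yhat - ys[bi]
        if (!all(is.finite(err))) abort("Non-finite training loss; aborting")
        dy <- 2 * err / length(bi)            # MSE training loss
        grads <- lstm_backward(params, fwd, dy, hidden, n_layers, T_len, l2)
        upd <- adam_step(params, grads, state, lr = learning_rate)
        params <- upd$params
        state <- upd$state
      }
      eval_mae <- function(ii) {
        if (length(ii) == 0L) return(NA_real_)
        f <- lstm_forward(params, slice_xs(ii), hidden, n_layers)
        mean(abs(f$yhat - ys[ii]))
      }
      val <- eval_mae(val_idx)
      hist <- c(hist, if (is.na(val)) eval_mae(tr_idx) else val)
      if (verbose)
        message(sprintf("epoch %d: val MAE %.5f (scaled)", ep, tail(hist, 1)))
      if (length(val_idx) > 0L) {
        if (val < best$val - 1e-6) {
          best <- list(params = params, val = val)
          stall <- 0L
        } else {
          stall <- stall + 1L
          if (stall >= patience) break
        }
      }
    }
    if (length(val_idx) > 0L && is.finite(best$val)) params <- best$params
    list(params = params, history = hist)
  })

  structure(list(params = result$params, hidden = hidden, n_layers = n_layers,
                 l2 = l2, T_len = T_len, C = C, scaler = sc_x,
                 y_center = y_center, y_scale = y_scale, n = n, seed = seed,
                 history = result$history),
            class = "ee_rnn")
}

#' @export
print.ee_rnn <- function(x, ...) {
  cat(sprintf("<ee_rnn> %d-step x %d-channel windows -> %d LSTM layer(s) of %d -> 1; seed %d\n",
              x$T_len, x$C, x$n_layers, x$hidden, x$seed))
  invisible(x)
}

#' Predict metabolic power with a fitted recurrent model
#' @param object An `ee_rnn` fit.
#' @param newdata Window tibble with list-column `matrix`, or a list of
#'   time-by-channel matrices.
#' @param ... Unused.
#' @return Numeric vector of estimates, W.
#' @export
predict.ee_rnn <- function(object, newdata, ...) {
  mats <- if (is.list(newdata) && !is.data.frame(newdata)) newdata else newdata$matrix
  if (any(vapply(mats, nrow, 1L) != object$T_len))
    abort(sprintf("Windows must have %d time steps", object$T_len))
  xs <- windows_to_xs(mats, object$scaler)
  fwd <- lstm_forward(xs = xs, params = object$params, hidden = object$hidden,
                      n_layers = object$n_layers)
  fwd$yhat * object$y_scale + object$y_center
}

#' @method glance ee_rnn
#' @export
glance.ee_rnn <- function(x, ...) {
  tibble(nobs = x$n, time_steps = x$T_len, channels = x$C,
         hidden = x$hidden, layers = x$n_layers, l2 = x$l2,
         epochs_run = length(x$history),
         final_val_mae_scaled = unname(tail(x$history, 1)))
}
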