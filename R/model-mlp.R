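# Feedforward network estimator: 3-4 fully connected hidden layers (defaults: 3 x 512, the midpoints of the
# 300-1000 unit band), ReLU activations, a linear scalar output, dropout and
# L2 weight decay on the hidden layers, trained with a mean-absolute-error
# loss by Adam.  Inputs and labels are column-standardized internally; the
# scaler is part of the fitted artifact.

mlp_init <- function(sizes) {
  params <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    fan_in <- sizes[l]
    params[[paste0("W", l)]] <-
      matrix(rnorm(fan_in * sizes[l + 1L], sd = sqrt(2 / fan_in)),
             fan_in, sizes[l + 1L])
    params[[paste0("b", l)]] <- rep(0, sizes[l + 1L])
  }
  params
}

mlp_forward <- function(params, X, n_layers, dropout = 0, training = FALSE) {
  acts <- vector("list", n_layers + 1L)
  masks <- vector("list", n_layers)
  H <- X
  for (l in seq_len(n_layers)) {
    acts[[l]] <- H
    Z <- sweep(H %*% params[[paste0("W", l)]], 2L, params[[paste0("b", l)]], "+")
    if (l <= n_layers - 1L) {
      Z[Z < 0] <- 0
      if (training && dropout > 0) {
        mask <- matrix(stats::rbinom(length(Z), 1L, 1 - dropout) / (1 - dropout),
                       nrow(Z), ncol(Z))
        Z <- Z * mask
        masks[[l]] <- mask
      }
    }
    H <- Z
  }
  acts[[n_layers + 1L]] <- H
  list(yhat = as.numeric(H), acts = acts, masks = masks)
}

mlp_backward <- function(params, fwd, dy, n_layers, l2) {
  grads <- list()
  delta <- matrix(dy, ncol = 1L)
  for (l in rev(seq_len(n_layers))) {
    A <- fwd$acts[[l]]
    grads[[paste0("W", l)]] <- crossprod(A, delta) + l2 * params[[paste0("W", l)]]
    grads[[paste0("b", l)]] <- colSums(delta)
    if (l > 1L) {
      delta <- delta %*% t(params[[paste0("W", l)]])
      if (!is.null(fwd$masks[[l - 1L]])) delta <- delta * fwd$masks[[l - 1L]]
      delta[fwd$acts[[l]] <= 0] <- 0   # ReLU gate (post-activation stored)
    }
  }
  grads
}

#' Feedforward network energy-expenditure model
#'
#' @param data Feature tibble from [assemble_features()] (matrix column `x`,
#'   label `y`).
#' @param hidden Hidden layer widths (3 or 4 layers in the intended design).
#' @param dropout Dropout rate on hidden activations, in `[0, 1)`.
#' @param l2 L2 weight-decay coefficient (>= 0).
#' @param loss Training loss, `"mae"` (default for per-cycle models) or
#'   `"mse"`.
#' @param epochs Maximum training epochs.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam learning rate.
#' @param validation_frac Fraction of training rows held out for early
#'   stopping (0 disables early stopping).
#' @param patience Epochs without validation improvement before stopping.
#' @param seed Integer seed driving initialization, shuffling and dropout;
#'   identical seed + data gives identical fits.
#' @param verbose Print per-epoch losses.
#' @return An `ee_mlp` object.
#' @export
fit_ee_mlp <- function(data, hidden = c(512, 512, 512), dropout = 0.2,
                       l2 = 1e-4, loss = c("mae", "mse"), epochs = 100,
                       batch_size = 64, learning_rate = 1e-3,
                       validation_frac = 0.1, patience = 10,
                       seed = 1, verbose = FALSE) {
  loss <- match.arg(loss)
  X <- as.matrix(data$x)
  y <- as.numeric(data$y)
  stopifnot(nrow(X) == length(y))
  if (!all(is.finite(X)) || !all(is.finite(y)))
    abort("Design matrix and labels must be finite")
  if (dropout < 0 || dropout >= 1) abort("dropout must be in [0, 1)")

  sc_x <- fit_scaler(X)
  y_center <- mean(y)
  y_scale <- max(stats::sd(y), 1e-12)
  Xs <- apply_scaler(X, sc_x)
  ys <- (y - y_center) / y_scale
  n <- nrow(Xs)

  history <- NULL
  result <- withr::with_seed(seed, {
    n_val <- if (validation_frac > 0) max(1L, floor(validation_frac * n)) else 0L
    idx <- sample.int(n)
    val_idx <- head(idx, n_val)
    tr_idx <- setdiff(idx, val_idx)
    if (length(tr_idx) < 2L) { tr_idx <- idx; val_idx <- integer(0) }

    sizes <- c(ncol(Xs), hidden, 1L)
    n_layers <- length(sizes) - 1L
    params <- mlp_init(sizes)
    state <- adam_state(params)
    best <- list(params = params, val = Inf, epoch = 0L)
    hist <- numeric(0)
    stall <- 0L

    for (ep in seq_len(epochs)) {
      ord <- sample(tr_idx)
      for (start in seq(1L, length(ord), by = batch_size)) {
        bi <- ord[start:min(start + batch_size - 1L, length(ord))]
        fwd <- mlp_forward(params, Xs[bi, , drop = FALSE], n_layers,
                           dropout = dropout, training = TRUE)
        err <- fwd$yhat - ys[bi]
        if (!all(is.finite(err))) abort("Non-finite training loss; aborting")
        dy <- if (loss == "mae") sign(err) / length(bi) else 2 * err / length(bi)
        grads <- mlp_backward(params, fwd, dy, n_layers, l2)
        upd <- adam_step(params, grads, state, lr = learning_rate)
        params <- upd$params
        state <- upd$state
      }
      eval_mae <- function(ii) {
        if (length(ii) == 0L) return(NA_real_)
        f <- mlp_forward(params, Xs[ii, , drop = FALSE], n_layers)
        mean(abs(f$yhat - ys[ii]))
      }
      val <- eval_mae(val_idx)
      hist <- c(hist, if (is.na(val)) eval_mae(tr_idx) else val)
      if (verbose)
        message(sprintf("epoch %d: val MAE %.5f (scaled)", ep, tail(hist, 1)))
      if (length(val_idx) > 0L) {
        if (val < best$val - 1e-6) {
          best <- list(params = params, val = val, epoch = ep)
          stall <- 0L
        } else {
          stall <- stall + 1L
          if (stall >= patience) break
        }
      }
    }
    if (length(val_idx) > 0L && is.finite(best$val)) params <- best$params
    list(params = params, n_layers = n_layers, history = hist)
  })

  structure(list(params = result$params, n_layers = result$n_layers,
                 hidden = hidden, dropout = dropout, l2 = l2, loss = loss,
                 scaler = sc_x, y_center = y_center, y_scale = y_scale,
                 feature_names = colnames(X), p = ncol(X), n = n,
                 seed = seed, history = result$history),
            class = "ee_mlp")
}

#' @export
print.ee_mlp <- function(x, ...) {
  cat(sprintf(
    "<ee_mlp> %d features -> [%s] -> 1; dropout %.2f, L2 %g, %s loss, seed %d\n",
    x$p, paste(x$hidden, collapse = ", "), x$dropout, x$l2, x$loss, x$seed))
  invisible(x)
}

#' Predict metabolic power with a fitted feedforward network
#' @param object An `ee_mlp` fit.
#' @param newdata Feature tibble with matrix column `x`, or a matrix.
#' @param ... Unused.
#' @return Numeric vector of estimates, W.
#' @export
predict.ee_mlp <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else as.matrix(newdata$x)
  if (ncol(X) != object$p)
    abort(sprintf("newdata has %d feature columns; model expects %d",
                  ncol(X), object$p))
  Xs <- apply_scaler(X, object$scaler)
  fwd <- mlp_forward(object$params, Xs, object$n_layers)
  fwd$yhat * object$y_scale + object$y_center
}

#' @method glance ee_mlp
#' @export
glance.ee_mlp <- function(x, ...) {
  tibble(nobs = x$n, p = x$p, layers = length(x$hidden),
         units = paste(x$hidden, collapse = "x"), dropout = x$dropout,
         l2 = x$l2, loss = x$loss, epochs_run = length(x$history),
         final_val_mae_scaled = unname(tail(x$history, 1)))
}
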