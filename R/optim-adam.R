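# Minimal Adam optimizer over a named list of parameter matrices/vectors.
# Shared by the feedforward and recurrent trainers.

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# column-standardization helpers (constant columns get scale 1)
fit_scaler <- function(X) {
  mu <- colMeans(X)
  s <- apply(X, 2L, stats::sd)
  s[!is.finite(s) | s < 1e-12] <- 1
  list(center = mu, scale = s)
}
apply_scaler <- function(X, sc) sweep(sweep(X, 2L, sc$center), 2L, sc$scale, "/")
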