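#' Ordinary least squares energy-expenditure model
#'
#' Fits `y = a' x + b` by ordinary least squares on the binned gait-cycle
#' features; no regularization and no feature selection.  When the design is
#' rank-deficient (common when the feature count exceeds the cycle count)
#' the minimum-norm least-squares solution is returned with a warning.
#'
#' @param data A feature tibble from [assemble_features()] (matrix column
#'   `x`, label column `y`), or anything with those columns.
#' @param quiet Suppress the rank-deficiency warning.
#' @return An object of class `ee_linear` with weights `a`, intercept `b`,
#'   training `r_squared`, and the feature names.
#' @export
fit_ee_linear <- function(data, quiet = FALSE) {
  X <- as.matrix(data$x)
  y <- as.numeric(data$y)
  if (nrow(X) < 2L) abort("Need at least 2 samples to fit")
  if (!all(is.finite(X)) || !all(is.finite(y)))
    abort("Design matrix and labels must be finite")
  xbar <- colMeans(X)
  ybar <- mean(y)
  Xc <- sweep(X, 2L, xbar)
  yc <- y - ybar
  sv <- svd(Xc)
  tol <- max(dim(Xc)) * .Machine$double.eps * max(sv$d, 0)
  r <- sum(sv$d > tol)
  if (r == 0L) {
    a <- rep(0, ncol(X))
  } else {
    a <- sv$v[, seq_len(r), drop = FALSE] %*%
      (crossprod(sv$u[, seq_len(r), drop = FALSE], yc) / sv$d[seq_len(r)])
    a <- as.numeric(a)
  }
  if (r < min(dim(Xc)) && !quiet)
    warn(sprintf("Rank-deficient design (rank %d < %d); minimum-norm solution",
                 r, ncol(Xc)))
  fitted <- as.numeric(Xc %*% a) + ybar
  sst <- sum(yc^2)
  ssr <- sum((y - fitted)^2)
  structure(list(a = setNames(a, colnames(X)), b = ybar - sum(xbar * a),
                 r_squared = if (sst > 0) 1 - ssr / sst else 1,
                 sigma = sqrt(ssr / max(1, nrow(X) - r - 1)),
                 rank = r, n = nrow(X), p = ncol(X),
                 feature_names = colnames(X)),
            class = "ee_linear")
}

#' @export
print.ee_linear <- function(x, ...) {
  cat(sprintf("<ee_linear> %d features, n = %d, rank %d, training R^2 = %.4f\n",
              x$p, x$n, x$rank, x$r_squared))
  invisible(x)
}

#' Predict metabolic power with a fitted linear model
#'
#' @param object An `ee_linear` fit.
#' @param newdata A feature tibble with matrix column `x`, or a numeric
#'   matrix with `p` columns.
#' @param ... Unused.
#' @return Numeric vector of estimates, W.
#' @export
predict.ee_linear <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else as.matrix(newdata$x)
  if (ncol(X) != object$p)
    abort(sprintf("newdata has %d feature columns; model expects %d",
                  ncol(X), object$p))
  as.numeric(X %*% object$a) + object$b
}

#' @method tidy ee_linear
#' @export
tidy.ee_linear <- function(x, ...) {
  tibble(term = c("(Intercept)", names(x$a) %||% paste0("x", seq_along(x$a))),
         estimate = c(x$b, unname(x$a)))
}

#' @method glance ee_linear
#' @export
glance.ee_linear <- function(x, ...) {
  tibble(r.squared = x$r_squared, sigma = x$sigma, rank = x$rank,
         nobs = x$n, p = x$p)
}
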