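#' Pearson correlation coefficient
#'
#' Direct product-moment implementation used throughout the package (and by
#' the training loss, where its gradient is needed in closed form). Errors on
#' degenerate input rather than returning `NA`.
#'
#' @param u,v Numeric vectors of equal length >= 2, each with nonzero
#'   variance.
#' @return Correlation in [-1, 1].
#' @export
pearson <- function(u, v) {
  u <- as.numeric(u); v <- as.numeric(v)
  n <- length(u)
  if (n != length(v)) {
    stop("vectors have different lengths (", n, " vs ", length(v), ")")
  }
  if (n < 2L) stop("need at least 2 samples for a correlation")
  uc <- u - mean(u)
  vc <- v - mean(v)
  su <- sqrt(sum(uc^2))
  sv <- sqrt(sum(vc^2))
  if (su == 0 || sv == 0) {
    stop("undefined correlation: input with zero variance")
  }
  r <- sum(uc * vc) / (su * sv)
  max(-1, min(1, r))
}

# gradient of pearson(u, v) with respect to v (u held fixed)
pearson_grad_v <- function(u, v) {
  uc <- u - mean(u)
  vc <- v - mean(v)
  su <- sqrt(sum(uc^2))
  sv <- sqrt(sum(vc^2))
  if (su == 0 || sv == 0) stop("undefined correlation gradient: zero variance")
  r <- sum(uc * vc) / (su * sv)
  uc / (su * sv) - r * vc / sv^2
}

#' Correlation-difference training loss
#'
#' The network objective: `J = rho(x, y) - rho(x, yhat)`, where `x` is the
#' input (stimulus-feature) batch, `y` the true output (EEG-feature) batch
#' and `yhat` the network prediction. The first term does not depend on the
#' network parameters, so minimizing `J` maximizes the correlation between
#' input and predicted output; `J = 0` when the prediction reproduces the
#' true input-output correlation exactly, and `|J| <= 2` always.
#'
#' Two batch conventions are supported. `"flatten"` (default) correlates the
#' batches flattened into single vectors, giving one scalar correlation per
#' batch; `"rowmean"` averages per-row correlations.
#'
#' @param x,y,yhat Numeric matrices of identical dimensions (rows are
#'   windows, columns features). Vectors are treated as single rows.
#' @param mode `"flatten"` or `"rowmean"`.
#' @param gradient If `TRUE`, attach the gradient of `J` with respect to
#'   `yhat` as attribute `"gradient"` (same shape as `yhat`).
#' @return Scalar loss `J`.
#' @export
correlation_loss <- function(x, y, yhat, mode = c("flatten", "rowmean"),
                             gradient = FALSE) {
  mode <- match.arg(mode)
  if (!is.matrix(x)) x <- matrix(as.numeric(x), nrow = 1L)
  if (!is.matrix(y)) y <- matrix(as.numeric(y), nrow = 1L)
  if (!is.matrix(yhat)) yhat <- matrix(as.numeric(yhat), nrow = 1L)
  if (!all(dim(x) == dim(y)) || !all(dim(y) == dim(yhat))) {
    stop("x, y and yhat must have identical dimensions")
  }
  if (length(x) < 2L) stop("batch too small for a correlation")
  if (mode == "flatten") {
    xf <- as.vector(x); yf <- as.vector(y); yhf <- as.vector(yhat)
    J <- pearson(xf, yf) - pearson(xf, yhf)
    if (gradient) {
      g <- -pearson_grad_v(xf, yhf)
      attr(J, "gradient") <- matrix(g, nrow(yhat), ncol(yhat))
    }
    J
  } else {
    N <- nrow(x)
    if (ncol(x) < 2L) stop("rowmean mode needs at least 2 features per row")
    Js <- numeric(N)
    G <- if (gradient) matrix(0, N, ncol(x)) else NULL
    for (i in seq_len(N)) {
      Js[i] <- pearson(x[i, ], y[i, ]) - pearson(x[i, ], yhat[i, ])
      if (gradient) G[i, ] <- -pearson_grad_v(x[i, ], yhat[i, ]) / N
    }
    J <- mean(Js)
    if (gradient) attr(J, "gradient") <- G
    J
  }
}
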