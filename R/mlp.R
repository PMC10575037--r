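#' Network architecture specification
#'
#' A single multilayer perceptron maps the `p` stimulus features of each
#' window to `p` predicted EEG features. The default architecture is
#' input 50 -> hidden 1000 -> hidden 550 -> output 50, with the configured
#' activation and a dropout layer after each hidden layer and a linear
#' output.
#'
#' @param layer_widths Integer vector `(p_in, hidden..., p_out)`.
#' @param dropout_rate Dropout probability in [0, 1) applied after each
#'   hidden activation during training (default 0.2).
#' @param activation `"relu"` (default) or `"tanh"`.
#' @param seed Integer seed for parameter initialization.
#' @return An object of class `sc_net_spec`.
#' @export
network_spec <- function(layer_widths = c(50L, 1000L, 550L, 50L),
                         dropout_rate = 0.2,
                         activation = c("relu", "tanh"), seed = 1L) {
  activation <- match.arg(activation)
  layer_widths <- as.integer(layer_widths)
  stopifnot(length(layer_widths) >= 2L, all(layer_widths >= 1L),
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(layer_widths = layer_widths, dropout_rate = dropout_rate,
                 activation = activation, seed = as.integer(seed)),
            class = "sc_net_spec")
}

#' Training configuration
#'
#' Hyperparameters of the gradient-based fit: Adam with the stated learning
#' rate, shuffled mini-batches, a validation split taken from the last rows
#' (preserving window order so validation windows are the most recent), and
#' early stopping on the validation loss.
#'
#' @param learning_rate Adam step size (default 1e-3).
#' @param batch_size Mini-batch rows (default 64).
#' @param max_epochs Upper bound on epochs (default 200).
#' @param validation_fraction Fraction of rows held out for validation,
#'   in (0, 1) (default 0.1).
#' @param patience Epochs without validation improvement before stopping
#'   (default 20).
#' @param loss_mode Batch correlation convention, see [correlation_loss()].
#' @param seed Integer seed for shuffling and dropout.
#' @return An object of class `sc_train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 64L,
                         max_epochs = 200L, validation_fraction = 0.1,
                         patience = 20L, loss_mode = "flatten", seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 2L, max_epochs >= 1L,
            validation_fraction > 0, validation_fraction < 1, patience >= 1L)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 validation_fraction = validation_fraction,
                 patience = as.integer(patience),
                 loss_mode = loss_mode, seed = as.integer(seed)),
            class = "sc_train_config")
}

act_fun <- function(name) {
  switch(name, relu = function(z) pmax(z, 0), tanh = tanh)
}
act_deriv <- function(name) {
  switch(name,
         relu = function(z, a) (z > 0) * 1,
         tanh = function(z, a) 1 - a^2)
}

#' Build an untrained network
#'
#' Allocates seeded He-normal (relu) or Glorot-normal (tanh) weights and zero
#' biases for the stack described by `spec`.
#'
#' @param spec An [network_spec()].
#' @return An object of class `sc_model` with untrained parameters.
#' @export
build_mlp <- function(spec) {
  stopifnot(inherits(spec, "sc_net_spec"))
  widths <- spec$layer_widths
  L <- length(widths) - 1L
  params <- withr::with_seed(spec$seed, {
    lapply(seq_len(L), function(l) {
      fan_in <- widths[l]
      sd0 <- if (spec$activation == "relu") sqrt(2 / fan_in) else
        sqrt(2 / (fan_in + widths[l + 1L]))
      list(W = matrix(stats::rnorm(fan_in * widths[l + 1L], sd = sd0),
                      fan_in, widths[l + 1L]),
           b = rep(0, widths[l + 1L]))
    })
  })
  structure(list(spec = spec, params = params, trained = FALSE,
                 history = NULL),
            class = "sc_model")
}

#' Number of learnable parameters in a model
#'
#' @param model An `sc_model`.
#' @return Integer count of weights plus biases.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, function(p) length(p$W) + length(p$b), numeric(1)))
}

#' @export
print.sc_model <- function(x, ...) {
  cat(sprintf("<sc_model> %s MLP %s, %s parameters%s\n",
              x$spec$activation,
              paste(x$spec$layer_widths, collapse = "-"),
              format(n_params(x), big.mark = ","),
              if (x$trained) sprintf(", trained %d epoch(s)",
                                     nrow(x$history)) else " (untrained)"))
  invisible(x)
}

# forward pass; returns output plus caches needed for backprop
mlp_forward <- function(params, spec, X, dropout = FALSE) {
  L <- length(params)
  act <- act_fun(spec$activation)
  A <- X
  caches <- vector("list", L)
  for (l in seq_len(L)) {
    Z <- sweep(A %*% params[[l]]$W, 2L, params[[l]]$b, FUN = "+")
    if (l < L) {
      Aout <- act(Z)
      M <- NULL
      if (dropout && spec$dropout_rate > 0) {
        keep <- 1 - spec$dropout_rate
        M <- matrix(stats::rbinom(length(Aout), 1L, keep) / keep,
                    nrow(Aout), ncol(Aout))
        Aout <- Aout * M
      }
      caches[[l]] <- list(A_in = A, Z = Z, A_act = Aout, mask = M)
      A <- Aout
    } else {
      caches[[l]] <- list(A_in = A, Z = Z)
      A <- Z  # linear output
    }
  }
  list(output = A, caches = caches)
}

mlp_backward <- function(params, spec, caches, G_out) {
  L <- length(params)
  dact <- act_deriv(spec$activation)
  grads <- vector("list", L)
  G <- G_out
  for (l in rev(seq_len(L))) {
    cache <- caches[[l]]
    grads[[l]] <- list(W = crossprod(cache$A_in, G), b = colSums(G))
    if (l > 1L) {
      G <- G %*% t(params[[l]]$W)
      prev <- caches[[l - 1L]]
      D <- dact(prev$Z, if (spec$activation == "tanh") tanh(prev$Z) else NULL)
      G <- G * D
      if (!is.null(prev$mask)) G <- G * prev$mask
    }
  }
  grads
}

#' Train the network with the correlation-difference loss
#'
#' Minimizes [correlation_loss()] by Adam over shuffled mini-batches. The
#' validation split is the last `validation_fraction` of the rows (window
#' order preserved); training stops early once the validation loss has not
#' improved for `patience` epochs, and the best-validation parameters are
#' restored. Fully deterministic given the spec and config seeds.
#'
#' @param model An untrained (or previously trained) `sc_model`.
#' @param F_in Input feature matrix (`sc_features` or `N x p_in` matrix).
#' @param F_out Target feature matrix with the same row count.
#' @param cfg An [train_config()].
#' @return The trained `sc_model`, with a `history` data frame of per-epoch
#'   train and validation loss.
#' @export
fit_mlp <- function(model, F_in, F_out, cfg = train_config()) {
  stopifnot(inherits(model, "sc_model"), inherits(cfg, "sc_train_config"))
  X <- if (inherits(F_in, "sc_features")) F_in$data else as.matrix(F_in)
  Y <- if (inherits(F_out, "sc_features")) F_out$data else as.matrix(F_out)
  if (nrow(X) != nrow(Y)) stop("input and target row counts differ")
  widths <- model$spec$layer_widths
  if (ncol(X) != widths[1L]) {
    stop("input width ", ncol(X), " does not match network input ",
         widths[1L])
  }
  if (ncol(Y) != widths[length(widths)]) {
    stop("target width ", ncol(Y), " does not match network output ",
         widths[length(widths)])
  }
  N <- nrow(X)
  n_val <- max(1L, round(cfg$validation_fraction * N))
  n_train <- N - n_val
  if (n_train < 2L) {
    stop("too few rows (", N, ") for a validation split of fraction ",
         cfg$validation_fraction)
  }
  idx_train <- seq_len(n_train)
  idx_val <- (n_train + 1L):N
  Xtr <- X[idx_train, , drop = FALSE]; Ytr <- Y[idx_train, , drop = FALSE]
  Xva <- X[idx_val, , drop = FALSE];   Yva <- Y[idx_val, , drop = FALSE]

  params <- model$params
  spec <- model$spec
  L <- length(params)
  adam_m <- lapply(params, function(p) list(W = p$W * 0, b = p$b * 0))
  adam_v <- lapply(params, function(p) list(W = p$W * 0, b = p$b * 0))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  best_val <- Inf
  best_params <- params
  wait <- 0L
  history <- list()

  eval_loss <- function(params, Xs, Ys) {
    out <- mlp_forward(params, spec, Xs, dropout = FALSE)$output
    as.numeric(correlation_loss(Xs, Ys, out, mode = cfg$loss_mode))
  }

  withr::with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      perm <- sample.int(n_train)
      batch_starts <- seq(1L, n_train, by = cfg$batch_size)
      for (bs in batch_starts) {
        rows <- perm[bs:min(bs + cfg$batch_size - 1L, n_train)]
        if (length(rows) < 2L) next
        Xb <- Xtr[rows, , drop = FALSE]
        Yb <- Ytr[rows, , drop = FALSE]
        fwd <- mlp_forward(params, spec, Xb, dropout = TRUE)
        J <- correlation_loss(Xb, Yb, fwd$output, mode = cfg$loss_mode,
                              gradient = TRUE)
        grads <- mlp_backward(params, spec, fwd$caches, attr(J, "gradient"))
        step <- step + 1L
        lr_t <- cfg$learning_rate *
          sqrt(1 - beta2^step) / (1 - beta1^step)
        for (l in seq_len(L)) {
          adam_m[[l]]$W <- beta1 * adam_m[[l]]$W + (1 - beta1) * grads[[l]]$W
          adam_m[[l]]$b <- beta1 * adam_m[[l]]$b + (1 - beta1) * grads[[l]]$b
          adam_v[[l]]$W <- beta2 * adam_v[[l]]$W + (1 - beta2) * grads[[l]]$W^2
          adam_v[[l]]$b <- beta2 * adam_v[[l]]$b + (1 - beta2) * grads[[l]]$b^2
          params[[l]]$W <- params[[l]]$W -
            lr_t * adam_m[[l]]$W / (sqrt(adam_v[[l]]$W) + eps)
          params[[l]]$b <- params[[l]]$b -
            lr_t * adam_m[[l]]$b / (sqrt(adam_v[[l]]$b) + eps)
        }
      }
      train_loss <- eval_loss(params, Xtr, Ytr)
      val_loss <- eval_loss(params, Xva, Yva)
      history[[epoch]] <- data.frame(epoch = epoch, train_loss = train_loss,
                                     val_loss = val_loss)
      if (val_loss < best_val - 1e-9) {
        best_val <- val_loss
        best_params <- params
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
  })

  model$params <- best_params
  model$trained <- TRUE
  model$history <- do.call(rbind, history)
  model$train_config <- cfg
  model
}

#' Predict output features
#'
#' Deterministic forward pass (dropout disabled); rows are processed
#' independently, so predicting row by row equals predicting in one batch.
#'
#' @param model A (trained) `sc_model`.
#' @param F_in `sc_features` or matrix with the network's input width.
#' @return Numeric matrix `N x p_out` of predicted features.
#' @export
predict_mlp <- function(model, F_in) {
  stopifnot(inherits(model, "sc_model"))
  X <- if (inherits(F_in, "sc_features")) F_in$data else as.matrix(F_in)
  widths <- model$spec$layer_widths
  if (ncol(X) != widths[1L]) {
    stop("input width ", ncol(X), " does not match network input ",
         widths[1L])
  }
  mlp_forward(model$params, model$spec, X, dropout = FALSE)$output
}
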