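test_that("pearson matches direct product-moment evaluation and cor()", {
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 5)
  expect_equal(pearson(x, y), 0.8315218, tolerance = 1e-6)
  expect_equal(pearson(x, y), cor(x, y))
  expect_equal(pearson(x, x), 1)
  expect_equal(pearson(x, -2 * x + 3), -1)
  expect_equal(pearson(3 * x + 1, y), pearson(x, y))
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson(1:3, 1:4), "different lengths")
})

test_that("correlation loss is zero at perfect prediction and bounded", {
  withr::with_seed(1, {
    x <- matrix(rnorm(20), 4, 5)
    y <- matrix(rnorm(20), 4, 5)
  })
  expect_equal(as.numeric(correlation_loss(x, y, y)), 0)
  expect_equal(as.numeric(correlation_loss(x, y, y, mode = "rowmean")), 0)
  withr::with_seed(2, {
    for (i in 1:20) {
      a <- matrix(rnorm(12), 3); b <- matrix(rnorm(12), 3)
      cc <- matrix(rnorm(12), 3)
      expect_lte(abs(as.numeric(correlation_loss(a, b, cc))), 2)
    }
  })
  # invariant to positive rescaling of the prediction
  yh <- matrix(rnorm(20), 4, 5)
  expect_equal(as.numeric(correlation_loss(x, y, yh)),
               as.numeric(correlation_loss(x, y, 7 * yh)))
  expect_error(correlation_loss(x, y, yh * 0), "zero variance")
  expect_error(correlation_loss(x, y[, 1:3], yh), "identical dimensions")
})

test_that("analytic loss gradient matches finite differences", {
  withr::with_seed(4, {
    x <- matrix(rnorm(12), 4, 3)
    y <- matrix(rnorm(12), 4, 3)
    yh <- matrix(rnorm(12), 4, 3)
  })
  for (mode in c("flatten", "rowmean")) {
    J <- correlation_loss(x, y, yh, mode = mode, gradient = TRUE)
    G <- attr(J, "gradient")
    h <- 1e-6
    G_fd <- matrix(0, 4, 3)
    for (i in 1:4) for (j in 1:3) {
      yp <- yh; yp[i, j] <- yp[i, j] + h
      ym <- yh; ym[i, j] <- ym[i, j] - h
      G_fd[i, j] <- (as.numeric(correlation_loss(x, y, yp, mode = mode)) -
                       as.numeric(correlation_loss(x, y, ym, mode = mode))) /
        (2 * h)
    }
    expect_lt(max(abs(G - G_fd)), 1e-5)
  }
})

test_that("the reference architecture has the documented parameter count", {
  m <- build_mlp(network_spec())
  expect_identical(n_params(m), 50 * 1000 + 1000 + 1000 * 550 + 550 +
                     550 * 50 + 50)
  expect_identical(n_params(m), 629100)
})

test_that("initialization and prediction are deterministic", {
  spec <- network_spec(c(6L, 12L, 8L, 6L), seed = 9)
  m1 <- build_mlp(spec)
  m2 <- build_mlp(spec)
  expect_identical(m1$params, m2$params)
  withr::with_seed(10, X <- matrix(rnorm(30), 5, 6))
  expect_identical(predict_mlp(m1, X), predict_mlp(m1, X))
  # row-wise independence: one-at-a-time equals batch
  batch <- predict_mlp(m1, X)
  rows <- do.call(rbind, lapply(1:5, function(i) {
    predict_mlp(m1, X[i, , drop = FALSE])
  }))
  expect_equal(batch, rows, tolerance = 1e-12)
  expect_error(predict_mlp(m1, X[, 1:4]), "input width")
})

# a feature set whose target is an orthogonal transform of the input:
# learnable exactly by the network, used by several training tests
identity_task <- function(n = 240L, p = 8L, seed = 1L) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    Q <- qr.Q(qr(matrix(rnorm(p * p), p, p)))
    list(X = X, Y = X %*% Q)
  })
}

test_that("training learns a noise-free linear mapping to high correlation", {
  task <- identity_task(seed = 21)
  spec <- network_spec(c(8L, 32L, 16L, 8L), dropout_rate = 0, seed = 5)
  cfg <- train_config(max_epochs = 200L, patience = 30L, batch_size = 32L,
                      learning_rate = 3e-3, seed = 6)
  m <- fit_mlp(build_mlp(spec), task$X, task$Y, cfg)
  yh <- predict_mlp(m, task$X)
  expect_gte(pearson(as.vector(task$X), as.vector(yh)), 0.99)
  expect_true(nrow(m$history) <= cfg$max_epochs)
})

test_that("training is reproducible and improves on the untrained network", {
  task <- identity_task(seed = 22)
  spec <- network_spec(c(8L, 32L, 16L, 8L), dropout_rate = 0.1, seed = 5)
  cfg <- train_config(max_epochs = 25L, patience = 10L, seed = 7)
  m1 <- fit_mlp(build_mlp(spec), task$X, task$Y, cfg)
  m2 <- fit_mlp(build_mlp(spec), task$X, task$Y, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)

  # margin over the untrained model on validation rows, median over 5 seeds
  n_val <- round(0.1 * nrow(task$X))
  idx_val <- (nrow(task$X) - n_val + 1):nrow(task$X)
  margins <- vapply(1:5, function(sd) {
    spec_s <- network_spec(c(8L, 32L, 16L, 8L), dropout_rate = 0.1, seed = sd)
    m0 <- build_mlp(spec_s)
    mt <- fit_mlp(m0, task$X, task$Y,
                  train_config(max_epochs = 40L, patience = 10L, seed = sd))
    rho0 <- pearson(as.vector(task$X[idx_val, ]),
                    as.vector(predict_mlp(m0, task$X[idx_val, ])))
    rho1 <- pearson(as.vector(task$X[idx_val, ]),
                    as.vector(predict_mlp(mt, task$X[idx_val, ])))
    rho1 - rho0
  }, numeric(1))
  expect_gt(median(margins), 0.1)
})

test_that("destroying the input/output pairing destroys the correlation", {
  # targets made from an independent draw: nothing to learn
  withr::with_seed(30, {
    X <- matrix(rnorm(200 * 6), 200, 6)
  })
  rhos <- vapply(1:5, function(sd) {
    withr::with_seed(100 + sd, Yperm <- matrix(rnorm(200 * 6), 200, 6))
    spec <- network_spec(c(6L, 16L, 8L, 6L), dropout_rate = 0.1, seed = sd)
    m <- fit_mlp(build_mlp(spec), X, Yperm,
                 train_config(max_epochs = 20L, patience = 5L, seed = sd))
    n_val <- 20L
    idx <- 181:200
    # correlation of prediction with an independent probe target
    withr::with_seed(200 + sd, probe <- matrix(rnorm(20 * 6), 20, 6))
    pearson(as.vector(probe), as.vector(predict_mlp(m, X[idx, ])))
  }, numeric(1))
  expect_lt(max(abs(rhos)), 0.35)
  expect_lt(abs(mean(rhos)), 0.15)
})

test_that("training guards against degenerate splits and width mismatches", {
  X <- matrix(rnorm(40), 10, 4)
  spec <- network_spec(c(4L, 8L, 4L))
  expect_error(fit_mlp(build_mlp(spec), X[1:2, ], X[1:2, ],
                       train_config(validation_fraction = 0.5)),
               "too few rows")
  expect_error(fit_mlp(build_mlp(spec), X, matrix(rnorm(30), 10, 3)),
               "target width")
})
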