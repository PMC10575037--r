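# independent enumeration oracle for the windowing index rule
enumerate_windows <- function(T_, w, o) {
  starts <- integer(0)
  n <- 0L
  repeat {
    s0 <- (w - o) * n
    if (s0 + w - 1L > T_ - 1L) break
    starts <- c(starts, s0)
    n <- n + 1L
  }
  starts
}

test_that("segment implements the inclusive window index rule", {
  cfg <- window_config(256, 128)
  x <- seq_len(256) - 1
  W1 <- segment(x, cfg)
  expect_identical(nrow(W1$data), 1L)
  expect_equal(W1$data[1, ], 0:255)

  x2 <- seq_len(1000) - 1
  W2 <- segment(x2, cfg)
  expect_identical(nrow(W2$data), 6L)
  # the reference configuration: window 1 (0-based) covers samples 128..383
  expect_equal(W2$data[2, ], 128:383)
  expect_equal(W2$data[6, ], 640:895)
  expect_identical(W2$provenance$start_sample, enumerate_windows(1000L, 256L, 128L))

  expect_error(segment(rnorm(100), cfg), "T = 100 < w = 256")
  expect_error(window_config(256, 256), "0 <= o < w")
})

test_that("windowing matches the enumeration oracle over random geometries", {
  withr::with_seed(99, {
    for (i in 1:25) {
      w <- sample(4:64, 1)
      o <- sample(0:(w - 1), 1)
      T_ <- w + sample(0:300, 1)
      x <- rnorm(T_)
      W <- segment(x, window_config(w, o))
      starts <- enumerate_windows(T_, w, o)
      expect_identical(W$provenance$start_sample, starts)
      n_check <- sample(seq_along(starts), 1)
      expect_equal(W$data[n_check, ],
                   x[(starts[n_check] + 1):(starts[n_check] + w)])
    }
  })
})

test_that("concat_windows stacks deterministically with provenance intact", {
  cfg <- window_config(8, 4)
  a <- segment(rnorm(20), cfg, "S2", 1L)
  b <- segment(rnorm(24), cfg, "S1", 3L)
  cc <- concat_windows(list(a, b))
  expect_identical(nrow(cc$data), nrow(a$data) + nrow(b$data))
  # sorted by (subject, trial, start): S1 rows first
  expect_identical(cc$provenance$subject_id[1], "S1")
  # every row maps back to its source range
  expect_equal(cc$data[1, ], b$data[1, ])
  expect_identical(nrow(concat_windows(list())$data), 0L)
  expect_error(concat_windows(list(a, segment(rnorm(30), window_config(10, 5)))),
               "mixed window lengths")
})

test_that("KLT basis identities hold: orthonormality, rank, round trip", {
  withr::with_seed(13, X <- matrix(rnorm(200), 20, 10))
  # rank-1 input
  r1 <- outer(rnorm(20), rnorm(10))
  b1 <- fit_klt(r1, p = 1, center = FALSE)
  expect_lt(b1$singular_values[2] / b1$singular_values[1], 1e-8)
  rec1 <- klt_reconstruct(klt_project(r1, b1), b1)
  expect_lt(norm(rec1$data - r1, "F") / norm(r1, "F"), 1e-8)

  # p = w exact inversion
  bfull <- fit_klt(X, p = 10)
  expect_lt(norm(crossprod(bfull$basis) - diag(10), "F"), 1e-8)
  rec <- klt_reconstruct(klt_project(X, bfull), bfull)
  expect_lt(norm(rec$data - X, "F"), 1e-8)

  expect_error(fit_klt(X, p = 11), "out of range")
  expect_error(fit_klt(X[1, , drop = FALSE], p = 1), "at least 2")
})

test_that("truncation error equals the discarded singular-value energy", {
  withr::with_seed(14, X <- matrix(rnorm(40), 10, 4))
  b <- fit_klt(X, p = 2)
  rec <- klt_reconstruct(klt_project(X, b), b)
  err <- norm(sweep(X, 2, b$mean) - sweep(rec$data, 2, b$mean), "F")
  d <- svd(sweep(X, 2, colMeans(X)))$d  # independent full SVD oracle
  expect_equal(err, sqrt(sum(d[3:4]^2)), tolerance = 1e-10)
})

test_that("projection identities: zero mean rows, variances, energy bound", {
  withr::with_seed(15, X <- matrix(rnorm(600), 30, 20))
  b <- fit_klt(X, p = 5)
  F_ <- klt_project(X, b)
  # replicated-mean input projects to zero
  M <- matrix(b$mean, 4, 20, byrow = TRUE)
  expect_lt(max(abs(klt_project(M, b)$data)), 1e-10)
  # column variances follow the SVD identity
  expect_equal(apply(F_$data, 2, var),
               b$singular_values[1:5]^2 / (nrow(X) - 1), tolerance = 1e-10)
  # orthogonal projection cannot create energy
  expect_lte(sum(F_$data^2), sum(sweep(X, 2, b$mean)^2))
  # truncation residual is orthogonal to the retained basis
  rec <- klt_reconstruct(F_, b)
  resid <- sweep(X, 2, b$mean) - sweep(rec$data, 2, b$mean)
  expect_lt(max(abs(crossprod(b$basis, t(resid)))), 1e-9)
})

test_that("reconstruction error is non-increasing in p and zero at full rank", {
  withr::with_seed(16, X <- matrix(rnorm(300), 30, 10))
  errs <- vapply(1:10, function(p) {
    b <- fit_klt(X, p)
    norm(X - klt_reconstruct(klt_project(X, b), b)$data, "F")
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-9))
  expect_lt(errs[10], 1e-8)
})

test_that("overlap_add inverts segment on the covered span", {
  cfg <- window_config(256, 128)
  withr::with_seed(17, x <- rnorm(1000))
  W <- segment(x, cfg, "S01", 1L)
  y <- overlap_add(W, cfg)
  expect_length(y, 896L)
  expect_equal(y, x[1:896])

  # single window, constants, and random geometries
  x1 <- rnorm(64)
  W1 <- segment(x1, window_config(64, 32))
  expect_equal(overlap_add(W1), x1)
  Wc <- segment(rep(3.5, 100), window_config(16, 8))
  expect_true(all(abs(overlap_add(Wc) - 3.5) < 1e-12))
  withr::with_seed(18, {
    for (i in 1:10) {
      w <- sample(4:50, 1); o <- sample(0:(w - 1), 1)
      x <- rnorm(w + sample(0:200, 1))
      W <- segment(x, window_config(w, o))
      y <- overlap_add(W)
      expect_equal(y, x[seq_along(y)])
    }
  })
  # corrupted spacing is rejected
  Wbad <- segment(rnorm(100), window_config(16, 8))
  Wbad$provenance$start_sample[2] <- 9L
  expect_error(overlap_add(Wbad), "non-uniform")
})

test_that("scree picks the smallest p reaching the energy threshold", {
  expect_identical(scree(c(1, 0, 0))$p, 1L)
  expect_identical(scree(c(1, 1, 1, 1), threshold = 0.95)$p, 4L)
  sv <- 2^-(1:12)
  res <- scree(sv, threshold = 0.9)
  # brute-force cumulative scan oracle
  cum <- cumsum(sv^2) / sum(sv^2)
  expect_identical(res$p, which(cum >= 0.9)[1])
  expect_equal(res$table$cumulative, cum)
  expect_error(scree(numeric(0)), "empty")
  expect_error(scree(c(1, 2)), "nonincreasing")
})

test_that("basis alignment preserves spans while matching coordinates", {
  # two noisy window ensembles of the same underlying stationary signal
  cfg <- tiny_synth(n_trials = 1L, duration_s = 80, n_channels = 4L,
                    seed = 55)
  env <- make_envelope(80, 128, seed = 56)
  tr <- make_trial(env, cfg, trial_seed = 57)
  proj <- fit_cca(tr$envelope, tr$eeg)
  wc <- window_config(128, 64)
  Wi <- segment(tr$envelope, wc)
  Wo <- segment(project_eeg(tr$eeg, proj), wc)
  bi <- fit_klt(Wi, 20)
  bo <- fit_klt(Wo, 20)
  boa <- align_klt(bo, bi)
  # same reconstruction error: alignment only rotates within blocks
  err0 <- norm(Wo$data - klt_reconstruct(klt_project(Wo, bo), bo)$data, "F")
  err1 <- norm(Wo$data - klt_reconstruct(klt_project(Wo, boa), boa)$data, "F")
  expect_equal(err0, err1, tolerance = 1e-9)
  # orthonormality preserved, component correspondence improved
  expect_lt(norm(crossprod(boa$basis) - diag(20), "F"), 1e-8)
  al0 <- mean(abs(diag(crossprod(bi$basis, bo$basis))))
  al1 <- mean(abs(diag(crossprod(bi$basis, boa$basis))))
  expect_gte(al1, al0)
})
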