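#' Fit linear CCA between a 1-D stimulus and multichannel EEG
#'
#' With a one-dimensional stimulus view, canonical correlation analysis
#' reduces to a single EEG spatial filter: the unit-norm vector `b`
#' maximizing the Pearson correlation between the stimulus and the filtered,
#' centered EEG. The maximizer has the closed form
#' `b ~ (C_yy + lambda I)^{-1} c_yx`, where `C_yy` is the EEG channel
#' covariance and `c_yx` the EEG/stimulus cross-covariance. The sign of `b`
#' is chosen so the canonical correlation `rho_1` is nonnegative.
#'
#' The stimulus-side canonical transform is an affine rescaling, which a
#' Pearson correlation ignores; the stimulus standard deviation is recorded
#' as `stim_scale` but never applied.
#'
#' @param stim Numeric stimulus vector of length `T`.
#' @param eeg Numeric `C x T` EEG matrix, `T > C`.
#' @param lambda Ridge regularizer added to the EEG covariance diagonal.
#'   Default `1e-6 * trace(C_yy) / C`, a small multiple of the mean channel
#'   variance for numerical safety. Use `lambda = 0` for the unregularized
#'   solution (errors if the covariance is singular).
#'
#' @return An object of class `sc_cca` with fields `spatial_filter`
#'   (unit norm), `canonical_corr`, `eeg_means`, `stim_mean`, `stim_scale`
#'   and `lambda`.
#' @export
fit_cca <- function(stim, eeg, lambda = NULL) {
  stim <- as.numeric(stim)
  if (!is.matrix(eeg)) eeg <- matrix(as.numeric(eeg), nrow = 1L)
  C <- nrow(eeg)
  T_ <- ncol(eeg)
  if (length(stim) != T_) {
    stop("stimulus length (", length(stim), ") does not match EEG time ",
         "dimension (", T_, ")")
  }
  if (T_ <= C) {
    stop("ill-posed CCA: need more time samples (", T_,
         ") than channels (", C, ")")
  }
  if (!all(is.finite(stim)) || !all(is.finite(eeg))) {
    stop("non-finite values in CCA inputs")
  }
  if (stats::sd(stim) == 0) stop("stimulus has zero variance")
  eeg_means <- rowMeans(eeg)
  stim_mean <- mean(stim)
  Yc <- eeg - eeg_means
  xc <- stim - stim_mean
  Cyy <- tcrossprod(Yc) / (T_ - 1)
  cyx <- as.vector(Yc %*% xc) / (T_ - 1)
  if (is.null(lambda)) lambda <- 1e-6 * sum(diag(Cyy)) / C
  stopifnot(lambda >= 0)
  A <- Cyy + diag(lambda, C)
  b <- tryCatch(solve(A, cyx), error = function(e) {
    stop("EEG covariance is singular; refit with lambda > 0 (",
         conditionMessage(e), ")")
  })
  nb <- sqrt(sum(b^2))
  if (nb == 0) {
    # no linear relation at all: fall back to first channel direction
    b <- c(1, rep(0, C - 1L))
  } else {
    b <- b / nb
  }
  proj <- as.vector(crossprod(b, Yc))
  rho <- if (stats::sd(proj) == 0) 0 else stats::cor(stim, proj)
  if (rho < 0) {
    b <- -b
    rho <- -rho
  }
  structure(
    list(spatial_filter = b, canonical_corr = rho, eeg_means = eeg_means,
         stim_mean = stim_mean, stim_scale = stats::sd(stim),
         lambda = lambda),
    class = "sc_cca"
  )
}

#' @export
print.sc_cca <- function(x, ...) {
  cat(sprintf("<sc_cca> %d-channel spatial filter, canonical correlation %.4f (lambda = %.3g)\n",
              length(x$spatial_filter), x$canonical_corr, x$lambda))
  invisible(x)
}

#' Project multichannel EEG onto the CCA spatial filter
#'
#' Returns `b' (eeg - training channel means)`: the one-dimensional EEG view
#' that is maximally correlated with the stimulus on the training data.
#'
#' @param eeg Numeric `C x T` matrix with the channel count the filter was
#'   fit on.
#' @param proj An `sc_cca` from [fit_cca()].
#' @return Numeric vector of length `T`.
#' @export
project_eeg <- function(eeg, proj) {
  stopifnot(inherits(proj, "sc_cca"))
  if (!is.matrix(eeg)) eeg <- matrix(as.numeric(eeg), nrow = 1L)
  if (nrow(eeg) != length(proj$spatial_filter)) {
    stop("EEG has ", nrow(eeg), " channels but the projection was fit on ",
         length(proj$spatial_filter))
  }
  as.vector(crossprod(proj$spatial_filter, eeg - proj$eeg_means))
}

#' Linear-CCA baseline correlation on a trial
#'
#' The per-trial Pearson correlation between the stimulus and the
#' CCA-projected EEG; averaged per subject this is the linear baseline
#' against which the network is compared.
#'
#' @param stim Stimulus vector.
#' @param eeg `C x T` EEG matrix aligned with `stim`.
#' @param proj An `sc_cca`.
#' @return Correlation in [-1, 1].
#' @export
baseline_correlation <- function(stim, eeg, proj) {
  stim <- as.numeric(stim)
  y <- project_eeg(eeg, proj)
  if (length(stim) != length(y)) {
    stop("stimulus and EEG lengths differ (", length(stim), " vs ",
         length(y), ")")
  }
  pearson(stim, y)
}
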