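#' Windowing configuration
#'
#' @param w Window length in samples.
#' @param o Number of overlapping samples, `0 <= o < w`. The hop between
#'   consecutive windows is `w - o`.
#' @return An object of class `sc_window_config`.
#' @export
window_config <- function(w, o) {
  w <- as.integer(w); o <- as.integer(o)
  if (is.na(w) || w < 1L) stop("window size w must be a positive integer")
  if (is.na(o) || o < 0L || o >= w) stop("overlap o must satisfy 0 <= o < w")
  structure(list(w = w, o = o), class = "sc_window_config")
}

#' Split a 1-D signal into overlapping rectangular windows
#'
#' Window `n` (0-based) holds samples `(w-o)n .. (w-o)n + w - 1` (0-based
#' inclusive). The number of windows is `floor((T - w) / (w - o)) + 1`;
#' trailing samples that do not fill a window are dropped.
#'
#' @param signal Numeric vector of length `T >= w`.
#' @param cfg An [window_config()].
#' @param subject_id,trial_id Optional provenance identifiers recorded per
#'   row.
#' @return An object of class `sc_windows`: a list with the `N x w` matrix
#'   `data`, a `provenance` data frame (`subject_id`, `trial_id`,
#'   `start_sample`, 0-based) and the window parameters `w`, `o`.
#' @export
segment <- function(signal, cfg, subject_id = NA_character_,
                    trial_id = NA_integer_) {
  stopifnot(inherits(cfg, "sc_window_config"))
  signal <- as.numeric(signal)
  T_ <- length(signal)
  w <- cfg$w; o <- cfg$o
  if (T_ < w) {
    stop("signal too short to window: T = ", T_, " < w = ", w)
  }
  hop <- w - o
  N <- (T_ - w) %/% hop + 1L
  starts <- (seq_len(N) - 1L) * hop
  data <- matrix(0, N, w)
  for (n in seq_len(N)) {
    data[n, ] <- signal[(starts[n] + 1L):(starts[n] + w)]
  }
  structure(
    list(data = data,
         provenance = data.frame(subject_id = rep(subject_id, N),
                                 trial_id = rep(as.integer(trial_id), N),
                                 start_sample = starts,
                                 stringsAsFactors = FALSE),
         w = w, o = o),
    class = "sc_windows"
  )
}

#' Concatenate window matrices from several trials or subjects
#'
#' Rows are stacked in deterministic (subject, trial, start sample) order,
#' with provenance preserved.
#'
#' @param windows_list List of `sc_windows` with equal window length.
#' @return A single `sc_windows`.
#' @export
concat_windows <- function(windows_list) {
  stopifnot(is.list(windows_list))
  windows_list <- Filter(Negate(is.null), windows_list)
  if (length(windows_list) == 0L) {
    return(structure(
      list(data = matrix(0, 0L, 0L),
           provenance = data.frame(subject_id = character(0),
                                   trial_id = integer(0),
                                   start_sample = integer(0),
                                   stringsAsFactors = FALSE),
           w = NA_integer_, o = NA_integer_),
      class = "sc_windows"
    ))
  }
  ok <- vapply(windows_list, inherits, logical(1), what = "sc_windows")
  if (!all(ok)) stop("all elements must be sc_windows objects")
  ws <- vapply(windows_list, function(x) x$w, integer(1))
  if (length(unique(ws)) != 1L) {
    stop("mixed window lengths: ", paste(unique(ws), collapse = ", "))
  }
  data <- do.call(rbind, lapply(windows_list, function(x) x$data))
  prov <- do.call(rbind, lapply(windows_list, function(x) x$provenance))
  ord <- order(prov$subject_id, prov$trial_id, prov$start_sample)
  structure(
    list(data = data[ord, , drop = FALSE],
         provenance = prov[ord, , drop = FALSE],
         w = windows_list[[1L]]$w, o = windows_list[[1L]]$o),
    class = "sc_windows"
  )
}

as_window_matrix <- function(X) {
  if (inherits(X, "sc_windows")) X$data else as.matrix(X)
}

#' Fit a truncated discrete Karhunen-Loeve (PCA) basis to windows
#'
#' Computes the singular value decomposition `X = U S V'` of the (optionally
#' mean-centered) window matrix and keeps the first `p` right singular
#' vectors as an orthonormal feature basis. Centering by the training-window
#' mean is the default (the PCA convention); `center = FALSE` applies the
#' transform to the raw windows. Each basis column's sign is fixed so its
#' largest-magnitude element is positive, making fits reproducible.
#'
#' @param X An `sc_windows` or plain `N x w` matrix with `N >= 2`.
#' @param p Number of components to retain, `1 <= p <= min(N, w)`.
#' @param center Subtract the column mean before the SVD (default `TRUE`).
#' @return An object of class `sc_klt`: `mean` (length `w`), `basis`
#'   (`w x p`, orthonormal columns), `singular_values` (full, nonincreasing),
#'   `p`, `w`, `center`.
#' @export
fit_klt <- function(X, p, center = TRUE) {
  M <- as_window_matrix(X)
  N <- nrow(M); w <- ncol(M)
  if (N < 2L) stop("need at least 2 windows to fit a basis")
  p <- as.integer(p)
  if (p < 1L || p > min(N, w)) {
    stop("p = ", p, " out of range; must satisfy 1 <= p <= min(N, w) = ",
         min(N, w))
  }
  mu <- if (center) colMeans(M) else rep(0, w)
  Mc <- sweep(M, 2L, mu)
  sv <- svd(Mc)
  V <- sv$v
  # deterministic sign: largest-magnitude element of each column positive
  for (j in seq_len(ncol(V))) {
    k <- which.max(abs(V[, j]))
    if (V[k, j] < 0) V[, j] <- -V[, j]
  }
  structure(
    list(mean = mu, basis = V[, seq_len(p), drop = FALSE],
         singular_values = sv$d, p = p, w = w, n_windows = N,
         center = center),
    class = "sc_klt"
  )
}

#' Align a KLT basis to a reference basis within degenerate blocks
#'
#' The retained components of a truncated KLT are only defined up to
#' rotation wherever singular values are equal, and for stationary windowed
#' signals the spectrum is full of near-degenerate (quasi-Fourier sine and
#' cosine) pairs: two bases fitted on two noisy realizations of the same
#' underlying signal then differ by essentially arbitrary rotations inside
#' those blocks, even though they span the same subspace. This breaks any
#' component-by-component correspondence between an input-view basis and an
#' output-view basis.
#'
#' `align_klt` fixes this gauge freedom deterministically: consecutive
#' components whose relative singular-value gap is below `gap_tol` are
#' grouped into a block, and each block of `basis` is rotated by orthogonal
#' Procrustes onto the same-index columns of `reference`. Rotations act
#' within blocks only, so the spanned subspace -- and therefore the
#' reconstruction error of the basis -- is unchanged; singleton blocks reduce
#' to a sign flip. The default tolerance `sqrt(2 / n_windows)` is the
#' relative sampling-error scale of the singular values, i.e. components are
#' treated as degenerate when the data cannot statistically order them.
#'
#' @param basis The `sc_klt` to align (e.g. the output-window basis).
#' @param reference The `sc_klt` to align to (e.g. the input-window basis),
#'   with the same window length and at least as many components.
#' @param gap_tol Relative singular-value gap below which consecutive
#'   components are treated as degenerate; default `sqrt(2 / n_windows)`.
#' @return `basis` with rotated/sign-fixed columns.
#' @export
align_klt <- function(basis, reference, gap_tol = NULL) {
  stopifnot(inherits(basis, "sc_klt"), inherits(reference, "sc_klt"))
  if (basis$w != reference$w) stop("window lengths differ")
  if (reference$p < basis$p) stop("reference basis has fewer components")
  if (is.null(gap_tol)) gap_tol <- sqrt(2 / basis$n_windows)
  p <- basis$p
  sv <- basis$singular_values[seq_len(p)]
  blocks <- if (p > 1L) {
    rel_gap <- (sv[-p] - sv[-1L]) / pmax(sv[-p], .Machine$double.eps)
    cumsum(c(1L, as.integer(rel_gap > gap_tol)))
  } else {
    1L
  }
  for (g in unique(blocks)) {
    J <- which(blocks == g)
    if (length(J) == 1L) {
      if (sum(basis$basis[, J] * reference$basis[, J]) < 0) {
        basis$basis[, J] <- -basis$basis[, J]
      }
    } else {
      M <- crossprod(basis$basis[, J, drop = FALSE],
                     reference$basis[, J, drop = FALSE])
      s <- svd(M)
      basis$basis[, J] <- basis$basis[, J, drop = FALSE] %*%
        (s$u %*% t(s$v))
    }
  }
  basis
}

#' @export
print.sc_klt <- function(x, ...) {
  energy <- sum(x$singular_values[seq_len(x$p)]^2) / sum(x$singular_values^2)
  cat(sprintf("<sc_klt> %d of %d components (%.1f%% energy), %scentered\n",
              x$p, x$w, 100 * energy, if (x$center) "" else "un"))
  invisible(x)
}

#' Project windows onto a KLT basis
#'
#' Computes `F = (X - mean) V_p`, the coordinates of each window in the
#' truncated basis.
#'
#' @param X An `sc_windows` (or matrix) with window length matching `basis`.
#' @param basis An `sc_klt`.
#' @return An object of class `sc_features`: `data` (`N x p`), `provenance`,
#'   and the originating `w`, `o`, `p`.
#' @export
klt_project <- function(X, basis) {
  stopifnot(inherits(basis, "sc_klt"))
  M <- as_window_matrix(X)
  if (ncol(M) != basis$w) {
    stop("window length ", ncol(M), " does not match basis (", basis$w, ")")
  }
  F_ <- sweep(M, 2L, basis$mean) %*% basis$basis
  prov <- if (inherits(X, "sc_windows")) X$provenance else NULL
  o <- if (inherits(X, "sc_windows")) X$o else NA_integer_
  structure(list(data = F_, provenance = prov, w = basis$w, o = o,
                 p = basis$p),
            class = "sc_features")
}

#' Reconstruct windows from truncated KLT features
#'
#' Computes `Xhat = F V_p' + mean`. With `p = w` this inverts
#' [klt_project()] exactly; with `p < w` the residual is orthogonal to the
#' retained basis.
#'
#' @param F_ An `sc_features` (or `N x p` matrix).
#' @param basis The `sc_klt` used for projection.
#' @return An `sc_windows` holding the reconstructed `N x w` windows.
#' @export
klt_reconstruct <- function(F_, basis) {
  stopifnot(inherits(basis, "sc_klt"))
  M <- if (inherits(F_, "sc_features")) F_$data else as.matrix(F_)
  if (ncol(M) != basis$p) {
    stop("feature width ", ncol(M), " does not match basis p = ", basis$p)
  }
  X <- M %*% t(basis$basis)
  X <- sweep(X, 2L, basis$mean, FUN = "+")
  prov <- if (inherits(F_, "sc_features") && !is.null(F_$provenance)) {
    F_$provenance
  } else {
    data.frame(subject_id = rep(NA_character_, nrow(X)),
               trial_id = rep(NA_integer_, nrow(X)),
               start_sample = rep(NA_integer_, nrow(X)),
               stringsAsFactors = FALSE)
  }
  o <- if (inherits(F_, "sc_features")) F_$o else NA_integer_
  structure(list(data = X, provenance = prov, w = basis$w, o = o),
            class = "sc_windows")
}

#' Overlap-add reconstruction of a 1-D signal from windows
#'
#' Inverts [segment()] over the covered span: windows are laid out at their
#' recorded start samples and overlapping samples are averaged with equal
#' weights, so unmodified windows reproduce the original signal exactly on
#' samples `0 .. (w-o)(N-1) + w - 1`.
#'
#' @param X An `sc_windows` whose provenance rows belong to one contiguous
#'   (subject, trial) segment with uniform hop `w - o`.
#' @param cfg Optional [window_config()] overriding the `w`, `o` stored in
#'   `X`.
#' @return Numeric vector of length `(w-o)(N-1) + w`.
#' @export
overlap_add <- function(X, cfg = NULL) {
  stopifnot(inherits(X, "sc_windows"))
  w <- if (!is.null(cfg)) cfg$w else X$w
  o <- if (!is.null(cfg)) cfg$o else X$o
  if (is.na(w) || is.na(o)) stop("window parameters unavailable")
  M <- X$data
  N <- nrow(M)
  if (N < 1L) stop("no windows to reconstruct")
  hop <- w - o
  starts <- X$provenance$start_sample
  if (!any(is.na(starts))) {
    if (N > 1L && any(diff(starts) != hop)) {
      stop("non-uniform window spacing in provenance; expected hop ", hop)
    }
  } else {
    starts <- (seq_len(N) - 1L) * hop
  }
  starts <- starts - starts[1L]
  out_len <- hop * (N - 1L) + w
  acc <- numeric(out_len)
  cnt <- numeric(out_len)
  for (n in seq_len(N)) {
    idx <- (starts[n] + 1L):(starts[n] + w)
    acc[idx] <- acc[idx] + M[n, ]
    cnt[idx] <- cnt[idx] + 1
  }
  acc / cnt
}

#' Suggest a truncation order from the singular-value profile
#'
#' Returns the smallest `p` whose leading components carry at least
#' `threshold` of the total squared singular-value energy, together with the
#' full energy table for scree inspection. Advisory only: the pipeline uses
#' the configured `n_components` regardless.
#'
#' @param sv Nonincreasing vector of singular values.
#' @param threshold Cumulative energy fraction to reach (default 0.95).
#' @return A list with `p` and a data frame `table` (component, sigma,
#'   energy fraction, cumulative fraction).
#' @export
scree <- function(sv, threshold = 0.95) {
  sv <- as.numeric(sv)
  if (length(sv) == 0L) stop("empty singular-value vector")
  if (any(diff(sv) > 1e-12)) stop("singular values must be nonincreasing")
  e <- sv^2
  total <- sum(e)
  frac <- if (total > 0) e / total else rep(0, length(e))
  cum <- cumsum(frac)
  p <- which(cum >= threshold)[1L]
  if (is.na(p)) p <- length(sv)
  list(p = as.integer(p),
       table = data.frame(component = seq_along(sv), sigma = sv,
                          energy_fraction = frac, cumulative = cum))
}
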