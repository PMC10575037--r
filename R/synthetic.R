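#' Configuration for the synthetic envelope/EEG generator
#'
#' Defines the study conditions emulated by the generator: a smooth
#' nonnegative 1-8 Hz speech-envelope surrogate drives `n_channels` EEG-like
#' channels through per-channel gains `mixing`, an optional sample lag and a
#' coupling nonlinearity, on top of spatially correlated Gaussian noise and
#' sparse high-amplitude artifact bursts.
#'
#' The noise model is equicorrelated: channel noise has standard deviation
#' `noise_sigma` and every channel pair shares correlation
#' `noise_spatial_corr`. Artifacts arrive as a Poisson process at
#' `artifact_rate` bursts per minute; each burst is a 0.25 s raised-cosine
#' bump of amplitude `artifact_amp * noise_sigma` with random sign, added to a
#' random quarter of the channels.
#'
#' @param n_subjects Number of subjects to simulate.
#' @param n_trials Trials per subject (default 20, matching typical
#'   listening-experiment designs).
#' @param fs Sampling rate in Hz (default 128).
#' @param duration_s Trial duration in seconds.
#' @param n_channels Number of EEG channels `C` (default 16; use 128 to mimic
#'   a high-density montage).
#' @param mixing Numeric vector of per-channel response gains `a_c`
#'   (length `C`). Default: exponentially decaying gains `exp(-(c-1)/4)`,
#'   i.e. a few strongly coupled channels and many weak ones.
#' @param lag_samples Nonnegative integer response latency in samples.
#' @param coupling One of `"linear"`, `"tanh"`, `"quadratic"`.
#' @param coupling_gain Slope used inside the nonlinear couplings.
#' @param noise_sigma Noise standard deviation (> 0 unless noiseless).
#' @param noise_spatial_corr Common inter-channel noise correlation in [0,1).
#' @param artifact_rate Artifact bursts per minute (>= 0).
#' @param artifact_amp Burst amplitude in units of `noise_sigma`.
#' @param seed Integer master seed; all per-trial seeds derive from it.
#'
#' @return An object of class `sc_synth_config`.
#' @export
synth_config <- function(n_subjects = 1L, n_trials = 20L, fs = 128,
                         duration_s = 60, n_channels = 16L, mixing = NULL,
                         lag_samples = 0L,
                         coupling = c("linear", "tanh", "quadratic"),
                         coupling_gain = 2, noise_sigma = 1,
                         noise_spatial_corr = 0.2, artifact_rate = 2,
                         artifact_amp = 8, seed = 1L) {
  coupling <- match.arg(coupling)
  if (is.null(mixing)) mixing <- exp(-(seq_len(n_channels) - 1) / 4)
  stopifnot(
    n_subjects >= 1L, n_trials >= 1L, fs > 0, duration_s > 0,
    n_channels >= 1L, length(mixing) == n_channels,
    lag_samples >= 0L, noise_sigma >= 0,
    noise_spatial_corr >= 0, noise_spatial_corr < 1,
    artifact_rate >= 0, artifact_amp >= 0
  )
  structure(
    list(n_subjects = as.integer(n_subjects), n_trials = as.integer(n_trials),
         fs = fs, duration_s = duration_s, n_channels = as.integer(n_channels),
         mixing = as.numeric(mixing), lag_samples = as.integer(lag_samples),
         coupling = coupling, coupling_gain = coupling_gain,
         noise_sigma = noise_sigma, noise_spatial_corr = noise_spatial_corr,
         artifact_rate = artifact_rate, artifact_amp = artifact_amp,
         seed = as.integer(seed)),
    class = "sc_synth_config"
  )
}

#' Generate a synthetic speech-envelope surrogate
#'
#' Band-limited (1-8 Hz) Gaussian noise is rectified, smoothed with a 50 ms
#' moving average and rescaled to unit standard deviation. The result is a
#' nonnegative, slowly varying signal whose spectral energy is concentrated in
#' the delta/theta range where cortical envelope tracking is strongest.
#'
#' @param duration_s Duration in seconds (> 0).
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed; the same seed reproduces the same envelope.
#'
#' @return Numeric vector of length `round(duration_s * fs)` with unit
#'   standard deviation.
#' @export
make_envelope <- function(duration_s, fs = 128, seed = 1L) {
  if (duration_s <= 0) stop("duration_s must be positive")
  n <- round(duration_s * fs)
  if (n < 1L) stop("duration_s * fs must be at least 1")
  withr::with_seed(seed, {
    x <- stats::rnorm(n)
    freq <- (seq_len(n) - 1) * fs / n
    # two-sided band mask for 1-8 Hz
    f_fold <- pmin(freq, fs - freq)
    mask <- f_fold >= 1 & f_fold <= 8
    if (!any(mask)) mask[2L] <- TRUE  # degenerate very short signals
    x_band <- Re(stats::fft(stats::fft(x) * mask, inverse = TRUE)) / n
    env <- abs(x_band)
    k <- max(1L, round(0.05 * fs))
    env <- as.numeric(stats::filter(env, rep(1 / k, k), sides = 2,
                                    circular = TRUE))
    s <- stats::sd(env)
    if (s > 0) env <- env / s
    env
  })
}

coupling_fun <- function(config) {
  switch(config$coupling,
         linear = function(s) s,
         tanh = function(s) tanh(config$coupling_gain * (s - mean(s))),
         quadratic = function(s) (s - mean(s))^2)
}

#' Generate one synthetic trial from an envelope
#'
#' Each channel is `a_c * g(s(t - lag)) + noise + artifacts`, where `g` is the
#' configured coupling function, the noise is equicorrelated Gaussian and the
#' artifacts are sparse raised-cosine bursts (see [synth_config()]). The
#' lagged envelope is zero-padded at the start.
#'
#' @param envelope Numeric stimulus envelope (typically [make_envelope()]).
#' @param config An `sc_synth_config`.
#' @param trial_seed Integer seed for the noise and artifact draws.
#' @param subject_id,trial_id Identifiers stored in the returned trial.
#'
#' @return An [trial()] object.
#' @export
make_trial <- function(envelope, config, trial_seed = 1L,
                       subject_id = "S01", trial_id = 1L) {
  stopifnot(inherits(config, "sc_synth_config"))
  n <- length(envelope)
  if (config$lag_samples >= n) {
    stop("lag_samples (", config$lag_samples,
         ") must be smaller than the envelope length (", n, ")")
  }
  C <- config$n_channels
  tau <- config$lag_samples
  s_lag <- if (tau > 0) c(rep(0, tau), envelope[seq_len(n - tau)]) else envelope
  z <- coupling_fun(config)(s_lag)
  eeg <- config$mixing %o% z
  withr::with_seed(trial_seed, {
    if (config$noise_sigma > 0) {
      r <- config$noise_spatial_corr
      shared <- stats::rnorm(n)
      indep <- matrix(stats::rnorm(C * n), C, n)
      noise <- config$noise_sigma *
        (sqrt(r) * rep(1, C) %o% shared + sqrt(1 - r) * indep)
      eeg <- eeg + noise
    }
    if (config$artifact_rate > 0 && config$artifact_amp > 0) {
      n_bursts <- stats::rpois(1L, config$artifact_rate * n / config$fs / 60)
      dur <- max(2L, round(0.25 * config$fs))
      bump <- 0.5 * (1 - cos(2 * pi * seq_len(dur) / (dur + 1)))
      amp <- config$artifact_amp * config$noise_sigma
      for (b in seq_len(n_bursts)) {
        onset <- sample.int(max(1L, n - dur), 1L)
        chans <- sample.int(C, max(1L, round(C / 4)))
        idx <- onset:(onset + dur - 1L)
        for (ch in chans) {
          eeg[ch, idx] <- eeg[ch, idx] + sample(c(-1, 1), 1L) * amp * bump
        }
      }
    }
  })
  trial(subject_id, trial_id, envelope, eeg, fs = config$fs)
}

# deterministic per-(subject, trial) seed derivation, kept below 2^31
derive_seed <- function(seed, subject, trial_i, salt = 0L) {
  as.integer((as.double(seed) + 7919 * subject + 104729 * trial_i +
                15485863 * salt) %% 2147483587)
}

#' Generate a full synthetic dataset
#'
#' Produces `n_subjects` subject datasets of `n_trials` trials each. Per-trial
#' envelope and noise seeds are derived deterministically from `config$seed`,
#' so the same configuration always yields the same data.
#'
#' @param config An `sc_synth_config`.
#' @return Named list of `sc_subject` objects (`S01`, `S02`, ...).
#' @export
make_dataset <- function(config) {
  stopifnot(inherits(config, "sc_synth_config"))
  subjects <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    sid <- sprintf("S%02d", i)
    trials <- vector("list", config$n_trials)
    for (j in seq_len(config$n_trials)) {
      env <- make_envelope(config$duration_s, config$fs,
                           seed = derive_seed(config$seed, i, j, salt = 1L))
      trials[[j]] <- make_trial(env, config,
                                trial_seed = derive_seed(config$seed, i, j,
                                                         salt = 2L),
                                subject_id = sid, trial_id = j)
    }
    subjects[[i]] <- subject_dataset(sid, trials, fs = config$fs)
  }
  names(subjects) <- vapply(subjects, function(s) s$subject_id, character(1))
  subjects
}

#' Theoretical maximal envelope/EEG correlation for linear synthetic data
#'
#' For linear coupling at lag 0 with artifacts disabled, the coupled component
#' equals the (unit-variance) envelope, so the best linear spatial filter `w`
#' maximizes `corr(s, w'eeg)`. The maximum is attained at
#' `w* = Sigma^{-1} a` and equals `rho* = sqrt(SNR / (1 + SNR))` with
#' `SNR = a' Sigma^{-1} a`, where `a` is the mixing vector and `Sigma` the
#' equicorrelated noise covariance
#' `sigma^2 [(1-r) I + r 11']`. Both quantities are evaluated in closed form
#' (Sherman-Morrison inverse).
#'
#' @param config An `sc_synth_config` with `coupling = "linear"`,
#'   `lag_samples = 0` and `artifact_rate = 0`.
#' @return `rho*` in [0, 1], with the optimal unit-norm spatial filter
#'   attached as attribute `"filter"`.
#' @export
oracle_correlation <- function(config) {
  stopifnot(inherits(config, "sc_synth_config"))
  if (config$coupling != "linear") {
    stop("oracle_correlation supports linear coupling only")
  }
  if (config$lag_samples != 0L) {
    stop("oracle_correlation requires lag_samples = 0")
  }
  if (config$artifact_rate > 0 && config$artifact_amp > 0) {
    stop("oracle_correlation requires artifacts disabled")
  }
  a <- config$mixing
  C <- config$n_channels
  sigma2 <- config$noise_sigma^2
  r <- config$noise_spatial_corr
  if (sigma2 == 0) {
    if (all(a == 0)) return(structure(0, filter = rep(0, C)))
    w <- a / sqrt(sum(a^2))
    return(structure(1, filter = w))
  }
  # Sigma^{-1} a via Sherman-Morrison on sigma^2[(1-r)I + r 11']
  sia <- (a - r * sum(a) / (1 - r + C * r)) / (sigma2 * (1 - r))
  snr <- sum(a * sia)
  rho <- sqrt(snr / (1 + snr))
  w <- if (all(sia == 0)) rep(0, C) else sia / sqrt(sum(sia^2))
  structure(rho, filter = w)
}
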