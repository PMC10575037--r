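#' Construct a single stimulus/response trial
#'
#' A trial pairs one continuous stimulus envelope with the simultaneously
#' recorded multichannel EEG. The envelope is a nonnegative amplitude
#' modulation sampled at `fs` Hz; the EEG is a channels-by-time matrix on the
#' same time base, so `ncol(eeg)` must equal `length(envelope)`.
#'
#' @param subject_id Character scalar identifying the subject.
#' @param trial_id Integer scalar identifying the trial within the subject.
#' @param envelope Numeric vector of length `T` (stimulus envelope).
#' @param eeg Numeric matrix with `C` rows (channels) and `T` columns.
#' @param fs Sampling rate in Hz shared by both views (default 128).
#'
#' @return An object of class `sc_trial`.
#' @export
#' @examples
#' tr <- trial("S01", 1, abs(sin(seq(0, 2, length.out = 256))),
#'             matrix(rnorm(4 * 256), 4, 256))
trial <- function(subject_id, trial_id, envelope, eeg, fs = 128) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  trial_id <- as.integer(trial_id)
  stopifnot(length(trial_id) == 1L, !is.na(trial_id))
  envelope <- as.numeric(envelope)
  if (!is.matrix(eeg)) eeg <- matrix(as.numeric(eeg), nrow = 1L)
  storage.mode(eeg) <- "double"
  if (length(envelope) < 1L) stop("trial ", trial_id, ": envelope is empty")
  if (nrow(eeg) < 1L) stop("trial ", trial_id, ": EEG has no channels")
  if (ncol(eeg) != length(envelope)) {
    stop("trial ", trial_id, ": envelope length (", length(envelope),
         ") does not match EEG time dimension (", ncol(eeg), ")")
  }
  structure(
    list(subject_id = subject_id, trial_id = trial_id, fs = fs,
         envelope = envelope, eeg = eeg),
    class = "sc_trial"
  )
}

#' @export
print.sc_trial <- function(x, ...) {
  cat(sprintf("<sc_trial> subject %s, trial %d: %d channels x %d samples @ %g Hz\n",
              x$subject_id, x$trial_id, nrow(x$eeg), ncol(x$eeg), x$fs))
  invisible(x)
}

#' Construct a subject dataset
#'
#' Bundles the trials of one subject. All trials must share the sampling rate
#' and channel count; trials are stored sorted by `trial_id`.
#'
#' @param subject_id Character scalar.
#' @param trials List of [trial()] objects.
#' @param fs Sampling rate in Hz; defaults to the rate of the first trial.
#'
#' @return An object of class `sc_subject`.
#' @export
subject_dataset <- function(subject_id, trials, fs = NULL) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L, is.list(trials))
  if (length(trials) > 0L) {
    ok <- vapply(trials, inherits, logical(1), what = "sc_trial")
    if (!all(ok)) stop("all elements of `trials` must be sc_trial objects")
    ids <- vapply(trials, function(t) t$trial_id, integer(1))
    trials <- trials[order(ids)]
    if (is.null(fs)) fs <- trials[[1L]]$fs
  } else if (is.null(fs)) {
    fs <- 128
  }
  structure(list(subject_id = subject_id, trials = trials, fs = fs),
            class = "sc_subject")
}

#' @export
print.sc_subject <- function(x, ...) {
  cat(sprintf("<sc_subject> %s: %d trial(s) @ %g Hz\n",
              x$subject_id, length(x$trials), x$fs))
  invisible(x)
}

#' Validate a subject dataset
#'
#' Checks every container invariant and returns a report instead of throwing:
#' envelope/EEG length agreement, finiteness of all values, at least one
#' channel and one sample per trial, a consistent channel count and sampling
#' rate across trials, and unique trial ids.
#'
#' @param dataset An `sc_subject`.
#'
#' @return A data frame with columns `trial_id`, `field`, `message`; zero rows
#'   if and only if every invariant holds.
#' @export
validate_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "sc_subject"))
  violations <- list()
  note <- function(trial_id, field, message) {
    violations[[length(violations) + 1L]] <<-
      data.frame(trial_id = trial_id, field = field, message = message,
                 stringsAsFactors = FALSE)
  }
  ids <- vapply(dataset$trials, function(t) t$trial_id, integer(1))
  if (anyDuplicated(ids)) {
    note(NA_integer_, "trial_id",
         paste("duplicated trial ids:",
               paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  n_channels <- NA_integer_
  for (tr in dataset$trials) {
    tid <- tr$trial_id
    if (length(tr$envelope) != ncol(tr$eeg)) {
      note(tid, "envelope",
           sprintf("envelope length %d != EEG time dimension %d",
                   length(tr$envelope), ncol(tr$eeg)))
    }
    if (length(tr$envelope) < 1L) note(tid, "envelope", "empty envelope")
    if (nrow(tr$eeg) < 1L) note(tid, "eeg", "no channels")
    if (!all(is.finite(tr$envelope))) {
      note(tid, "envelope", "non-finite values in envelope")
    }
    if (!all(is.finite(tr$eeg))) {
      note(tid, "eeg", "non-finite values in EEG")
    }
    if (!isTRUE(all.equal(tr$fs, dataset$fs))) {
      note(tid, "fs", sprintf("trial fs %g differs from subject fs %g",
                              tr$fs, dataset$fs))
    }
    if (is.na(n_channels)) {
      n_channels <- nrow(tr$eeg)
    } else if (nrow(tr$eeg) != n_channels) {
      note(tid, "eeg", sprintf("channel count %d differs from first trial (%d)",
                               nrow(tr$eeg), n_channels))
    }
  }
  if (length(violations) == 0L) {
    return(data.frame(trial_id = integer(0), field = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, violations)
}
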