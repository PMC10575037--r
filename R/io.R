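#' Save a subject dataset in the portable on-disk layout
#'
#' The portable layout is one directory per subject holding a plain-text JSON
#' metadata file (`subject.json`: subject id, sampling rate, channel count and
#' a per-trial file table) and one flat binary file per trial. Each trial file
#' stores a `(C+1) x T` double matrix column-major, little-endian: row 1 is
#' the envelope, rows 2..C+1 the EEG channels. Doubles are written verbatim,
#' so a save/load round trip is bit-exact.
#'
#' @param dataset An `sc_subject`.
#' @param path Directory to write to (created if needed).
#'
#' @return Invisibly, a character vector manifest of the files written
#'   (metadata file first).
#' @export
save_subject <- function(dataset, path) {
  stopifnot(inherits(dataset, "sc_subject"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create directory: ", path)
  n_channels <- if (length(dataset$trials) > 0L) {
    nrow(dataset$trials[[1L]]$eeg)
  } else {
    NA_integer_
  }
  trial_meta <- lapply(dataset$trials, function(tr) {
    list(trial_id = tr$trial_id,
         file = sprintf("trial_%04d.bin", tr$trial_id),
         n_samples = ncol(tr$eeg))
  })
  meta <- list(format = "stimcorr-portable-v1",
               subject_id = dataset$subject_id,
               fs = dataset$fs,
               n_channels = n_channels,
               trials = trial_meta)
  meta_path <- file.path(path, "subject.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  written <- meta_path
  for (tr in dataset$trials) {
    f <- file.path(path, sprintf("trial_%04d.bin", tr$trial_id))
    con <- file(f, "wb")
    writeBin(as.vector(rbind(tr$envelope, tr$eeg)), con, size = 8L,
             endian = "little")
    close(con)
    written <- c(written, f)
  }
  invisible(written)
}

#' Load a subject dataset
#'
#' Reads a subject saved with [save_subject()]. Trials are returned sorted by
#' trial id, so two loads of the same path yield identical objects.
#'
#' The `public_dataset` layout refers to per-subject MATLAB-style container
#' files distributed with public speech-EEG corpora; reading those containers
#' is not bundled with this package, and requesting that layout raises an
#' informative error. Convert such data to the portable layout first.
#'
#' @param path Subject directory.
#' @param layout Either `"portable"` (default) or `"public_dataset"`.
#'
#' @return An `sc_subject`.
#' @export
load_subject <- function(path, layout = c("portable", "public_dataset")) {
  layout <- match.arg(layout)
  if (layout == "public_dataset") {
    stop("reading MATLAB-style container files is not bundled with this ",
         "package; convert the data to the portable layout (see ",
         "?save_subject) and load with layout = \"portable\"")
  }
  if (!dir.exists(path)) stop("subject directory does not exist: ", path)
  meta_path <- file.path(path, "subject.json")
  if (!file.exists(meta_path)) {
    stop("not a portable subject directory (missing subject.json): ", path)
  }
  meta <- tryCatch(jsonlite::read_json(meta_path, simplifyVector = FALSE),
                   error = function(e) {
                     stop("unreadable subject metadata in ", meta_path, ": ",
                          conditionMessage(e))
                   })
  if (!identical(meta$format, "stimcorr-portable-v1")) {
    stop("unrecognized portable-layout format tag in ", meta_path)
  }
  n_channels <- meta$n_channels
  trials <- lapply(meta$trials, function(tm) {
    f <- file.path(path, tm$file)
    if (!file.exists(f)) {
      stop("missing trial file for trial ", tm$trial_id, ": ", f)
    }
    n_samples <- as.integer(tm$n_samples)
    n_values <- (n_channels + 1L) * n_samples
    expected_bytes <- 8 * n_values
    if (file.info(f)$size != expected_bytes) {
      stop("trial ", tm$trial_id, ": file holds ", file.info(f)$size,
           " bytes but metadata implies ", expected_bytes,
           " (", n_channels, " channels + envelope, ", n_samples, " samples)")
    }
    con <- file(f, "rb")
    on.exit(close(con), add = TRUE)
    values <- readBin(con, what = "double", n = n_values, size = 8L,
                      endian = "little")
    m <- matrix(values, nrow = n_channels + 1L, ncol = n_samples)
    trial(meta$subject_id, tm$trial_id, envelope = m[1L, ],
          eeg = m[-1L, , drop = FALSE], fs = meta$fs)
  })
  subject_dataset(meta$subject_id, trials, fs = meta$fs)
}

#' Save a whole collection of subjects
#'
#' Writes one portable subject directory per element under `path`.
#'
#' @param subjects List of `sc_subject` objects.
#' @param path Parent output directory.
#' @return Invisibly, the subject directories written.
#' @export
save_dataset <- function(subjects, path) {
  dirs <- character(0)
  for (s in subjects) {
    d <- file.path(path, s$subject_id)
    save_subject(s, d)
    dirs <- c(dirs, d)
  }
  invisible(dirs)
}

#' Load every portable subject directory under a path
#'
#' @param path Directory whose subdirectories each hold one portable subject.
#' @return Named list of `sc_subject` objects, sorted by subject id.
#' @export
load_dataset <- function(path) {
  if (!dir.exists(path)) stop("dataset directory does not exist: ", path)
  dirs <- list.dirs(path, recursive = FALSE)
  dirs <- dirs[file.exists(file.path(dirs, "subject.json"))]
  dirs <- sort(dirs)
  if (length(dirs) == 0L) stop("no portable subject directories under ", path)
  subjects <- lapply(dirs, load_subject)
  names(subjects) <- vapply(subjects, function(s) s$subject_id, character(1))
  subjects
}
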