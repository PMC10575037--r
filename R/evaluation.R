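#' Run one leave-one-trial-out fold for a subject
#'
#' Trains the full pipeline on all trials except `test_trial_id` and
#' evaluates on the held-out trial. Training: CCA is fit on the concatenation
#' of the training trials; each training trial's envelope and CCA-projected
#' EEG are windowed; separate KLT bases (input and output) are fit on the
#' training windows only; the network is fit on the projected features.
#' Testing: the held-out EEG is projected with the training CCA, both views
#' are windowed and projected with the training bases, the network predicts
#' the EEG features, the prediction is reconstructed through the output basis
#' and overlap-added back to a time-domain signal, and `rho_proposed` is the
#' Pearson correlation between the held-out envelope (restricted to the
#' covered span) and that predicted signal. `rho_lcca` is the linear baseline
#' correlation on the same held-out trial.
#'
#' The held-out trial never contributes to the CCA, the bases or the network
#' fit.
#'
#' @param subject An `sc_subject` with at least 2 trials.
#' @param test_trial_id Trial id held out for testing.
#' @param config An [run_config()].
#' @return An object of class `sc_fold`: `subject_id`, `test_trial_id`,
#'   `rho_lcca`, `rho_proposed`, with the fitted `sc_cca`, bases and model
#'   attached.
#' @export
run_fold <- function(subject, test_trial_id, config = run_config()) {
  stopifnot(inherits(subject, "sc_subject"), inherits(config, "sc_run_config"))
  ids <- vapply(subject$trials, function(t) t$trial_id, integer(1))
  if (length(ids) < 2L) stop("need at least 2 trials for cross-testing")
  k <- match(as.integer(test_trial_id), ids)
  if (is.na(k)) stop("no trial with id ", test_trial_id, " in subject ",
                     subject$subject_id)
  test <- subject$trials[[k]]
  train <- subject$trials[-k]
  wc <- window_config(config$window, config$overlap)
  if (ncol(test$eeg) < wc$w) {
    stop("held-out trial ", test_trial_id, " is shorter than one window (",
         ncol(test$eeg), " < ", wc$w, ")")
  }

  stim_all <- unlist(lapply(train, function(t) t$envelope))
  eeg_all <- do.call(cbind, lapply(train, function(t) t$eeg))
  proj <- fit_cca(stim_all, eeg_all, lambda = config$lambda)

  win_in <- concat_windows(lapply(train, function(t) {
    segment(t$envelope, wc, subject$subject_id, t$trial_id)
  }))
  win_out <- concat_windows(lapply(train, function(t) {
    segment(project_eeg(t$eeg, proj), wc, subject$subject_id, t$trial_id)
  }))
  N <- nrow(win_in$data)
  p <- config$n_components
  if (p > min(N, wc$w)) {
    stop("n_components = ", p, " exceeds min(N, w) = ", min(N, wc$w),
         "; use more/longer training trials or a smaller p")
  }
  basis_in <- fit_klt(win_in, p, center = config$center)
  basis_out <- fit_klt(win_out, p, center = config$center)
  if (isTRUE(config$align_output_basis)) {
    basis_out <- align_klt(basis_out, basis_in)
  }
  F_in <- klt_project(win_in, basis_in)
  F_out <- klt_project(win_out, basis_out)

  spec <- network_spec(c(p, config$hidden, p),
                       dropout_rate = config$dropout_rate,
                       activation = config$activation,
                       seed = derive_seed(config$seed, 0L, k, salt = 3L))
  tcfg <- config$train
  tcfg$seed <- derive_seed(config$seed, 0L, k, salt = 4L)
  model <- fit_mlp(build_mlp(spec), F_in, F_out, tcfg)

  u_test <- project_eeg(test$eeg, proj)
  win_in_test <- segment(test$envelope, wc, subject$subject_id, test$trial_id)
  F_in_test <- klt_project(win_in_test, basis_in)
  pred_feat <- predict_mlp(model, F_in_test)

  if (config$eval_domain == "feature") {
    rho_proposed <- pearson(as.vector(F_in_test$data), as.vector(pred_feat))
  } else {
    F_in_test$data <- pred_feat  # reuse provenance/window geometry
    pred_windows <- klt_reconstruct(F_in_test, basis_out)
    y_hat <- overlap_add(pred_windows, wc)
    rho_proposed <- pearson(test$envelope[seq_along(y_hat)], y_hat)
  }
  rho_lcca <- baseline_correlation(test$envelope, test$eeg, proj)

  structure(list(subject_id = subject$subject_id,
                 test_trial_id = test$trial_id,
                 rho_lcca = rho_lcca, rho_proposed = rho_proposed,
                 cca = proj, basis_in = basis_in, basis_out = basis_out,
                 model = model),
            class = "sc_fold")
}

#' @export
print.sc_fold <- function(x, ...) {
  cat(sprintf("<sc_fold> %s / trial %d: rho_lcca = %.3f, rho_proposed = %.3f\n",
              x$subject_id, x$test_trial_id, x$rho_lcca, x$rho_proposed))
  invisible(x)
}

#' Leave-one-trial-out cross-testing for one subject
#'
#' Runs [run_fold()] once per trial, each trial serving as the test set
#' exactly once (in trial-id order), and averages the fold correlations.
#'
#' @param subject An `sc_subject` with at least 2 trials.
#' @param config An [run_config()].
#' @return An object of class `sc_subject_summary`: `subject_id`,
#'   `mean_lcca`, `mean_proposed`, `n_folds` and a `folds` data frame.
#' @export
cross_test <- function(subject, config = run_config()) {
  stopifnot(inherits(subject, "sc_subject"))
  ids <- sort(vapply(subject$trials, function(t) t$trial_id, integer(1)))
  if (length(ids) < 2L) stop("need at least 2 trials for cross-testing")
  folds <- lapply(ids, function(tid) {
    f <- tryCatch(run_fold(subject, tid, config), error = function(e) {
      stop("fold for subject ", subject$subject_id, ", test trial ", tid,
           " failed: ", conditionMessage(e))
    })
    data.frame(subject_id = f$subject_id, test_trial_id = f$test_trial_id,
               rho_lcca = f$rho_lcca, rho_proposed = f$rho_proposed,
               stringsAsFactors = FALSE)
  })
  folds <- do.call(rbind, folds)
  structure(list(subject_id = subject$subject_id,
                 mean_lcca = mean(folds$rho_lcca),
                 mean_proposed = mean(folds$rho_proposed),
                 n_folds = nrow(folds), folds = folds),
            class = "sc_subject_summary")
}

#' @export
print.sc_subject_summary <- function(x, ...) {
  cat(sprintf("<sc_subject_summary> %s (%d folds): LCCA %.3f, proposed %.3f\n",
              x$subject_id, x$n_folds, x$mean_lcca, x$mean_proposed))
  invisible(x)
}

#' Build a subject summary from known per-subject values
#'
#' Convenience constructor for consuming published per-subject correlation
#' tables (each printed value is that subject's fold mean).
#'
#' @param subject_id Character id.
#' @param mean_lcca,mean_proposed Per-subject mean correlations.
#' @param n_folds Fold count behind the means (if known).
#' @return An `sc_subject_summary`.
#' @export
subject_summary <- function(subject_id, mean_lcca, mean_proposed,
                            n_folds = NA_integer_) {
  structure(list(subject_id = as.character(subject_id),
                 mean_lcca = as.numeric(mean_lcca),
                 mean_proposed = as.numeric(mean_proposed),
                 n_folds = as.integer(n_folds), folds = NULL),
            class = "sc_subject_summary")
}

#' Aggregate subject summaries into overall means
#'
#' The overall figure for each method is the unweighted arithmetic mean of
#' the per-subject means, kept at full precision (rounding is display-only).
#'
#' @param summaries List of `sc_subject_summary`.
#' @return A list with the per-subject data frame `per_subject` and
#'   `overall_lcca`, `overall_proposed`.
#' @export
aggregate_summaries <- function(summaries) {
  if (length(summaries) < 1L) stop("no subject summaries to aggregate")
  ok <- vapply(summaries, inherits, logical(1), what = "sc_subject_summary")
  if (!all(ok)) stop("all elements must be sc_subject_summary objects")
  per_subject <- data.frame(
    subject_id = vapply(summaries, function(s) s$subject_id, character(1)),
    lcca = vapply(summaries, function(s) s$mean_lcca, numeric(1)),
    proposed = vapply(summaries, function(s) s$mean_proposed, numeric(1)),
    stringsAsFactors = FALSE
  )
  list(per_subject = per_subject,
       overall_lcca = mean(per_subject$lcca),
       overall_proposed = mean(per_subject$proposed))
}

#' Relative improvement in percent
#'
#' `100 * (new - ref) / ref`; displayed to 2 decimals in reports.
#'
#' @param overall_new,overall_ref Overall correlations (reference nonzero).
#' @return Percent improvement.
#' @export
relative_improvement <- function(overall_new, overall_ref) {
  if (overall_ref == 0) stop("reference value is zero")
  100 * (overall_new - overall_ref) / overall_ref
}

round3 <- function(x) as.numeric(sprintf("%.3f", x))

#' Build and optionally write a comparison report
#'
#' Produces the per-subject table (LCCA and proposed columns, plus an
#' optional external published column keyed by subject id) with an Overall
#' row of unweighted means. The relative improvement of the proposed method
#' is computed against the external column when present, otherwise against
#' the LCCA baseline, using the 3-decimal displayed overall values (the
#' convention of the printed tables it mirrors).
#'
#' @param summaries List of `sc_subject_summary`.
#' @param external Optional data frame with columns `subject_id` and one
#'   named numeric column of externally published per-subject correlations.
#' @param path Optional output stem; writes `<path>.tsv` (3-decimal display,
#'   improvement as a trailing comment line) and `<path>.json` (full
#'   precision).
#' @return An object of class `sc_report`: `table` (per-subject rows plus
#'   Overall), `overall` (full precision), `relative_improvement_percent`.
#' @export
comparison_report <- function(summaries, external = NULL, path = NULL) {
  agg <- aggregate_summaries(summaries)
  tab <- agg$per_subject
  names(tab) <- c("Subject", "LCCA", "Proposed")
  external_name <- NULL
  if (!is.null(external)) {
    stopifnot(is.data.frame(external), "subject_id" %in% names(external))
    value_cols <- setdiff(names(external), "subject_id")
    if (length(value_cols) != 1L) {
      stop("external table must have exactly one value column")
    }
    external_name <- value_cols
    missing <- setdiff(tab$Subject, as.character(external$subject_id))
    if (length(missing) > 0L) {
      stop("external column lacks subject(s): ",
           paste(missing, collapse = ", "))
    }
    tab[[external_name]] <-
      external[[external_name]][match(tab$Subject,
                                      as.character(external$subject_id))]
    tab <- tab[, c("Subject", "LCCA", external_name, "Proposed")]
  }
  overall <- c(LCCA = agg$overall_lcca, Proposed = agg$overall_proposed)
  if (!is.null(external_name)) {
    overall[external_name] <- mean(tab[[external_name]])
  }
  ref <- if (!is.null(external_name)) overall[[external_name]] else
    overall[["LCCA"]]
  improvement <- relative_improvement(round3(overall[["Proposed"]]),
                                      round3(ref))
  overall_row <- tab[1L, ]
  overall_row$Subject <- "Overall"
  for (cn in setdiff(names(tab), "Subject")) {
    overall_row[[cn]] <- overall[[cn]]
  }
  full <- rbind(tab, overall_row)
  rownames(full) <- NULL
  report <- structure(
    list(table = full, overall = overall,
         relative_improvement_percent = improvement,
         reference_column = if (is.null(external_name)) "LCCA" else
           external_name),
    class = "sc_report"
  )
  if (!is.null(path)) write_report(report, path)
  report
}

#' @export
print.sc_report <- function(x, ...) {
  disp <- x$table
  for (cn in setdiff(names(disp), "Subject")) {
    disp[[cn]] <- sprintf("%.3f", disp[[cn]])
  }
  print(disp, row.names = FALSE)
  cat(sprintf("Relative improvement of Proposed vs %s: %.2f%%\n",
              x$reference_column, x$relative_improvement_percent))
  invisible(x)
}

#' Write a comparison report to disk
#'
#' @param report An `sc_report`.
#' @param path Output stem (without extension).
#' @return Invisibly, the paths written (`.tsv` and `.json`).
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "sc_report"))
  tsv <- paste0(path, ".tsv")
  jsn <- paste0(path, ".json")
  disp <- report$table
  for (cn in setdiff(names(disp), "Subject")) {
    disp[[cn]] <- sprintf("%.3f", disp[[cn]])
  }
  con <- file(tsv, "w")
  utils::write.table(disp, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sprintf("# relative_improvement_percent vs %s: %.2f",
                     report$reference_column,
                     report$relative_improvement_percent), con)
  close(con)
  jsonlite::write_json(
    list(table = report$table, overall = as.list(report$overall),
         relative_improvement_percent = report$relative_improvement_percent,
         reference_column = report$reference_column),
    jsn, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(c(tsv, jsn))
}

#' Read back a written comparison report
#'
#' @param path Stem used in [write_report()] (reads `<path>.json`).
#' @return An `sc_report`.
#' @export
read_report <- function(path) {
  jsn <- paste0(path, ".json")
  if (!file.exists(jsn)) stop("report file does not exist: ", jsn)
  x <- jsonlite::read_json(jsn, simplifyVector = TRUE)
  structure(
    list(table = as.data.frame(x$table, stringsAsFactors = FALSE),
         overall = unlist(x$overall),
         relative_improvement_percent = x$relative_improvement_percent,
         reference_column = x$reference_column),
    class = "sc_report"
  )
}
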