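#' Pipeline run configuration
#'
#' Collects every tunable of the analysis pipeline. The defaults are the
#' reference operating point for 128 Hz speech/EEG data: 256-sample (2 s)
#' windows with 50% overlap and 50 retained KLT components, with hidden
#' layers of 1000 and 550 units.
#'
#' @param window Window size `w` in samples (default 256).
#' @param overlap Overlapping samples `o` (default 128, i.e. 50%).
#' @param n_components Retained KLT components `p` (default 50).
#' @param hidden Hidden-layer widths of the network (default `c(1000, 550)`).
#' @param dropout_rate Dropout probability (default 0.2).
#' @param activation Hidden activation, `"relu"` or `"tanh"`.
#' @param train An [train_config()].
#' @param lambda CCA ridge regularizer; `NULL` for the data-driven default
#'   (see [fit_cca()]).
#' @param center Mean-center windows before the KLT (default `TRUE`; set
#'   `FALSE` for the uncentered transform).
#' @param align_output_basis Rotate the output-window basis onto the
#'   input-window basis within numerically degenerate singular-value blocks
#'   (see [align_klt()]); default `TRUE`. Without it the coordinates of the
#'   two views have arbitrary relative phase inside near-degenerate blocks
#'   and time-domain reconstruction of the predictions decorrelates.
#' @param eval_domain Where the held-out correlation is computed: `"time"`
#'   (default; envelope vs overlap-added predicted EEG) or `"feature"`
#'   (flattened feature batches).
#' @param seed Master seed for model initialization and training.
#' @return An object of class `sc_run_config`.
#' @export
run_config <- function(window = 256L, overlap = 128L, n_components = 50L,
                       hidden = c(1000L, 550L), dropout_rate = 0.2,
                       activation = "relu", train = train_config(),
                       lambda = NULL, center = TRUE,
                       align_output_basis = TRUE,
                       eval_domain = c("time", "feature"), seed = 1L) {
  eval_domain <- match.arg(eval_domain)
  wc <- window_config(window, overlap)
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > wc$w) {
    stop("n_components must satisfy 1 <= p <= window size")
  }
  structure(list(window = wc$w, overlap = wc$o,
                 n_components = n_components,
                 hidden = as.integer(hidden), dropout_rate = dropout_rate,
                 activation = activation, train = train, lambda = lambda,
                 center = center, align_output_basis = align_output_basis,
                 eval_domain = eval_domain,
                 seed = as.integer(seed)),
            class = "sc_run_config")
}

config_from_list <- function(x, builder, extra = list()) {
  known <- names(formals(builder))
  unknown <- setdiff(names(x), known)
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(builder, utils::modifyList(extra, x))
}

#' Read a run or simulation configuration from YAML
#'
#' Keys mirror the arguments of [run_config()] / [synth_config()] /
#' [train_config()]; a `train:` sub-map in a run configuration is passed to
#' [train_config()]. Unknown keys are an error.
#'
#' @param path YAML file.
#' @param type `"run"` or `"synth"`.
#' @return An `sc_run_config` or `sc_synth_config`.
#' @export
read_config <- function(path, type = c("run", "synth")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("configuration file does not exist: ", path)
  x <- yaml::read_yaml(path)
  if (is.null(x)) x <- list()
  if (type == "synth") return(config_from_list(x, synth_config))
  if (!is.null(x$train)) {
    x$train <- config_from_list(x$train, train_config)
  }
  config_from_list(x, run_config)
}
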