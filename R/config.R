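#' Run configuration for the prioritization pipeline
#'
#' Collects every tunable threshold used by the expression screen, the
#' RT-qPCR validation layer and the variant funnel in one validated object.
#' No stage of the pipeline hard-codes a threshold; everything flows from
#' this configuration.
#'
#' @param up_threshold Fold-change ratio above which a gene counts as
#'   increased between two timepoints (test/reference ratio, strict
#'   inequality). Default 1.5.
#' @param down_threshold Fold-change ratio above which a gene counts as
#'   decreased (reference/test ratio, strict inequality). Default 2.25.
#'   The up/down asymmetry mirrors the original screen design.
#' @param signal_floor Minimum normalized signal: a gene is kept only if at
#'   least one sample reaches this value. Default 5 (linear-scale signal
#'   units).
#' @param alpha_test Significance level for the two-sample expression tests.
#'   Default 0.05.
#' @param alpha_homoscedasticity Significance level of the variance-ratio
#'   F-test that gates the choice between Student's and Welch's t-test.
#'   Default 0.05.
#' @param seed Integer seed used by the simulation generators. Default 0.
#'
#' @return An object of class `cati_config` (a named list).
#' @examples
#' cfg <- cati_config()
#' cfg$up_threshold
#' @export
cati_config <- function(up_threshold = 1.5,
                        down_threshold = 2.25,
                        signal_floor = 5,
                        alpha_test = 0.05,
                        alpha_homoscedasticity = 0.05,
                        seed = 0L) {
  stopifnot(
    is.numeric(up_threshold), length(up_threshold) == 1L, up_threshold > 1,
    is.numeric(down_threshold), length(down_threshold) == 1L, down_threshold > 1,
    is.numeric(signal_floor), length(signal_floor) == 1L, signal_floor > 0,
    is.numeric(alpha_test), alpha_test > 0, alpha_test < 1,
    is.numeric(alpha_homoscedasticity),
    alpha_homoscedasticity > 0, alpha_homoscedasticity < 1,
    is.numeric(seed), length(seed) == 1L
  )
  structure(
    list(
      up_threshold = up_threshold,
      down_threshold = down_threshold,
      signal_floor = signal_floor,
      alpha_test = alpha_test,
      alpha_homoscedasticity = alpha_homoscedasticity,
      seed = as.integer(seed)
    ),
    class = "cati_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Unknown keys are rejected so that typos in a config file fail loudly
#' rather than silently falling back to defaults.
#'
#' @param path Path to a YAML file whose keys are a subset of the
#'   [cati_config()] arguments.
#' @return A `cati_config` object.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(cati_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0L) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  }
  do.call(cati_config, vals)
}

#' Write a run configuration to a YAML file
#'
#' @param config A `cati_config` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "cati_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.cati_config <- function(x, ...) {
  cat("Pipeline configuration\n")
  cat(sprintf("  up threshold      : > %g-fold (test/reference)\n", x$up_threshold))
  cat(sprintf("  down threshold    : > %g-fold (reference/test)\n", x$down_threshold))
  cat(sprintf("  signal floor      : %g (kept if any sample >= floor)\n", x$signal_floor))
  cat(sprintf("  test alpha        : %g\n", x$alpha_test))
  cat(sprintf("  F-test alpha      : %g\n", x$alpha_homoscedasticity))
  cat(sprintf("  seed              : %d\n", x$seed))
  invisible(x)
}

# Structured stage logging to stderr. Silent unless the option
# `catifunnel.verbose` is TRUE (the command-line wrapper turns it on) so that
# programmatic use and tests stay quiet.
cf_log <- function(stage, n_in, n_out, params = NULL) {
  if (!isTRUE(getOption("catifunnel.verbose", FALSE))) return(invisible(NULL))
  p <- if (is.null(params) || length(params) == 0L) "" else
    paste0(" [", paste(names(params), unlist(params), sep = "=", collapse = ", "), "]")
  message(sprintf("[catifunnel] %-28s in=%d out=%d%s", stage, n_in, n_out, p))
  invisible(NULL)
}
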