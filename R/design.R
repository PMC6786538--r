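#' Describe a time-course experiment design
#'
#' Captures the layout of a replicated time-course expression experiment:
#' the ordered time points, the biological conditions, which condition (if
#' any) is the control, and the number of replicates per condition.
#'
#' @param time_points Numeric vector of T >= 2 strictly increasing time
#'   labels (hours, weeks, ... -- units are the user's).
#' @param conditions Character vector of condition names (Z >= 1), order
#'   preserved in all downstream outputs.
#' @param control Name of the control condition, or `NULL` for
#'   single-condition mode. Must be one of `conditions`, and requires
#'   Z >= 2.
#' @param replicates Replicates per condition: a single positive integer, or
#'   a named integer vector (one entry per condition) when counts differ.
#'   Unequal counts force mean summarization at load time (see
#'   [load_expression()]).
#' @param replicate_summary One of `"none"`, `"mean"`, `"median"`: whether
#'   replicates are collapsed to a single profile per time point before
#'   modelling.
#'
#' @return An object of class `experiment_design`.
#' @examples
#' experiment_design(time_points = c(0, 2, 6, 12, 18, 24),
#'                   conditions = c("control", "induced"),
#'                   control = "control", replicates = 3)
#' @export
experiment_design <- function(time_points, conditions, control = NULL,
                              replicates,
                              replicate_summary = c("none", "mean", "median")) {
  replicate_summary <- match.arg(replicate_summary)
  time_points <- as.numeric(time_points)
  conditions <- as.character(conditions)
  if (length(time_points) < 2L)
    stop("invalid design: need at least 2 time points, got ",
         length(time_points))
  if (any(diff(time_points) <= 0))
    stop("invalid design: time_points must be strictly increasing")
  if (length(conditions) < 1L || anyDuplicated(conditions))
    stop("invalid design: conditions must be a non-empty set of unique names")
  if (!is.null(control)) {
    control <- as.character(control)
    if (length(control) != 1L || !control %in% conditions)
      stop("invalid design: control ('", control,
           "') must be one of the conditions")
    if (length(conditions) < 2L)
      stop("invalid design: a control requires at least 2 conditions")
  }
  if (is.null(names(replicates))) {
    if (length(replicates) != 1L)
      stop("invalid design: 'replicates' must be a single count or named per condition")
    replicates <- stats::setNames(rep(as.integer(replicates),
                                      length(conditions)), conditions)
  } else {
    replicates <- replicates[conditions]
    if (anyNA(replicates))
      stop("invalid design: named 'replicates' must cover every condition")
    replicates <- stats::setNames(as.integer(replicates), conditions)
  }
  if (any(is.na(replicates)) || any(replicates < 1L))
    stop("invalid design: replicate counts must be positive integers")
  structure(
    list(time_points = time_points, conditions = conditions,
         control = control, replicates = replicates,
         replicate_summary = replicate_summary),
    class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("Time-course design:", length(x$time_points), "time points (",
      paste(x$time_points, collapse = ", "), ")\n")
  cat("Conditions:", paste(x$conditions, collapse = ", "), "\n")
  cat("Control:", if (is.null(x$control)) "<none>" else x$control, "\n")
  cat("Replicates:", paste(sprintf("%s=%d", names(x$replicates), x$replicates),
                           collapse = ", "),
      "| summary:", x$replicate_summary, "\n")
  invisible(x)
}

# number of time points
design_T <- function(design) length(design$time_points)

# TRUE when all conditions share one replicate count
design_balanced <- function(design) length(unique(design$replicates)) == 1L
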