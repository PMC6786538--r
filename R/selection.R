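#' The null path: no change at any time step
#'
#' The all-`N` sequence a feature's decoded path is compared against; a
#' feature "rejects" this null when its path contains at least one `C`.
#'
#' @param length Number of time steps (T-1), at least 1.
#' @return Character vector of `"N"` of the given length.
#' @export
null_path <- function(length) {
  length <- as.integer(length)
  if (is.na(length) || length < 1L)
    stop("invalid input: path length must be at least 1")
  rep("N", length)
}

#' Select relevant features by comparing decoded paths across conditions
#'
#' With a control condition: a feature is relevant when its control path is
#' entirely `N` (flat over time) while at least one non-control condition's
#' path contains a `C`. Features whose control path changes are excluded
#' outright -- observed changes there cannot be attributed to the condition.
#' Without a control, any feature whose path contains a `C` is kept and flat
#' features are discarded.
#'
#' An optional per-step mode only credits a case `C` at time steps where the
#' control is `N` at the same step.
#'
#' @param paths Named list (one element per condition, names = condition
#'   names) of character path matrices as returned by [decode_condition()]:
#'   features x (T-1), entries "N"/"C", rownames = feature ids.
#' @param design The [experiment_design()].
#' @param mode `"whole-path"` (default) or `"per-step"`.
#' @return A data frame with one row per feature: `feature_id`, `relevant`
#'   (logical), `reason` (one of `control-flat-case-change`,
#'   `flat-everywhere`, `control-changes`, `single-condition-change`,
#'   `single-condition-flat`), and one `path_<condition>` string column per
#'   condition (e.g. `"NCNNN"`).
#' @export
select_relevant <- function(paths, design, mode = c("whole-path", "per-step")) {
  mode <- match.arg(mode)
  stopifnot(inherits(design, "experiment_design"))
  if (!all(design$conditions %in% names(paths)))
    stop("alignment error: missing decoded paths for condition(s): ",
         paste(setdiff(design$conditions, names(paths)), collapse = ", "))
  paths <- paths[design$conditions]
  ids <- rownames(paths[[1L]])
  for (p in paths) {
    if (!identical(rownames(p), ids) || ncol(p) != ncol(paths[[1L]]))
      stop("alignment error: path matrices disagree on features or length")
  }

  change_mat <- vapply(paths, function(p) rowSums(p == "C") > 0,
                       logical(length(ids)))
  change_mat <- matrix(change_mat, nrow = length(ids),
                       dimnames = list(ids, names(paths)))

  if (is.null(design$control)) {
    any_change <- rowSums(change_mat) > 0
    relevant <- any_change
    reason <- ifelse(any_change, "single-condition-change",
                     "single-condition-flat")
  } else {
    ctrl <- design$control
    cases <- setdiff(design$conditions, ctrl)
    control_flat <- !change_mat[, ctrl]
    if (mode == "whole-path") {
      case_change <- rowSums(change_mat[, cases, drop = FALSE]) > 0
      relevant <- control_flat & case_change
      reason <- ifelse(!control_flat, "control-changes",
                       ifelse(case_change, "control-flat-case-change",
                              "flat-everywhere"))
    } else {
      # credit a case change only where the control is simultaneously N;
      # the control need not be flat across the whole path in this mode
      ctrl_n <- paths[[ctrl]] == "N"
      case_change <- rep(FALSE, length(ids))
      for (cs in cases)
        case_change <- case_change |
          rowSums((paths[[cs]] == "C") & ctrl_n) > 0
      relevant <- case_change
      reason <- ifelse(case_change, "control-flat-case-change",
                       ifelse(!control_flat, "control-changes",
                              "flat-everywhere"))
    }
  }

  out <- data.frame(feature_id = ids, relevant = unname(relevant),
                    reason = unname(reason), stringsAsFactors = FALSE)
  for (cond in names(paths))
    out[[paste0("path_", cond)]] <-
      apply(paths[[cond]], 1L, paste, collapse = "")
  rownames(out) <- NULL
  out
}
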