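#' Plot the EM log-likelihood trace
#'
#' A quick convergence diagnostic: the curve must be non-decreasing.
#'
#' @param fit An `hmm_fit` from [em_fit()].
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the trace.
#' @export
plot_loglik_trace <- function(fit, ...) {
  stopifnot(inherits(fit, "hmm_fit"))
  tr <- fit$log_likelihood_trace
  graphics::plot(seq_along(tr), tr, type = "b", pch = 16,
                 xlab = "EM iteration", ylab = "total log-likelihood", ...)
  invisible(tr)
}

#' Plot one feature's expression profile across conditions
#'
#' Replicates are drawn as thin lines, their mean as a thick one, one color
#' per condition.
#'
#' @param tensors Named list of [condition_tensor()] objects.
#' @param feature_id Feature to plot.
#' @param time_points Time axis (defaults to 1..T).
#' @return Invisibly, `NULL`.
#' @export
plot_feature_profile <- function(tensors, feature_id, time_points = NULL) {
  stopifnot(length(tensors) >= 1L)
  Tn <- dim(tensors[[1L]]$values)[3L]
  if (is.null(time_points)) time_points <- seq_len(Tn)
  vals <- lapply(tensors, function(ten) {
    i <- match(feature_id, ten$feature_ids)
    if (is.na(i)) stop("feature '", feature_id, "' not found in condition '",
                       ten$condition, "'")
    matrix(ten$values[i, , ], dim(ten$values)[2L], Tn)
  })
  ylim <- range(unlist(vals))
  cols <- grDevices::hcl.colors(length(vals), "Dark 2")
  graphics::plot(NA, xlim = range(time_points), ylim = ylim, xlab = "time",
                 ylab = "expression", main = feature_id)
  for (k in seq_along(vals)) {
    v <- vals[[k]]
    for (r in seq_len(nrow(v)))
      graphics::lines(time_points, v[r, ], col = cols[k], lwd = 0.8)
    graphics::lines(time_points, colMeans(v), col = cols[k], lwd = 2.5)
  }
  graphics::legend("topleft", legend = names(tensors), col = cols, lwd = 2,
                   bty = "n")
  invisible(NULL)
}
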