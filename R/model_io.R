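#' Serialize fitted model parameters to JSON
#'
#' Writes states, initial distribution, transition matrix, emission means
#' and covariances -- plus fit metadata when given an `hmm_fit` -- so a run
#' can be reproduced or a model reused for decoding.
#'
#' @param x An [hmm_parameters()] or `hmm_fit` object.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_model_json <- function(x, path) {
  if (inherits(x, "hmm_fit")) {
    params <- x$parameters
    meta <- list(iterations = x$iterations, converged = x$converged,
                 n_sequences = x$n_sequences, restart = x$restart,
                 final_log_likelihood =
                   utils::tail(x$log_likelihood_trace, 1L),
                 config = unclass(x$config))
  } else {
    params <- x
    meta <- NULL
  }
  stopifnot(inherits(params, "hmm_parameters"))
  R <- ncol(params$means)
  doc <- list(
    states = params$states,
    initial = unname(params$initial),
    transition = unname(params$transition),
    means = unname(params$means),
    covariances = list(N = matrix(params$covariances[, , 1L], R, R),
                       C = matrix(params$covariances[, , 2L], R, R)))
  if (!is.null(meta)) doc$fit <- meta
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read model parameters back from JSON
#'
#' @param path JSON file written by [write_model_json()].
#' @return An [hmm_parameters()] object.
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(x) if (is.matrix(x)) x else
    do.call(rbind, lapply(x, unlist))
  means <- as_mat(doc$means)
  R <- ncol(means)
  covs <- array(0, c(R, R, 2L))
  covs[, , 1L] <- as_mat(doc$covariances$N)
  covs[, , 2L] <- as_mat(doc$covariances$C)
  hmm_parameters(unlist(doc$initial), as_mat(doc$transition), means, covs)
}
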