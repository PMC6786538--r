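# Batch Viterbi over equal-length sequences.
# obs: n x Tm x R. Returns integer path matrix (n x Tm, 1 = N, 2 = C) and
# per-sequence joint log-probability of the decoded path and observations.
# Ties are broken toward state N at every step, so an exactly symmetric
# instance decodes to the all-N (null) path.
viterbi_batch <- function(params, obs, ridge = 1e-6) {
  d <- dim(obs)
  n <- d[1L]; Tm <- d[2L]
  logB <- emission_logB(params, obs, ridge)
  logA <- log(params$transition)
  logpi <- log(params$initial)

  phi <- matrix(logB[, 1L, ], n, 2L)
  phi[, 1L] <- phi[, 1L] + logpi[1L]
  phi[, 2L] <- phi[, 2L] + logpi[2L]
  back <- if (Tm > 1L) array(1L, c(n, Tm, 2L)) else NULL
  if (Tm > 1L) for (t in 2:Tm) {
    newphi <- matrix(0, n, 2L)
    for (j in 1:2) {
      cand_n <- phi[, 1L] + logA[1L, j]
      cand_c <- phi[, 2L] + logA[2L, j]
      from_c <- cand_c > cand_n              # tie -> N
      newphi[, j] <- ifelse(from_c, cand_c, cand_n) + logB[, t, j]
      back[, t, j] <- 1L + from_c
    }
    phi <- newphi
  }
  path <- matrix(1L, n, Tm)
  last_c <- phi[, 2L] > phi[, 1L]            # tie -> N
  path[, Tm] <- 1L + last_c
  logp <- ifelse(last_c, phi[, 2L], phi[, 1L])
  if (Tm > 1L) for (t in (Tm - 1L):1L) {
    idx <- cbind(seq_len(n), t + 1L, path[, t + 1L])
    path[, t] <- back[idx]
  }
  list(path = path, log_probability = logp)
}

#' Decode the most probable hidden-state path for one feature
#'
#' Runs the Viterbi algorithm under fitted parameters, returning the
#' maximum-joint-probability sequence over \{N, C\}. Exact ties are broken in
#' favour of `N`, the null state, so ambiguity never creates a selection.
#'
#' @param params An [hmm_parameters()] object (typically `fit$parameters`).
#' @param sequence Numeric matrix, (T-1) x R, of one feature's replicate
#'   differences in one condition (vector accepted when R = 1).
#' @param feature_id,condition Identifiers carried into the result.
#' @return An object of class `state_path`: `feature_id`, `condition`,
#'   `states` (character vector over \{"N","C"\} of length T-1) and
#'   `log_probability` (joint log-probability of path and observations).
#' @export
viterbi_decode <- function(params, sequence, feature_id = NA_character_,
                           condition = NA_character_) {
  stopifnot(inherits(params, "hmm_parameters"))
  sequence <- as_sequence_matrix(sequence, ncol(params$means))
  if (nrow(sequence) < 1L)
    stop("invalid input: empty observation sequence")
  obs <- array(sequence, c(1L, nrow(sequence), ncol(sequence)))
  vb <- viterbi_batch(params, obs)
  structure(list(feature_id = feature_id, condition = condition,
                 states = c("N", "C")[vb$path[1L, ]],
                 log_probability = vb$log_probability[1L]),
            class = "state_path")
}

#' @export
print.state_path <- function(x, ...) {
  cat(sprintf("<state_path> %s [%s]: %s (log P = %.4f)\n",
              x$feature_id, x$condition, paste(x$states, collapse = ""),
              x$log_probability))
  invisible(x)
}

#' Decode every feature of a delta tensor
#'
#' Vectorized Viterbi over all features of one condition. Decoding each
#' sequence is independent of every other sequence, so this is equivalent to
#' calling [viterbi_decode()] feature by feature.
#'
#' @param params An [hmm_parameters()] object.
#' @param delta A [delta_tensor()].
#' @return A character matrix, features x (T-1), entries "N"/"C", rownames =
#'   feature ids, with per-feature path log-probabilities in attribute
#'   `log_probability`.
#' @export
decode_condition <- function(params, delta) {
  stopifnot(inherits(params, "hmm_parameters"), inherits(delta, "delta_tensor"))
  obs <- aperm(delta$deltas, c(1L, 3L, 2L))
  vb <- viterbi_batch(params, obs)
  paths <- matrix(c("N", "C")[vb$path], nrow(vb$path), ncol(vb$path),
                  dimnames = list(delta$feature_ids, NULL))
  attr(paths, "log_probability") <- stats::setNames(vb$log_probability,
                                                    delta$feature_ids)
  paths
}
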