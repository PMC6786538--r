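#' Two-state Gaussian hidden Markov model parameters
#'
#' The model has two hidden states over consecutive-time expression
#' differences: `N` ("no change", the null state, small dispersion) and `C`
#' ("change", large dispersion). Each state emits an R-dimensional vector --
#' the differences of the R biological replicates at one time step -- from a
#' multivariate normal distribution. Because the model sees expression
#' *changes* rather than levels, both emission means are zero in practice;
#' fitting constrains them to zero by default (see [em_config()]).
#'
#' @param initial Length-2 probability vector over (N, C).
#' @param transition 2x2 row-stochastic transition matrix, rows/cols (N, C).
#' @param means 2 x R matrix of emission means, rows (N, C).
#' @param covariances R x R x 2 array of emission covariances, slices (N, C).
#' @return An object of class `hmm_parameters`.
#' @export
hmm_parameters <- function(initial, transition, means, covariances) {
  means <- rbind(means)
  if (is.matrix(covariances))
    covariances <- array(c(covariances, covariances),
                         dim = c(dim(covariances), 2L))[, , 1:2]
  stopifnot(length(initial) == 2L, all(dim(transition) == c(2L, 2L)),
            nrow(means) == 2L, length(dim(covariances)) == 3L,
            dim(covariances)[3L] == 2L,
            dim(covariances)[1L] == ncol(means))
  if (abs(sum(initial) - 1) > 1e-10 || any(initial < 0))
    stop("initial state distribution must be a probability vector")
  if (any(abs(rowSums(transition) - 1) > 1e-10) || any(transition < 0))
    stop("transition matrix must be row-stochastic")
  states <- c("N", "C")
  names(initial) <- states
  dimnames(transition) <- list(states, states)
  rownames(means) <- states
  dimnames(covariances)[[3L]] <- states
  structure(list(initial = initial, transition = transition, means = means,
                 covariances = covariances, states = states),
            class = "hmm_parameters")
}

#' @export
print.hmm_parameters <- function(x, ...) {
  R <- ncol(x$means)
  cat("Two-state Gaussian HMM (emission dimension ", R, ")\n", sep = "")
  cat("  initial:    N=", signif(x$initial[1], 4), " C=",
      signif(x$initial[2], 4), "\n", sep = "")
  cat("  transition rows:  N -> (", paste(signif(x$transition[1, ], 4),
                                          collapse = ", "),
      ")   C -> (", paste(signif(x$transition[2, ], 4), collapse = ", "),
      ")\n", sep = "")
  sds <- sqrt(vapply(1:2, function(s)
    mean(diag(matrix(x$covariances[, , s], R, R))), 0))
  cat("  per-state sd (mean diag): N=", signif(sds[1], 4), " C=",
      signif(sds[2], 4), "\n", sep = "")
  invisible(x)
}

state_index <- function(state) {
  i <- match(state, c("N", "C"))
  if (is.na(i)) stop("unknown state '", state, "' (expected 'N' or 'C')")
  i
}

# Multivariate normal log-density for a matrix of row observations.
# Cholesky-based; a ridge is added to the diagonal when the factorization
# fails, and a hard error raised if it still fails.
mvn_logdensity <- function(Y, mean, cov, ridge = 1e-6) {
  Y <- rbind(Y)
  R <- ncol(Y)
  ch <- tryCatch(chol(cov), error = function(e) NULL)
  if (is.null(ch))
    ch <- tryCatch(chol(cov + diag(ridge, R)), error = function(e)
      stop("numerical error: emission covariance is not positive definite ",
           "even after ridge regularization"))
  Yc <- sweep(Y, 2L, mean, check.margin = FALSE)
  Q <- Yc %*% backsolve(ch, diag(R))
  -0.5 * (R * log(2 * pi) + 2 * sum(log(diag(ch))) + rowSums(Q * Q))
}

#' Emission log-density of one observation under one state
#'
#' @param params An [hmm_parameters()] object.
#' @param observation Numeric vector of length R (one time step's replicate
#'   differences).
#' @param state `"N"` or `"C"`.
#' @return The multivariate normal log-density (scalar).
#' @export
emission_logdensity <- function(params, observation, state) {
  stopifnot(inherits(params, "hmm_parameters"))
  s <- state_index(state)
  R <- ncol(params$means)
  if (length(observation) != R)
    stop("shape error: observation has length ", length(observation),
         " but the emission dimension is ", R)
  as.numeric(mvn_logdensity(matrix(observation, 1L), params$means[s, ],
                            params$covariances[, , s]))
}

# log emission densities for a batch of sequences:
# obs is n x Tm x R; returns n x Tm x 2
emission_logB <- function(params, obs, ridge = 1e-6) {
  d <- dim(obs)
  n <- d[1L]; Tm <- d[2L]; R <- d[3L]
  Y <- matrix(obs, n * Tm, R)
  logB <- array(NA_real_, c(n, Tm, 2L))
  for (s in 1:2)
    logB[, , s] <- mvn_logdensity(Y, params$means[s, ],
                                  params$covariances[, , s], ridge)
  logB
}

# Scaled forward-backward over a batch of equal-length sequences.
# obs: n x Tm x R. Returns per-sequence log-likelihoods, smoothed state
# posteriors gamma (n x Tm x 2), and summed pairwise transition posteriors
# xi_sum (2 x 2), plus per-step xi when keep_xi = TRUE (used by the public
# single-sequence interface).
forward_backward_batch <- function(params, obs, keep_xi = FALSE,
                                   ridge = 1e-6) {
  d <- dim(obs)
  n <- d[1L]; Tm <- d[2L]
  logB <- emission_logB(params, obs, ridge)
  A <- params$transition
  pi0 <- params$initial

  alpha <- array(0, c(n, Tm, 2L))
  ms <- matrix(0, n, Tm)       # per-step max log emission (scaling offset)
  cs <- matrix(0, n, Tm)       # per-step normalizers
  lb <- logB[, 1L, , drop = FALSE]; dim(lb) <- c(n, 2L)
  m <- pmax(lb[, 1L], lb[, 2L])
  a <- exp(lb - m) * matrix(pi0, n, 2L, byrow = TRUE)
  cc <- pmax(rowSums(a), .Machine$double.xmin)
  alpha[, 1L, ] <- a / cc; ms[, 1L] <- m; cs[, 1L] <- cc
  if (Tm > 1L) for (t in 2:Tm) {
    pred <- alpha[, t - 1L, ] %*% A
    dim(pred) <- c(n, 2L)
    lb <- logB[, t, , drop = FALSE]; dim(lb) <- c(n, 2L)
    m <- pmax(lb[, 1L], lb[, 2L])
    a <- pred * exp(lb - m)
    cc <- pmax(rowSums(a), .Machine$double.xmin)
    alpha[, t, ] <- a / cc; ms[, t] <- m; cs[, t] <- cc
  }
  loglik <- rowSums(log(cs) + ms)

  beta <- array(0, c(n, Tm, 2L))
  beta[, Tm, ] <- 1
  if (Tm > 1L) for (t in (Tm - 1L):1L) {
    lb <- logB[, t + 1L, , drop = FALSE]; dim(lb) <- c(n, 2L)
    tmp <- beta[, t + 1L, ] * exp(lb - ms[, t + 1L])
    dim(tmp) <- c(n, 2L)
    beta[, t, ] <- (tmp %*% t(A)) / cs[, t + 1L]
  }

  gamma <- alpha * beta
  norm <- gamma[, , 1L] + gamma[, , 2L]
  gamma[, , 1L] <- gamma[, , 1L] / norm
  gamma[, , 2L] <- gamma[, , 2L] / norm

  xi_sum <- matrix(0, 2L, 2L)
  xi_steps <- if (keep_xi && Tm > 1L) array(0, c(Tm - 1L, 2L, 2L)) else NULL
  if (Tm > 1L) for (t in 1L:(Tm - 1L)) {
    u <- alpha[, t, ]; dim(u) <- c(n, 2L)
    lb <- logB[, t + 1L, , drop = FALSE]; dim(lb) <- c(n, 2L)
    v <- exp(lb - ms[, t + 1L]) * beta[, t + 1L, ] / cs[, t + 1L]
    dim(v) <- c(n, 2L)
    xt <- crossprod(u, v) * A
    xi_sum <- xi_sum + xt
    if (keep_xi) {
      # normalize per step when reporting a single sequence
      xi_steps[t, , ] <- xt / sum(xt)
    }
  }
  list(loglik = loglik, gamma = gamma, xi_sum = xi_sum, xi_steps = xi_steps)
}

#' Forward-backward smoothing for one observation sequence
#'
#' Computes, in a scaled (numerically stable) regime, the per-step posterior
#' state probabilities, the pairwise transition posteriors, and the sequence
#' log-likelihood under the model.
#'
#' @param params An [hmm_parameters()] object.
#' @param sequence Numeric matrix, (T-1) x R (rows = time steps), or a
#'   vector when R = 1.
#' @return A list with `posteriors` ((T-1) x 2, columns N, C),
#'   `transition_posteriors` ((T-2) x 2 x 2, `NULL` for length-1 sequences)
#'   and `log_likelihood`.
#' @export
forward_backward <- function(params, sequence) {
  stopifnot(inherits(params, "hmm_parameters"))
  sequence <- as_sequence_matrix(sequence, ncol(params$means))
  if (nrow(sequence) < 1L)
    stop("invalid input: empty observation sequence")
  obs <- array(sequence, c(1L, nrow(sequence), ncol(sequence)))
  fb <- forward_backward_batch(params, obs, keep_xi = TRUE)
  post <- matrix(fb$gamma[1L, , ], ncol = 2L,
                 dimnames = list(NULL, c("N", "C")))
  list(posteriors = post, transition_posteriors = fb$xi_steps,
       log_likelihood = fb$loglik[1L])
}

as_sequence_matrix <- function(sequence, R) {
  if (is.null(dim(sequence))) {
    if (R == 1L) sequence <- matrix(sequence, ncol = 1L)
    else stop("shape error: sequence must be a (T-1) x R matrix")
  }
  if (ncol(sequence) != R)
    stop("shape error: sequence has ", ncol(sequence),
         " columns but the emission dimension is ", R)
  sequence
}
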