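#' Settings for the expectation-maximization fit
#'
#' @param tol Convergence threshold on the relative change in total
#'   log-likelihood between iterations.
#' @param max_iter Maximum EM iterations per restart.
#' @param restarts Number of seeded random restarts; the first uses the
#'   deterministic initialization, later ones jitter it, and the fit with
#'   the best final log-likelihood is kept.
#' @param seed Integer seed controlling the restart jitter.
#' @param zero_mean When `TRUE` (default) the emission means are held at the
#'   zero vector. Differenced expression is centred at zero by construction
#'   (only a minority of steps carry real changes, in either direction), so
#'   freeing the means mostly adds estimation variance; a switch is kept for
#'   data where that assumption is suspect.
#' @param covariance `"full"` (R x R per state, default) or `"diagonal"`.
#' @param var_floor Lower floor applied to the eigenvalues of each state
#'   covariance; prevents collapse on constant features.
#' @param ridge Diagonal ridge added when a Cholesky factorization fails.
#' @param conditions Optional character vector restricting which conditions'
#'   sequences enter the fit (default: all, control included).
#' @return A list of class `em_config`.
#' @export
em_config <- function(tol = 1e-6, max_iter = 500L, restarts = 3L,
                      seed = 1729L, zero_mean = TRUE,
                      covariance = c("full", "diagonal"),
                      var_floor = 1e-8, ridge = 1e-6, conditions = NULL) {
  covariance <- match.arg(covariance)
  stopifnot(tol > 0, max_iter >= 1L, restarts >= 1L, var_floor > 0)
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 restarts = as.integer(restarts), seed = as.integer(seed),
                 zero_mean = isTRUE(zero_mean), covariance = covariance,
                 var_floor = var_floor, ridge = ridge,
                 conditions = conditions),
            class = "em_config")
}

# Stack delta tensors into one observation array: sequences x steps x R.
# Every feature of every (requested) condition is one independent sequence.
pool_sequences <- function(deltas, conditions = NULL) {
  if (inherits(deltas, "delta_tensor")) deltas <- list(deltas)
  stopifnot(length(deltas) >= 1L)
  if (!is.null(conditions)) {
    keep <- vapply(deltas, function(d) d$condition %in% conditions, NA)
    if (!any(keep))
      stop("no delta tensors match the requested conditions")
    deltas <- deltas[keep]
  }
  Rs <- vapply(deltas, function(d) dim(d$deltas)[2L], 0L)
  Tms <- vapply(deltas, function(d) dim(d$deltas)[3L], 0L)
  if (length(unique(Rs)) != 1L || length(unique(Tms)) != 1L)
    stop("alignment error: delta tensors disagree on replicate count or ",
         "number of time steps")
  blocks <- lapply(deltas, function(d) aperm(d$deltas, c(1L, 3L, 2L)))
  obs <- array(0, c(sum(vapply(blocks, function(b) dim(b)[1L], 0L)),
                    Tms[1L], Rs[1L]))
  at <- 0L
  for (b in blocks) {
    obs[at + seq_len(dim(b)[1L]), , ] <- b
    at <- at + dim(b)[1L]
  }
  obs
}

em_initial_params <- function(obs, config, jitter = FALSE) {
  R <- dim(obs)[3L]
  pooled_var <- stats::var(as.vector(obs))
  if (!is.finite(pooled_var) || pooled_var < config$var_floor)
    pooled_var <- max(config$var_floor, pooled_var, na.rm = TRUE)
  scales <- c(0.25, 2.0)        # (N, C) multiples of the pooled variance
  A <- matrix(c(0.9, 0.1, 0.1, 0.9), 2L, byrow = TRUE)
  pi0 <- c(0.5, 0.5)
  if (jitter) {
    scales <- scales * exp(stats::rnorm(2L, 0, 0.3))
    eps <- stats::runif(2L, 0.02, 0.3)
    A <- rbind(c(1 - eps[1L], eps[1L]), c(eps[2L], 1 - eps[2L]))
    p <- stats::runif(1L, 0.2, 0.8)
    pi0 <- c(p, 1 - p)
  }
  covs <- array(0, c(R, R, 2L))
  for (s in 1:2) covs[, , s] <- diag(pooled_var * scales[s], R)
  hmm_parameters(pi0, A, matrix(0, 2L, R), covs)
}

regularize_cov <- function(S, config) {
  S <- (S + t(S)) / 2
  if (config$covariance == "diagonal") S <- diag(diag(S), nrow = nrow(S))
  e <- eigen(S, symmetric = TRUE)
  floored <- any(e$values < config$var_floor)
  if (floored) {
    vals <- pmax(e$values, config$var_floor)
    S <- e$vectors %*% (vals * t(e$vectors))
    S <- (S + t(S)) / 2
  }
  list(cov = S, floored = floored)
}

em_run_once <- function(obs, config, params) {
  n <- dim(obs)[1L]; Tm <- dim(obs)[2L]; R <- dim(obs)[3L]
  Y <- matrix(obs, n * Tm, R)
  trace <- numeric(0)
  converged <- FALSE
  floored_any <- FALSE
  prev <- NA_real_
  it <- 0L
  while (it < config$max_iter) {
    it <- it + 1L
    fb <- forward_backward_batch(params, obs, ridge = config$ridge)
    total <- sum(fb$loglik)
    trace <- c(trace, total)

    # M-step
    g1 <- fb$gamma[, 1L, ]; dim(g1) <- c(n, 2L)
    pi0 <- colMeans(g1)
    pi0 <- pi0 / sum(pi0)
    if (Tm > 1L) {
      rs <- rowSums(fb$xi_sum)
      A <- params$transition
      ok <- rs > .Machine$double.xmin
      A[ok, ] <- fb$xi_sum[ok, , drop = FALSE] / rs[ok]
    } else {
      A <- params$transition
    }
    means <- params$means
    covs <- params$covariances
    for (s in 1:2) {
      w <- as.vector(fb$gamma[, , s])
      sw <- sum(w)
      mu <- if (config$zero_mean) numeric(R) else colSums(Y * w) / sw
      Yc <- sweep(Y, 2L, mu, check.margin = FALSE)
      S <- crossprod(Yc, Yc * w) / sw
      reg <- regularize_cov(S, config)
      floored_any <- floored_any || reg$floored
      means[s, ] <- mu
      covs[, , s] <- reg$cov
    }
    params <- hmm_parameters(pi0, A, means, covs)

    if (!is.na(prev)) {
      rel <- abs(total - prev) / max(abs(prev), .Machine$double.eps)
      if (rel < config$tol) { converged <- TRUE; break }
    }
    prev <- total
  }
  if (floored_any)
    warning("variance floor (", config$var_floor,
            ") applied to a state covariance during EM")
  # final log-likelihood under the last parameter update
  final <- sum(forward_backward_batch(params, obs,
                                      ridge = config$ridge)$loglik)
  trace <- c(trace, final)
  list(params = params, trace = trace, iterations = it,
       converged = converged)
}

# enforce the label convention: state C has the larger covariance trace
relabel_states <- function(params) {
  tr <- vapply(1:2, function(s)
    sum(diag(matrix(params$covariances[, , s],
                    ncol(params$means), ncol(params$means)))), 0)
  if (tr[1L] <= tr[2L]) return(params)
  swap <- c(2L, 1L)
  hmm_parameters(params$initial[swap], params$transition[swap, swap],
                 params$means[swap, , drop = FALSE],
                 params$covariances[, , swap, drop = FALSE])
}

#' Fit the two-state HMM by expectation-maximization
#'
#' All features of all (requested) conditions are pooled as independent
#' observation sequences of length T-1, so the fit sees
#' features x conditions sequences with R-dimensional observations -- the
#' rearrangement that makes estimation feasible despite few samples.
#' Baum-Welch updates guarantee a non-decreasing total log-likelihood;
#' after fitting, the state with the larger covariance trace is labelled
#' `C` ("change").
#'
#' @param deltas A [delta_tensor()] or list of them (one per condition).
#' @param config An [em_config()].
#' @return An object of class `hmm_fit`: `parameters`
#'   ([hmm_parameters()]), `log_likelihood_trace`, `iterations`,
#'   `converged`, `n_sequences`, `restart` (index of the winning restart)
#'   and the `config` used.
#' @export
em_fit <- function(deltas, config = em_config()) {
  stopifnot(inherits(config, "em_config"))
  obs <- pool_sequences(deltas, config$conditions)
  if (dim(obs)[1L] < 2L)
    stop("refusing to fit: need at least 2 observation sequences, got ",
         dim(obs)[1L])
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  best <- NULL
  for (k in seq_len(config$restarts)) {
    set.seed(config$seed + k - 1L)
    params0 <- em_initial_params(obs, config, jitter = k > 1L)
    run <- em_run_once(obs, config, params0)
    if (is.null(best) || utils::tail(run$trace, 1L) >
        utils::tail(best$trace, 1L)) {
      best <- run
      best$restart <- k
    }
  }
  structure(list(parameters = relabel_states(best$params),
                 log_likelihood_trace = best$trace,
                 iterations = best$iterations,
                 converged = best$converged,
                 n_sequences = dim(obs)[1L],
                 restart = best$restart,
                 config = config),
            class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf("EM fit over %d sequences: %d iterations (%s), final log-likelihood %.4f (restart %d)\n",
              x$n_sequences, x$iterations,
              if (x$converged) "converged" else "max_iter reached",
              utils::tail(x$log_likelihood_trace, 1L), x$restart))
  print(x$parameters)
  invisible(x)
}
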