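# Independent brute-force oracles: exhaustive enumeration over all 2^(T-1)
# hidden-state paths. Deliberately naive and loop-based -- these must not
# share code with the implementation they check.

enum_paths <- function(Tm) {
  as.matrix(expand.grid(rep(list(1:2), Tm)))
}

# joint log-probability of one path and the observation sequence
oracle_path_logprob <- function(params, sequence, path) {
  sequence <- rbind(sequence)
  states <- c("N", "C")
  lp <- log(params$initial[path[1L]]) +
    emission_logdensity(params, sequence[1L, ], states[path[1L]])
  if (nrow(sequence) > 1L) {
    for (t in 2:nrow(sequence)) {
      lp <- lp + log(params$transition[path[t - 1L], path[t]]) +
        emission_logdensity(params, sequence[t, ], states[path[t]])
    }
  }
  unname(lp)
}

# log-likelihood by summation over every path (log-sum-exp)
oracle_loglik <- function(params, sequence) {
  paths <- enum_paths(nrow(rbind(sequence)))
  lps <- apply(paths, 1L, function(p) oracle_path_logprob(params, sequence, p))
  m <- max(lps)
  m + log(sum(exp(lps - m)))
}

# best path by enumeration; among exact ties prefers the path with more N
# states early (matches a DP that breaks ties toward N)
oracle_viterbi <- function(params, sequence) {
  paths <- enum_paths(nrow(rbind(sequence)))
  lps <- apply(paths, 1L, function(p) oracle_path_logprob(params, sequence, p))
  best <- which(lps >= max(lps) - 0)
  list(path = paths[best[1L], ], log_probability = max(lps))
}

# random valid two-state parameters with PD covariances
random_params <- function(R, zero_mean = TRUE) {
  p <- runif(1, 0.1, 0.9)
  a <- runif(2, 0.05, 0.95)
  A <- rbind(c(a[1], 1 - a[1]), c(1 - a[2], a[2]))
  means <- if (zero_mean) matrix(0, 2, R) else
    matrix(rnorm(2 * R, 0, 0.5), 2, R)
  covs <- array(0, c(R, R, 2))
  for (s in 1:2) {
    M <- matrix(rnorm(R * R), R, R)
    covs[, , s] <- crossprod(M) / R + diag(runif(1, 0.05, 1), R)
  }
  hmm_parameters(c(p, 1 - p), A, means, covs)
}

# tiny delta tensor filled with given or random values
random_delta_tensor <- function(G, R, Tm, condition = "case", sd = 1) {
  delta_tensor(condition, array(rnorm(G * R * Tm, 0, sd), c(G, R, Tm)),
               sprintf("g%03d", seq_len(G)))
}

random_condition_tensor <- function(G, R, Tn, condition = "case") {
  condition_tensor(condition, array(rnorm(G * R * Tn, 5, 2), c(G, R, Tn)),
                   sprintf("g%03d", seq_len(G)))
}
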