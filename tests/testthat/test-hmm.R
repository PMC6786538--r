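std_params <- function(R = 1) {
  covs <- array(0, c(R, R, 2))
  covs[, , 1] <- diag(1, R); covs[, , 2] <- diag(1, R)
  hmm_parameters(c(0.5, 0.5), matrix(0.5, 2, 2), matrix(0, 2, R), covs)
}

test_that("emission log-density matches the normal closed form", {
  p <- std_params(1)
  expect_equal(emission_logdensity(p, 0, "N"), log(1 / sqrt(2 * pi)),
               tolerance = 1e-12)
  # identical state parameters give identical densities
  for (x in c(-2.3, 0.4, 7)) {
    expect_equal(emission_logdensity(p, x, "N"),
                 emission_logdensity(p, x, "C"))
  }
  expect_error(emission_logdensity(p, c(1, 2), "N"), "shape error")
  expect_error(emission_logdensity(p, 1, "Z"), "unknown state")
})

test_that("diagonal-covariance density is the sum of univariate densities", {
  set.seed(5)
  for (i in 1:10) {
    v <- runif(2, 0.2, 3); mu <- rnorm(2)
    covs <- array(0, c(2, 2, 2))
    covs[, , 1] <- diag(v); covs[, , 2] <- diag(2, 2)
    p <- hmm_parameters(c(0.5, 0.5), matrix(0.5, 2, 2),
                        rbind(mu, c(0, 0)), covs)
    x <- rnorm(2)
    naive <- dnorm(x[1], mu[1], sqrt(v[1]), log = TRUE) +
      dnorm(x[2], mu[2], sqrt(v[2]), log = TRUE)
    expect_equal(emission_logdensity(p, x, "N"), naive, tolerance = 1e-10)
  }
})

test_that("forward-backward handles boundary cases", {
  p <- std_params(1)
  # length-1 sequence: posterior proportional to initial x emission
  fb <- forward_backward(p, matrix(0.3, 1, 1))
  w <- c(0.5, 0.5) * dnorm(0.3)
  expect_equal(as.vector(fb$posteriors), w / sum(w))
  expect_null(fb$transition_posteriors)

  # full symmetry: posteriors 0.5/0.5 at every step
  fb2 <- forward_backward(p, matrix(c(-1, 0, 2, 0.5), 4, 1))
  expect_equal(unname(fb2$posteriors), matrix(0.5, 4, 2))

  expect_error(forward_backward(p, matrix(0, 0, 1)), "empty observation")
})

test_that("forward likelihood and posteriors agree with path enumeration", {
  set.seed(17)
  for (i in 1:15) {
    R <- sample(1:3, 1); Tm <- sample(1:6, 1)
    p <- random_params(R, zero_mean = i %% 2 == 0)
    y <- matrix(rnorm(Tm * R), Tm, R)
    fb <- forward_backward(p, y)
    expect_equal(fb$log_likelihood, oracle_loglik(p, y), tolerance = 1e-8)
    expect_equal(unname(rowSums(fb$posteriors)), rep(1, Tm),
                 tolerance = 1e-10)
    # posterior of state C at each step from the enumeration
    paths <- enum_paths(Tm)
    lps <- apply(paths, 1, function(pp) oracle_path_logprob(p, y, pp))
    wts <- exp(lps - max(lps)); wts <- wts / sum(wts)
    for (t in seq_len(Tm)) {
      expect_equal(unname(fb$posteriors[t, "C"]),
                   sum(wts[paths[, t] == 2]), tolerance = 1e-8)
    }
  }
})

test_that("Viterbi equals exhaustive argmax over all paths", {
  set.seed(23)
  for (i in 1:15) {
    R <- sample(1:3, 1); Tm <- sample(2:10, 1)
    p <- random_params(R)
    y <- matrix(rnorm(Tm * R, 0, 1.5), Tm, R)
    got <- viterbi_decode(p, y, "g", "c")
    want <- oracle_viterbi(p, y)
    expect_equal(got$log_probability, want$log_probability,
                 tolerance = 1e-8)
    expect_identical(got$states, c("N", "C")[want$path])
  }
})

test_that("Viterbi ties break toward N and strong emissions dominate", {
  # exact symmetry: every path has identical probability, N must win
  p <- std_params(1)
  v <- viterbi_decode(p, matrix(c(0.7, -1, 0), 3, 1))
  expect_identical(v$states, c("N", "N", "N"))

  # near-flat transitions: one huge observation flips only its own step
  covs <- array(0, c(1, 1, 2)); covs[, , 1] <- 0.04; covs[, , 2] <- 1
  p2 <- hmm_parameters(c(0.5, 0.5), matrix(0.5, 2, 2), matrix(0, 2, 1), covs)
  v2 <- viterbi_decode(p2, matrix(c(0.01, 5, -0.01), 3, 1))
  expect_identical(v2$states, c("N", "C", "N"))
})

test_that("decoding a sequence is independent of other sequences", {
  set.seed(31)
  p <- random_params(2)
  d <- random_delta_tensor(20, 2, 5)
  paths <- decode_condition(p, d)
  for (g in c(1, 7, 20)) {
    single <- viterbi_decode(p, t(d$deltas[g, , ]), d$feature_ids[g], "case")
    expect_identical(unname(paths[g, ]), single$states)
  }
  # permuted input decodes to permuted output
  perm <- sample(20)
  d2 <- delta_tensor("case", d$deltas[perm, , ], d$feature_ids[perm])
  expect_identical(as.vector(decode_condition(p, d2)),
                   as.vector(paths[perm, ]))
})

test_that("model parameters survive a JSON round trip", {
  set.seed(41)
  p <- random_params(3, zero_mean = FALSE)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_model_json(p, tmp)
  q <- read_model_json(tmp)
  expect_equal(q$initial, p$initial)
  expect_equal(q$transition, p$transition)
  expect_equal(q$means, p$means)
  expect_equal(q$covariances, p$covariances)
})
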