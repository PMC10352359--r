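# The HMM engine: decoding correctness against exhaustive-path oracles,
# fit invariants, determinism, and state matching.

test_that("forward-backward matches exhaustive enumeration on toys", {
  for (seed in 1:10) {
    set.seed(seed)
    K <- sample(2:3, 1); T <- sample(4:7, 1); R <- 3
    model <- toy_model(K, R, seed = seed)
    X <- matrix(rnorm(T * R), T, R)
    post <- forward_backward(model, X)
    oracle <- oracle_enumerate(model, X)
    expect_equal(post$log_evidence, oracle$log_evidence, tolerance = 1e-8)
    expect_equal(post$gamma, oracle$gamma, tolerance = 1e-8)
    expect_equal(unname(rowSums(post$gamma)), rep(1, T), tolerance = 1e-8)
    vit <- viterbi(model, X)
    expect_equal(as.integer(vit), oracle$viterbi)
    expect_equal(attr(vit, "logp"), oracle$viterbi_logp, tolerance = 1e-8)
  }
})

test_that("decoding respects subject boundaries as chain restarts", {
  model <- toy_model(2, 3, seed = 4)
  set.seed(4)
  X1 <- matrix(rnorm(5 * 3), 5, 3); X2 <- matrix(rnorm(4 * 3), 4, 3)
  joint <- forward_backward(model, rbind(X1, X2),
                            boundaries = cbind(start = c(0L, 5L), end = c(5L, 9L)))
  sep1 <- forward_backward(model, X1)
  sep2 <- forward_backward(model, X2)
  expect_equal(joint$log_evidence, sep1$log_evidence + sep2$log_evidence)
  expect_equal(joint$gamma, rbind(sep1$gamma, sep2$gamma))
})

test_that("label permutation symmetry holds for decoding", {
  model <- toy_model(3, 4, seed = 6)
  set.seed(6)
  X <- matrix(rnorm(8 * 4), 8, 4)
  perm <- c(3, 1, 2)
  permuted <- model
  permuted$initial <- model$initial[perm]
  permuted$transition <- model$transition[perm, perm]
  permuted$state_mean <- model$state_mean[perm, ]
  permuted$state_cov <- model$state_cov[perm]
  a <- forward_backward(model, X)
  b <- forward_backward(permuted, X)
  expect_equal(a$log_evidence, b$log_evidence)
  # state k of the original sits at position which(perm == k) in the permuted model
  expect_equal(a$gamma, b$gamma[, match(seq_len(3), perm)])
})

test_that("viterbi path beats random candidate paths", {
  model <- toy_model(3, 3, seed = 9)
  set.seed(9)
  X <- matrix(rnorm(30 * 3), 30, 3)
  vit <- viterbi(model, X)
  logd <- oracle_log_dens(model, X)
  path_logp <- function(p) {
    v <- log(model$initial[p[1]]) + logd[1, p[1]]
    for (t in 2:length(p)) v <- v + log(model$transition[p[t - 1], p[t]]) +
        logd[t, p[t]]
    v
  }
  best <- path_logp(as.integer(vit))
  for (i in 1:200) {
    expect_lte(path_logp(sample.int(3, 30, replace = TRUE)), best)
  }
})

test_that("a one-state model reduces to sample moments and trivial decoding", {
  set.seed(2)
  X <- matrix(rnorm(3000 * 3), 3000, 3) %*% matrix(c(1, .4, 0, 0, 1, .2, 0, 0, 1), 3)
  m <- fit_hmm(X, K = 1, n_restarts = 1, seed = 1)
  expect_equal(m$transition, matrix(1, 1, 1))
  expect_equal(drop(m$state_mean), colMeans(X), tolerance = 1e-2)
  expect_equal(m$state_cov[[1]], cov(X), tolerance = 2e-2)
  post <- forward_backward(m, X)
  expect_true(all(post$gamma == 1))
  # log evidence equals the summed Gaussian log density of the single state
  ld <- sum(oracle_log_dens(m, X))
  expect_equal(post$log_evidence, ld, tolerance = 1e-6)
})

test_that("fitting is deterministic given the seed", {
  sc <- small_cohort(n_per_group = 3, T = 60, seed = 13)
  cd <- standardize_concatenate(sc$cohort)
  m1 <- fit_hmm(cd, K = 3, n_restarts = 2, seed = 5, max_cycles = 40)
  m2 <- fit_hmm(cd, K = 3, n_restarts = 2, seed = 5, max_cycles = 40)
  expect_identical(m1$transition, m2$transition)
  expect_identical(m1$state_mean, m2$state_mean)
  expect_identical(m1$metadata$trace, m2$metadata$trace)
})

test_that("fit invariants: stochasticity, SPD, monotone objective", {
  sc <- small_cohort(n_per_group = 4, T = 80, seed = 29)
  cd <- standardize_concatenate(sc$cohort)
  m <- fit_hmm(cd, K = 4, n_restarts = 2, seed = 3)
  expect_equal(unname(rowSums(m$transition)), rep(1, 4), tolerance = 1e-12)
  expect_equal(sum(m$initial), 1, tolerance = 1e-12)
  for (k in 1:4)
    expect_gt(min(eigen(m$state_cov[[k]], symmetric = TRUE,
                        only.values = TRUE)$values), 0)
  tr <- m$metadata$trace
  expect_true(all(diff(tr) >= -1e-6 * pmax(1, abs(tr[-1]))))
  # reported objective is the best across restarts
  expect_equal(m$metadata$objective, max(m$metadata$restart_objectives))
})

test_that("recovered transition reproduces the truth's stationary law", {
  truth <- make_hmm_truth(3, 8, self_stick = 0.85, mean_scale = 1.2, seed = 44)
  s <- simulate_subject(truth, 6000, seed = 3)
  m <- fit_hmm(s$data, K = 3, n_restarts = 2, seed = 8)
  perm <- match_states(truth, m)
  pi_hat <- stationary_distribution(m$transition)[perm]
  expect_lt(max(abs(pi_hat - stationary_distribution(truth$transition))), 0.03)
})

test_that("state matching recovers identity and reversal", {
  m <- toy_model(4, 5, seed = 12)
  expect_equal(match_states(m, m), 1:4)
  rev_m <- m
  rev_m$state_mean <- m$state_mean[4:1, ]
  rev_m$state_cov <- m$state_cov[4:1]
  expect_equal(match_states(m, rev_m), 4:1)
  # oracle: exhaustive permutation search on correlation similarity
  m2 <- toy_model(4, 5, seed = 13)
  sim <- outer(1:4, 1:4, Vectorize(function(i, j)
    cor(m$state_mean[i, ], m2$state_mean[j, ])))
  perms <- as.matrix(expand.grid(rep(list(1:4), 4)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  scores <- apply(perms, 1, function(p) sum(sim[cbind(1:4, p)]))
  expect_equal(match_states(m, m2), unname(perms[which.max(scores), ]))
})

test_that("models serialize to JSON and back", {
  sc <- small_cohort(n_per_group = 2, T = 50, seed = 3)
  cd <- standardize_concatenate(sc$cohort)
  m <- fit_hmm(cd, K = 2, n_restarts = 1, seed = 1, max_cycles = 30)
  f <- file.path(withr_local_tempdir(), "model.json")
  write_hmm_model(m, f)
  m2 <- read_hmm_model(f)
  expect_equal(m2$transition, m$transition)
  expect_equal(m2$state_mean, m$state_mean)
  expect_equal(m2$state_cov, m$state_cov)
  expect_equal(m2$initial, m$initial)
})

test_that("invalid models are rejected at decode time", {
  model <- toy_model(2, 3, seed = 1)
  model$state_cov[[1]] <- matrix(0, 3, 3)  # not SPD
  expect_error(forward_backward(model, matrix(rnorm(12), 4, 3)),
               "positive definite")
  model2 <- toy_model(2, 3, seed = 1)
  expect_error(forward_backward(model2, matrix(rnorm(8), 4, 2)), "regions")
})
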