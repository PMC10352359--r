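# Shared fixtures and independent oracles, built in code at test time.

# An arbitrary valid Gaussian HMM with random (but reproducible) parameters.
toy_model <- function(K, R, seed = 1, sticky = 0.7) {
  set.seed(seed)
  A <- matrix(stats::runif(K * K), K, K) + diag(sticky * K, K)
  A <- A / rowSums(A)
  init <- stats::runif(K); init <- init / sum(init)
  means <- matrix(stats::rnorm(K * R, sd = 1.5), K, R)
  covs <- lapply(seq_len(K), function(k) {
    W <- matrix(stats::rnorm(R * R, sd = 0.3), R, R)
    crossprod(W) + diag(R)
  })
  structure(list(K = K, R = R, initial = init, transition = A,
                 state_mean = means, state_cov = covs),
            class = "hmm_model")
}

# Dense log-density table (T x K) via plain-R multivariate normal density.
oracle_log_dens <- function(model, X) {
  sapply(seq_len(model$K), function(k) {
    S <- model$state_cov[[k]]
    Si <- solve(S)
    ld <- as.numeric(determinant(S)$modulus)
    apply(X, 1, function(x) {
      d <- x - model$state_mean[k, ]
      -0.5 * (length(x) * log(2 * pi) + ld + sum(d * (Si %*% d)))
    })
  })
}

# Exhaustive enumeration over all K^T latent paths: exact log evidence,
# smoothed posteriors, and the argmax path. Only feasible for tiny T.
oracle_enumerate <- function(model, X) {
  T <- nrow(X); K <- model$K
  logd <- oracle_log_dens(model, X)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T)))
  lp <- apply(paths, 1, function(p) {
    v <- log(model$initial[p[1]]) + logd[1, p[1]]
    if (T > 1) for (t in 2:T)
      v <- v + log(model$transition[p[t - 1], p[t]]) + logd[t, p[t]]
    v
  })
  m <- max(lp)
  log_evidence <- m + log(sum(exp(lp - m)))
  gamma <- sapply(seq_len(K), function(k)
    sapply(seq_len(T), function(t) sum(exp(lp[paths[, t] == k] - m)) /
             sum(exp(lp - m))))
  list(log_evidence = log_evidence,
       gamma = matrix(gamma, T, K),
       viterbi = as.integer(paths[which.max(lp), ]),
       viterbi_logp = max(lp))
}

# Small ready-made cohort shared by io / metrics tests.
small_cohort <- function(n_per_group = 3, T = 40, K = 3, R = 6, seed = 42) {
  truth <- make_hmm_truth(K, R, self_stick = 0.6, mean_scale = 1, seed = seed)
  spec <- cohort_spec(n_control = n_per_group, n_case = n_per_group, T = T,
                      truth_control = truth, target_state = K, delta = 0.1,
                      seed = seed)
  list(truth = truth, spec = spec, cohort = simulate_cohort(spec))
}

withr_local_tempdir <- function(env = parent.frame()) {
  withr::local_tempdir(.local_envir = env)
}

# Minimal parcel_set from a vector of network labels.
as_parcel_set_test <- function(networks) {
  df <- data.frame(region = paste0("r", seq_along(networks)),
                   network = networks, exclude = 0L)
  brainstates:::as_parcel_set(df)
}

# View a ground truth as a decodable model in the standardized data space.
list_truth_as_model <- function(truth, cd) {
  ctr <- cd$standardization$center %||% rep(0, truth$R)
  scl <- cd$standardization$scale %||% rep(1, truth$R)
  D <- diag(1 / scl, truth$R)
  structure(list(
    K = truth$K, R = truth$R, initial = truth$initial,
    transition = truth$transition,
    state_mean = sweep(sweep(truth$means, 2, ctr, "-"), 2, scl, "/"),
    state_cov = lapply(truth$covariances, function(S) D %*% S %*% D)),
    class = "hmm_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
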