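# Classical decoding of a fitted (or hand-specified) Gaussian HMM: smoothed
# per-timepoint state probabilities and the jointly most probable path. The
# chain restarts from the initial distribution at every subject boundary.

model_log_params <- function(model) {
  check_prob_vector(model$initial, name = "initial distribution")
  check_transition(model$transition)
  list(log_init = log(pmax(model$initial, .Machine$double.xmin)),
       log_trans = log(pmax(model$transition, .Machine$double.xmin)))
}

model_log_dens <- function(model, X) {
  if (ncol(X) != model$R)
    stopf("data has %d columns but model expects %d regions", ncol(X), model$R)
  K <- model$K
  logb <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) {
    logb[, k] <- log_mvnorm(X, model$state_mean[k, ],
                            model$state_cov[[k]])
  }
  logb
}

#' Posterior state probabilities (forward-backward)
#'
#' Computes, for every timepoint, the probability of each state given the
#' whole of that subject's observations and the model (the smoothed posterior
#' gamma), together with the log evidence of the data under the model. Uses a
#' numerically scaled forward-backward recursion; every gamma row sums to 1.
#'
#' @param model An `hmm_model` (or any list with `K`, `R`, `initial`,
#'   `transition`, `state_mean`, `state_cov`).
#' @param x A `concat_data` or numeric matrix.
#' @param boundaries Optional boundary matrix for a bare matrix input.
#' @return A `state_posterior`: `gamma` (rows x K), `viterbi` (filled lazily by
#'   [viterbi()]; `NULL` here), `log_evidence`, `boundaries`.
#' @export
forward_backward <- function(model, x, boundaries = NULL) {
  inp <- resolve_input(x, boundaries)
  lp <- model_log_params(model)
  for (k in seq_len(model$K)) chol_spd(model$state_cov[[k]],
                                       sprintf("state %d covariance", k))
  logb <- model_log_dens(model, inp$X)
  fb <- fb_core(logb, inp$boundaries[, 1], inp$boundaries[, 2],
                lp$log_init, lp$log_trans)
  structure(
    list(gamma = fb$gamma, viterbi = NULL, log_evidence = fb$loglik,
         boundaries = inp$boundaries, subject_id = inp$subject_id),
    class = "state_posterior"
  )
}

#' Most probable state path (Viterbi)
#'
#' Decodes the jointly most probable state sequence per subject segment.
#'
#' @inheritParams forward_backward
#' @return Integer vector of 1-based state labels (attribute `logp` carries
#'   the summed log probability of the decoded paths).
#' @export
viterbi <- function(model, x, boundaries = NULL) {
  inp <- resolve_input(x, boundaries)
  lp <- model_log_params(model)
  for (k in seq_len(model$K)) chol_spd(model$state_cov[[k]],
                                       sprintf("state %d covariance", k))
  logb <- model_log_dens(model, inp$X)
  vt <- viterbi_core(logb, inp$boundaries[, 1], inp$boundaries[, 2],
                     lp$log_init, lp$log_trans)
  structure(as.integer(vt$path), logp = vt$logp)
}

#' Decode both posteriors and the Viterbi path
#'
#' Convenience wrapper returning a complete `state_posterior` with both the
#' smoothed gamma and the Viterbi path.
#'
#' @inheritParams forward_backward
#' @export
decode_states <- function(model, x, boundaries = NULL) {
  post <- forward_backward(model, x, boundaries)
  post$viterbi <- viterbi(model, x, boundaries)
  post
}

#' Match the states of two models
#'
#' Finds the permutation `p` of `1..K` maximizing the total similarity between
#' states of `model_a` and states `p` of `model_b`. Similarity is the Pearson
#' correlation of state means; ties are broken by the Frobenius distance of
#' the state covariances. For `K <= 8` the assignment is solved exactly by
#' enumeration over all permutations; beyond that a greedy assignment is used.
#'
#' State labels of an HMM are arbitrary, so every cross-run or truth-vs-fit
#' comparison should go through this matching first.
#'
#' @param model_a,model_b Models (or `hmm_truth` objects) with equal `K`, `R`.
#' @return Integer permutation: state `k` of `model_a` corresponds to state
#'   `match_states(a, b)[k]` of `model_b`.
#' @export
match_states <- function(model_a, model_b) {
  get_means <- function(m) if (is.matrix(m$means)) m$means else m$state_mean
  get_covs <- function(m) if (!is.null(m$covariances)) m$covariances else m$state_cov
  ma <- get_means(model_a); mb <- get_means(model_b)
  ca <- get_covs(model_a); cb <- get_covs(model_b)
  K <- nrow(ma)
  if (nrow(mb) != K || ncol(mb) != ncol(ma))
    stopf("models must share K and R to be matched")

  sim <- matrix(0, K, K)
  tie <- matrix(0, K, K)
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      s <- suppressWarnings(stats::cor(ma[i, ], mb[j, ]))
      if (!is.finite(s)) s <- -sqrt(mean((ma[i, ] - mb[j, ])^2))
      sim[i, j] <- s
      tie[i, j] <- -sqrt(sum((ca[[i]] - cb[[j]])^2))
    }
  }
  if (K == 1L) return(1L)
  if (K <= 8L) {
    perms <- permutations_of(K)
    idx <- cbind(rep(seq_len(K), nrow(perms)), as.vector(t(perms)))
    scores <- rowSums(matrix(sim[idx], nrow(perms), K, byrow = TRUE))
    best <- max(scores)
    cand <- which(scores > best - 1e-12)
    if (length(cand) > 1L) {
      tiescore <- rowSums(matrix(tie[cbind(rep(seq_len(K), length(cand)),
                                           as.vector(t(perms[cand, , drop = FALSE])))],
                                 length(cand), K, byrow = TRUE))
      cand <- cand[which.max(tiescore)]
    } else cand <- cand[1]
    return(as.integer(perms[cand, ]))
  }
  # greedy fallback for large K
  perm <- integer(K)
  used <- logical(K)
  for (i in order(apply(sim, 1L, max), decreasing = TRUE)) {
    j <- order(sim[i, ] + 1e-9 * tie[i, ], decreasing = TRUE)
    j <- j[!used[j]][1]
    perm[i] <- j
    used[j] <- TRUE
  }
  perm
}

permutations_of <- function(K) {
  if (K == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(K - 1L)
  out <- matrix(0L, 0, K)
  for (pos in seq_len(K)) {
    block <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], K,
                   sub[, seq(pos, K - 1L)[seq_len(K - pos)], drop = FALSE])
    out <- rbind(out, block)
  }
  storage.mode(out) <- "integer"
  out
}
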