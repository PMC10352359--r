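# Variational-Bayes inversion of the multivariate-Gaussian hidden Markov
# model. Conjugate priors: Dirichlet on the initial distribution and on each
# transition row, Gaussian-Wishart on each state's (mean, precision). The
# scalar objective tracked across cycles is the (negative) variational free
# energy; surplus states lose responsibility mass under the free-energy
# penalty and collapse onto their priors, which is what occupancy-based model
# order selection exploits.

#' Prior configuration for the variational HMM
#'
#' @param alpha_init Dirichlet pseudo-count for each entry of the initial
#'   distribution.
#' @param alpha_trans Dirichlet pseudo-count for each entry of a transition
#'   row. Small values (< 1) favour sparse state usage and help surplus states
#'   empty out.
#' @param beta0 Prior precision-scaling of the state means (small = vague).
#' @param nu0_extra Wishart degrees of freedom in excess of `R + 1`
#'   (`nu0 = R + 1 + nu0_extra`).
#' @param cov_floor Relative diagonal floor used when a covariance must be
#'   repaired to positive definiteness, as a fraction of the mean column
#'   variance.
#' @return A list of class `hmm_prior`.
#' @export
hmm_prior <- function(alpha_init = 1, alpha_trans = 0.1, beta0 = 1e-2,
                      nu0_extra = 1, cov_floor = 1e-6) {
  stopifnot(alpha_init > 0, alpha_trans > 0, beta0 > 0, nu0_extra > 0,
            cov_floor >= 0)
  structure(list(alpha_init = alpha_init, alpha_trans = alpha_trans,
                 beta0 = beta0, nu0_extra = nu0_extra, cov_floor = cov_floor),
            class = "hmm_prior")
}

# Resolve a concat_data or bare matrix into (X, boundaries)
resolve_input <- function(x, boundaries = NULL) {
  if (inherits(x, "concat_data")) {
    list(X = x$matrix, boundaries = x$boundaries,
         subject_id = x$subject_id)
  } else {
    X <- as.matrix(x)
    if (is.null(boundaries))
      boundaries <- cbind(start = 0L, end = nrow(X))
    list(X = X, boundaries = boundaries,
         subject_id = paste0("seg", seq_len(nrow(boundaries))))
  }
}

# Expected log emission density under q(mu_k, Lambda_k); n x K matrix.
# Uses the cached posterior-mean precision W_k and its log-determinant.
vb_elog_dens <- function(X, post) {
  n <- nrow(X); R <- ncol(X); K <- length(post$nu)
  out <- matrix(0, n, K)
  x2 <- NULL
  for (k in seq_len(K)) {
    Wk <- post$W[[k]]
    elogdet <- sum(digamma((post$nu[k] + 1 - seq_len(R)) / 2)) +
      R * log(2) + post$logdetW[k]
    m <- post$m[k, ]
    Wm <- Wk %*% m
    XW <- X %*% Wk
    quad <- rowSums(XW * X) - 2 * drop(X %*% Wm) + drop(crossprod(m, Wm))
    out[, k] <- 0.5 * (elogdet - R * log(2 * pi)) -
      0.5 * (R / post$beta[k] + post$nu[k] * quad)
  }
  out
}

# Gaussian-Wishart M-step given responsibilities; returns posterior list.
vb_mstep_gw <- function(X, gamma, prior_gw) {
  n <- nrow(X); R <- ncol(X); K <- ncol(gamma)
  Nk <- colSums(gamma)
  post <- list(beta = prior_gw$beta0 + Nk,
               nu = prior_gw$nu0 + Nk,
               m = matrix(0, K, R),
               Winv = vector("list", K),
               W = vector("list", K),
               logdetW = numeric(K),
               Nk = Nk)
  for (k in seq_len(K)) {
    if (Nk[k] > 0) {
      xbar <- colSums(X * gamma[, k]) / Nk[k]
    } else {
      xbar <- prior_gw$m0
    }
    post$m[k, ] <- (prior_gw$beta0 * prior_gw$m0 + Nk[k] * xbar) / post$beta[k]
    Xc <- sweep(X, 2L, xbar, "-")
    Sk <- crossprod(Xc, Xc * gamma[, k])          # N_k * S_k
    d0 <- xbar - prior_gw$m0
    Winv <- prior_gw$W0inv + Sk +
      (prior_gw$beta0 * Nk[k] / post$beta[k]) * tcrossprod(d0)
    Winv <- (Winv + t(Winv)) / 2
    ch <- tryCatch(chol(Winv), error = function(e) NULL)
    if (is.null(ch)) {
      Winv <- Winv + diag(prior_gw$floor_abs, R)
      ch <- chol(Winv)
    }
    post$Winv[[k]] <- Winv
    post$W[[k]] <- chol2inv(ch)
    post$logdetW[k] <- -2 * sum(log(diag(ch)))
  }
  post
}

kl_dirichlet <- function(alpha_q, alpha_p) {
  a0q <- sum(alpha_q); a0p <- sum(alpha_p)
  lgamma(a0q) - sum(lgamma(alpha_q)) - lgamma(a0p) + sum(lgamma(alpha_p)) +
    sum((alpha_q - alpha_p) * (digamma(alpha_q) - digamma(a0q)))
}

# KL(q || p) for the Gaussian-Wishart factor of state k.
kl_gauss_wishart <- function(post, k, prior_gw) {
  m <- post$m[k, ]; beta <- post$beta[k]; nu <- post$nu[k]
  Wq <- post$W[[k]]; logdetWq <- post$logdetW[k]
  R <- length(m)
  elogdet <- sum(digamma((nu + 1 - seq_len(R)) / 2)) + R * log(2) + logdetWq
  # Gaussian part, expectation over q(Lambda)
  d <- m - prior_gw$m0
  quad <- prior_gw$beta0 * nu * sum(d * (Wq %*% d))
  kl_gauss <- 0.5 * (R * (prior_gw$beta0 / beta - 1 - log(prior_gw$beta0 / beta)) +
                       quad)
  # Wishart part
  nu0 <- prior_gw$nu0
  logZ_q <- (nu / 2) * logdetWq + nu * R / 2 * log(2) + lmvgamma(nu / 2, R)
  logZ_p <- (nu0 / 2) * prior_gw$logdetW0 + nu0 * R / 2 * log(2) +
    lmvgamma(nu0 / 2, R)
  kl_wish <- (nu - nu0) / 2 * elogdet - nu * R / 2 +
    (nu / 2) * sum(prior_gw$W0inv * Wq) + logZ_p - logZ_q
  kl_gauss + kl_wish
}

# Hard labels -> smoothed responsibilities
labels_to_gamma <- function(labels, K, smooth = 0.1) {
  n <- length(labels)
  gamma <- matrix(smooth / K, n, K)
  gamma[cbind(seq_len(n), labels)] <- 1 - smooth + smooth / K
  gamma
}

# Segment-aware hard transition counts for initialization
hard_transition_counts <- function(labels, K, boundaries) {
  counts <- matrix(0, K, K)
  first <- numeric(K)
  for (s in seq_len(nrow(boundaries))) {
    idx <- (boundaries[s, 1] + 1L):boundaries[s, 2]
    lab <- labels[idx]
    first[lab[1]] <- first[lab[1]] + 1
    if (length(lab) > 1L) {
      from <- lab[-length(lab)]; to <- lab[-1L]
      for (i in seq_along(from)) counts[from[i], to[i]] <- counts[from[i], to[i]] + 1
    }
  }
  list(counts = counts, first = first)
}

vb_single_run <- function(X, boundaries, K, max_cycles, tol, seed, prior) {
  n <- nrow(X); R <- ncol(X)
  colvar <- apply(X, 2L, stats::var)
  prior_gw <- list(
    m0 = colMeans(X),
    beta0 = prior$beta0,
    nu0 = R + 1 + prior$nu0_extra,
    W0inv = diag(colvar * (R + 1 + prior$nu0_extra), R),
    floor_abs = max(prior$cov_floor * mean(colvar), 1e-12)
  )
  prior_gw$logdetW0 <- -sum(log(diag(prior_gw$W0inv)))
  a_init0 <- rep(prior$alpha_init, K)
  a_trans0 <- matrix(prior$alpha_trans, K, K)

  # --- initialization: k-means on a row subsample, nearest-centre labels ---
  labels <- with_seed(seed, {
    idx <- if (n > 2000L) sample.int(n, 2000L) else seq_len(n)
    km <- tryCatch(
      stats::kmeans(X[idx, , drop = FALSE], centers = min(K, length(idx)),
                    iter.max = 50L, nstart = 3L),
      error = function(e) NULL
    )
    if (is.null(km)) {
      sample.int(K, n, replace = TRUE)
    } else {
      centers <- km$centers
      if (nrow(centers) < K) {
        extra <- X[sample.int(n, K - nrow(centers)), , drop = FALSE]
        centers <- rbind(centers, extra)
      }
      d2 <- outer(rowSums(X^2), rep(1, K)) - 2 * X %*% t(centers) +
        outer(rep(1, n), rowSums(centers^2))
      max.col(-d2, ties.method = "first")
    }
  })
  gamma <- labels_to_gamma(labels, K)
  hc <- hard_transition_counts(labels, K, boundaries)
  post_gw <- vb_mstep_gw(X, gamma, prior_gw)
  a_init <- a_init0 + hc$first
  a_trans <- a_trans0 + hc$counts

  trace <- numeric(0)
  elbo_prev <- -Inf
  converged <- FALSE
  fb <- NULL
  for (cycle in seq_len(max_cycles)) {
    elog_pi <- digamma(a_init) - digamma(sum(a_init))
    elog_A <- digamma(a_trans) - digamma(rowSums(a_trans))
    logb <- vb_elog_dens(X, post_gw)
    fb <- fb_core(logb, boundaries[, 1], boundaries[, 2], elog_pi,
                  matrix(elog_A, K, K))
    if (!is.finite(fb$loglik))
      stopf("non-finite objective at cycle %d", cycle)
    kl <- kl_dirichlet(a_init, a_init0)
    for (j in seq_len(K)) kl <- kl + kl_dirichlet(a_trans[j, ], a_trans0[j, ])
    for (k in seq_len(K)) kl <- kl + kl_gauss_wishart(post_gw, k, prior_gw)
    elbo <- fb$loglik - kl
    trace <- c(trace, elbo)
    if (cycle > 1L && abs(elbo - elbo_prev) < tol * abs(elbo)) {
      converged <- TRUE
      # parameters already consistent with this ELBO; stop here
      break
    }
    elbo_prev <- elbo
    # --- M-step ---
    gamma <- fb$gamma
    a_init <- a_init0 + fb$init_counts
    a_trans <- a_trans0 + fb$xi
    post_gw <- vb_mstep_gw(X, gamma, prior_gw)
  }

  Nk <- colSums(fb$gamma)
  list(elbo = trace[length(trace)], trace = trace, cycles = length(trace),
       converged = converged, gamma = fb$gamma,
       a_init = a_init, a_trans = a_trans, post_gw = post_gw,
       occupancy = Nk / n)
}

#' Fit a Gaussian hidden Markov model by variational Bayes
#'
#' Runs `n_restarts` independent variational-Bayes inversions (restart `i`
#' seeded with `seed + i - 1`), each alternating a forward-backward E-step
#' over the whole concatenation (the chain restarts from the initial
#' distribution at every subject boundary) with conjugate M-step updates,
#' until the relative change of the variational objective falls below `tol`
#' or `max_cycles` is reached. The restart with the best objective (lowest
#' free energy) is returned.
#'
#' States that the data cannot support lose responsibility mass and collapse
#' onto their priors; they are retained in the model and flagged in
#' `metadata$prior_dominated`.
#'
#' @param x A `concat_data` (from [standardize_concatenate()]) or a numeric
#'   matrix (rows = timepoints).
#' @param K Number of states (>= 1).
#' @param max_cycles Maximum variational cycles per restart (default 500).
#' @param tol Relative objective-change convergence tolerance.
#' @param n_restarts Independent initializations.
#' @param seed Integer seed; all randomness derives from it.
#' @param prior An [hmm_prior()] configuration.
#' @param boundaries Optional explicit boundary matrix when `x` is a bare
#'   matrix (columns `start`, `end`; 0-based half-open).
#' @return An `hmm_model`: `K`, `R`, `initial`, `transition` (posterior-mean,
#'   row-stochastic), `state_mean` (K x R), `state_cov` (list of K SPD
#'   matrices), and `metadata` (free-energy trace, cycles, restart index,
#'   occupancy, flags, seed).
#' @export
fit_hmm <- function(x, K, max_cycles = 500L, tol = 1e-7, n_restarts = 5L,
                    seed = 1L, prior = hmm_prior(), boundaries = NULL) {
  K <- check_scalar_int(K, "K", min = 1)
  max_cycles <- check_scalar_int(max_cycles, "max_cycles", min = 1)
  n_restarts <- check_scalar_int(n_restarts, "n_restarts", min = 1)
  inp <- resolve_input(x, boundaries)
  if (nrow(inp$X) <= K)
    stopf("need many more rows (%d) than states (%d)", nrow(inp$X), K)

  runs <- vector("list", n_restarts)
  for (i in seq_len(n_restarts)) {
    runs[[i]] <- vb_single_run(inp$X, inp$boundaries, K, max_cycles, tol,
                               seed = seed + i - 1L, prior = prior)
  }
  elbos <- vapply(runs, function(r) r$elbo, numeric(1))
  best_i <- which.max(elbos)
  best <- runs[[best_i]]

  R <- ncol(inp$X)
  state_cov <- lapply(seq_len(K), function(k) {
    S <- best$post_gw$Winv[[k]] / (best$post_gw$nu[k] - R - 1)
    (S + t(S)) / 2
  })
  model <- structure(
    list(K = K, R = R,
         initial = as.numeric(best$a_init / sum(best$a_init)),
         transition = best$a_trans / rowSums(best$a_trans),
         state_mean = best$post_gw$m,
         state_cov = state_cov,
         metadata = list(
           objective = best$elbo,
           free_energy = -best$elbo,
           trace = best$trace,
           cycles = best$cycles,
           converged = best$converged,
           restart = best_i,
           restart_objectives = elbos,
           occupancy = best$occupancy,
           prior_dominated = best$occupancy * nrow(inp$X) < R + 1,
           seed = as.integer(seed),
           prior = prior,
           n_rows = nrow(inp$X))),
    class = "hmm_model"
  )
  model
}

#' @export
print.hmm_model <- function(x, ...) {
  cat(sprintf("Gaussian HMM (variational Bayes): K = %d states, R = %d regions\n",
              x$K, x$R))
  cat(sprintf("  free energy %.2f after %d cycles (restart %d of %d)%s\n",
              x$metadata$free_energy, x$metadata$cycles, x$metadata$restart,
              length(x$metadata$restart_objectives),
              if (x$metadata$converged) "" else " [not converged]"))
  occ <- paste(sprintf("%.3f", x$metadata$occupancy), collapse = ", ")
  cat("  occupancy: ", occ, "\n", sep = "")
  invisible(x)
}

#' Serialize a fitted model to JSON
#' @param model An `hmm_model`.
#' @param path Output file.
#' @export
write_hmm_model <- function(model, path) {
  stopifnot(inherits(model, "hmm_model"))
  obj <- list(K = model$K, R = model$R, initial = model$initial,
              transition = model$transition, state_mean = model$state_mean,
              state_cov = model$state_cov,
              metadata = model$metadata[c("objective", "free_energy", "cycles",
                                          "converged", "restart", "occupancy",
                                          "seed", "n_rows")])
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a model written by [write_hmm_model()]
#' @param path JSON file.
#' @export
read_hmm_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(x, nr, nc) {
    if (is.matrix(x)) return(x)
    matrix(unlist(x), nr, nc, byrow = TRUE)
  }
  covs <- obj$state_cov
  if (is.array(covs) && length(dim(covs)) == 3L) {
    covs <- lapply(seq_len(dim(covs)[1]), function(k) covs[k, , ])
  } else {
    covs <- lapply(seq_len(obj$K), function(k) as_mat(covs[[k]], obj$R, obj$R))
  }
  structure(
    list(K = obj$K, R = obj$R, initial = obj$initial,
         transition = as_mat(obj$transition, obj$K, obj$K),
         state_mean = as_mat(obj$state_mean, obj$K, obj$R),
         state_cov = covs,
         metadata = obj$metadata),
    class = "hmm_model"
  )
}
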