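# Synthetic cohorts: ground-truth Markov-switching Gaussian time series with a
# two-group design (altered stickiness of one target state) and a severity
# score tied to the target state's realized occupancy.

#' Construct a ground-truth Gaussian HMM
#'
#' Builds a K-state hidden Markov model with a sticky, symmetric transition
#' structure: every diagonal entry equals `self_stick` and the remaining row
#' mass is spread uniformly over the other states. State means are drawn with
#' Euclidean norm `mean_scale * sqrt(R)` (so `mean_scale` is the per-region
#' root-mean-square activity of a state) and covariances are built from random
#' rank-2 factors plus a diagonal floor, guaranteeing symmetric positive
#' definiteness. The initial distribution is the chain's stationary
#' distribution, which removes burn-in transients at short scan lengths.
#'
#' @param K Number of states (>= 1).
#' @param R Number of regions (>= 1).
#' @param self_stick Self-transition probability in `[0, 1)` (for `K = 1` the
#'   single state necessarily has self-transition 1).
#' @param mean_scale Per-region RMS amplitude of the state means; `0` gives
#'   zero-mean emissions in every state.
#' @param seed Integer seed; the construction is fully reproducible from it.
#' @return An object of class `hmm_truth` with fields `K`, `R`, `initial`,
#'   `transition`, `means` (K x R matrix) and `covariances` (list of K R x R
#'   matrices).
#' @export
make_hmm_truth <- function(K, R, self_stick = 0.5, mean_scale = 1, seed = 1L) {
  K <- check_scalar_int(K, "K", min = 1)
  R <- check_scalar_int(R, "R", min = 1)
  if (!is.numeric(self_stick) || length(self_stick) != 1L ||
      self_stick < 0 || self_stick >= 1) {
    if (K > 1L || !isTRUE(all.equal(self_stick, 1)))
      stopf("`self_stick` must lie in [0, 1)")
  }
  if (mean_scale < 0) stopf("`mean_scale` must be >= 0")

  if (K == 1L) {
    transition <- matrix(1, 1, 1)
  } else {
    off <- (1 - self_stick) / (K - 1)
    transition <- matrix(off, K, K)
    diag(transition) <- self_stick
  }

  out <- with_seed(seed, {
    means <- matrix(0, K, R)
    if (mean_scale > 0) {
      for (k in seq_len(K)) {
        z <- stats::rnorm(R)
        means[k, ] <- mean_scale * sqrt(R) * z / sqrt(sum(z^2))
      }
    }
    covariances <- vector("list", K)
    for (k in seq_len(K)) {
      W <- matrix(stats::rnorm(R * 2L), R, 2L)
      S <- tcrossprod(W) / 2
      covariances[[k]] <- 0.5 * S + diag(0.5, R)
    }
    list(means = means, covariances = covariances)
  })

  structure(
    list(K = K, R = R,
         initial = stationary_distribution(transition),
         transition = transition,
         means = out$means,
         covariances = out$covariances,
         self_stick = if (K == 1L) 1 else self_stick,
         mean_scale = mean_scale,
         seed = as.integer(seed)),
    class = "hmm_truth"
  )
}

#' @export
print.hmm_truth <- function(x, ...) {
  cat(sprintf("Ground-truth Gaussian HMM: K = %d states, R = %d regions\n",
              x$K, x$R))
  cat(sprintf("  diagonal self-transition: %s; mean RMS amplitude: %s\n",
              format(x$self_stick), format(x$mean_scale)))
  invisible(x)
}

#' Expected dwell time of a state
#'
#' Closed-form mean run length of a Markov chain state: visits to state `k`
#' have geometric length with mean `1 / (1 - A[k, k])` timepoints. Used as the
#' analytic yardstick for the averaged-lifetime statistic.
#'
#' @param transition Row-stochastic transition matrix.
#' @param k State index (1-based).
#' @return Expected dwell time in timepoints; `Inf` when `A[k, k] = 1`.
#' @export
expected_dwell <- function(transition, k) {
  check_transition(transition)
  k <- check_scalar_int(k, "k", min = 1)
  if (k > nrow(transition)) stopf("state index %d out of range", k)
  a <- transition[k, k]
  if (a >= 1) Inf else 1 / (1 - a)
}

#' Stationary distribution of a transition matrix
#'
#' Solves `pi %*% A = pi` for the unique stationary law of an irreducible,
#' aperiodic chain. Gives the long-run fractional occupancy implied by a
#' transition matrix.
#'
#' @param transition Row-stochastic transition matrix.
#' @return Probability vector of length `K`.
#' @export
stationary_distribution <- function(transition) {
  check_transition(transition)
  K <- nrow(transition)
  if (K == 1L) return(1)
  e <- eigen(t(transition))
  mods <- Mod(e$values)
  near_one <- which(abs(e$values - 1) < 1e-9)
  if (length(near_one) != 1L || sum(mods > 1 - 1e-9) > 1L)
    stopf("chain has no unique stationary distribution (reducible or periodic)")
  v <- Re(e$vectors[, near_one])
  pi_star <- v / sum(v)
  if (any(pi_star < -1e-10))
    stopf("chain has no unique stationary distribution (reducible or periodic)")
  pmax(pi_star, 0) / sum(pmax(pi_star, 0))
}

#' Raise one state's self-transition probability
#'
#' Returns a copy of a ground-truth model in which state `state`'s
#' self-transition is increased by `delta`, with that row's off-diagonal mass
#' shrunk proportionally so the row still sums to one. All other rows and the
#' emission parameters are untouched; the initial distribution is reset to the
#' new stationary law. This is the mechanism by which the case group's dynamics
#' differ from controls.
#'
#' @param truth An `hmm_truth` object.
#' @param state Target state index.
#' @param delta Increment of the self-transition probability (may be negative);
#'   the result must stay in `[0, 1)`.
#' @return A new `hmm_truth`.
#' @export
perturb_self_transition <- function(truth, state, delta) {
  stopifnot(inherits(truth, "hmm_truth"))
  state <- check_scalar_int(state, "state", min = 1)
  if (state > truth$K) stopf("state index %d out of range", state)
  A <- truth$transition
  new_diag <- A[state, state] + delta
  if (new_diag < 0 || new_diag >= 1)
    stopf("perturbed self-transition %.3f outside [0, 1)", new_diag)
  off <- A[state, -state]
  if (sum(off) <= 0 && delta != 0)
    stopf("row %d has no off-diagonal mass to renormalize", state)
  A[state, -state] <- off * (1 - new_diag) / sum(off)
  A[state, state] <- new_diag
  truth$transition <- A
  truth$initial <- stationary_distribution(A)
  truth
}

# Simulate a latent Markov path of length T (internal; vector of 1-based states)
simulate_markov_path <- function(initial, transition, T) {
  K <- length(initial)
  path <- integer(T)
  cum_init <- cumsum(initial)
  cum_trans <- t(apply(transition, 1L, cumsum))
  if (K == 1L) return(rep(1L, T))
  u <- stats::runif(T)
  path[1L] <- findInterval(u[1L], cum_init, left.open = TRUE) + 1L
  for (t in 2L:T) {
    path[t] <- findInterval(u[t], cum_trans[path[t - 1L], ], left.open = TRUE) + 1L
  }
  pmin(path, K)
}

#' Simulate one subject's time series from a ground-truth HMM
#'
#' Samples a latent state path from the truth's initial distribution and
#' transition matrix, then draws each timepoint from the multivariate normal
#' of the active state.
#'
#' @param truth An `hmm_truth`.
#' @param T Number of timepoints (>= 2).
#' @param seed Integer seed (per subject).
#' @param subject_id,group,age,sex,severity Identity and covariates attached to
#'   the subject; defaults are placeholders for single-subject use.
#' @param emissions If `FALSE`, only the latent path is generated (`data` is
#'   `NULL`); useful for large dynamics-only simulations.
#' @return An object of class `subject_ts` with fields `subject_id`, `group`,
#'   `age`, `sex`, `severity`, `data` (T x R matrix) and `latent_path`.
#' @export
simulate_subject <- function(truth, T, seed,
                             subject_id = "s1", group = "control",
                             age = NA_real_, sex = NA_character_,
                             severity = NA_real_, emissions = TRUE) {
  stopifnot(inherits(truth, "hmm_truth"))
  T <- check_scalar_int(T, "T", min = 2)
  with_seed(seed, {
    path <- simulate_markov_path(truth$initial, truth$transition, T)
    data <- NULL
    if (emissions) {
      data <- matrix(stats::rnorm(T * truth$R), T, truth$R)
      for (k in unique(path)) {
        idx <- which(path == k)
        U <- chol_spd(truth$covariances[[k]])
        data[idx, ] <- data[idx, , drop = FALSE] %*% U
        data[idx, ] <- sweep(data[idx, , drop = FALSE], 2L, truth$means[k, ], "+")
      }
    }
    structure(
      list(subject_id = subject_id, group = group, age = age, sex = sex,
           severity = severity, data = data, latent_path = path,
           T = T, R = truth$R),
      class = "subject_ts"
    )
  })
}

#' Specify a two-group synthetic cohort
#'
#' Describes a cohort of control and case subjects whose time series follow
#' Markov-switching multivariate normals. The two groups share emission
#' parameters; the case group's transition matrix differs only in the target
#' state's self-transition probability, raised by `delta` (off-diagonal mass
#' renormalized proportionally). A severity score, generated for case subjects
#' only (emulating a self-rated depression scale available for patients), is a
#' linear function of each subject's realized fractional occupancy of the
#' target state plus Gaussian noise.
#'
#' Defaults describe the package's reference simulation: a 6-state model over
#' 20 regions, 232 timepoints per subject (the retained scan length of a
#' TR = 2 s acquisition), control self-transition 0.45 (mean state dwell of
#' about 3.6 s), and a case increment of +0.15 on state 6. The stickiness
#' default comes from an a-priori operating-characteristic calculation for
#' the default two-group design; see the package vignette.
#'
#' @param n_control,n_case Subjects per group.
#' @param T Timepoints per subject.
#' @param truth_control Ground-truth `hmm_truth` for controls.
#' @param target_state State whose stickiness differs in cases.
#' @param delta Increment of the target state's self-transition for cases.
#' @param severity_slope,severity_noise_sd Linear link from realized target-state
#'   FO to the severity score of case subjects.
#' @param age_range Uniform range for the age covariate (years).
#' @param sex_p Probability of the "female" label.
#' @param medication_p Probability a case subject carries the medication flag.
#' @param seed Integer master seed for the cohort.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_control = 60L, n_case = 60L, T = 232L,
                        truth_control = make_hmm_truth(6L, 20L,
                                                       self_stick = 0.45,
                                                       mean_scale = 1,
                                                       seed = 1L),
                        target_state = 6L, delta = 0.15,
                        severity_slope = 40, severity_noise_sd = 6,
                        age_range = c(18, 65), sex_p = 0.6,
                        medication_p = 0.5, seed = 1L) {
  stopifnot(inherits(truth_control, "hmm_truth"))
  spec <- list(
    n_control = check_scalar_int(n_control, "n_control", min = 1),
    n_case = check_scalar_int(n_case, "n_case", min = 1),
    T = check_scalar_int(T, "T", min = 2),
    truth_control = truth_control,
    truth_case = perturb_self_transition(truth_control, target_state, delta),
    target_state = check_scalar_int(target_state, "target_state", min = 1),
    delta = delta,
    severity_slope = severity_slope,
    severity_noise_sd = severity_noise_sd,
    age_range = age_range,
    sex_p = sex_p,
    medication_p = medication_p,
    seed = as.integer(seed)
  )
  structure(spec, class = "cohort_spec")
}

#' Simulate a two-group cohort
#'
#' Generates every subject of a [cohort_spec()]: controls follow
#' `truth_control`, cases follow `truth_case`. Each case subject's severity is
#' `severity_slope * FO_target + N(0, severity_noise_sd)` where `FO_target` is
#' that subject's realized (hard-path) fractional occupancy of the target
#' state; controls carry a missing severity. Age and sex are generated
#' independently of the dynamics. Regenerating a cohort from the same spec and
#' seed reproduces it exactly.
#'
#' @param spec A `cohort_spec`.
#' @param emissions If `FALSE`, latent paths only (fast dynamics-level studies).
#' @return A list with `subjects` (list of `subject_ts`) and `manifest`
#'   (tibble: subject_id, group, age, sex, severity, medication, path).
#' @export
simulate_cohort <- function(spec, emissions = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_control + spec$n_case
  groups <- rep(c("control", "case"), c(spec$n_control, spec$n_case))
  ids <- sprintf("sub-%03d", seq_len(n))

  covars <- with_seed(spec$seed, {
    list(
      age = stats::runif(n, spec$age_range[1], spec$age_range[2]),
      sex = ifelse(stats::runif(n) < spec$sex_p, "female", "male"),
      medication = ifelse(groups == "case",
                          as.integer(stats::runif(n) < spec$medication_p), 0L),
      sev_noise = stats::rnorm(n, 0, spec$severity_noise_sd),
      subject_seeds = sample.int(.Machine$integer.max - 1L, n)
    )
  })

  subjects <- vector("list", n)
  severity <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    truth_i <- if (groups[i] == "case") spec$truth_case else spec$truth_control
    subjects[[i]] <- simulate_subject(
      truth_i, spec$T, seed = covars$subject_seeds[i],
      subject_id = ids[i], group = groups[i],
      age = covars$age[i], sex = covars$sex[i], emissions = emissions
    )
    if (groups[i] == "case") {
      fo_target <- mean(subjects[[i]]$latent_path == spec$target_state)
      severity[i] <- spec$severity_slope * fo_target + covars$sev_noise[i]
      subjects[[i]]$severity <- severity[i]
    }
  }

  manifest <- tibble::tibble(
    subject_id = ids, group = groups,
    age = covars$age, sex = covars$sex,
    severity = severity, medication = covars$medication,
    path = NA_character_
  )
  list(subjects = subjects, manifest = manifest)
}

#' Write a cohort to disk
#'
#' Writes one tab-separated matrix per subject (rows = timepoints, columns =
#' regions, no header), a manifest CSV with header
#' `subject_id,group,age,sex,severity,medication,path`, and a sidecar file of
#' latent state paths (test use only).
#'
#' @param cohort Result of [simulate_cohort()] (with emissions).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest with populated `path` column.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- cohort$manifest
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    if (is.null(s$data)) stopf("subject %s has no emission data to write", s$subject_id)
    f <- file.path(dir, paste0(s$subject_id, ".tsv"))
    # %.17g guarantees the doubles survive the text round-trip bitwise
    chr <- matrix(sprintf("%.17g", s$data), nrow(s$data))
    data.table::fwrite(data.table::as.data.table(chr), f, sep = "\t",
                       col.names = FALSE, quote = FALSE)
    manifest$path[i] <- f
    data.table::fwrite(
      data.table::data.table(state = s$latent_path),
      file.path(dir, paste0(s$subject_id, "_latent.tsv")),
      sep = "\t", col.names = FALSE
    )
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
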