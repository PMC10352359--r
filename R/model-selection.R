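# Sweeping the a-priori state count with repeated restarts, counting occupied
# states, and selecting the working model: the smallest K past which raising
# K adds no occupied states, then the repetition with the lowest free energy.

#' Sweep the number of states
#'
#' Fits the model for every `K` in `K_range`, `reps` times each with distinct
#' seeds (`base_seed + 1000 * K + rep`), and records for each run the final
#' objective (negative free energy) and the cohort-mean fractional occupancy
#' of every state. Deterministic given `base_seed`.
#'
#' @param x A `concat_data` (or matrix; see [fit_hmm()]).
#' @param K_range Integer vector of state counts to try (e.g. `5:12`).
#' @param reps Repetitions per `K` (>= 1).
#' @param base_seed Integer seed stem.
#' @param occupancy_threshold Minimum cohort-mean FO for a state to count as
#'   occupied (default 0.01).
#' @param n_restarts Within-fit restarts; defaults to 1 because the sweep's
#'   repetitions already are independent initializations.
#' @param ... Passed to [fit_hmm()] (e.g. `max_cycles`, `tol`, `prior`).
#' @return A `state_sweep`: list with `records` (tibble: K, rep, seed,
#'   objective, free_energy, occupied, converged and a `mean_fo` list-column)
#'   and `models` (list of fitted `hmm_model`s, aligned with records rows).
#' @export
sweep_states <- function(x, K_range, reps = 5L, base_seed = 1L,
                         occupancy_threshold = 0.01, n_restarts = 1L, ...) {
  if (length(K_range) == 0L) stopf("`K_range` must be non-empty")
  reps <- check_scalar_int(reps, "reps", min = 1)
  K_range <- sort(unique(as.integer(K_range)))
  rows <- list(); models <- list(); r <- 0L
  for (K in K_range) {
    for (rep_i in seq_len(reps)) {
      seed <- as.integer(base_seed + 1000L * K + rep_i)
      model <- tryCatch(
        fit_hmm(x, K, seed = seed, n_restarts = n_restarts, ...),
        error = function(e) stopf("fit failed at K = %d, rep = %d: %s",
                                  K, rep_i, conditionMessage(e))
      )
      post <- forward_backward(model, x)
      fo <- fractional_occupancy(post$gamma, post$boundaries)
      mean_fo <- colMeans(fo)
      occ <- occupied_states(mean_fo, occupancy_threshold)
      r <- r + 1L
      rows[[r]] <- tibble::tibble(
        K = K, rep = rep_i, seed = seed,
        objective = model$metadata$objective,
        free_energy = model$metadata$free_energy,
        occupied = occ$count,
        converged = model$metadata$converged,
        mean_fo = list(mean_fo)
      )
      models[[r]] <- model
    }
  }
  structure(list(records = dplyr::bind_rows(rows), models = models,
                 occupancy_threshold = occupancy_threshold),
            class = "state_sweep")
}

#' Count occupied states
#'
#' A state counts as occupied when its cohort-mean fractional occupancy
#' reaches `threshold`. Surplus states of an over-specified model collapse
#' onto their priors and fall below any reasonable threshold.
#'
#' @param group_mean_fo Non-negative FO vector (sums to about 1).
#' @param threshold Occupancy floor in `(0, 1)`; default 0.01.
#' @return List with `count` and logical `mask`.
#' @export
occupied_states <- function(group_mean_fo, threshold = 0.01) {
  if (any(group_mean_fo < -1e-8))
    stopf("fractional occupancies must be non-negative")
  if (threshold <= 0 || threshold >= 1) stopf("`threshold` must be in (0, 1)")
  mask <- group_mean_fo >= threshold
  if (!any(mask))
    warning("no state reaches the occupancy threshold", call. = FALSE)
  list(count = sum(mask), mask = mask)
}

#' Select the working model from a sweep
#'
#' Applies the occupancy-plateau rule: per `K`, the representative occupied
#' count is the modal count over repetitions (ties toward fewer states). The
#' chosen `K` is the smallest one whose occupied count is shared by every
#' larger `K` in the sweep; among its repetitions the one with the best
#' objective (lowest free energy) wins, ties broken by the lowest repetition
#' index. If only the vacuous plateau at the largest `K` exists, the
#' best-objective model at the largest `K` is returned with a warning.
#'
#' @param sweep A `state_sweep` from [sweep_states()] (or its `records`
#'   tibble, together with `models`).
#' @param models Optional list of models when `sweep` is a bare tibble.
#' @return The chosen `hmm_model`, with `metadata$selection` describing the
#'   rule outcome (chosen K, effective/occupied K, plateau flag).
#' @export
select_model <- function(sweep, models = NULL) {
  if (inherits(sweep, "state_sweep")) {
    records <- sweep$records
    models <- sweep$models
  } else {
    records <- sweep
    if (is.null(models)) stopf("`models` must be supplied with a bare records table")
  }
  if (nrow(records) == 0L) stopf("empty sweep: no records")

  Ks <- sort(unique(records$K))
  modal_occ <- vapply(Ks, function(K) {
    occ <- records$occupied[records$K == K]
    tab <- table(occ)
    as.integer(names(tab)[which.max(tab)])  # ties resolve to fewer states
  }, integer(1))

  plateau_found <- FALSE
  chosen_K <- Ks[length(Ks)]
  if (length(Ks) == 1L) {
    plateau_found <- TRUE
    chosen_K <- Ks
  } else {
    for (i in seq_along(Ks)) {
      if (all(modal_occ[i:length(Ks)] == modal_occ[i]) && i < length(Ks)) {
        plateau_found <- TRUE
        chosen_K <- Ks[i]
        break
      }
    }
    if (!plateau_found)
      warning("no occupancy plateau in K range; returning best model at largest K",
              call. = FALSE)
  }

  cand <- which(records$K == chosen_K)
  cand <- cand[order(records$free_energy[cand], records$rep[cand])]
  best_row <- cand[1]
  model <- models[[best_row]]
  model$metadata$selection <- list(
    chosen_K = chosen_K,
    effective_K = records$occupied[best_row],
    plateau_found = plateau_found,
    rep = records$rep[best_row],
    record = records[best_row, ]
  )
  model
}
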