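# Per-subject temporal statistics (fractional occupancy, averaged lifetime,
# switching rate, transition matrices) and per-state spatial characterization
# (activity maps, FC matrices, network-block summaries).
#
# FO is computed from the soft posteriors (gamma): it is a time proportion and
# inherits the posterior's uncertainty. ALT, SR and transition matrices are
# visit/switch constructs and are computed from the hard Viterbi path.

check_boundaries <- function(boundaries, n) {
  if (!is.matrix(boundaries) || ncol(boundaries) < 2L)
    stopf("boundaries must be a matrix with columns start, end")
  if (nrow(boundaries) == 0L) stopf("empty subject range")
  if (boundaries[1, 1] != 0L || boundaries[nrow(boundaries), 2] != n ||
      any(boundaries[, 2] <= boundaries[, 1]) ||
      (nrow(boundaries) > 1L &&
       any(boundaries[-1L, 1] != boundaries[-nrow(boundaries), 2])))
    stopf("boundaries must tile rows 0..%d exactly", n)
  invisible(boundaries)
}

#' Per-subject fractional occupancy
#'
#' FO of subject `s` in state `k` is the mean posterior probability of state
#' `k` over that subject's timepoints: the proportion of scan time spent in
#' the state. Each subject's FO vector sums to 1.
#'
#' @param gamma Posterior probability matrix (rows x K), e.g. from
#'   [forward_backward()]. A hard path may be supplied instead as an integer
#'   vector together with `K`.
#' @param boundaries Subject boundary matrix (0-based half-open rows).
#' @param K Number of states (only needed when `gamma` is a hard path).
#' @return Numeric matrix, subjects x K.
#' @export
fractional_occupancy <- function(gamma, boundaries, K = NULL) {
  if (is.vector(gamma)) {
    if (is.null(K)) K <- max(gamma)
    gamma <- diag(K)[gamma, , drop = FALSE]
  }
  check_boundaries(boundaries, nrow(gamma))
  S <- nrow(boundaries)
  out <- matrix(0, S, ncol(gamma))
  for (s in seq_len(S)) {
    idx <- (boundaries[s, 1] + 1L):boundaries[s, 2]
    out[s, ] <- colMeans(gamma[idx, , drop = FALSE])
  }
  out
}

run_lengths_by_state <- function(path, K) {
  r <- rle(path)
  out <- vector("list", K)
  for (k in seq_len(K)) out[[k]] <- r$lengths[r$values == k]
  out
}

#' Per-subject averaged lifetime
#'
#' Mean number of consecutive timepoints per visit to a state before
#' switching to any other state, computed from the Viterbi path; runs never
#' span subject boundaries. States a subject never visits carry `NA`. The
#' seconds variant multiplies by the repetition time.
#'
#' @param viterbi Integer state path over all concatenated rows.
#' @param boundaries Subject boundary matrix.
#' @param K Number of states.
#' @param tr_seconds Repetition time in seconds (default 2, i.e. TR = 2000 ms).
#' @return List with matrices `timepoints` and `seconds` (subjects x K).
#' @export
average_lifetime <- function(viterbi, boundaries, K, tr_seconds = 2) {
  check_boundaries(boundaries, length(viterbi))
  S <- nrow(boundaries)
  alt <- matrix(NA_real_, S, K)
  for (s in seq_len(S)) {
    idx <- (boundaries[s, 1] + 1L):boundaries[s, 2]
    runs <- run_lengths_by_state(viterbi[idx], K)
    for (k in seq_len(K)) if (length(runs[[k]])) alt[s, k] <- mean(runs[[k]])
  }
  list(timepoints = alt, seconds = alt * tr_seconds)
}

#' Per-subject switching rate
#'
#' Fraction of consecutive within-subject timepoint pairs at which the
#' decoded state changes; 0 for a constant path, 1 for a strictly
#' alternating one.
#'
#' @inheritParams average_lifetime
#' @return Numeric vector, one rate per subject.
#' @export
switching_rate <- function(viterbi, boundaries) {
  check_boundaries(boundaries, length(viterbi))
  S <- nrow(boundaries)
  out <- numeric(S)
  for (s in seq_len(S)) {
    idx <- (boundaries[s, 1] + 1L):boundaries[s, 2]
    if (length(idx) < 2L)
      stopf("switching rate undefined for subject %d with T < 2", s)
    p <- viterbi[idx]
    out[s] <- mean(p[-1L] != p[-length(p)])
  }
  out
}

#' Per-subject (and group-average) transition matrices
#'
#' Row-normalized counts of consecutive within-subject state pairs from the
#' Viterbi path. Rows of states with no outgoing transition are `NA`; the
#' group average is taken over subjects entrywise, ignoring missing rows.
#'
#' @inheritParams average_lifetime
#' @return List with `subject` (list of K x K matrices) and `group_average`.
#' @export
subject_transition_matrix <- function(viterbi, boundaries, K) {
  check_boundaries(boundaries, length(viterbi))
  S <- nrow(boundaries)
  mats <- vector("list", S)
  for (s in seq_len(S)) {
    idx <- (boundaries[s, 1] + 1L):boundaries[s, 2]
    p <- viterbi[idx]
    counts <- matrix(0, K, K)
    if (length(p) > 1L) {
      from <- p[-length(p)]; to <- p[-1L]
      for (i in seq_along(from)) counts[from[i], to[i]] <- counts[from[i], to[i]] + 1
    }
    rs <- rowSums(counts)
    A <- counts / ifelse(rs > 0, rs, NA_real_)
    mats[[s]] <- A
  }
  arr <- array(unlist(mats), dim = c(K, K, S))
  group_average <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  group_average[is.nan(group_average)] <- NA_real_
  list(subject = mats, group_average = group_average)
}

#' All temporal metrics for a decoded cohort
#'
#' Convenience wrapper computing FO (soft, from gamma), ALT, SR and the
#' per-subject transition matrices (hard, from the Viterbi path) in one pass.
#'
#' @param posterior A `state_posterior` from [decode_states()] (must contain
#'   both `gamma` and `viterbi`), or a list with those fields plus
#'   `boundaries`.
#' @param K Number of states.
#' @param subject_id Optional subject identifiers (defaults to those recorded
#'   in the posterior).
#' @param tr_seconds Repetition time in seconds.
#' @return A `temporal_metrics` object: `fo`, `alt_tp`, `alt_s`, `sr`,
#'   `transition`, `subject_id`, `K`.
#' @export
temporal_metrics <- function(posterior, K, subject_id = NULL, tr_seconds = 2) {
  if (is.null(posterior$viterbi))
    stopf("posterior has no Viterbi path; use decode_states()")
  b <- posterior$boundaries
  fo <- fractional_occupancy(posterior$gamma, b)
  alt <- average_lifetime(posterior$viterbi, b, K, tr_seconds)
  sr <- switching_rate(posterior$viterbi, b)
  tm <- subject_transition_matrix(posterior$viterbi, b, K)
  n_unvisited <- sum(is.na(alt$timepoints))
  if (n_unvisited > 0)
    message(sprintf("%d subject-state pairs were never visited (ALT missing)",
                    n_unvisited))
  structure(
    list(fo = fo, alt_tp = alt$timepoints, alt_s = alt$seconds, sr = sr,
         transition = tm, K = K,
         subject_id = subject_id %||% posterior$subject_id),
    class = "temporal_metrics"
  )
}

#' Tidy table of temporal metrics
#'
#' @param metrics A `temporal_metrics`.
#' @return Tibble with columns subject_id, state, fo, alt_tp, alt_s plus the
#'   per-subject switching rate repeated across that subject's rows.
#' @export
metrics_table <- function(metrics) {
  stopifnot(inherits(metrics, "temporal_metrics"))
  S <- nrow(metrics$fo); K <- metrics$K
  tibble::tibble(
    subject_id = rep(metrics$subject_id, each = K),
    state = rep(seq_len(K), S),
    fo = as.vector(t(metrics$fo)),
    alt_tp = as.vector(t(metrics$alt_tp)),
    alt_s = as.vector(t(metrics$alt_s)),
    sr = rep(metrics$sr, each = K)
  )
}

#' Functional connectivity of a state
#'
#' Converts a state's covariance matrix into the correlation matrix that is
#' reported as the state's functional connectivity.
#'
#' @param state_cov SPD covariance matrix.
#' @return Correlation matrix with unit diagonal.
#' @export
state_fc <- function(state_cov) {
  if (any(diag(state_cov) <= 0))
    stopf("invalid covariance: non-positive diagonal entries")
  fc <- stats::cov2cor(state_cov)
  diag(fc) <- 1
  fc
}

#' Network-block summary of a connectivity matrix
#'
#' Averages pairwise FC within and between named networks. Within-network
#' means exclude the diagonal; between-network means average all cross pairs.
#' Networks with a single region have no within pairs and carry `NA`.
#'
#' @param fc Correlation matrix (regions x regions).
#' @param parcels A `parcel_set` whose rows match the columns of `fc`.
#' @return Symmetric matrix (networks x networks) of block means.
#' @export
network_block_fc <- function(fc, parcels) {
  if (nrow(parcels) != ncol(fc))
    stopf("parcellation has %d regions but fc is %d x %d",
          nrow(parcels), nrow(fc), ncol(fc))
  nets <- unique(parcels$network)
  B <- matrix(NA_real_, length(nets), length(nets),
              dimnames = list(nets, nets))
  for (i in seq_along(nets)) {
    for (j in seq(i, length(nets))) {
      ri <- which(parcels$network == nets[i])
      rj <- which(parcels$network == nets[j])
      block <- fc[ri, rj, drop = FALSE]
      vals <- if (i == j) block[upper.tri(block)] else as.vector(block)
      if (length(vals) == 0L) {
        message(sprintf("network %s has a single region; within-network FC undefined",
                        nets[i]))
        next
      }
      B[i, j] <- B[j, i] <- mean(vals)
    }
  }
  B
}

block_fc_values <- function(fc, parcels, net_i, net_j) {
  ri <- which(parcels$network == net_i)
  rj <- which(parcels$network == net_j)
  block <- fc[ri, rj, drop = FALSE]
  if (net_i == net_j) block[upper.tri(block)] else as.vector(block)
}

#' Compare network-block FC across states
#'
#' For every network block (within- and between-network), performs two-sample
#' t-tests between all pairs of states over the block's constituent pairwise
#' FC values, and Bonferroni-adjusts the p-values over the total number of
#' comparisons performed.
#'
#' @param fc_list List of per-state correlation matrices (length >= 2).
#' @param parcels A `parcel_set` matching the matrices.
#' @param alpha Significance level for the adjusted flag.
#' @return Tibble: network_1, network_2, state_1, state_2, t, p_raw, p_bonf,
#'   flag.
#' @export
compare_blocks_across_states <- function(fc_list, parcels, alpha = 0.05) {
  K <- length(fc_list)
  if (K < 2L) stopf("need at least two states to compare")
  nets <- unique(parcels$network)
  rows <- list(); r <- 0L
  for (i in seq_along(nets)) {
    for (j in seq(i, length(nets))) {
      vals <- lapply(fc_list, block_fc_values, parcels = parcels,
                     net_i = nets[i], net_j = nets[j])
      if (any(lengths(vals) < 2L)) {
        message(sprintf("block %s-%s has fewer than 2 FC values; test skipped",
                        nets[i], nets[j]))
        next
      }
      for (s1 in seq_len(K - 1L)) {
        for (s2 in seq(s1 + 1L, K)) {
          x <- vals[[s1]]; y <- vals[[s2]]
          if (stats::sd(c(x, y)) == 0 || isTRUE(all.equal(x, y))) {
            tt <- list(statistic = c(t = 0), p.value = 1)
          } else {
            tt <- stats::t.test(x, y)
          }
          r <- r + 1L
          rows[[r]] <- tibble::tibble(
            network_1 = nets[i], network_2 = nets[j],
            state_1 = s1, state_2 = s2,
            t = unname(tt$statistic), p_raw = tt$p.value
          )
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  m <- nrow(out)
  out$p_bonf <- pmin(1, out$p_raw * m)
  out$flag <- out$p_bonf <= alpha
  out
}
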