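# Reading cohorts and parcellation maps; standardizing and concatenating
# subject time series into the single matrix the HMM is fit on, with exact
# subject-boundary bookkeeping.

#' Read a parcellation map
#'
#' A parcellation map is a CSV with header `region,network,exclude` assigning
#' each region (in fixed column order of the subject matrices) to one named
#' network; `exclude` (0/1) marks regions dropped before any computation, e.g.
#' signal-loss regions.
#'
#' @param path CSV path.
#' @return A `parcel_set`: tibble with columns `region`, `network`, `exclude`,
#'   restricted to retained regions, plus attribute `n_total` (rows before
#'   exclusion).
#' @export
read_parcellation <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("region", "network")
  if (!all(req %in% names(df)))
    stopf("parcellation file must have columns region,network[,exclude]")
  if (is.null(df$exclude)) df$exclude <- 0L
  as_parcel_set(df)
}

as_parcel_set <- function(df) {
  if (anyDuplicated(df$region))
    stopf("duplicate region names in parcellation")
  n_total <- nrow(df)
  keep_idx <- which(df$exclude == 0)
  out <- tibble::as_tibble(df[keep_idx, c("region", "network")])
  attr(out, "n_total") <- n_total
  attr(out, "keep_idx") <- keep_idx
  class(out) <- c("parcel_set", class(out))
  out
}

#' Synthetic example parcellation
#'
#' Constructs a stand-in for the atlas used in whole-brain state studies: 100
#' cortical regions across seven networks (visual VN, somatomotor SMN, dorsal
#' attention DAN, salience SN, limbic LN, frontoparietal FPN, default mode
#' DMN), of which five limbic orbitofrontal/temporal-pole regions are marked
#' excluded for signal loss, plus 16 subcortical regions (bilateral
#' hippocampus, amygdala, anterior/posterior thalamus, nucleus accumbens,
#' globus pallidus, putamen, caudate) in a "subcortical" network. After
#' exclusion this yields 111 retained regions in 8 networks. The region names
#' and per-network counts are synthetic: they mimic the structure, not the
#' actual atlas lookup table.
#'
#' @return A `parcel_set` of 111 retained regions (116 rows before exclusion).
#' @export
example_parcellation <- function() {
  as_parcel_set(example_parcellation_table())
}

# Full 116-row table including the excluded limbic rows (internal; useful for
# writing a complete parcellation CSV).
example_parcellation_table <- function() {
  cortical_counts <- c(VN = 14L, SMN = 16L, DAN = 13L, SN = 12L, LN = 10L,
                       FPN = 13L, DMN = 22L)
  stopifnot(sum(cortical_counts) == 100L)
  net <- rep(names(cortical_counts), cortical_counts)
  region <- unlist(lapply(names(cortical_counts), function(nm) {
    sprintf("%s_%02d", nm, seq_len(cortical_counts[[nm]]))
  }))
  exclude <- integer(100L)
  # five limbic regions discarded for signal loss (orbitofrontal / temporal pole)
  exclude[which(net == "LN")[1:5]] <- 1L
  sub_structs <- c("HIP", "AMY", "pTHA", "aTHA", "NAc", "GP", "PUT", "CAU")
  sub_region <- as.vector(t(outer(sub_structs, c("L", "R"), paste, sep = "_")))
  data.frame(
    region = c(region, sub_region),
    network = c(net, rep("subcortical", 16L)),
    exclude = c(exclude, integer(16L)),
    stringsAsFactors = FALSE
  )
}

read_subject_matrix <- function(path, subject_id) {
  m <- tryCatch(
    as.matrix(data.table::fread(path, sep = "\t", header = FALSE)),
    error = function(e) stopf("subject %s: cannot parse %s (%s)",
                              subject_id, path, conditionMessage(e))
  )
  if (!is.numeric(m) || anyNA(m)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))),
                 arr.ind = TRUE)
    loc <- if (nrow(bad)) sprintf(" at row %d, column %d", bad[1, 1], bad[1, 2]) else ""
    stopf("subject %s: missing or non-numeric value%s in %s", subject_id, loc, path)
  }
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  m
}

#' Read a cohort from a manifest
#'
#' Reads the manifest CSV (`subject_id,group,age,sex,severity,medication,path`)
#' and every referenced subject matrix (tab-separated, rows = timepoints),
#' validating each against the parcellation's region count.
#'
#' @param manifest_path Manifest CSV.
#' @param parcel_path Optional parcellation CSV; when given, every subject
#'   matrix must have one column per retained region. Matrices that still
#'   carry the excluded regions (one column per parcellation row) are
#'   accepted: the excluded columns are dropped before any computation.
#' @return A list with `subjects` (list of `subject_ts`), `manifest` (tibble)
#'   and `parcels` (`parcel_set` or `NULL`).
#' @export
read_cohort <- function(manifest_path, parcel_path = NULL) {
  manifest <- tibble::as_tibble(utils::read.csv(manifest_path,
                                                stringsAsFactors = FALSE))
  req <- c("subject_id", "group", "path")
  if (!all(req %in% names(manifest)))
    stopf("manifest must contain columns: %s", paste(req, collapse = ", "))
  if (nrow(manifest) == 0L) stopf("manifest is empty: no subjects to read")
  if (anyDuplicated(manifest$subject_id))
    stopf("duplicate subject_id in manifest: %s",
          manifest$subject_id[duplicated(manifest$subject_id)][1])
  parcels <- if (!is.null(parcel_path)) read_parcellation(parcel_path) else NULL

  subjects <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    m <- read_subject_matrix(row$path, row$subject_id)
    if (!is.null(parcels)) {
      n_total <- attr(parcels, "n_total")
      if (ncol(m) == n_total && n_total != nrow(parcels)) {
        # matrix still carries the excluded regions: drop them up front
        m <- m[, attr(parcels, "keep_idx"), drop = FALSE]
      } else if (ncol(m) != nrow(parcels)) {
        stopf("subject %s: %d columns but parcellation defines %d regions",
              row$subject_id, ncol(m), nrow(parcels))
      }
    }
    col_or <- function(nm, default) {
      if (nm %in% names(manifest)) row[[nm]] else default
    }
    subjects[[i]] <- structure(
      list(subject_id = row$subject_id, group = row$group,
           age = col_or("age", NA_real_), sex = col_or("sex", NA_character_),
           severity = col_or("severity", NA_real_),
           data = m, latent_path = NULL, T = nrow(m), R = ncol(m)),
      class = "subject_ts"
    )
  }
  Rs <- vapply(subjects, function(s) s$R, integer(1))
  if (length(unique(Rs)) != 1L)
    stopf("subjects disagree on region count: %s",
          paste(unique(Rs), collapse = ", "))
  list(subjects = subjects, manifest = manifest, parcels = parcels)
}

#' Standardize and concatenate a cohort
#'
#' Stacks all subject matrices (in manifest order) into one `sum(T_s) x R`
#' matrix and z-scores it. `mode = "global"` standardizes each column of the
#' stacked matrix; `mode = "per_subject"` z-scores each column within each
#' subject before stacking. Subject row ranges are recorded as half-open
#' 0-based `[start, end)` intervals that tile the row space exactly.
#'
#' @param subjects A list of `subject_ts` (or the list returned by
#'   [read_cohort()] / [simulate_cohort()], from which `$subjects` is taken).
#' @param mode `"global"` (default) or `"per_subject"`.
#' @return A `concat_data` object: `matrix`, `boundaries` (integer matrix with
#'   columns `start`, `end`), `subject_id`, and `standardization` record.
#' @export
standardize_concatenate <- function(subjects, mode = c("global", "per_subject")) {
  mode <- match.arg(mode)
  if (!is.null(subjects$subjects)) subjects <- subjects$subjects
  if (length(subjects) == 0L) stopf("empty cohort: nothing to concatenate")
  Rs <- vapply(subjects, function(s) ncol(s$data), integer(1))
  if (length(unique(Rs)) != 1L) stopf("subjects disagree on region count")
  R <- Rs[1]
  Ts <- vapply(subjects, function(s) nrow(s$data), integer(1))
  ends <- cumsum(Ts)
  starts <- c(0L, ends[-length(ends)])
  ids <- vapply(subjects, function(s) s$subject_id, character(1))

  mats <- lapply(subjects, function(s) s$data)
  record <- list(mode = mode)
  if (mode == "per_subject") {
    for (i in seq_along(mats)) {
      sdv <- apply(mats[[i]], 2L, stats::sd)
      if (any(sdv == 0))
        stopf("degenerate channel: column %d has zero variance within subject %s",
              which(sdv == 0)[1], ids[i])
      mats[[i]] <- scale(mats[[i]])
      attributes(mats[[i]])[c("scaled:center", "scaled:scale")] <- NULL
    }
    X <- do.call(rbind, mats)
  } else {
    X <- do.call(rbind, mats)
    ctr <- colMeans(X)
    sdv <- apply(X, 2L, stats::sd)
    if (any(sdv == 0))
      stopf("degenerate channel: column %d has zero variance globally",
            which(sdv == 0)[1])
    X <- sweep(sweep(X, 2L, ctr, "-"), 2L, sdv, "/")
    record$center <- ctr
    record$scale <- sdv
  }
  dimnames(X) <- NULL

  structure(
    list(matrix = X,
         boundaries = cbind(start = starts, end = as.integer(ends)),
         subject_id = ids,
         standardization = record),
    class = "concat_data"
  )
}

#' @export
print.concat_data <- function(x, ...) {
  cat(sprintf("Concatenated time series: %d rows x %d regions, %d subjects (%s standardization)\n",
              nrow(x$matrix), ncol(x$matrix), nrow(x$boundaries),
              x$standardization$mode))
  invisible(x)
}

#' Extract one subject's rows from a concatenated matrix
#'
#' @param concatenated A `concat_data`.
#' @param subject_index 1-based subject position in manifest order.
#' @return That subject's `T x R` block.
#' @export
slice_subject <- function(concatenated, subject_index) {
  stopifnot(inherits(concatenated, "concat_data"))
  i <- check_scalar_int(subject_index, "subject_index", min = 1)
  nb <- nrow(concatenated$boundaries)
  if (i > nb) stopf("subject_index %d out of range (cohort has %d subjects)", i, nb)
  b <- concatenated$boundaries[i, ]
  concatenated$matrix[(b[["start"]] + 1L):b[["end"]], , drop = FALSE]
}
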