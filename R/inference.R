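# Group inference battery: rank-based inverse normal transform, fixed-effect
# linear models with age and sex covariates, Tukey post-hoc contrasts,
# Bonferroni correction per temporal feature, bootstrap Cohen's d, and
# severity correlations.

#' Rank-based inverse normal transform (Blom)
#'
#' Maps values onto normal quantiles by rank:
#' `qnorm((r - 3/8) / (n + 1/4))`, with ties receiving average ranks. Missing
#' values pass through as missing and do not consume ranks. The output is
#' strictly monotone in the input ranks, so any strictly monotone transform of
#' the input leaves it unchanged.
#'
#' @param values Numeric vector (may contain `NA`).
#' @return Transformed vector of the same length.
#' @export
inverse_normal_transform <- function(values) {
  ok <- is.finite(values)
  x <- values[ok]
  n <- length(x)
  if (n < 2L) stopf("need at least 2 finite values")
  if (stats::sd(x) == 0) stopf("degenerate ranks: all values identical")
  r <- rank(x, ties.method = "average")
  out <- values
  out[ok] <- stats::qnorm((r - 3 / 8) / (n + 1 / 4))
  out
}

#' Fixed-effect linear model for one metric
#'
#' Ordinary least squares of a (typically inverse-normal-transformed) metric
#' on group plus the age and sex covariates. Age is centered before fitting
#' (affects the intercept only); sex enters as a binary indicator. With two
#' groups the group t statistic is reported; with three or more, the partial
#' F for the group factor given the covariates.
#'
#' @param metric Numeric response (missing values dropped pairwise with a
#'   message).
#' @param group Factor (or coercible) with >= 2 levels.
#' @param age,sex Covariates aligned with `metric` (either may be `NULL` to
#'   omit).
#' @return List: `statistic` (named `t` or `F`), `p`, `coefficients` tibble,
#'   `model` (the `lm` fit), `df_residual`, `n_used`.
#' @export
fixed_effect_lm <- function(metric, group, age = NULL, sex = NULL) {
  df <- data.frame(metric = metric, group = factor(group))
  if (!is.null(age)) df$age <- as.numeric(age) - mean(as.numeric(age), na.rm = TRUE)
  if (!is.null(sex)) df$sex <- factor(sex)
  keep <- stats::complete.cases(df)
  if (sum(!keep) > 0)
    message(sprintf("dropping %d rows with missing values", sum(!keep)))
  df <- df[keep, , drop = FALSE]
  df$group <- droplevels(df$group)
  if (nlevels(df$group) < 2L) stopf("need at least 2 groups")

  fit <- stats::lm(metric ~ ., data = df)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stopf("rank-deficient design; collinear columns: %s",
          paste(bad, collapse = ", "))
  }
  sm <- summary(fit)
  coefs <- tibble::tibble(
    term = rownames(sm$coefficients),
    estimate = unname(sm$coefficients[, 1]),
    se = unname(sm$coefficients[, 2]),
    t = unname(sm$coefficients[, 3]),
    p = unname(sm$coefficients[, 4])
  )
  if (stats::var(df$metric) == 0) {
    # a metric identical across subjects carries no group information
    statistic <- if (nlevels(df$group) == 2L) c(t = 0) else c(F = 0)
    p <- 1
  } else if (nlevels(df$group) == 2L) {
    term <- paste0("group", levels(df$group)[2])
    statistic <- c(t = coefs$t[coefs$term == term])
    p <- unname(coefs$p[coefs$term == term])
  } else {
    dr <- stats::drop1(fit, scope = ~group, test = "F")
    statistic <- c(F = dr[["F value"]][2])
    p <- dr[["Pr(>F)"]][2]
  }
  list(statistic = statistic, p = p, coefficients = coefs, model = fit,
       df_residual = fit$df.residual, n_used = nrow(df))
}

#' Tukey post-hoc pairwise contrasts
#'
#' Pairwise group contrasts from the fixed-effect model's estimated marginal
#' means, adjusted with the studentized-range (Tukey) method using the
#' model's residual variance. With exactly two groups the Tukey-adjusted p
#' equals the unadjusted pairwise p.
#'
#' @inheritParams fixed_effect_lm
#' @return Tibble: contrast, estimate, se, t, p_adj.
#' @export
tukey_posthoc <- function(metric, group, age = NULL, sex = NULL) {
  fe <- fixed_effect_lm(metric, group, age, sex)
  grp <- factor(group)
  small <- names(table(droplevels(grp[stats::complete.cases(metric)])))[
    table(droplevels(grp[stats::complete.cases(metric)])) < 2]
  if (length(small))
    message(sprintf("groups with < 2 subjects skipped in contrasts: %s",
                    paste(small, collapse = ", ")))
  emm <- emmeans::emmeans(fe$model, "group")
  prs <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = "tukey"))
  tibble::tibble(
    contrast = as.character(prs$contrast),
    estimate = prs$estimate,
    se = prs$SE,
    t = prs$t.ratio,
    p_adj = prs$p.value
  )
}

#' Bonferroni correction
#'
#' Flags tests at `alpha / m` and reports `min(1, m * p)`, dividing the
#' threshold by the number of comparisons in the family (for the temporal
#' features, the number of states).
#'
#' @param p_values Raw p-values.
#' @param m Family size (>= 1); defaults to `length(p_values)`.
#' @param alpha Family-wise level.
#' @return Tibble: p_raw, p_bonf, flag.
#' @export
bonferroni <- function(p_values, m = length(p_values), alpha = 0.05) {
  m <- check_scalar_int(m, "m", min = 1)
  tibble::tibble(
    p_raw = p_values,
    p_bonf = pmin(1, m * p_values),
    flag = p_values <= alpha / m
  )
}

#' Cohen's d with a bootstrap confidence interval
#'
#' `d = (mean(x) - mean(y)) / s_pooled`, with a percentile confidence
#' interval over `B` paired resamples (both samples resampled independently
#' in each replicate). Reproducible from `seed`.
#'
#' @param x,y Numeric samples (>= 2 values each).
#' @param B Number of bootstrap resamples (default 2000).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return List: `d`, `ci` (length-2), `B`.
#' @export
cohens_d_bootstrap <- function(x, y, B = 2000L, seed = 1L, conf = 0.95) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L) stopf("need >= 2 values per sample")
  B <- check_scalar_int(B, "B", min = 1)
  d_of <- function(a, b) {
    sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
      (length(a) + length(b) - 2)
    if (sp2 <= 0) stopf("degenerate variance: pooled SD is zero")
    (mean(a) - mean(b)) / sqrt(sp2)
  }
  d <- d_of(x, y)
  boot <- with_seed(seed, {
    vapply(seq_len(B), function(i) {
      a <- x[sample.int(length(x), replace = TRUE)]
      b <- y[sample.int(length(y), replace = TRUE)]
      sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
        (length(a) + length(b) - 2)
      if (sp2 <= 0) return(NA_real_)
      (mean(a) - mean(b)) / sqrt(sp2)
    }, numeric(1))
  })
  qs <- stats::quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, names = FALSE)
  list(d = d, ci = qs, B = B)
}

#' Pearson correlation between a metric and severity
#'
#' Classical two-sided Pearson test with pairwise deletion of missing values.
#'
#' @param metric,severity Paired numeric vectors.
#' @return List: `r`, `p`, `n_used`.
#' @export
pearson_severity <- function(metric, severity) {
  keep <- is.finite(metric) & is.finite(severity)
  if (sum(keep) < 3L) stopf("need at least 3 paired finite values")
  x <- metric[keep]; y <- severity[keep]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("degenerate input: zero variance")
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n_used = sum(keep))
}

#' Configuration for the group analysis battery
#'
#' @param alpha Family-wise level.
#' @param severity_threshold Severity split for the symptomatic label
#'   (default 7: scores strictly above are symptomatic, at or below
#'   asymptomatic).
#' @param boot_B Bootstrap resamples for effect sizes.
#' @param seed Integer seed for the bootstrap.
#' @export
group_analysis_config <- function(alpha = 0.05, severity_threshold = 7,
                                  boot_B = 2000L, seed = 1L) {
  list(alpha = alpha, severity_threshold = severity_threshold,
       boot_B = check_scalar_int(boot_B, "boot_B", min = 1),
       seed = as.integer(seed))
}

#' Run the full group analysis battery
#'
#' For every temporal feature (per-state FO, per-state ALT, and the scalar
#' SR): inverse-normal transform, two-group fixed-effect model (case vs
#' control with age and sex), Bonferroni correction over the K states of each
#' feature (family size 1 for SR), bootstrap Cohen's d for every two-group
#' contrast, a three-group model (control vs asymptomatic vs symptomatic,
#' split at the severity threshold) with Tukey post-hoc contrasts, and
#' Pearson correlations of case-subject severity with each state's FO and
#' ALT.
#'
#' @param metrics A `temporal_metrics` (subjects aligned with `manifest`).
#' @param manifest Tibble with subject_id, group ("control"/"case"), age,
#'   sex, severity (NA for controls), medication.
#' @param config A [group_analysis_config()].
#' @return A `group_stats_report`: tibbles `two_group`, `three_group`,
#'   `tukey`, `correlations`, plus `config`.
#' @export
run_group_analysis <- function(metrics, manifest,
                               config = group_analysis_config()) {
  stopifnot(inherits(metrics, "temporal_metrics"))
  req <- c("subject_id", "group", "age", "sex", "severity")
  if (!all(req %in% names(manifest)))
    stopf("manifest lacks required columns: %s",
          paste(setdiff(req, names(manifest)), collapse = ", "))
  ord <- match(metrics$subject_id, manifest$subject_id)
  if (anyNA(ord)) stopf("metrics and manifest disagree on subject ids")
  manifest <- manifest[ord, ]
  K <- metrics$K

  grp2 <- factor(manifest$group, levels = c("control", "case"))
  sev3 <- ifelse(manifest$group == "control", "control",
                 ifelse(manifest$severity > config$severity_threshold,
                        "symptomatic", "asymptomatic"))
  sev3 <- factor(sev3, levels = c("control", "asymptomatic", "symptomatic"))

  features <- c(stats::setNames(lapply(seq_len(K), function(k)
    list(name = "fo", state = k, values = metrics$fo[, k], m = K)),
    paste0("fo", seq_len(K))),
    stats::setNames(lapply(seq_len(K), function(k)
      list(name = "alt", state = k, values = metrics$alt_tp[, k], m = K)),
      paste0("alt", seq_len(K))),
    list(sr = list(name = "sr", state = NA_integer_, values = metrics$sr, m = 1L)))

  two_rows <- list(); three_rows <- list(); tukey_rows <- list()
  boot_seed <- config$seed
  for (f in features) {
    v <- suppressMessages(inverse_normal_transform(f$values))
    fe <- suppressMessages(fixed_effect_lm(v, grp2, manifest$age, manifest$sex))
    keep <- is.finite(v)
    raw_means <- tapply(f$values[keep], grp2[keep], mean)
    int_means <- tapply(v[keep], grp2[keep], mean)
    boot_seed <- boot_seed + 1L
    boot <- cohens_d_bootstrap(v[keep & grp2 == "case"],
                               v[keep & grp2 == "control"],
                               B = config$boot_B, seed = boot_seed)
    two_rows[[length(two_rows) + 1L]] <- tibble::tibble(
      feature = f$name, state = f$state,
      statistic = unname(fe$statistic), p_raw = fe$p,
      mean_control_raw = unname(raw_means["control"]),
      mean_case_raw = unname(raw_means["case"]),
      mean_control_int = unname(int_means["control"]),
      mean_case_int = unname(int_means["case"]),
      d = boot$d, ci_low = boot$ci[1], ci_high = boot$ci[2],
      m = f$m
    )
    fe3 <- suppressMessages(fixed_effect_lm(v, sev3, manifest$age, manifest$sex))
    three_rows[[length(three_rows) + 1L]] <- tibble::tibble(
      feature = f$name, state = f$state,
      statistic = unname(fe3$statistic), p_raw = fe3$p, m = f$m
    )
    tk <- suppressMessages(tukey_posthoc(v, sev3, manifest$age, manifest$sex))
    tk$feature <- f$name; tk$state <- f$state
    tukey_rows[[length(tukey_rows) + 1L]] <- tk
  }
  two_group <- dplyr::bind_rows(two_rows)
  two_group$p_bonf <- pmin(1, two_group$p_raw * two_group$m)
  two_group$flag <- two_group$p_raw <= config$alpha / two_group$m
  three_group <- dplyr::bind_rows(three_rows)
  three_group$p_bonf <- pmin(1, three_group$p_raw * three_group$m)
  three_group$flag <- three_group$p_raw <= config$alpha / three_group$m
  tukey <- dplyr::bind_rows(tukey_rows)

  # severity correlations (case subjects only, FO and ALT per state)
  case_idx <- manifest$group == "case"
  corr_rows <- list()
  for (k in seq_len(K)) {
    for (feat in c("fo", "alt")) {
      vals <- if (feat == "fo") metrics$fo[case_idx, k] else metrics$alt_tp[case_idx, k]
      ps <- tryCatch(pearson_severity(vals, manifest$severity[case_idx]),
                     error = function(e) list(r = NA_real_, p = NA_real_,
                                              n_used = NA_integer_))
      corr_rows[[length(corr_rows) + 1L]] <- tibble::tibble(
        feature = feat, state = k, r = ps$r, p = ps$p, n_used = ps$n_used,
        flagged_two_group = any(two_group$flag[two_group$feature == feat &
                                                 two_group$state == k])
      )
    }
  }
  structure(
    list(two_group = two_group[, c("feature", "state", "statistic", "p_raw",
                                   "p_bonf", "flag", "d", "ci_low", "ci_high",
                                   "mean_control_raw", "mean_case_raw",
                                   "mean_control_int", "mean_case_int")],
         three_group = three_group[, c("feature", "state", "statistic",
                                       "p_raw", "p_bonf", "flag")],
         tukey = tukey[, c("feature", "state", "contrast", "estimate", "se",
                           "t", "p_adj")],
         correlations = dplyr::bind_rows(corr_rows),
         config = config),
    class = "group_stats_report"
  )
}

#' @export
print.group_stats_report <- function(x, ...) {
  cat("Group statistics report\n")
  cat(sprintf("  two-group tests: %d (flagged: %d)\n",
              nrow(x$two_group), sum(x$two_group$flag)))
  cat(sprintf("  three-group tests: %d (flagged: %d)\n",
              nrow(x$three_group), sum(x$three_group$flag)))
  cat(sprintf("  severity correlations: %d\n", nrow(x$correlations)))
  invisible(x)
}
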