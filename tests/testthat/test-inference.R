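# The statistical battery: INT, fixed-effect models, Tukey, Bonferroni,
# bootstrap effect sizes, severity correlations, and the orchestrator.

test_that("inverse normal transform reproduces the Blom quantiles", {
  out <- sort(inverse_normal_transform(c(3.2, -1, 10)))
  # oracle: normal quantiles at (r - 3/8) / (n + 1/4) for r = 1..3
  expect_equal(out, qnorm((1:3 - 3 / 8) / 3.25), tolerance = 1e-10)
  expect_equal(out[2], 0)
  expect_equal(round(out[3], 4), 0.8694)

  # median of an odd-length tie-free sample maps to 0
  x <- c(5, 1, 9, 2, 7)
  expect_equal(inverse_normal_transform(x)[x == 5], 0)

  # ties share the average-rank value
  tr <- inverse_normal_transform(c(1, 2, 2, 5))
  expect_equal(tr[2], tr[3])

  # NA pass-through without consuming ranks
  tr_na <- inverse_normal_transform(c(1, NA, 3, 2))
  expect_true(is.na(tr_na[2]))
  expect_equal(tr_na[!is.na(tr_na)],
               inverse_normal_transform(c(1, 3, 2)))

  expect_error(inverse_normal_transform(rep(4, 5)), "identical")
  expect_error(inverse_normal_transform(c(1, NA)), "at least 2")
})

test_that("INT is invariant under strictly monotone input transforms", {
  set.seed(5)
  x <- rnorm(40)
  expect_equal(inverse_normal_transform(x),
               inverse_normal_transform(exp(2 * x)))
  expect_equal(inverse_normal_transform(x),
               inverse_normal_transform(rank(x)))
})

test_that("fixed-effect models recover exact structure and edge cases", {
  set.seed(8)
  n <- 40
  group <- factor(rep(c("control", "case"), each = n / 2),
                  levels = c("control", "case"))
  age <- runif(n, 20, 60)
  sex <- sample(c("f", "m"), n, TRUE)

  # constant metric with covariates: group t = 0, p = 1
  fe0 <- suppressWarnings(fixed_effect_lm(5 + 0 * age, group, age, sex))
  expect_equal(unname(fe0$statistic), 0, tolerance = 1e-8)
  expect_equal(fe0$p, 1, tolerance = 1e-8)

  # noiseless linear structure recovered exactly
  y <- 1 * (group == "case") + 0.1 * age
  fe <- suppressWarnings(fixed_effect_lm(y, group, age, sex))
  cf <- fe$coefficients
  expect_equal(cf$estimate[cf$term == "groupcase"], 1, tolerance = 1e-10)
  expect_equal(cf$estimate[cf$term == "age"], 0.1, tolerance = 1e-10)

  # t is sign-symmetric in group order
  set.seed(9); y2 <- rnorm(n)
  t_ab <- fixed_effect_lm(y2, factor(group, levels = c("control", "case")), age, sex)
  t_ba <- fixed_effect_lm(y2, factor(group, levels = c("case", "control")), age, sex)
  expect_equal(unname(t_ab$statistic), -unname(t_ba$statistic), tolerance = 1e-10)

  # three groups yield a partial F for group
  g3 <- rep(c("a", "b", "c"), length.out = n)
  fe3 <- fixed_effect_lm(y2, g3, age, sex)
  expect_named(fe3$statistic, "F")

  # collinear covariate raises a design error
  expect_error(fixed_effect_lm(y2, group, age, ifelse(group == "case", "f", "m")),
               "collinear|rank")
})

test_that("type-I error of the battery is calibrated on null features", {
  set.seed(33)
  n <- 60; reps <- 500
  group <- rep(c("control", "case"), each = n / 2)
  # each replicate is its own null cohort: covariates drawn afresh
  rej <- vapply(seq_len(reps), function(i) {
    age <- runif(n, 18, 65)
    sex <- sample(c("f", "m"), n, TRUE)
    y <- inverse_normal_transform(rnorm(n))
    fixed_effect_lm(y, group, age, sex)$p <= 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("Tukey with two groups equals the unadjusted pairwise test", {
  set.seed(12)
  n <- 30
  group <- rep(c("a", "b"), each = n / 2)
  age <- runif(n, 20, 50); sex <- sample(c("f", "m"), n, TRUE)
  y <- rnorm(n) + (group == "b") * 0.8
  tk <- tukey_posthoc(y, group, age, sex)
  fe <- fixed_effect_lm(y, group, age, sex)
  expect_equal(tk$p_adj, fe$p, tolerance = 1e-10)
  # oracle: studentized range with q = sqrt(2) |t| reproduces the same p
  p_q <- 1 - ptukey(sqrt(2) * abs(tk$t), 2, fe$df_residual)
  expect_equal(tk$p_adj, p_q, tolerance = 1e-10)
})

test_that("Tukey three-group contrasts are adjusted and never anti-conservative", {
  set.seed(13)
  n <- 45
  group <- rep(c("a", "b", "c"), each = 15)
  age <- runif(n, 20, 50); sex <- sample(c("f", "m"), n, TRUE)
  y <- rnorm(n) + (group == "c") * 1
  tk <- tukey_posthoc(y, group, age, sex)
  expect_equal(nrow(tk), 3L)
  fit <- lm(y ~ g + a + s, data = data.frame(y = y, g = factor(group),
                                             a = age - mean(age), s = factor(sex)))
  # oracle per pair: p_adj = P(q > sqrt(2)|t|) with the model residual df
  for (i in seq_len(3)) {
    expect_gte(tk$p_adj[i] + 1e-12,
               2 * pt(-abs(tk$t[i]), fit$df.residual) - 1e-9)
    expect_equal(tk$p_adj[i], 1 - ptukey(sqrt(2) * abs(tk$t[i]), 3,
                                         fit$df.residual), tolerance = 1e-8)
  }
})

test_that("bonferroni flags at alpha/m and caps corrected p at 1", {
  # threshold arithmetic: p = 0.009 with 6 states misses 0.05/6 = 0.00833
  bc <- bonferroni(0.009, m = 6)
  expect_false(bc$flag)
  expect_equal(bc$p_bonf, 0.054)
  expect_true(bonferroni(0, m = 100)$flag)
  expect_equal(bonferroni(0.7, m = 1), tibble::tibble(p_raw = 0.7, p_bonf = 0.7,
                                                      flag = FALSE))
  expect_equal(bonferroni(0.3, m = 5)$p_bonf, 1)
})

test_that("bootstrap Cohen's d: point value, antisymmetry, coverage", {
  set.seed(21)
  x <- rnorm(50); y <- rnorm(50)
  same <- cohens_d_bootstrap(x, x, B = 200, seed = 1)
  expect_equal(same$d, 0)
  expect_true(same$ci[1] <= 0 && same$ci[2] >= 0)

  ab <- cohens_d_bootstrap(x, y, B = 500, seed = 2)
  ba <- cohens_d_bootstrap(y, x, B = 500, seed = 2)
  expect_equal(ab$d, -ba$d)
  expect_true(ab$ci[1] <= ab$d && ab$ci[2] >= ab$d)

  big_x <- rnorm(2000, 1); big_y <- rnorm(2000, 0)
  big <- cohens_d_bootstrap(big_x, big_y, B = 500, seed = 3)
  expect_lt(abs(big$d - 1), 0.1)

  expect_error(cohens_d_bootstrap(rep(1, 5), rep(1, 5)), "pooled SD")
})

test_that("severity correlations behave like Pearson with pairwise deletion", {
  x <- 1:10
  ps <- pearson_severity(x, 2 * x + 3)
  expect_equal(ps$r, 1)
  set.seed(2)
  a <- rnorm(30); b <- 0.5 * a + rnorm(30)
  raw <- cor.test(a, b)
  scaled <- pearson_severity(10 * a - 2, b / 3 + 1)
  expect_equal(scaled$r, unname(raw$estimate))
  expect_equal(scaled$p, raw$p.value)
  with_na <- pearson_severity(c(a, NA), c(b, 5))
  expect_equal(with_na$n_used, 30L)
  expect_error(pearson_severity(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("the full battery flags the perturbed state with the injected sign", {
  truth <- make_hmm_truth(4, 6, self_stick = 0.5, mean_scale = 1, seed = 3)
  spec <- cohort_spec(n_control = 50, n_case = 50, T = 232,
                      truth_control = truth, target_state = 4, delta = 0.2,
                      seed = 77)
  coh <- simulate_cohort(spec, emissions = FALSE)
  path <- unlist(lapply(coh$subjects, `[[`, "latent_path"))
  ends <- cumsum(vapply(coh$subjects, `[[`, 0L, "T"))
  bounds <- cbind(start = c(0L, ends[-length(ends)]), end = ends)
  post <- list(gamma = diag(4)[path, ], viterbi = path, boundaries = bounds,
               subject_id = coh$manifest$subject_id)
  tm <- suppressMessages(temporal_metrics(post, K = 4))
  rep_out <- suppressMessages(
    run_group_analysis(tm, coh$manifest,
                       group_analysis_config(boot_B = 200, seed = 1)))
  two <- rep_out$two_group
  # target-state FO flagged, with cases above controls
  row_t <- two[two$feature == "fo" & two$state == 4, ]
  expect_true(row_t$flag)
  expect_gt(row_t$mean_case_raw, row_t$mean_control_raw)
  expect_gt(row_t$d, 0)
  # ALT of the target state rises with stickiness as well
  row_a <- two[two$feature == "alt" & two$state == 4, ]
  expect_true(row_a$flag)
  expect_gt(row_a$mean_case_raw, row_a$mean_control_raw)
  # report schema is stable
  expect_equal(names(two), c("feature", "state", "statistic", "p_raw", "p_bonf",
                             "flag", "d", "ci_low", "ci_high",
                             "mean_control_raw", "mean_case_raw",
                             "mean_control_int", "mean_case_int"))
  expect_equal(nrow(two), 4 + 4 + 1)
  # severity correlation positive for the target state's FO
  ct <- rep_out$correlations
  expect_gt(ct$r[ct$feature == "fo" & ct$state == 4], 0)
  # three-group model produced with Tukey contrasts for every feature
  expect_equal(nrow(rep_out$tukey), 9 * 3)
})

test_that("missing manifest columns raise a schema error", {
  sc <- small_cohort(n_per_group = 2, T = 30, seed = 9)
  cd <- standardize_concatenate(sc$cohort)
  post <- decode_states(list_truth_as_model(sc$truth, cd), cd)
  tm <- suppressMessages(temporal_metrics(post, K = sc$truth$K))
  bad_manifest <- sc$cohort$manifest[, c("subject_id", "group")]
  expect_error(run_group_analysis(tm, bad_manifest), "lacks required")
})
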