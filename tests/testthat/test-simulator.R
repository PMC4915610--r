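test_that("stratum probabilities follow the closed-form normal law", {
  m <- binormal_model(lambda = 0.1, mu_w_case = 0.6)
  pr <- population_stratum_probs(m)
  expect_equal(pr$p_control_cond, rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(pr$p_case_cond[3], 1 - pnorm(qnorm(2 / 3) - 0.6),
               tolerance = 1e-12)
  expect_equal(sum(pr$p_case_joint), 0.1, tolerance = 1e-12)
  expect_equal(sum(pr$p_control_joint), 0.9, tolerance = 1e-12)
})

test_that("model construction rejects invalid correlation structures", {
  expect_error(binormal_model(rho_xy = 0.9, rho_xw = 0.9, rho_yw = -0.9),
               "positive definite")
  expect_error(binormal_model(lambda = 1.2), "lambda")
  expect_error(binormal_model(cutpoints = c(1, 0)), "increasing")
})

test_that("generated cohorts recover the model moments", {
  m <- binormal_model(lambda = 0.1, mu_Dx = 1, sigma_Dx = 1.5,
                      rho_xy = 0.5, rho_xw = 0.3, rho_yw = 0.5)
  coh <- generate_cohort(m, 200000, seed = 100)
  df <- as.data.frame(coh)
  cs <- df[df$disease == 1, ]; ct <- df[df$disease == 0, ]
  n1 <- nrow(cs); n0 <- nrow(ct)
  # means and SDs within 3 SE
  expect_lt(abs(mean(cs$x) - 1), 3 * 1.5 / sqrt(n1))
  expect_lt(abs(mean(cs$y) - 1), 3 / sqrt(n1))
  expect_lt(abs(mean(cs$w_star) - 0.6), 3 / sqrt(n1))
  expect_lt(abs(mean(ct$x)), 3 / sqrt(n0))
  expect_lt(abs(sd(cs$x) - 1.5), 3 * 1.5 / sqrt(2 * n1))
  expect_lt(abs(sd(ct$y) - 1), 3 / sqrt(2 * n0))
  # all three conditional correlations, both arms
  for (arm in list(cs, ct)) {
    n <- nrow(arm)
    expect_lt(abs(cor(arm$x, arm$y) - 0.5), 3 * (1 - 0.25) / sqrt(n))
    expect_lt(abs(cor(arm$x, arm$w_star) - 0.3), 3 * (1 - 0.09) / sqrt(n))
    expect_lt(abs(cor(arm$y, arm$w_star) - 0.5), 3 * (1 - 0.25) / sqrt(n))
  }
  # full-cohort empirical AUC close to the closed form
  ve <- empirical_auc_variance(coh, "x")
  expect_lt(abs(ve$estimate - pnorm(1 / sqrt(1 + 1.5^2))), 3 * ve$se)
  # prevalence
  expect_lt(abs(n1 / 200000 - 0.1), 3 * sqrt(0.1 * 0.9 / 200000))
})

test_that("cohort generation is reproducible under a seed", {
  m <- binormal_model()
  c1 <- generate_cohort(m, 500, seed = 42)
  c2 <- generate_cohort(m, 500, seed = 42)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
})

test_that("Bernoulli sampling uses the matched design probabilities", {
  m <- binormal_model(lambda = 0.1, rho_xw = 0.3)
  d <- design_spec("bernoulli", p_case = 0.2)
  coh <- generate_cohort(m, 20000, seed = 3)
  s <- apply_bernoulli(coh, d, m, seed = 4)
  df <- as.data.frame(s)
  pr <- population_stratum_probs(m)
  want <- 0.2 * pr$p_case_joint / pr$p_control_joint
  # recorded true probabilities match the rule exactly
  for (k in 1:3) {
    got <- unique(df$p_true[df$disease == 0 & df$stratum == as.character(k)])
    expect_equal(got, want[k], tolerance = 1e-12)
  }
  expect_true(all(df$p_true[df$disease == 1] == 0.2))
  # markers masked iff unsampled
  expect_true(all(is.na(df$x[df$sampled == 0])))
  expect_true(all(!is.na(df$x[df$sampled == 1])))
  # realised counts near expectation (binomial 3 SE)
  nD <- sum(df$disease == 1 & df$sampled == 1)
  ED <- sum(df$disease == 1) * 0.2
  expect_lt(abs(nD - ED), 3 * sqrt(ED * 0.8))
  # determinism
  s2 <- apply_bernoulli(coh, d, m, seed = 4)
  expect_identical(as.data.frame(s2), df)
})

test_that("expected Bernoulli control counts match cases per stratum", {
  # with p_case = 1 the matched rule equates expected control and case
  # counts per stratum; check the MC average over replicated sampling
  m <- binormal_model(lambda = 0.1, rho_xw = 0.3)
  d <- design_spec("bernoulli", p_case = 1)
  coh <- generate_cohort(m, 5000, seed = 9)
  df0 <- as.data.frame(coh)
  reps <- 200
  cnt <- matrix(0, reps, 3)
  set.seed(10)
  for (r in seq_len(reps)) {
    s <- apply_bernoulli(coh, d, m)
    df <- as.data.frame(s)
    cnt[r, ] <- sapply(as.character(1:3), function(k) {
      sum(df$disease == 0 & df$sampled == 1 & df$stratum == k)
    })
  }
  pr <- population_stratum_probs(m)
  expected <- 5000 * pr$p_case_joint  # N * P(W = w, D = 1) * p_c, p_c = 1
  for (k in 1:3) {
    se <- sd(cnt[, k]) / sqrt(reps)
    expect_lt(abs(mean(cnt[, k]) - expected[k]), 3 * se + 1)
  }
})

test_that("FPS draws fixed counts with exact frequency matching", {
  m <- binormal_model(lambda = 0.1, rho_xw = 0.3)
  d <- design_spec("fps", p_case = 0.2)
  coh <- generate_cohort(m, 5000, seed = 5)
  s <- apply_fps(coh, d, seed = 6)
  df <- as.data.frame(s)
  full <- as.data.frame(coh)
  nD <- sum(df$disease == 1 & df$sampled == 1)
  expect_equal(nD, round(sum(df$disease == 1) * 0.2))
  # per-stratum control counts equal the realised case counts, using
  # the cases' covariate strata from the pre-design cohort
  case_w <- full$stratum[df$disease == 1 & df$sampled == 1]
  for (k in as.character(1:3)) {
    expect_equal(sum(df$disease == 0 & df$sampled == 1 & df$stratum == k),
                 sum(case_w == k))
  }
  # repeat draws: control counts conditionally fixed given case draw
  expect_identical(as.data.frame(apply_fps(coh, d, seed = 6)), df)
  # impossible request errors
  d2 <- design_spec("fps", p_case = 1)
  tiny <- generate_cohort(binormal_model(lambda = 0.6), 200, seed = 8)
  expect_error(apply_fps(tiny, d2), "fewer controls")
})

test_that("gamma-marker generator recovers marginals and copula", {
  m <- binormal_model(lambda = 0.3, rho_xy = 0, rho_xw = 0, rho_yw = 0)
  shp <- list(case = list(shape_x = 4, rate_x = 1, shape_y = 2, rate_y = 0.5),
              control = list(shape_x = 2, rate_x = 1, shape_y = 2, rate_y = 1))
  coh <- generate_gamma_cohort(m, shp, 50000, seed = 21)
  df <- as.data.frame(coh)
  cs <- df[df$disease == 1, ]; ct <- df[df$disease == 0, ]
  expect_lt(abs(mean(cs$x) - 4), 3 * 2 / sqrt(nrow(cs)))
  expect_lt(abs(mean(ct$y) - 2), 3 * sqrt(2) / sqrt(nrow(ct)))
  expect_lt(abs(cor(cs$x, cs$y)), 3 / sqrt(nrow(cs)))
  expect_identical(
    as.data.frame(generate_gamma_cohort(m, shp, 1000, seed = 3)),
    as.data.frame(generate_gamma_cohort(m, shp, 1000, seed = 3)))
})
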