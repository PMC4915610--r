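test_that("placements match hand computations and the AUC identity", {
  # equal-weight controls {0,1,2}, case value 1.5 -> F = 2/3
  df <- data.frame(id = 1:4, disease = c(1, 0, 0, 0),
                   stratum = c("cs", "s", "s", "s"), sampled = 1,
                   x = c(1.5, 0, 1, 2))
  coh <- cohort_data(df)
  wfD <- fit_stratum_weights(coh, "case")
  wfC <- fit_stratum_weights(coh, "control")
  pl <- placements(coh, "x", wfD, wfC)
  expect_equal(pl$case$F_x, 2 / 3)

  # two-stratum fixture: placements equal the brute-force weighted
  # proportions, and their IPW means both equal the IPW AUC
  coh <- toy_cohort()
  wfD <- fit_stratum_weights(coh, "case")
  wfC <- fit_stratum_weights(coh, "control")
  case <- as.data.frame(coh)[as.data.frame(coh)$disease == 1 &
                               as.data.frame(coh)$sampled == 1, ]
  ctrl <- as.data.frame(coh)[as.data.frame(coh)$disease == 0 &
                               as.data.frame(coh)$sampled == 1, ]
  u <- 1 / wfD$p_hat[wfD$sampled]
  w <- 1 / wfC$p_hat[wfC$sampled]
  bf <- bf_placements(case$x, u, ctrl$x, w)
  pl <- placements(coh, "x", wfD, wfC)
  expect_equal(pl$case$F_x, bf$F_case, tolerance = 1e-12)
  expect_equal(pl$control$S_x, bf$S_control, tolerance = 1e-12)
  a <- ipw_auc(coh, "x", wfD, wfC)$estimate
  expect_equal(sum(u * pl$case$F_x) / sum(u), a, tolerance = 1e-12)
  expect_equal(sum(w * pl$control$S_x) / sum(w), a, tolerance = 1e-12)
  expect_true(all(pl$case$F_x >= 0 & pl$case$F_x <= 1))
  expect_true(all(pl$control$S_x >= 0 & pl$control$S_x <= 1))
})

test_that("single-marker variance plug-in equals the brute-force formula", {
  coh <- toy_cohort()
  wfD <- fit_stratum_weights(coh, "case")
  wfC <- fit_stratum_weights(coh, "control")
  for (marker in c("x", "y")) {
    vr <- auc_variance(coh, marker, wfD, wfC)
    bf <- bf_auc_sigma(coh, marker, estimated = TRUE)
    expect_equal(vr$sigma, bf$sigma, tolerance = 1e-10)
    expect_equal(vr$estimate, bf$auc, tolerance = 1e-12)
    # known-weights form drops only the quadratic corrections
    vk <- auc_variance(coh, marker, wfD, wfC, weights_estimated = FALSE)
    bk <- bf_auc_sigma(coh, marker, estimated = FALSE)
    expect_equal(vk$sigma, bk$sigma, tolerance = 1e-10)
    expect_gte(vk$sigma, vr$sigma)
  }
})

test_that("delta variance equals the expanded sum of per-marker terms", {
  # Sigma_xy = Sigma_x + Sigma_y - 2 * (centred cross terms) with the
  # correction in the difference of the per-marker B vectors; verified
  # against an element-wise reconstruction from raw data.
  coh <- toy_cohort()
  wfD <- fit_stratum_weights(coh, "case")
  wfC <- fit_stratum_weights(coh, "control")
  vr <- delta_auc_variance(coh, wfD, wfC)

  df <- as.data.frame(coh)
  tabD <- stratum_table(coh, "case"); tabC <- stratum_table(coh, "control")
  cs <- df[df$disease == 1 & df$sampled == 1, ]
  ct <- df[df$disease == 0 & df$sampled == 1, ]
  pD <- (tabD$n_k / tabD$N_k)[match(cs$stratum, tabD$stratum)]
  pC <- (tabC$n_k / tabC$N_k)[match(ct$stratum, tabC$stratum)]
  u <- 1 / pD; w <- 1 / pC
  lam <- sum(df$disease == 1) / nrow(df)
  plx <- bf_placements(cs$x, u, ct$x, w)
  ply <- bf_placements(cs$y, u, ct$y, w)
  Ax <- sum(u * plx$F_case) / sum(u); Ay <- sum(u * ply$F_case) / sum(u)

  arm <- function(fx, fy, A_x, A_y, p, stratum, tab) {
    uu <- 1 / p
    g <- (fy - A_y) - (fx - A_x)
    s <- sum(uu^2 * g^2) / sum(uu)
    corr <- 0
    for (k in seq_len(nrow(tab))) {
      pik <- tab$n_k[k] / tab$N_k[k]
      if (pik >= 1) next
      sel <- stratum == tab$stratum[k]
      Bk <- sum(uu[sel]^2 * g[sel]) / sum(uu)
      Ik <- (tab$N_k[k] / sum(tab$N_k)) / (pik * (1 - pik))
      corr <- corr + Bk^2 / Ik
    }
    s - corr
  }
  sD <- arm(plx$F_case, ply$F_case, Ax, Ay, pD, cs$stratum, tabD)
  sC <- arm(plx$S_control, ply$S_control, Ax, Ay, pC, ct$stratum, tabC)
  expect_equal(vr$sigma, sD / lam + sC / (1 - lam), tolerance = 1e-10)
  expect_equal(vr$estimate, Ay - Ax, tolerance = 1e-12)
})

test_that("identical markers give exactly zero delta variance", {
  coh <- toy_cohort()
  df <- as.data.frame(coh)
  df$y <- df$x
  same <- cohort_data(df)
  wfD <- fit_stratum_weights(same, "case")
  wfC <- fit_stratum_weights(same, "control")
  vr <- delta_auc_variance(same, wfD, wfC)
  expect_lt(abs(vr$sigma), 1e-10)
})

test_that("with everyone sampled the plug-in is the classical variance", {
  set.seed(31)
  n <- 120
  df <- data.frame(id = 1:n, disease = rep(c(1, 0), c(30, 90)),
                   stratum = rep(c("cs", "s"), c(30, 90)), sampled = 1,
                   x = c(rnorm(30, 1), rnorm(90)))
  coh <- cohort_data(df)
  wfD <- fit_stratum_weights(coh, "case")
  wfC <- fit_stratum_weights(coh, "control")
  vr <- auc_variance(coh, "x", wfD, wfC)
  # classical full-data expression from raw placements
  pl <- bf_placements(df$x[df$disease == 1], rep(1, 30),
                      df$x[df$disease == 0], rep(1, 90))
  A <- mean(pl$F_case)
  lam <- 30 / n
  classical <- mean((pl$F_case - A)^2) / lam +
    mean((pl$S_control - A)^2) / (1 - lam)
  expect_equal(vr$sigma, classical, tolerance = 1e-12)
  # inflation/coupling/correction components all vanish
  nul <- vr$components[grepl("inflation|coupling|correction",
                             names(vr$components))]
  expect_true(all(abs(nul) < 1e-14))
  # empirical variance path gives the same report
  ve <- empirical_auc_variance(coh, "x")
  expect_equal(ve$sigma, vr$sigma, tolerance = 1e-12)
  expect_equal(ve$se, vr$se, tolerance = 1e-12)
})

test_that("Wald inference matches the closed form", {
  vr <- structure(list(sigma = 1, se = 0.05, N = 400, lambda_hat = 0.5,
                       method = "ipw"), class = "variance_report")
  w <- wald_test(0.6, vr, null_value = 0.5)
  expect_equal(w$statistic, 2)
  expect_equal(w$p_value, 2 * pnorm(-2), tolerance = 1e-12)
  expect_equal(w$ci, c(0.6 - qnorm(0.975) * 0.05, 0.6 + qnorm(0.975) * 0.05),
               tolerance = 1e-12)
  w0 <- wald_test(0.5, vr, null_value = 0.5)
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p_value, 1)
  # CI excludes the null iff p < level
  expect_equal(w$p_value < 0.05, w$ci[1] > 0.5 || w$ci[2] < 0.5)
  vr0 <- structure(list(sigma = 0, se = 0, N = 400, method = "ipw"),
                   class = "variance_report")
  expect_error(wald_test(0.6, vr0, 0.5), "positive standard error")
})

test_that("DeLong test equals the structural-components computation", {
  set.seed(12)
  ax <- rnorm(9, 1); ay <- 0.5 * ax + rnorm(9)
  bx <- rnorm(11); by <- 0.4 * bx + rnorm(11)
  df <- data.frame(id = 1:20, disease = rep(c(1, 0), c(9, 11)),
                   stratum = rep(c("cs", "s"), c(9, 11)), sampled = 1,
                   x = c(ax, bx), y = c(ay, by))
  coh <- cohort_data(df)
  dl <- delong_test(coh)
  bf <- bf_delong(ax, ay, bx, by)
  expect_equal(dl$estimate, bf$delta, tolerance = 1e-12)
  expect_equal(dl$se, sqrt(bf$var), tolerance = 1e-12)
  # identical markers: documented p = 1 convention
  df$y <- df$x
  expect_equal(delong_test(cohort_data(df))$p_value, 1)
})

test_that("DeLong test agrees with pROC's implementation", {
  set.seed(13)
  ax <- rnorm(25, 0.8); ay <- 0.6 * ax + rnorm(25, 0.4)
  bx <- rnorm(40); by <- 0.6 * bx + rnorm(40)
  df <- data.frame(id = 1:65, disease = rep(c(1, 0), c(25, 40)),
                   stratum = rep(c("cs", "s"), c(25, 40)), sampled = 1,
                   x = c(ax, bx), y = c(ay, by))
  dl <- delong_test(cohort_data(df))
  rt <- pROC::roc.test(
    pROC::roc(rep(c(1, 0), c(25, 40)), c(ax, bx), quiet = TRUE,
              direction = "<"),
    pROC::roc(rep(c(1, 0), c(25, 40)), c(ay, by), quiet = TRUE,
              direction = "<"),
    method = "delong", paired = TRUE)
  expect_equal(abs(dl$statistic), abs(unname(rt$statistic)), tolerance = 1e-8)
  expect_equal(dl$p_value, rt$p.value, tolerance = 1e-8)
})

test_that("bootstrap is deterministic and degenerates correctly", {
  coh <- toy_cohort()
  # the tiny fixture loses a stratum in some replicates: warned, counted
  expect_warning(b1 <- bootstrap_variance(coh, "auc", B = 120, seed = 9),
                 "dropped")
  b2 <- suppressWarnings(bootstrap_variance(coh, "auc", B = 120, seed = 9))
  expect_identical(b1$replicates, b2$replicates)
  expect_gt(b1$dropped, 0)
  expect_error(bootstrap_variance(coh, "auc", B = 50), "B >= 100")
  # perfectly separated markers keep AUC = 1 in every replicate
  df <- data.frame(id = 1:40, disease = rep(c(1, 0), each = 20),
                   stratum = rep(c("cs", "s"), each = 20), sampled = 1,
                   x = c(21:40, 1:20))
  sep <- cohort_data(df)
  bs <- bootstrap_variance(sep, "auc", B = 100, seed = 2)
  expect_equal(bs$var, 0)
})

test_that("negative plug-in variances are clipped with a warning", {
  expect_warning(
    twophaseAUC:::.new_variance_report(-1e-6, 100, 0.5, c(a = 1), 0.5,
                                       "ipw", TRUE),
    "clipped")
})
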