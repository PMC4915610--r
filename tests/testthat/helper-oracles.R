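# Independent brute-force oracles: everything here is computed with
# explicit double sums and elementwise loops, no reuse of the package's
# sort/cumsum kernels.

# Weighted Mann-Whitney statistic via the full double sum.
bf_wauc <- function(a, u, b, w, ties = "strict") {
  num <- 0
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      sc <- if (a[i] > b[j]) 1 else if (a[i] == b[j] && ties == "midrank") 0.5 else 0
      num <- num + u[i] * w[j] * sc
    }
  }
  num / (sum(u) * sum(w))
}

# Placement values via double sums.
bf_placements <- function(a, u, b, w, ties = "strict") {
  Fv <- vapply(a, function(v) {
    s <- sum(w[b < v]) + if (ties == "midrank") 0.5 * sum(w[b == v]) else 0
    s / sum(w)
  }, numeric(1))
  Sv <- vapply(b, function(v) {
    s <- sum(u[a > v]) + if (ties == "midrank") 0.5 * sum(u[a == v]) else 0
    s / sum(u)
  }, numeric(1))
  list(F_case = Fv, S_control = Sv)
}

# One arm's variance contribution, written out term by term in the
# printed decomposition (placement variance + second-moment inflation +
# AUC coupling - weight-estimation quadratic form with diagonal
# stratum information).
bf_arm_sigma <- function(f, p, stratum, stratum_tab, A, estimated = TRUE) {
  u <- 1 / p
  W <- sum(u)
  q <- (1 - p) / p
  EF <- sum(u * f) / W
  varF <- sum(u * (f - EF)^2) / W
  infl <- sum(u * q * f^2) / W
  coup <- -2 * A * sum(u * q * f) / W + A^2 * sum(u * q) / W
  corr <- 0
  if (estimated) {
    for (k in seq_len(nrow(stratum_tab))) {
      pik <- stratum_tab$n_k[k] / stratum_tab$N_k[k]
      if (pik >= 1) next
      sel <- stratum == stratum_tab$stratum[k]
      Bk <- sum(u[sel]^2 * (f[sel] - A)) / W
      Ik <- (stratum_tab$N_k[k] / sum(stratum_tab$N_k)) / (pik * (1 - pik))
      corr <- corr + Bk^2 / Ik
    }
  }
  varF + infl + coup - corr
}

# Full Theorem-1-style plug-in from raw per-subject data.
bf_auc_sigma <- function(coh, marker = "x", estimated = TRUE, ties = "strict") {
  df <- as.data.frame(coh)
  tabD <- stratum_table(coh, "case")
  tabC <- stratum_table(coh, "control")
  cs <- df[df$disease == 1 & df$sampled == 1, ]
  ct <- df[df$disease == 0 & df$sampled == 1, ]
  pD <- (tabD$n_k / tabD$N_k)[match(cs$stratum, tabD$stratum)]
  pC <- (tabC$n_k / tabC$N_k)[match(ct$stratum, tabC$stratum)]
  u <- 1 / pD
  w <- 1 / pC
  A <- bf_wauc(cs[[marker]], u, ct[[marker]], w, ties)
  pl <- bf_placements(cs[[marker]], u, ct[[marker]], w, ties)
  lam <- sum(df$disease == 1) / nrow(df)
  sD <- bf_arm_sigma(pl$F_case, pD, cs$stratum, tabD, A, estimated)
  sC <- bf_arm_sigma(pl$S_control, pC, ct$stratum, tabC, A, estimated)
  list(sigma = sD / lam + sC / (1 - lam), auc = A, lambda = lam)
}

# Stratified double-sum representation of the IPW AUC (the
# finite-population stratified sampling form): explicit quadruple sum
# over case strata, control strata and subjects.
bf_stratified_auc <- function(coh, marker = "x") {
  df <- as.data.frame(coh)
  tabD <- stratum_table(coh, "case")
  tabC <- stratum_table(coh, "control")
  cs <- df[df$disease == 1 & df$sampled == 1, ]
  ct <- df[df$disease == 0 & df$sampled == 1, ]
  num <- 0
  den <- 0
  for (kD in seq_len(nrow(tabD))) {
    piD <- tabD$n_k[kD] / tabD$N_k[kD]
    xi <- cs[[marker]][cs$stratum == tabD$stratum[kD]]
    for (kC in seq_len(nrow(tabC))) {
      piC <- tabC$n_k[kC] / tabC$N_k[kC]
      xj <- ct[[marker]][ct$stratum == tabC$stratum[kC]]
      for (a in xi) {
        for (b in xj) {
          num <- num + (a > b) / (piD * piC)
          den <- den + 1 / (piD * piC)
        }
      }
    }
  }
  num / den
}

# DeLong structural-component variance of AUC_y - AUC_x, spelled out.
bf_delong <- function(ax, ay, bx, by) {
  m <- length(ax); n <- length(bx)
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v10x <- vapply(seq_len(m), function(i) mean(psi(ax[i], bx)), numeric(1))
  v10y <- vapply(seq_len(m), function(i) mean(psi(ay[i], by)), numeric(1))
  v01x <- vapply(seq_len(n), function(j) mean(psi(ax, bx[j])), numeric(1))
  v01y <- vapply(seq_len(n), function(j) mean(psi(ay, by[j])), numeric(1))
  delta <- mean(v10y) - mean(v10x)
  v <- (var(v10x) + var(v10y) - 2 * cov(v10x, v10y)) / m +
    (var(v01x) + var(v01y) - 2 * cov(v01x, v01y)) / n
  list(delta = delta, var = v)
}

# Small deterministic two-stratum fixture (<= 10 sampled per arm).
toy_cohort <- function() {
  df <- data.frame(
    id = 1:24,
    disease = c(rep(1, 8), rep(0, 16)),
    stratum = c(rep("a", 4), rep("b", 4), rep("u", 8), rep("v", 8)),
    sampled = c(1, 1, 0, 0, 1, 1, 1, 0,
                1, 1, 1, 0, 0, 0, 0, 0, 1, 1, 0, 0, 0, 0, 0, 0),
    x = NA_real_, y = NA_real_)
  df$x[df$sampled == 1] <- c(2.1, 0.4, 3.0, -0.2, 0.9, 1.1, 0.5, 2.2, 1.7, -1.3)
  df$y[df$sampled == 1] <- c(1.0, 2.0, -0.5, 1.4, 0.3, -1.0, 2.5, 0.1, 0.6, 1.9)
  cohort_data(df)
}

# Standard simulation setting used across tests (single-marker null).
null_model <- function(rho_xw = 0.3) {
  binormal_model(mu_Dx = 0, sigma_Dx = 1, mu_Dy = 1, sigma_Dy = 1,
                 rho_xy = 0, rho_xw = rho_xw, rho_yw = 0.5)
}
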