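#' Population placement moments of a bi-normal marker model
#'
#' Deterministic numerical-integration computation of the population
#' moments entering the design-variance formulas for a single marker
#' `X` bivariate normal with the latent covariate `W*` given disease:
#' the variance of the case placement `F(X_case)` (control CDF at a
#' case marker), the variance of the control placement `S(X_control)`
#' (case survival at a control marker), and the within-stratum
#' variances of `S` among controls for each covariate stratum, together
#' with the control stratum probabilities. Controls have `X` and `W*`
#' standard normal; cases have `X ~ N(mu_Dx, sigma_Dx^2)`.
#'
#' @param m a [binormal_model()] (only `mu_Dx`, `sigma_Dx`, `rho_xw`,
#'   `cutpoints`, `lambda` are used; the design-efficiency analysis is
#'   a single-marker calculation).
#' @param rel_tol quadrature relative tolerance.
#' @return a `population_moments` object: `var_F_case`, `var_S_control`,
#'   `var_S_stratum` (per control stratum), `p_control_stratum`,
#'   `p_case_stratum`, `auc`.
#' @details Placements use the closed-form conditional normal CDFs:
#'   `F(x) = pnorm(x)` and `S(v) = 1 - pnorm((v - mu_Dx) / sigma_Dx)`.
#'   Conditioning on a stratum `a < W* <= b` tilts the control marker
#'   density by the conditional normal probability of the stratum given
#'   `X = x`.
#' @export
population_moments <- function(m, rel_tol = 1e-8) {
  mu <- m$mu_Dx; sg <- m$sigma_Dx; rho <- m$rho_xw
  qint <- function(f) {
    r <- tryCatch(stats::integrate(f, -Inf, Inf, rel.tol = rel_tol,
                                   abs.tol = 0),
                  error = function(e) NULL)
    if (is.null(r) || r$message != "OK") {
      stop("quadrature failed to converge at rel_tol = ", rel_tol,
           call. = FALSE)
    }
    r$value
  }
  # case placements: F(x) = pnorm(x), X_case ~ N(mu, sg^2)
  EF <- qint(function(x) stats::pnorm(x) * stats::dnorm(x, mu, sg))
  EF2 <- qint(function(x) stats::pnorm(x)^2 * stats::dnorm(x, mu, sg))
  # control placements: S(v) = 1 - pnorm((v - mu)/sg), X_control ~ N(0,1)
  S <- function(v) 1 - stats::pnorm((v - mu) / sg)
  ES <- qint(function(v) S(v) * stats::dnorm(v))
  ES2 <- qint(function(v) S(v)^2 * stats::dnorm(v))

  cuts <- c(-Inf, m$cutpoints, Inf)
  K <- length(cuts) - 1L
  p_ctrl <- diff(stats::pnorm(cuts))
  p_case <- diff(stats::pnorm(cuts, mean = m$mu_w_case))
  var_S_k <- numeric(K)
  s <- sqrt(1 - rho^2)
  for (k in seq_len(K)) {
    # P(a < W* <= b | X = x) for controls; W* | X = x ~ N(rho x, 1 - rho^2)
    wgt <- function(x) {
      stats::pnorm((cuts[k + 1L] - rho * x) / s) -
        stats::pnorm((cuts[k] - rho * x) / s)
    }
    dens <- function(x) stats::dnorm(x) * wgt(x) / p_ctrl[k]
    ESk <- qint(function(x) S(x) * dens(x))
    ES2k <- qint(function(x) S(x)^2 * dens(x))
    var_S_k[k] <- ES2k - ESk^2
  }
  structure(list(var_F_case = EF2 - EF^2,
                 var_S_control = ES2 - ES^2,
                 var_S_stratum = var_S_k,
                 p_control_stratum = p_ctrl,
                 p_case_stratum = p_case,
                 auc = EF, lambda = m$lambda),
            class = "population_moments")
}

.check_pi <- function(pi) {
  if (any(pi <= 0)) {
    stop("control sampling fraction must be positive", call. = FALSE)
  }
  if (any(pi > 1)) {
    stop("control sampling fraction exceeds 1", call. = FALSE)
  }
  pi
}

#' Asymptotic variance of the IPW AUC under stratified control sampling
#'
#' Design with all cases included in phase two and controls drawn
#' without replacement within covariate strata (frequency matching),
#' analysed with estimated per-stratum weights. The variance is the
#' case placement variance over `N * lambda` plus, over `N (1-lambda)`,
#' the control placement variance inflated by the within-stratum
#' finite-sampling penalties `var{S | stratum} P(stratum) (1-pi)/pi`.
#'
#' @param pm a [population_moments()].
#' @param N phase-one cohort size.
#' @param lambda disease prevalence (defaults to the model's).
#' @param pi_control per-stratum control sampling fractions; default is
#'   1:1 frequency matching to cases with all cases sampled, i.e.
#'   `pi_k = lambda P_case(k) / ((1 - lambda) P_control(k))`.
#' @return a `design_variance` with `variance`, itemised `terms` and
#'   `pi_control`.
#' @export
variance_design_stratified <- function(pm, N, lambda = pm$lambda,
                                       pi_control = NULL) {
  if (is.null(pi_control)) {
    pi_control <- lambda * pm$p_case_stratum /
      ((1 - lambda) * pm$p_control_stratum)
  }
  .check_pi(pi_control)
  case_term <- pm$var_F_case / (N * lambda)
  base_term <- pm$var_S_control / (N * (1 - lambda))
  penalty <- sum(pm$var_S_stratum * pm$p_control_stratum *
                   (1 - pi_control) / pi_control) / (N * (1 - lambda))
  structure(list(variance = case_term + base_term + penalty,
                 terms = c(case = case_term, control_base = base_term,
                           control_penalty = penalty),
                 pi_control = pi_control, N = N, lambda = lambda,
                 design = "stratified-matched"),
            class = "design_variance")
}

#' Asymptotic variance of the empirical AUC under SRS control sampling
#'
#' Design with all cases (fraction `pi_case`) and a simple random
#' sample of controls of matching size, i.e. a single control stratum
#' with fraction `pi_control = pi_case * lambda / (1 - lambda)`.
#' Algebraically this is the stratified-design formula with one
#' stratum.
#'
#' @inheritParams variance_design_stratified
#' @param pi_case case phase-two sampling fraction.
#' @param pi_control overall control sampling fraction; default derived
#'   from `pi_case` by the 1:1 matching rule.
#' @return a `design_variance`.
#' @export
variance_design_srs <- function(pm, N, lambda = pm$lambda, pi_case = 1,
                                pi_control = pi_case * lambda / (1 - lambda)) {
  .check_pi(pi_control)
  case_term <- pm$var_F_case / (N * lambda)
  base_term <- pm$var_S_control / (N * (1 - lambda))
  penalty <- pm$var_S_control * (1 - pi_control) / pi_control /
    (N * (1 - lambda))
  structure(list(variance = case_term + base_term + penalty,
                 terms = c(case = case_term, control_base = base_term,
                           control_penalty = penalty),
                 pi_control = pi_control, N = N, lambda = lambda,
                 design = "srs"),
            class = "design_variance")
}

#' @export
print.design_variance <- function(x, ...) {
  cat(sprintf("Design variance (%s): %.6g  (N = %d, lambda = %.3g)\n",
              x$design, x$variance, x$N, x$lambda))
  cat("  terms:", paste(sprintf("%s = %.4g", names(x$terms), x$terms),
                        collapse = ", "), "\n")
  cat("  control sampling fraction(s):",
      paste(sprintf("%.4g", x$pi_control), collapse = ", "), "\n")
  invisible(x)
}

#' Relative efficiency of matched stratified versus SRS control sampling
#'
#' Tabulates, over a grid of marker-covariate correlations, the ratio
#' of the asymptotic variance of the empirical AUC under simple random
#' control sampling to the asymptotic variance of the IPW AUC under
#' stratified frequency-matched control sampling (same phase-one size,
#' all cases in phase two). Values above 1 favour the stratified
#' matched design.
#'
#' @param mu_Dx case mean(s) of the marker (one curve per value);
#'   controls standard normal, case SD 1.
#' @param rho_grid grid of conditional correlations in (-1, 1).
#' @param N phase-one cohort size.
#' @param lambda disease prevalence.
#' @param cutpoint stratum boundary on `W*` (default the median, two
#'   strata).
#' @param mu_w_case case mean of `W*`.
#' @return data.frame with columns `rho`, `auc`, `var_srs`,
#'   `var_stratified`, `efficiency`.
#' @export
relative_efficiency_curve <- function(mu_Dx, rho_grid = seq(-0.9, 0.9, by = 0.1),
                                      N = 5000, lambda = 0.1,
                                      cutpoint = stats::qnorm(0.5),
                                      mu_w_case = 0.6) {
  if (any(abs(rho_grid) >= 1)) stop("rho grid must lie in (-1, 1)", call. = FALSE)
  rows <- lapply(mu_Dx, function(mu) {
    do.call(rbind, lapply(rho_grid, function(rho) {
      m <- binormal_model(lambda = lambda, mu_w_case = mu_w_case,
                          cutpoints = cutpoint, mu_Dx = mu, sigma_Dx = 1,
                          rho_xw = rho)
      pm <- population_moments(m)
      v2 <- variance_design_stratified(pm, N = N, lambda = lambda)
      v1 <- variance_design_srs(pm, N = N, lambda = lambda, pi_case = 1)
      data.frame(rho = rho, mu_Dx = mu, auc = pm$auc,
                 var_srs = v1$variance, var_stratified = v2$variance,
                 efficiency = v1$variance / v2$variance)
    }))
  })
  do.call(rbind, rows)
}
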