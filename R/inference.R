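# Placement kernel: for case values `a` with IPW weights `u` and control
# values `b` with IPW weights `w`, the case placement F(a_i) is the
# normalised control weight strictly below a_i (plus half the tied
# weight under midrank), and the control placement S(b_j) is the
# normalised case weight strictly above b_j. The weighted means of both
# placement sets equal the IPW AUC.
.placements_kernel <- function(a, u, b, w, ties) {
  su <- sum(u); sw <- sum(w)
  kf <- .wt_below(a, b, w)
  Fv <- kf$below
  ks <- .wt_below(b, a, u)
  Sv <- su - (ks$below + ks$tied)
  if (ties == "midrank") {
    Fv <- Fv + 0.5 * kf$tied
    Sv <- Sv + 0.5 * ks$tied
  }
  list(F_case = Fv / sw, S_control = Sv / su)
}

#' Placement values under IPW weighting
#'
#' For each sampled case, the IPW-estimated control CDF at its marker
#' value (strict-inequality convention matching the AUC indicator); for
#' each sampled control, the IPW-estimated case survival at its marker
#' value. The IPW-weighted mean of either set equals the IPW AUC.
#'
#' @inheritParams ipw_auc
#' @return list with data.frames `case` (`id`, one `F_<marker>` column)
#'   and `control` (`id`, one `S_<marker>` column).
#' @export
placements <- function(c, marker = c("x", "y"), wf_case, wf_control,
                       ties = c("strict", "midrank")) {
  marker <- match.arg(marker)
  ties <- match.arg(ties)
  case <- .arm_view(c, "case"); ctrl <- .arm_view(c, "control")
  .check_fit_arm(wf_case, case, "case")
  .check_fit_arm(wf_control, ctrl, "control")
  a <- case[[marker]][case$sampled]; b <- ctrl[[marker]][ctrl$sampled]
  u <- 1 / wf_case$p_hat[case$sampled]
  w <- 1 / wf_control$p_hat[ctrl$sampled]
  pk <- .placements_kernel(a, u, b, w, ties)
  out <- list(case = data.frame(id = case$id[case$sampled], F = pk$F_case),
              control = data.frame(id = ctrl$id[ctrl$sampled], S = pk$S_control))
  names(out$case)[2] <- paste0("F_", marker)
  names(out$control)[2] <- paste0("S_", marker)
  out
}

# One arm's contribution to the asymptotic variance (before the 1/lambda
# factor): plug-in of E{(1/p) g^2} minus the weight-estimation quadratic
# form B^T I^-1 B with B = E{g (1/p) dp/dtheta}, where g is the centred
# placement (or centred placement difference). All population
# expectations are IPW-weighted empirical moments over the arm's sampled
# subjects. Also itemises the printed-form components: placement
# variance, uncentred second-moment inflation, AUC-coupling remainder,
# and the correction.
.arm_sigma <- function(g, u, score_s, info, correct, auc_terms) {
  W <- sum(u)
  q <- u - 1                       # (1 - p)/p evaluated at 1/p = u
  placement_var <- sum(u * g^2) / W
  sigma <- sum(u^2 * g^2) / W      # E{(1/p) g^2} = var + centred inflation
  correction <- 0
  if (correct && ncol(score_s) > 0L) {
    B <- colSums(score_s * (u^2 * g)) / W
    qf <- tryCatch(solve(info, B), error = function(e) {
      stop("information matrix restricted to estimated strata is singular; ",
           "merge sampling strata", call. = FALSE)
    })
    correction <- drop(crossprod(B, qf))
  }
  # Printed-form itemisation: g = f - A with f the raw placement(s);
  # inflation E{q f^2} and coupling -2A E{q f} + A^2 E{q} recombine to
  # the centred inflation above.
  A <- auc_terms$A
  f <- auc_terms$f
  inflation <- sum(u * q * f^2) / W
  coupling <- -2 * A * sum(u * q * f) / W + A^2 * sum(u * q) / W
  list(sigma = sigma - correction,
       components = c(placement_var = placement_var,
                      second_moment_inflation = inflation,
                      auc_coupling = coupling,
                      weight_correction = -correction))
}

.new_variance_report <- function(sigma, N, lambda_hat, components, estimate,
                                 method, weights_estimated) {
  if (sigma < 0) {
    warning("plug-in asymptotic variance was negative (", format(sigma),
            "); clipped to 0", call. = FALSE)
    sigma <- 0
  }
  structure(list(sigma = sigma, se = sqrt(sigma / N), N = N,
                 lambda_hat = lambda_hat, components = components,
                 estimate = estimate, method = method,
                 weights_estimated = weights_estimated),
            class = "variance_report")
}

# Shared driver for the single-marker variance: takes arm views plus
# weight fits and returns the report. Used by both the IPW and the
# empirical (all-weights-one) variance.
.auc_variance_kernel <- function(case, ctrl, marker, u_all_case, u_all_ctrl,
                                 wf_case, wf_control, weights_estimated,
                                 ties, N, lambda_hat, method) {
  a <- case[[marker]][case$sampled]; b <- ctrl[[marker]][ctrl$sampled]
  u <- u_all_case[case$sampled]; w <- u_all_ctrl[ctrl$sampled]
  pk <- .placements_kernel(a, u, b, w, ties)
  A <- sum(u * pk$F_case) / sum(u)    # equals the (IPW) AUC estimate
  sc_case <- if (is.null(wf_case)) matrix(0, length(a), 0) else
    wf_case$score[case$sampled, , drop = FALSE]
  sc_ctrl <- if (is.null(wf_control)) matrix(0, length(b), 0) else
    wf_control$score[ctrl$sampled, , drop = FALSE]
  sd_case <- .arm_sigma(pk$F_case - A, u, sc_case,
                        if (is.null(wf_case)) NULL else wf_case$information,
                        weights_estimated, list(A = A, f = pk$F_case))
  sd_ctrl <- .arm_sigma(pk$S_control - A, w, sc_ctrl,
                        if (is.null(wf_control)) NULL else wf_control$information,
                        weights_estimated, list(A = A, f = pk$S_control))
  sigma <- sd_case$sigma / lambda_hat + sd_ctrl$sigma / (1 - lambda_hat)
  comps <- c(stats::setNames(sd_case$components,
                             paste0("case_", names(sd_case$components))),
             stats::setNames(sd_ctrl$components,
                             paste0("control_", names(sd_ctrl$components))))
  .new_variance_report(sigma, N, lambda_hat, comps, A, method,
                       weights_estimated)
}

#' Asymptotic variance of the IPW AUC estimator
#'
#' Plug-in of the closed-form asymptotic variance of
#' `sqrt(N) (AUChat - AUC)` for one marker under two-phase sampling:
#' per arm, the IPW second moment of the centred placement values
#' `E{(1/p)(placement - AUC)^2}` minus, when the weights were
#' estimated, the quadratic-form correction built from the weight
#' model's score and information. All population expectations are
#' estimated by IPW-weighted empirical moments over sampled subjects,
#' so they target case/control-population moments under the biased
#' design. Strata with sampling fraction 1 have nothing estimated and
#' contribute zero correction. With all probabilities equal to 1 the
#' formula reduces to the classical full-data AUC variance
#' `var{F(X_case)}/lambda + var{S(X_control)}/(1 - lambda)`.
#'
#' @inheritParams ipw_auc
#' @param weights_estimated if `TRUE` (default for fitted weights) the
#'   weight-estimation corrections are subtracted; with [known_weights()]
#'   fits the corrections are always dropped.
#' @return a `variance_report` with `sigma` (variance of the
#'   `sqrt(N)`-scaled estimator), `se = sqrt(sigma / N)`, `lambda_hat`,
#'   the named variance `components`, and the point `estimate`.
#' @export
auc_variance <- function(c, marker = c("x", "y"), wf_case, wf_control,
                         weights_estimated = NULL,
                         ties = c("strict", "midrank")) {
  marker <- match.arg(marker)
  ties <- match.arg(ties)
  case <- .arm_view(c, "case"); ctrl <- .arm_view(c, "control")
  .check_fit_arm(wf_case, case, "case")
  .check_fit_arm(wf_control, ctrl, "control")
  if (is.null(weights_estimated)) {
    weights_estimated <- wf_case$kind != "known" || wf_control$kind != "known"
  }
  ct <- attr(c, "counts")
  .auc_variance_kernel(case, ctrl, marker,
                       1 / wf_case$p_hat, 1 / wf_control$p_hat,
                       wf_case, wf_control, weights_estimated, ties,
                       N = ct$N, lambda_hat = ct$N_case / ct$N,
                       method = "ipw")
}

#' Asymptotic variance of the empirical AUC on the phase-two sample
#'
#' The classical (unweighted) asymptotic variance of the Mann-Whitney
#' AUC treating the sampled cases and controls as representative:
#' `var{F(X_case)}/lambda + var{S(X_control)}/(1 - lambda)` with
#' moments and `lambda` computed on the phase-two sample. This is the
#' variance behind the naive Wald CI; under biased sampling the CI is
#' centred at a biased estimate.
#'
#' @inheritParams empirical_auc
#' @return a `variance_report` (with `N` the phase-two sample size).
#' @export
empirical_auc_variance <- function(c, marker = c("x", "y"),
                                   ties = c("strict", "midrank")) {
  marker <- match.arg(marker)
  ties <- match.arg(ties)
  case <- .arm_view(c, "case"); ctrl <- .arm_view(c, "control")
  n_case <- sum(case$sampled); n_ctrl <- sum(ctrl$sampled)
  sub_case <- lapply(case, function(v) if (is.null(v)) NULL else v[case$sampled])
  sub_ctrl <- lapply(ctrl, function(v) if (is.null(v)) NULL else v[ctrl$sampled])
  sub_case$sampled <- rep(TRUE, n_case); sub_ctrl$sampled <- rep(TRUE, n_ctrl)
  .auc_variance_kernel(sub_case, sub_ctrl, marker,
                       rep(1, n_case), rep(1, n_ctrl), NULL, NULL,
                       weights_estimated = FALSE, ties = ties,
                       N = n_case + n_ctrl,
                       lambda_hat = n_case / (n_case + n_ctrl),
                       method = "empirical")
}

# Delta variant of the arm kernel: g is the difference of centred
# placements between markers y and x.
.delta_variance_kernel <- function(case, ctrl, u_all_case, u_all_ctrl,
                                   wf_case, wf_control, weights_estimated,
                                   ties, N, lambda_hat, method) {
  u <- u_all_case[case$sampled]; w <- u_all_ctrl[ctrl$sampled]
  pkx <- .placements_kernel(case$x[case$sampled], u, ctrl$x[ctrl$sampled], w, ties)
  pky <- .placements_kernel(case$y[case$sampled], u, ctrl$y[ctrl$sampled], w, ties)
  Ax <- sum(u * pkx$F_case) / sum(u)
  Ay <- sum(u * pky$F_case) / sum(u)
  gc <- (pky$F_case - Ay) - (pkx$F_case - Ax)
  gb <- (pky$S_control - Ay) - (pkx$S_control - Ax)
  sc_case <- if (is.null(wf_case)) matrix(0, length(gc), 0) else
    wf_case$score[case$sampled, , drop = FALSE]
  sc_ctrl <- if (is.null(wf_control)) matrix(0, length(gb), 0) else
    wf_control$score[ctrl$sampled, , drop = FALSE]
  dA <- Ay - Ax
  sd_case <- .arm_sigma(gc, u, sc_case,
                        if (is.null(wf_case)) NULL else wf_case$information,
                        weights_estimated,
                        list(A = dA, f = pky$F_case - pkx$F_case))
  sd_ctrl <- .arm_sigma(gb, w, sc_ctrl,
                        if (is.null(wf_control)) NULL else wf_control$information,
                        weights_estimated,
                        list(A = dA, f = pky$S_control - pkx$S_control))
  sigma <- sd_case$sigma / lambda_hat + sd_ctrl$sigma / (1 - lambda_hat)
  comps <- c(stats::setNames(sd_case$components,
                             paste0("case_", names(sd_case$components))),
             stats::setNames(sd_ctrl$components,
                             paste0("control_", names(sd_ctrl$components))))
  .new_variance_report(sigma, N, lambda_hat, comps, dA, method,
                       weights_estimated)
}

#' Asymptotic variance of the IPW difference in AUC
#'
#' Plug-in asymptotic variance of `sqrt(N) (DeltaAUChat - DeltaAUC)`
#' for two markers measured on the same phase-two subjects. Per arm it
#' is the IPW second moment of the paired difference of centred
#' placements, `E{(1/p) [(F_y - AUC_y) - (F_x - AUC_x)]^2}`, minus the
#' weight-estimation quadratic form in
#' `DeltaAUC * Q - (R_y - R_x)`. The paired construction automatically
#' carries the cross-marker covariance and second-moment cross terms;
#' it is identically 0 when the two markers coincide.
#'
#' @inheritParams auc_variance
#' @return a `variance_report` with `estimate` the IPW Delta AUC.
#' @export
delta_auc_variance <- function(c, wf_case, wf_control,
                               weights_estimated = NULL,
                               ties = c("strict", "midrank")) {
  ties <- match.arg(ties)
  if (attr(c, "n_markers") < 2L) {
    stop("delta_auc_variance needs a cohort with two markers", call. = FALSE)
  }
  case <- .arm_view(c, "case"); ctrl <- .arm_view(c, "control")
  .check_fit_arm(wf_case, case, "case")
  .check_fit_arm(wf_control, ctrl, "control")
  if (is.null(weights_estimated)) {
    weights_estimated <- wf_case$kind != "known" || wf_control$kind != "known"
  }
  ct <- attr(c, "counts")
  .delta_variance_kernel(case, ctrl, 1 / wf_case$p_hat, 1 / wf_control$p_hat,
                         wf_case, wf_control, weights_estimated, ties,
                         N = ct$N, lambda_hat = ct$N_case / ct$N,
                         method = "ipw")
}

#' Asymptotic variance of the empirical Delta AUC on the phase-two sample
#'
#' Paired-placement (DeLong-type) variance of `AUC_y - AUC_x` computed
#' on the sampled subjects with unit weights.
#'
#' @inheritParams empirical_auc
#' @return a `variance_report` (with `N` the phase-two sample size).
#' @export
empirical_delta_variance <- function(c, ties = c("strict", "midrank")) {
  ties <- match.arg(ties)
  if (attr(c, "n_markers") < 2L) {
    stop("empirical_delta_variance needs a cohort with two markers",
         call. = FALSE)
  }
  case <- .arm_view(c, "case"); ctrl <- .arm_view(c, "control")
  n_case <- sum(case$sampled); n_ctrl <- sum(ctrl$sampled)
  sub_case <- lapply(case, function(v) if (is.null(v)) NULL else v[case$sampled])
  sub_ctrl <- lapply(ctrl, function(v) if (is.null(v)) NULL else v[ctrl$sampled])
  sub_case$sampled <- rep(TRUE, n_case); sub_ctrl$sampled <- rep(TRUE, n_ctrl)
  .delta_variance_kernel(sub_case, sub_ctrl, rep(1, n_case), rep(1, n_ctrl),
                         NULL, NULL, weights_estimated = FALSE, ties = ties,
                         N = n_case + n_ctrl,
                         lambda_hat = n_case / (n_case + n_ctrl),
                         method = "empirical")
}

#' Wald test and confidence interval
#'
#' Normal-reference Wald inference for an AUC or Delta AUC estimate
#' with a plug-in asymptotic variance.
#'
#' @param estimate point estimate (or an `auc_result` /
#'   `delta_auc_result`, whose numeric estimate is extracted).
#' @param vr a `variance_report` from one of the variance functions.
#' @param null_value null value (0.5 for a single AUC, 0 for Delta AUC).
#' @param level confidence level.
#' @return a `test_result` with `statistic` (z), `p_value`, `ci`
#'   (untransformed), `ci_clipped` (clipped to the parameter range),
#'   `null`, `method`.
#' @export
wald_test <- function(estimate, vr, null_value = 0.5, level = 0.95) {
  is_delta <- inherits(estimate, "delta_auc_result")
  if (inherits(estimate, "auc_result")) estimate <- estimate$estimate
  if (is_delta) estimate <- estimate$delta
  if (vr$se <= 0) stop("Wald inference needs a positive standard error",
                       call. = FALSE)
  z <- (estimate - null_value) / vr$se
  zq <- stats::qnorm(1 - (1 - level) / 2)
  ci <- c(estimate - zq * vr$se, estimate + zq * vr$se)
  rng <- if (is_delta || null_value == 0) c(-1, 1) else c(0, 1)
  structure(list(statistic = z,
                 p_value = 2 * stats::pnorm(-abs(z)),
                 ci = ci,
                 ci_clipped = pmin(pmax(ci, rng[1]), rng[2]),
                 level = level, estimate = estimate, se = vr$se,
                 null = null_value,
                 method = paste0(vr$method, "-wald")),
            class = "test_result")
}

#' DeLong-DeLong test for equal AUC of two paired markers
#'
#' The classical nonparametric comparison of correlated AUCs via
#' structural components (midrank convention), computed on the sampled
#' subjects with unit weights. It assumes phase-two cases and controls
#' are representative of their populations; under biased sampling it is
#' included as the standard-practice comparator whose type-I error can
#' be far from nominal. When the two markers are identical the variance
#' of the difference degenerates; by convention the test then reports
#' `Delta = 0`, `p = 1`.
#'
#' @param c a [cohort_data()] object with two markers.
#' @param level confidence level for the reported interval.
#' @return a `test_result` with the AUC difference, its DeLong standard
#'   error, z statistic and two-sided p-value.
#' @export
delong_test <- function(c, level = 0.95) {
  if (attr(c, "n_markers") < 2L) {
    stop("delong_test needs a cohort with two markers", call. = FALSE)
  }
  case <- .arm_view(c, "case"); ctrl <- .arm_view(c, "control")
  ax <- case$x[case$sampled]; ay <- case$y[case$sampled]
  bx <- ctrl$x[ctrl$sampled]; by <- ctrl$y[ctrl$sampled]
  m <- length(ax); n <- length(bx)
  if (m < 2L || n < 2L) {
    stop("delong_test needs at least two sampled cases and controls",
         call. = FALSE)
  }
  comp <- function(a, b) {
    pk <- .placements_kernel(a, rep(1, length(a)), b, rep(1, length(b)),
                             "midrank")
    pk  # V10 = F_case, V01 = S_control
  }
  cx <- comp(ax, bx); cy <- comp(ay, by)
  auc_x <- mean(cx$F_case); auc_y <- mean(cy$F_case)
  delta <- auc_y - auc_x
  s10 <- stats::var(cbind(cx$F_case, cy$F_case))
  s01 <- stats::var(cbind(cx$S_control, cy$S_control))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  if (v <= .Machine$double.eps) {
    if (isTRUE(all.equal(delta, 0))) {
      return(structure(list(statistic = 0, p_value = 1, ci = c(0, 0),
                            ci_clipped = c(0, 0), level = level,
                            estimate = 0, se = 0, null = 0,
                            method = "delong"),
                       class = "test_result"))
    }
    stop("degenerate DeLong variance with unequal AUCs", call. = FALSE)
  }
  se <- sqrt(v)
  z <- delta / se
  zq <- stats::qnorm(1 - (1 - level) / 2)
  ci <- c(delta - zq * se, delta + zq * se)
  structure(list(statistic = z, p_value = 2 * stats::pnorm(-abs(z)),
                 ci = ci, ci_clipped = pmin(pmax(ci, -1), 1),
                 level = level, estimate = delta, se = se, null = 0,
                 method = "delong"),
            class = "test_result")
}

#' Two-phase bootstrap variance
#'
#' Design-respecting bootstrap check of the plug-in variances: each
#' replicate resamples the phase-one cases and the phase-one controls
#' with replacement (carrying their phase-two indicators and markers),
#' re-estimates the stratum sampling fractions on the replicate, and
#' recomputes the statistic. Replicates in which some stratum loses all
#' its phase-two subjects are dropped with a warning count.
#'
#' @param c a [cohort_data()] object.
#' @param statistic `"auc"` or `"delta"`.
#' @param marker marker for `statistic = "auc"`.
#' @param B number of replicates (>= 100).
#' @param seed integer seed; results are reproducible given the seed.
#' @param ties tie convention passed to the estimators.
#' @return list with `var`, `se`, `B_used`, `dropped`, and the
#'   replicate estimates `replicates`.
#' @export
bootstrap_variance <- function(c, statistic = c("auc", "delta"),
                               marker = "x", B = 500, seed = 1,
                               ties = c("strict", "midrank")) {
  statistic <- match.arg(statistic)
  ties <- match.arg(ties)
  if (B < 100) stop("bootstrap needs B >= 100", call. = FALSE)
  df <- as.data.frame(c)
  cases <- df[df$disease == 1, , drop = FALSE]
  ctrls <- df[df$disease == 0, , drop = FALSE]
  set.seed(seed)
  vals <- rep(NA_real_, B)
  dropped <- 0L
  for (b in seq_len(B)) {
    rb <- rbind(cases[sample.int(nrow(cases), replace = TRUE), , drop = FALSE],
                ctrls[sample.int(nrow(ctrls), replace = TRUE), , drop = FALSE])
    rb$id <- seq_len(nrow(rb))
    cb <- cohort_data(rb, n_markers = attr(c, "n_markers"))
    res <- tryCatch({
      wfD <- fit_stratum_weights(cb, "case")
      wfC <- fit_stratum_weights(cb, "control")
      if (statistic == "auc") ipw_auc(cb, marker, wfD, wfC, ties)$estimate
      else delta_auc(cb, wfD, wfC, "ipw", ties)$delta
    }, error = function(e) NA_real_)
    if (is.na(res)) dropped <- dropped + 1L else vals[b] <- res
  }
  if (dropped > 0L) {
    warning(dropped, " bootstrap replicate(s) dropped (empty stratum)",
            call. = FALSE)
  }
  ok <- vals[!is.na(vals)]
  list(var = stats::var(ok), se = stats::sd(ok), B_used = length(ok),
       dropped = dropped, replicates = ok)
}

#' @export
print.variance_report <- function(x, ...) {
  cat(sprintf("Asymptotic variance report (%s%s)\n", x$method,
              if (x$weights_estimated) ", estimated weights" else ""))
  cat(sprintf("  estimate = %.4f, sigma = %.4f, se = %.5f (N = %d, lambda_hat = %.3f)\n",
              x$estimate, x$sigma, x$se, x$N, x$lambda_hat))
  cat("  components:\n")
  for (nm in names(x$components)) {
    cat(sprintf("    %-33s %10.5f\n", nm, x$components[[nm]]))
  }
  invisible(x)
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: estimate = %.4f, se = %.5f, z = %.3f, p = %.4g\n",
              x$method, x$estimate, x$se, x$statistic, x$p_value))
  cat(sprintf("  %g%% CI (%.4f, %.4f), null = %g\n",
              100 * x$level, x$ci[1], x$ci[2], x$null))
  invisible(x)
}
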