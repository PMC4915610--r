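#' Bi-normal two-marker data-generating model
#'
#' The synthetic-cohort model used throughout the simulation studies: a
#' binary disease `D` with prevalence `lambda`; a latent continuous
#' covariate `W*` that is standard normal among controls and
#' `N(mu_w_case, 1)` among cases, discretised into a covariate stratum
#' `W` at fixed cutpoints (default tertiles of the control
#' distribution); and markers `X`, `Y` jointly normal with `W*` given
#' `D`. Among controls `X` and `Y` are standard normal; among cases `X`
#' is `N(mu_Dx, sigma_Dx^2)` and `Y` is `N(mu_Dy, sigma_Dy^2)`. The
#' conditional correlations `rho_xy`, `rho_xw`, `rho_yw` are the same in
#' both arms. The implied single-marker accuracies are
#' `AUC_x = pnorm(mu_Dx / sqrt(1 + sigma_Dx^2))` and analogously for `Y`.
#'
#' @param lambda disease prevalence `P(D = 1)`.
#' @param mu_w_case case mean of the latent covariate `W*`.
#' @param cutpoints increasing stratum boundaries on `W*`; the default
#'   tertile cuts give three strata equally likely among controls.
#' @param mu_Dx,sigma_Dx case mean and SD of marker `X`.
#' @param mu_Dy,sigma_Dy case mean and SD of marker `Y`.
#' @param rho_xy,rho_xw,rho_yw conditional correlations given `D`.
#' @return a `binormal_model` object (with precomputed Cholesky factor
#'   of the conditional correlation matrix, checked positive definite).
#' @export
binormal_model <- function(lambda = 0.1, mu_w_case = 0.6,
                           cutpoints = stats::qnorm(c(1 / 3, 2 / 3)),
                           mu_Dx = 1, sigma_Dx = 1,
                           mu_Dy = 1, sigma_Dy = 1,
                           rho_xy = 0, rho_xw = 0, rho_yw = 0) {
  if (lambda <= 0 || lambda >= 1) stop("lambda must be in (0,1)", call. = FALSE)
  if (is.unsorted(cutpoints, strictly = TRUE)) {
    stop("cutpoints must be strictly increasing", call. = FALSE)
  }
  R <- matrix(c(1, rho_xy, rho_xw,
                rho_xy, 1, rho_yw,
                rho_xw, rho_yw, 1), 3, 3,
              dimnames = list(c("x", "y", "w"), c("x", "y", "w")))
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch) || any(diag(ch) < 1e-8)) {
    stop("conditional correlation matrix of (X, Y, W*) is not positive ",
         "definite", call. = FALSE)
  }
  structure(list(lambda = lambda, mu_w_case = mu_w_case,
                 cutpoints = cutpoints,
                 mu_Dx = mu_Dx, sigma_Dx = sigma_Dx,
                 mu_Dy = mu_Dy, sigma_Dy = sigma_Dy,
                 rho_xy = rho_xy, rho_xw = rho_xw, rho_yw = rho_yw,
                 chol = ch,
                 auc_x = stats::pnorm(mu_Dx / sqrt(1 + sigma_Dx^2)),
                 auc_y = stats::pnorm(mu_Dy / sqrt(1 + sigma_Dy^2))),
            class = "binormal_model")
}

#' @export
print.binormal_model <- function(x, ...) {
  cat(sprintf("Bi-normal model: lambda = %.3g, %d covariate strata\n",
              x$lambda, length(x$cutpoints) + 1L))
  cat(sprintf("  cases: X ~ N(%.3g, %.3g^2), Y ~ N(%.3g, %.3g^2), W* ~ N(%.3g, 1)\n",
              x$mu_Dx, x$sigma_Dx, x$mu_Dy, x$sigma_Dy, x$mu_w_case))
  cat(sprintf("  rho_xy = %.2f, rho_xw* = %.2f, rho_yw* = %.2f\n",
              x$rho_xy, x$rho_xw, x$rho_yw))
  cat(sprintf("  implied AUC_x = %.4f, AUC_y = %.4f\n", x$auc_x, x$auc_y))
  invisible(x)
}

#' Population stratum probabilities implied by a bi-normal model
#'
#' Exact normal-CDF computation of `P(W = w, D = d)` for every
#' covariate stratum and arm; needed by the matched Bernoulli control
#' sampling rule. Rows for `D = 1` sum to `lambda`, rows for `D = 0` to
#' `1 - lambda`.
#'
#' @param m a [binormal_model()].
#' @return data.frame with columns `stratum`, `p_case_joint`
#'   (`P(W, D=1)`), `p_control_joint`, `p_case_cond` (`P(W | D=1)`),
#'   `p_control_cond`.
#' @export
population_stratum_probs <- function(m) {
  cuts <- c(-Inf, m$cutpoints, Inf)
  k <- length(cuts) - 1L
  p_case <- diff(stats::pnorm(cuts, mean = m$mu_w_case, sd = 1))
  p_ctrl <- diff(stats::pnorm(cuts))
  data.frame(stratum = as.character(seq_len(k)),
             p_case_joint = m$lambda * p_case,
             p_control_joint = (1 - m$lambda) * p_ctrl,
             p_case_cond = p_case,
             p_control_cond = p_ctrl,
             stringsAsFactors = FALSE)
}

# Draw (x, y, w_star) for one arm from the conditional trivariate
# normal; returns a 3-column matrix.
.draw_arm <- function(n, m, case) {
  z <- matrix(stats::rnorm(3L * n), n, 3L) %*% m$chol
  if (case) {
    z[, 1] <- m$mu_Dx + m$sigma_Dx * z[, 1]
    z[, 2] <- m$mu_Dy + m$sigma_Dy * z[, 2]
    z[, 3] <- m$mu_w_case + z[, 3]
  }
  z
}

#' Generate a fully observed phase-one cohort
#'
#' Draws `N` subjects: disease by Bernoulli(`lambda`), then
#' `(X, Y, W*)` from the arm's conditional trivariate normal, with the
#' covariate stratum `W` cut from `W*`. Every subject is marked
#' `sampled = 1` (markers fully observed); apply [apply_bernoulli()] or
#' [apply_fps()] to impose a phase-two design.
#'
#' @param m a [binormal_model()].
#' @param N phase-one cohort size (>= 2).
#' @param seed optional integer seed.
#' @return a [cohort_data()] object with two markers; the `stratum`
#'   column holds the covariate stratum `W` and an extra `w_star`
#'   column keeps the latent covariate.
#' @export
generate_cohort <- function(m, N, seed = NULL) {
  if (N < 2) stop("N must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  d <- stats::rbinom(N, 1L, m$lambda)
  n_case <- sum(d)
  if (n_case == 0L || n_case == N) {
    stop("degenerate cohort draw: one arm is empty; increase N", call. = FALSE)
  }
  vals <- matrix(NA_real_, N, 3L)
  vals[d == 1L, ] <- .draw_arm(n_case, m, case = TRUE)
  vals[d == 0L, ] <- .draw_arm(N - n_case, m, case = FALSE)
  w <- as.character(findInterval(vals[, 3], m$cutpoints) + 1L)
  out <- data.frame(id = seq_len(N), disease = d, stratum = w,
                    sampled = 1L, x = vals[, 1], y = vals[, 2],
                    w_star = vals[, 3], stringsAsFactors = FALSE)
  cohort_data(out, n_markers = 2L, validate = FALSE)
}

#' Phase-two sampling design specification
#'
#' @param kind `"bernoulli"` (independent per-subject draws with design
#'   probabilities) or `"fps"` (finite-population stratified sampling:
#'   fixed counts without replacement).
#' @param p_case constant phase-two sampling rate for cases.
#' @param control_rule `"matched"` (default): for Bernoulli, a control
#'   in stratum `w` is sampled with probability
#'   `p_case * P(W = w, D = 1) / P(W = w, D = 0)` so biomarkers are
#'   measured on equal expected numbers of cases and controls per
#'   stratum; for FPS, exactly as many controls as realised cases are
#'   drawn per stratum. Alternatively a named numeric vector of
#'   per-stratum control sampling fractions.
#' @return a `design_spec` object.
#' @export
design_spec <- function(kind = c("bernoulli", "fps"), p_case = 0.2,
                        control_rule = "matched") {
  kind <- match.arg(kind)
  if (p_case <= 0 || p_case > 1) stop("p_case must be in (0,1]", call. = FALSE)
  if (is.numeric(control_rule) && is.null(names(control_rule))) {
    stop("explicit control fractions must be named by stratum", call. = FALSE)
  }
  structure(list(kind = kind, p_case = p_case, control_rule = control_rule),
            class = "design_spec")
}

# Control sampling probabilities by stratum for a Bernoulli design.
.control_probs <- function(d, m) {
  if (is.numeric(d$control_rule)) {
    return(d$control_rule)
  }
  tab <- population_stratum_probs(m)
  pr <- d$p_case * tab$p_case_joint / tab$p_control_joint
  names(pr) <- tab$stratum
  pr
}

#' Apply Bernoulli phase-two sampling to a cohort
#'
#' Cases are sampled independently with probability `p_case`; controls
#' independently with the per-stratum probability given by the design's
#' control rule (true-model probabilities for `"matched"`). Markers of
#' unsampled subjects are masked. The true per-subject probability is
#' recorded in a `p_true` column for known-weights analyses. Because
#' case sampling does not depend on the covariate stratum, the sampling
#' `stratum` label for cases is collapsed to `"all"`; controls keep
#' their covariate stratum as sampling stratum.
#'
#' @param c a fully observed cohort from [generate_cohort()].
#' @param d a [design_spec()] with `kind = "bernoulli"`.
#' @param m the [binormal_model()] that generated the cohort (used for
#'   the matched control rule).
#' @param seed optional integer seed.
#' @return a [cohort_data()] object with `sampled`, masked markers and
#'   `p_true`.
#' @export
apply_bernoulli <- function(c, d, m, seed = NULL) {
  if (d$kind != "bernoulli") stop("design kind is not 'bernoulli'", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  df <- as.data.frame(c)
  pr_ctrl <- .control_probs(d, m)
  if (any(pr_ctrl > 1)) {
    stop("implied control sampling probability exceeds 1 in stratum(s): ",
         paste(names(pr_ctrl)[pr_ctrl > 1], collapse = ", "), call. = FALSE)
  }
  is_case <- df$disease == 1
  p <- numeric(nrow(df))
  p[is_case] <- d$p_case
  idx <- match(df$stratum[!is_case], names(pr_ctrl))
  if (anyNA(idx)) {
    stop("control stratum without a sampling probability", call. = FALSE)
  }
  p[!is_case] <- pr_ctrl[idx]
  df$sampled <- stats::rbinom(nrow(df), 1L, p)
  df$p_true <- p
  df$x[df$sampled == 0L] <- NA_real_
  df$y[df$sampled == 0L] <- NA_real_
  df$stratum[is_case] <- "all"
  cohort_data(df, n_markers = attr(c, "n_markers"), validate = FALSE)
}

#' Apply finite-population stratified sampling to a cohort
#'
#' Draws `n_case = round(N * lambda_hat * p_case)` cases by simple
#' random sampling without replacement across strata (case sampling is
#' unstratified, so case sampling stratum collapses to `"all"`), then,
#' per covariate stratum, draws without replacement as many controls as
#' the realised number of sampled cases in that stratum (frequency
#' matching). A stratum with fewer available controls than required is
#' an error; the design must be changed rather than silently truncated.
#'
#' @param c a fully observed cohort from [generate_cohort()].
#' @param d a [design_spec()] with `kind = "fps"`.
#' @param seed optional integer seed.
#' @return a [cohort_data()] object with fixed phase-two counts.
#' @export
apply_fps <- function(c, d, seed = NULL) {
  if (d$kind != "fps") stop("design kind is not 'fps'", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  df <- as.data.frame(c)
  is_case <- df$disease == 1
  case_rows <- which(is_case)
  n_case <- round(length(case_rows) * d$p_case)
  if (n_case < 1L) stop("FPS design samples no cases", call. = FALSE)
  sampled_cases <- case_rows[sample.int(length(case_rows), n_case)]
  need <- table(df$stratum[sampled_cases])
  if (is.numeric(d$control_rule)) {
    ctrl_tab <- table(df$stratum[!is_case])
    need <- round(d$control_rule[names(ctrl_tab)] * as.numeric(ctrl_tab))
    names(need) <- names(ctrl_tab)
  }
  sampled_ctrls <- integer(0)
  for (w in names(need)) {
    avail <- which(!is_case & df$stratum == w)
    if (length(avail) < need[[w]]) {
      stop("stratum '", w, "' has fewer controls (", length(avail),
           ") than required (", need[[w]], ")", call. = FALSE)
    }
    sampled_ctrls <- c(sampled_ctrls, avail[sample.int(length(avail), need[[w]])])
  }
  df$sampled <- 0L
  df$sampled[c(sampled_cases, sampled_ctrls)] <- 1L
  df$x[df$sampled == 0L] <- NA_real_
  df$y[df$sampled == 0L] <- NA_real_
  df$stratum[is_case] <- "all"
  df$p_true <- NULL
  cohort_data(df, n_markers = attr(c, "n_markers"), validate = FALSE)
}

#' Generate a cohort with gamma-distributed markers
#'
#' Extension hook mirroring [generate_cohort()] with gamma marginals
#' for the markers, linked to each other and to the latent covariate by
#' a Gaussian copula with the model's conditional correlations. The
#' covariate keeps its normal marginal, so the stratified sampling
#' designs apply unchanged. Shapes/rates are free parameters; this
#' generator is a documented extension point and is not calibrated to
#' any published table.
#'
#' @param m a [binormal_model()] supplying prevalence, covariate law,
#'   stratum cutpoints and the copula correlations.
#' @param shapes named list with per-arm gamma parameters:
#'   `case = list(shape_x=, rate_x=, shape_y=, rate_y=)` and `control`
#'   alike.
#' @param N phase-one cohort size.
#' @param seed optional integer seed.
#' @return a [cohort_data()] object with two markers.
#' @export
generate_gamma_cohort <- function(m, shapes, N, seed = NULL) {
  if (N < 2) stop("N must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  d <- stats::rbinom(N, 1L, m$lambda)
  n_case <- sum(d)
  if (n_case == 0L || n_case == N) {
    stop("degenerate cohort draw: one arm is empty; increase N", call. = FALSE)
  }
  draw <- function(n, arm, case) {
    z <- matrix(stats::rnorm(3L * n), n, 3L) %*% m$chol
    data.frame(
      x = stats::qgamma(stats::pnorm(z[, 1]), shape = arm$shape_x,
                        rate = arm$rate_x),
      y = stats::qgamma(stats::pnorm(z[, 2]), shape = arm$shape_y,
                        rate = arm$rate_y),
      w_star = if (case) m$mu_w_case + z[, 3] else z[, 3])
  }
  vals <- as.data.frame(matrix(NA_real_, N, 3L))
  names(vals) <- c("x", "y", "w_star")
  vals[d == 1L, ] <- draw(n_case, shapes$case, TRUE)
  vals[d == 0L, ] <- draw(N - n_case, shapes$control, FALSE)
  w <- as.character(findInterval(vals$w_star, m$cutpoints) + 1L)
  cohort_data(data.frame(id = seq_len(N), disease = d, stratum = w,
                         sampled = 1L, x = vals$x, y = vals$y,
                         w_star = vals$w_star, stringsAsFactors = FALSE),
              n_markers = 2L)
}
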