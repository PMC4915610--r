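# Weighted comparison kernel shared by the AUC estimators and the
# placement values. For each value in `v`, returns the total reference
# weight strictly below it and the weight tied with it, via one sort
# and cumulative sums (O(n log n) instead of the O(n^2) double sum).
.wt_below <- function(v, ref, w_ref) {
  o <- order(ref)
  rs <- ref[o]
  cw <- c(0, cumsum(w_ref[o]))
  i_lt <- findInterval(v, rs, left.open = TRUE)  # count of ref <  v
  i_le <- findInterval(v, rs)                    # count of ref <= v
  list(below = cw[i_lt + 1L], tied = cw[i_le + 1L] - cw[i_lt + 1L])
}

# Weighted Mann-Whitney kernel: sum_i sum_j u_i w_j [I(a_i > b_j) (+ ties/2)]
# normalised by (sum u)(sum w).
.wauc_kernel <- function(a, u, b, w, ties) {
  k <- .wt_below(a, b, w)
  num <- k$below
  if (ties == "midrank") num <- num + 0.5 * k$tied
  sum(u * num) / (sum(u) * sum(w))
}

.new_auc_result <- function(marker, estimate, method, weights_used,
                            n_case, n_control, ties) {
  structure(list(marker = marker, estimate = estimate, method = method,
                 weights_used = weights_used, n_case = n_case,
                 n_control = n_control, ties = ties),
            class = "auc_result")
}

#' Empirical AUC on the phase-two sample
#'
#' The standard Mann-Whitney estimate of `P(X_case > X_control)`
#' computed over all sampled case-control pairs, ignoring the sampling
#' design. Under biased phase-two sampling this estimator is generally
#' inconsistent for the population AUC; it is provided as the naive
#' comparator for [ipw_auc()].
#'
#' @param c a [cohort_data()] object.
#' @param marker `"x"` or `"y"`.
#' @param ties `"strict"` (ties count 0, matching the strict indicator
#'   for continuous markers) or `"midrank"` (ties count 1/2).
#' @return an `auc_result`.
#' @export
empirical_auc <- function(c, marker = c("x", "y"), ties = c("strict", "midrank")) {
  marker <- match.arg(marker)
  ties <- match.arg(ties)
  case <- .arm_view(c, "case"); ctrl <- .arm_view(c, "control")
  a <- case[[marker]][case$sampled]
  b <- ctrl[[marker]][ctrl$sampled]
  if (length(a) == 0L || length(b) == 0L) {
    stop("empirical AUC needs at least one sampled case and control",
         call. = FALSE)
  }
  est <- .wauc_kernel(a, rep(1, length(a)), b, rep(1, length(b)), ties)
  .new_auc_result(marker, est, "empirical", NULL, length(a), length(b), ties)
}

#' Inverse-probability-weighted AUC
#'
#' The IPW estimate of the population AUC under two-phase sampling:
#' every sampled case-control pair is weighted by the product of the
#' subjects' inverse (estimated) phase-two sampling probabilities, and
#' the weighted count of concordant pairs is divided by the weighted
#' count of all pairs. With per-stratum empirical weights this is
#' algebraically the stratified double-sum representation used for
#' finite-population stratified sampling. Being a ratio estimator, it
#' is invariant to rescaling all weights within an arm.
#'
#' @inheritParams empirical_auc
#' @param wf_case,wf_control `weight_fit` objects for the two arms (see
#'   [fit_stratum_weights()], [fit_logistic_weights()], [known_weights()]).
#' @return an `auc_result`.
#' @export
ipw_auc <- function(c, marker = c("x", "y"), wf_case, wf_control,
                    ties = c("strict", "midrank")) {
  marker <- match.arg(marker)
  ties <- match.arg(ties)
  case <- .arm_view(c, "case"); ctrl <- .arm_view(c, "control")
  .check_fit_arm(wf_case, case, "case")
  .check_fit_arm(wf_control, ctrl, "control")
  a <- case[[marker]][case$sampled]
  b <- ctrl[[marker]][ctrl$sampled]
  if (length(a) == 0L || length(b) == 0L) {
    stop("IPW AUC needs at least one sampled case and control", call. = FALSE)
  }
  u <- 1 / wf_case$p_hat[case$sampled]
  w <- 1 / wf_control$p_hat[ctrl$sampled]
  est <- .wauc_kernel(a, u, b, w, ties)
  .new_auc_result(marker, est, "ipw", list(case = wf_case, control = wf_control),
                  length(a), length(b), ties)
}

#' Difference in AUC between two markers
#'
#' Estimates `Delta AUC = AUC_y - AUC_x` for two markers measured on
#' the same phase-two subjects, with a shared weighting scheme.
#'
#' @inheritParams ipw_auc
#' @param method `"ipw"` or `"empirical"`; `wf_case`/`wf_control` are
#'   only used for `"ipw"`.
#' @return a `delta_auc_result` with elements `estimate_x`,
#'   `estimate_y` and `delta = AUC_y - AUC_x`.
#' @export
delta_auc <- function(c, wf_case = NULL, wf_control = NULL,
                      method = c("ipw", "empirical"),
                      ties = c("strict", "midrank")) {
  method <- match.arg(method)
  ties <- match.arg(ties)
  if (attr(c, "n_markers") < 2L) {
    stop("delta_auc needs a cohort with two markers", call. = FALSE)
  }
  est <- function(m) {
    if (method == "ipw") ipw_auc(c, m, wf_case, wf_control, ties)
    else empirical_auc(c, m, ties)
  }
  ax <- est("x"); ay <- est("y")
  structure(list(estimate_x = ax, estimate_y = ay,
                 delta = ay$estimate - ax$estimate, method = method),
            class = "delta_auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC(%s) = %.4f  [%s, %d cases x %d controls, ties = %s]\n",
              x$marker, x$estimate, x$method, x$n_case, x$n_control, x$ties))
  invisible(x)
}

#' @export
print.delta_auc_result <- function(x, ...) {
  cat(sprintf("Delta AUC (y - x) = %.4f  [%s; AUC_x = %.4f, AUC_y = %.4f]\n",
              x$delta, x$method, x$estimate_x$estimate, x$estimate_y$estimate))
  invisible(x)
}
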