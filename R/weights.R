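#' Phase-two sampling-weight models
#'
#' A `weight_fit` describes the fitted phase-two sampling-probability
#' model for one arm (cases or controls): per-subject fitted
#' probabilities over all phase-one subjects of the arm, the score
#' vectors d p / d theta, and the information matrix needed by the
#' asymptotic variance formulas. Cases and controls are always modelled
#' separately, never pooled.
#'
#' @name weight_fit
#' @keywords internal
NULL

.new_weight_fit <- function(arm, kind, theta, p_hat, score, information,
                            estimated, sampled, ids) {
  if (any(p_hat <= 0 | is.na(p_hat))) {
    stop("subjects with zero sampling probability cannot be weighted (",
         arm, " arm)", call. = FALSE)
  }
  structure(list(arm = arm, kind = kind, theta = theta, p_hat = p_hat,
                 score = score, information = information,
                 estimated = estimated, sampled = sampled, ids = ids),
            class = "weight_fit")
}

#' Fit per-stratum empirical sampling fractions for one arm
#'
#' Estimates each stratum's phase-two sampling probability as
#' `n_k / N_k`, the proportion of the arm's phase-one subjects in
#' stratum `k` that were sampled. The information matrix is diagonal
#' with entry `P(k) / (pi_k (1 - pi_k))` for each stratum whose
#' fraction lies strictly inside (0, 1); strata with fraction exactly 1
#' are excluded from the estimated set and contribute no
#' weight-estimation correction (nothing about their weight is
#' estimated).
#'
#' @param c a [cohort_data()] object.
#' @param arm `"case"` or `"control"`.
#' @return a `weight_fit`.
#' @export
fit_stratum_weights <- function(c, arm = c("case", "control")) {
  arm <- match.arg(arm)
  tab <- stratum_table(c, arm)
  if (any(tab$n_k == 0L)) {
    stop("subjects with zero sampling probability cannot be weighted: ",
         arm, " stratum(s) with no phase-two subjects: ",
         paste(tab$stratum[tab$n_k == 0L], collapse = ", "), call. = FALSE)
  }
  av <- .arm_view(c, arm)
  pi_k <- tab$n_k / tab$N_k
  names(pi_k) <- tab$stratum
  idx <- match(av$stratum, tab$stratum)
  p_hat <- pi_k[idx]

  est <- which(pi_k < 1)
  p_share <- tab$N_k / sum(tab$N_k)            # phase-one stratum shares P(k)
  info <- diag(x = p_share[est] / (pi_k[est] * (1 - pi_k[est])),
               nrow = length(est))
  dimnames(info) <- list(tab$stratum[est], tab$stratum[est])

  # score d p_i / d theta_k = 1{subject i in stratum k}, estimated strata only
  score <- matrix(0, nrow = length(idx), ncol = length(est),
                  dimnames = list(NULL, tab$stratum[est]))
  for (j in seq_along(est)) score[idx == est[j], j] <- 1

  .new_weight_fit(arm, "stratum", theta = pi_k, p_hat = unname(p_hat),
                  score = score, information = info,
                  estimated = tab$stratum[est],
                  sampled = av$sampled, ids = av$id)
}

#' Fit a logistic sampling-probability model for one arm
#'
#' Maximum-likelihood logistic regression of the phase-two sampling
#' indicator on phase-one covariates, within one arm. The per-subject
#' score is `p (1 - p) x` and the information matrix is the average of
#' `(1/p + 1/(1-p)) (dp/dtheta)(dp/dtheta)^T` over the arm's phase-one
#' subjects, which coincides with the usual logistic information
#' `E{p (1 - p) x x^T}`.
#'
#' @param c a [cohort_data()] object whose data contain `covariates`.
#' @param arm `"case"` or `"control"`.
#' @param covariates character vector of column names available for all
#'   phase-one subjects of the arm; an intercept is always included.
#' @param p_floor fitted probabilities at or below this floor are a
#'   hard error: inverse weights would be unstable and the design
#'   should be re-stratified rather than silently truncated.
#' @return a `weight_fit`.
#' @export
fit_logistic_weights <- function(c, arm = c("case", "control"),
                                 covariates, p_floor = 1e-8) {
  arm <- match.arg(arm)
  df <- as.data.frame(c)
  df <- df[df$disease == (arm == "case"), , drop = FALSE]
  miss <- setdiff(covariates, names(df))
  if (length(miss) > 0L) {
    stop("covariate column(s) not in cohort: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(df[covariates])) {
    stop("logistic weights need covariate values for all phase-one ",
         arm, "s", call. = FALSE)
  }
  fml <- stats::as.formula(paste("sampled ~",
                                 paste(covariates, collapse = " + ")))
  fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(), data = df))
  if (!fit$converged) {
    stop("logistic weight model did not converge for the ", arm, " arm",
         call. = FALSE)
  }
  p_hat <- unname(stats::fitted(fit))
  if (any(p_hat <= p_floor)) {
    stop("fitted sampling probability at or below ", p_floor, " in the ",
         arm, " arm; redesign the sampling strata", call. = FALSE)
  }
  X <- stats::model.matrix(fit)
  score <- X * (p_hat * (1 - p_hat))
  info <- crossprod(X * sqrt(p_hat * (1 - p_hat))) / nrow(X)
  .new_weight_fit(arm, "logistic", theta = stats::coef(fit), p_hat = p_hat,
                  score = score, information = info,
                  estimated = colnames(X),
                  sampled = df$sampled == 1, ids = df$id)
}

#' Use known (design) sampling probabilities for one arm
#'
#' For Bernoulli designs the true per-subject sampling probability is
#' known; this constructor wraps it as a `weight_fit` with nothing
#' estimated, so downstream variances use the known-weights form
#' (second-moment inflation terms retained, weight-estimation
#' corrections dropped).
#'
#' @param c a [cohort_data()] object.
#' @param arm `"case"` or `"control"`.
#' @param p either a numeric vector over the arm's phase-one subjects
#'   (cohort row order) or the name of a cohort column (default
#'   `"p_true"`).
#' @return a `weight_fit` with `kind = "known"`.
#' @export
known_weights <- function(c, arm = c("case", "control"), p = "p_true") {
  arm <- match.arg(arm)
  av <- .arm_view(c, arm)
  if (is.character(p)) {
    df <- as.data.frame(c)
    if (is.null(df[[p]])) {
      stop("cohort has no column '", p, "' with known probabilities",
           call. = FALSE)
    }
    pv <- df[[p]][df$disease == (arm == "case")]
  } else {
    pv <- as.numeric(p)
    if (length(pv) != length(av$id)) {
      stop("known p must have one value per phase-one ", arm, call. = FALSE)
    }
  }
  if (anyNA(pv)) stop("known probabilities contain NA (", arm, ")", call. = FALSE)
  .new_weight_fit(arm, "known", theta = numeric(0), p_hat = pv,
                  score = matrix(0, length(pv), 0),
                  information = matrix(0, 0, 0), estimated = character(0),
                  sampled = av$sampled, ids = av$id)
}

#' @export
print.weight_fit <- function(x, ...) {
  cat(sprintf("Sampling-weight fit (%s arm, kind = %s)\n", x$arm, x$kind))
  if (x$kind == "stratum") {
    cat("  stratum fractions:",
        paste(sprintf("%s = %.4g", names(x$theta), x$theta), collapse = ", "),
        "\n")
  } else if (x$kind == "logistic") {
    cat("  coefficients:",
        paste(sprintf("%s = %.4g", names(x$theta), x$theta), collapse = ", "),
        "\n")
  } else {
    cat("  known design probabilities, range",
        sprintf("[%.4g, %.4g]\n", min(x$p_hat), max(x$p_hat)))
  }
  cat(sprintf("  %d phase-one subjects, %d sampled; %d estimated parameter(s)\n",
              length(x$p_hat), sum(x$sampled), length(x$estimated)))
  invisible(x)
}

# Align a weight fit with an arm view; errors if any sampled subject
# lacks a usable weight.
.check_fit_arm <- function(wf, av, arm) {
  if (length(wf$p_hat) != length(av$id) || !identical(wf$ids, av$id)) {
    stop("weight fit does not cover the cohort's phase-one ", arm, "s",
         call. = FALSE)
  }
  invisible(TRUE)
}
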