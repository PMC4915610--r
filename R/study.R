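#' Define one Monte-Carlo simulation cell
#'
#' A cell is one setting of the operating-characteristic study: a
#' data-generating model, a phase-two design, a target parameter, a
#' phase-one size and a replicate count. [run_cell()] repeatedly
#' generates a cohort, applies the design, fits per-stratum empirical
#' sampling weights, and computes both the IPW and the naive empirical
#' estimator with their analytic variances (plus the DeLong comparator
#' for the two-marker target).
#'
#' @param model a [binormal_model()].
#' @param design a [design_spec()].
#' @param target `"auc_x"` (single-marker AUC) or `"delta"`
#'   (`AUC_y - AUC_x`).
#' @param N phase-one cohort size per replicate.
#' @param reps number of Monte-Carlo replicates (>= 100).
#' @param seed integer seed; per-replicate seeds are pre-drawn from it
#'   so serial and chunked runs agree.
#' @param level confidence/test level.
#' @param label optional cell label for table output.
#' @return a `simulation_cell` object.
#' @export
simulation_cell <- function(model, design, target = c("auc_x", "delta"),
                            N = 5000, reps = 2000, seed = 1,
                            level = 0.95, label = NULL) {
  target <- match.arg(target)
  if (reps < 100) stop("a simulation cell needs reps >= 100", call. = FALSE)
  structure(list(model = model, design = design, target = target,
                 N = N, reps = as.integer(reps), seed = as.integer(seed),
                 level = level,
                 label = label %||% sprintf("%s_%s_pc%g", target, design$kind,
                                            design$p_case)),
            class = "simulation_cell")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One replicate of a cell; returns a named numeric vector of per-rep
# statistics, or NULL on estimation failure.
.run_rep <- function(cell, rep_seed) {
  set.seed(rep_seed)
  coh <- generate_cohort(cell$model, cell$N)
  samp <- if (cell$design$kind == "bernoulli") {
    apply_bernoulli(coh, cell$design, cell$model)
  } else {
    apply_fps(coh, cell$design)
  }
  wfD <- fit_stratum_weights(samp, "case")
  wfC <- fit_stratum_weights(samp, "control")
  if (cell$target == "auc_x") {
    vi <- auc_variance(samp, "x", wfD, wfC)
    ve <- empirical_auc_variance(samp, "x")
    c(est_ipw = vi$estimate, se_ipw = vi$se,
      est_emp = ve$estimate, se_emp = ve$se)
  } else {
    vi <- delta_auc_variance(samp, wfD, wfC)
    ve <- empirical_delta_variance(samp)
    dl <- delong_test(samp, level = cell$level)
    c(est_ipw = vi$estimate, se_ipw = vi$se,
      est_emp = ve$estimate, se_emp = ve$se,
      z_delong = dl$statistic)
  }
}

#' Run one simulation cell
#'
#' @param cell a [simulation_cell()].
#' @param verbose print a progress line every 500 replicates.
#' @return a `cell_summary`: a data.frame of operating characteristics
#'   (bias x 100, Var x N, coverage %, rejection %) with Monte-Carlo
#'   standard errors, one row per estimator/test, plus the analytic
#'   truth, failure count and the per-replicate statistics.
#' @details The truth is the model's closed-form AUC (or AUC
#'   difference), not a mega-simulation. Replicates whose estimation
#'   fails (e.g. an empty sampling stratum) are recorded; a cell with
#'   more than 1% failures is marked invalid.
#' @export
run_cell <- function(cell, verbose = FALSE) {
  set.seed(cell$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, cell$reps)
  truth <- if (cell$target == "auc_x") cell$model$auc_x else
    cell$model$auc_y - cell$model$auc_x
  null_value <- if (cell$target == "auc_x") 0.5 else 0
  zq <- stats::qnorm(1 - (1 - cell$level) / 2)

  rows <- vector("list", cell$reps)
  failures <- 0L
  for (i in seq_len(cell$reps)) {
    r <- tryCatch(.run_rep(cell, rep_seeds[i]), error = function(e) NULL)
    if (is.null(r)) failures <- failures + 1L else rows[[i]] <- r
    if (verbose && i %% 500L == 0L) {
      message(sprintf("[%s] %d/%d replicates", cell$label, i, cell$reps))
    }
  }
  stat <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  R <- nrow(stat)

  summarise <- function(est, se) {
    bias <- mean(est) - truth
    vv <- stats::var(est)
    cover <- abs(est - truth) <= zq * se
    reject <- abs(est - null_value) / se > zq
    c(bias100 = 100 * bias,
      bias100_se = 100 * stats::sd(est) / sqrt(R),
      varN = cell$N * vv,
      varN_se = cell$N * vv * sqrt(2 / (R - 1)),
      coverage = 100 * mean(cover),
      coverage_se = 100 * sqrt(mean(cover) * (1 - mean(cover)) / R),
      power = 100 * mean(reject),
      power_se = 100 * sqrt(mean(reject) * (1 - mean(reject)) / R))
  }
  met <- rbind(ipw = summarise(stat[, "est_ipw"], stat[, "se_ipw"]),
               empirical = summarise(stat[, "est_emp"], stat[, "se_emp"]))
  metrics <- data.frame(estimator = rownames(met), met, row.names = NULL)
  if (cell$target == "delta") {
    rej <- abs(stat[, "z_delong"]) > zq
    metrics <- rbind(metrics,
                     data.frame(estimator = "delong",
                                bias100 = NA, bias100_se = NA,
                                varN = NA, varN_se = NA,
                                coverage = NA, coverage_se = NA,
                                power = 100 * mean(rej),
                                power_se = 100 * sqrt(mean(rej) * (1 - mean(rej)) / R)))
  }
  structure(list(label = cell$label, cell = cell, truth = truth,
                 metrics = metrics, reps_used = R, failures = failures,
                 valid = failures <= 0.01 * cell$reps,
                 stats = stat),
            class = "cell_summary")
}

#' @export
print.cell_summary <- function(x, ...) {
  cat(sprintf("Simulation cell '%s': %d replicates (%d failed)%s\n",
              x$label, x$reps_used, x$failures,
              if (!x$valid) "  ** INVALID (>1% failures)" else ""))
  cat(sprintf("  truth = %.4f (analytic)\n", x$truth))
  print(format(x$metrics, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Run a list of simulation cells and write a long-format table
#'
#' @param cells list of [simulation_cell()] objects.
#' @param out optional CSV path for the long-format results.
#' @param cache_dir optional directory; each cell's summary is cached
#'   under its label and reused when the stored configuration matches
#'   (a cached file whose configuration differs is an error).
#' @param verbose passed to [run_cell()].
#' @return data.frame of metrics, one row per cell x estimator,
#'   invisibly the list of summaries as attribute `"summaries"`.
#' @export
run_table <- function(cells, out = NULL, cache_dir = NULL, verbose = FALSE) {
  summaries <- lapply(cells, function(cl) {
    key <- paste(deparse(cl[setdiff(names(cl), "label")]), collapse = "")
    if (!is.null(cache_dir)) {
      dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
      f <- file.path(cache_dir, paste0(cl$label, ".rds"))
      if (file.exists(f)) {
        hit <- readRDS(f)
        if (!identical(hit$key, key)) {
          stop("cache entry '", cl$label, "' was produced by a different ",
               "configuration", call. = FALSE)
        }
        return(hit$summary)
      }
    }
    s <- run_cell(cl, verbose = verbose)
    if (!is.null(cache_dir)) {
      saveRDS(list(key = key, summary = s),
              file.path(cache_dir, paste0(cl$label, ".rds")))
    }
    s
  })
  tab <- do.call(rbind, lapply(summaries, function(s) {
    cbind(data.frame(label = s$label, design = s$cell$design$kind,
                     target = s$cell$target, N = s$cell$N,
                     p_case = s$cell$design$p_case, reps = s$reps_used,
                     truth = s$truth, stringsAsFactors = FALSE),
          s$metrics)
  }))
  if (!is.null(out)) utils::write.csv(tab, out, row.names = FALSE)
  attr(tab, "summaries") <- summaries
  invisible(tab)
}
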